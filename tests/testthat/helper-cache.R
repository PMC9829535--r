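# Session-level cache so expensive trained agents are built once and
# shared across test files.

.qc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .qc_cache)) {
    assign(key, force(expr), envir = .qc_cache)
  }
  get(key, envir = .qc_cache)
}

# tiny configs for unit tests (not the reduced experiment profile)
tiny_config <- function(task = "task1", seed = 1L, epochs = 8L,
                        alpha = 0.02) {
  sac_config(alpha = alpha, epochs = epochs, hidden = c(32L, 32L),
             batch_size = 128L, warmup_steps = 300L, replay_size = 20000,
             lr = 1e-3, seed = seed)
}

tiny_task1_agent <- function(seed = 1L) {
  cached(paste0("t1_", seed), {
    sac_train(make_env(env_config("task1"), seed), tiny_config("task1", seed))
  })
}

tiny_task2_agent <- function(seed = 1L) {
  cached(paste0("t2_", seed), {
    sac_train(make_env(env_config("task2"), seed),
              tiny_config("task2", seed, epochs = 4L))
  })
}

# a two-point trajectory segment (one movement vector)
seg <- function(x0, y0, x1, y1) data.frame(x = c(x0, x1), y = c(y0, y1))

# a constant-output critic net: zero weights, chosen output bias
const_net <- function(hidden, value, n_in = 7L) {
  net <- qcompose:::mlp_init(c(n_in, hidden, 1L))
  net$W <- lapply(net$W, function(w) w * 0)
  net$b <- lapply(net$b, function(b) b * 0)
  net$b[[length(net$b)]] <- value
  net
}
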
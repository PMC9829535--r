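# Shared reduced-scale agent-experiment chain for the acceptance tests:
# every expensive stage is trained once per seed and cached.

# composition contrasts run on two seeds; the costlier single-variant
# experiments (alpha = 0 transfer, ablation, visitation, unit fractions)
# on the first seed
accept_seeds <- function() 1:2
accept_seed_one <- function() 1L

accept_profile <- function() train_profile("reduced")

chain_task1 <- function(seed, alpha = NULL) {
  key <- paste0("c_t1_", seed, "_", if (is.null(alpha)) "d" else alpha)
  cached(key, pretrain_subtask("task1", seed, accept_profile(), alpha = alpha))
}

chain_task2 <- function(seed) {
  cached(paste0("c_t2_", seed),
         pretrain_subtask("task2", seed, accept_profile()))
}

chain_finetune <- function(seed, kind) {
  cached(paste0("c_ft_", kind, "_", seed), {
    pr <- accept_profile()
    init <- switch(kind,
      scratch = NULL,
      average = compose_q(chain_task1(seed), chain_task2(seed), "average",
                          seed = seed + 100L),
      max = compose_q(chain_task1(seed), chain_task2(seed), "max",
                      seed = seed + 100L),
      average_alpha0 = compose_q(chain_task1(seed, alpha = 0),
                                 chain_task2(seed), "average",
                                 seed = seed + 100L),
      ablation_full = ablate(compose_q(chain_task1(seed), chain_task2(seed),
                                       "average", seed = seed + 100L),
                             chain_q_units(seed), mode = "full",
                             seed = seed + 300L),
      ablation_control = ablate(compose_q(chain_task1(seed), chain_task2(seed),
                                          "average", seed = seed + 100L),
                                chain_q_units(seed), mode = "control",
                                seed = seed + 300L))
    finetune_composite(init, seed + 20L, pr)
  })
}

chain_cls1 <- function(seed) {
  cached(paste0("c_cls1_", seed),
         classify_agent_units(chain_task1(seed), n_samples = 20000L,
                              shuffles = 400L, seed = seed + 200L))
}

chain_cls2 <- function(seed) {
  cached(paste0("c_cls2_", seed),
         classify_agent_units(chain_task2(seed), n_samples = 20000L,
                              shuffles = 400L, seed = seed + 201L))
}

# Q-representing hidden units of the composed network: movement-Q units
# live in the Task 1 subnetwork, lick-Q units in the Task 2 subnetwork
chain_q_units <- function(seed) {
  u1 <- chain_cls1(seed)$units
  u1 <- u1[u1$q_move, c("subnet", "layer", "index")]
  u2 <- chain_cls2(seed)$units
  u2 <- u2[u2$q_lick, c("subnet", "layer", "index")]
  if (nrow(u2)) u2$subnet <- 2L
  rbind(u1, u2)
}

seed_mean <- function(kind, seeds = accept_seeds(),
                      window = accept_profile()$early_epochs) {
  mean(sapply(seeds, function(s) {
    early_return(chain_finetune(s, kind), window)
  }))
}
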
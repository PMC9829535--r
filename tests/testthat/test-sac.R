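test_that("training configuration echoes the study hyperparameters", {
  cfg <- sac_config()
  expect_equal(cfg$replay_size, 1000000L)
  expect_equal(cfg$polyak, 0.995)
  expect_equal(cfg$lr, 1e-4)
  expect_equal(cfg$gamma, 0.95)
  expect_equal(cfg$steps_per_epoch, 300L)
  expect_equal(cfg$epochs, 200L)
  expect_equal(cfg$hidden, c(256L, 256L, 256L))
  expect_error(sac_config(alpha = -0.1), "alpha")
  expect_error(sac_config(polyak = 1.2))
})

test_that("network gradients match finite differences", {
  set.seed(51)
  net <- qcompose:::mlp_init(c(4, 6, 5, 2))
  X <- matrix(stats::rnorm(12), 3, 4)
  Tgt <- matrix(stats::rnorm(6), 3, 2)
  loss_of <- function(net) {
    out <- qcompose:::mlp_forward(net, X)
    sum((out - Tgt)^2)
  }
  fw <- qcompose:::mlp_forward(net, X, cache = TRUE)
  bk <- qcompose:::mlp_backward(net, fw, 2 * (fw$out - Tgt), need_dX = TRUE)
  eps <- 1e-6
  for (l in seq_along(net$W)) {
    for (idx in sample(length(net$W[[l]]), 4)) {
      np <- net; np$W[[l]][idx] <- np$W[[l]][idx] + eps
      nm <- net; nm$W[[l]][idx] <- nm$W[[l]][idx] - eps
      num <- (loss_of(np) - loss_of(nm)) / (2 * eps)
      expect_equal(bk$gW[[l]][idx], num, tolerance = 1e-5)
    }
  }
  # gradient with respect to the inputs
  for (idx in 1:4) {
    Xp <- X; Xp[1, idx] <- Xp[1, idx] + eps
    Xm <- X; Xm[1, idx] <- Xm[1, idx] - eps
    num <- (sum((qcompose:::mlp_forward(net, Xp) - Tgt)^2) -
              sum((qcompose:::mlp_forward(net, Xm) - Tgt)^2)) / (2 * eps)
    expect_equal(bk$dX[1, idx], num, tolerance = 1e-5)
  }
})

test_that("ablation masks zero activations in forward and backward passes", {
  set.seed(53)
  net <- qcompose:::mlp_init(c(4, 6, 6, 1))
  net$mask <- list(rep(1, 6), c(0, 0, 0, 0, 0, 0))
  X <- matrix(stats::rnorm(40), 10, 4)
  out <- qcompose:::mlp_forward(net, X)
  # all last-hidden-layer units zeroed: output is the bias alone
  expect_equal(as.numeric(out), rep(net$b[[3]], 10))
})

test_that("polyak target updates are exact", {
  p_t <- list(matrix(1, 2, 2), rep(2, 2))
  p_o <- list(matrix(3, 2, 2), rep(4, 2))
  out <- qcompose:::polyak_update(p_t, p_o, 0.995)
  expect_equal(out[[1]], matrix(0.995 * 1 + 0.005 * 3, 2, 2))
  expect_equal(out[[2]], rep(0.995 * 2 + 0.005 * 4, 2))
})

test_that("composite critics implement the combining operators exactly", {
  n1 <- const_net(c(8, 8), 0.2)
  n2 <- const_net(c(8, 8), 0.6)
  X <- matrix(stats::rnorm(35), 5, 7)
  avg <- qcompose:::critic_composite(n1, n2, "average")
  mx <- qcompose:::critic_composite(n1, n2, "max")
  expect_equal(as.numeric(qcompose:::critic_forward(avg, X)), rep(0.4, 5))
  expect_equal(as.numeric(qcompose:::critic_forward(mx, X)), rep(0.6, 5))
  # identical subnetworks: the average equals either one
  same <- qcompose:::critic_composite(n1, n1, "average")
  expect_equal(as.numeric(qcompose:::critic_forward(same, X)), rep(0.2, 5))
  expect_error(qcompose:::critic_composite(n1, const_net(c(4, 4), 1), "average"),
               "mismatch")
})

test_that("average composition equals the critic mean at initialization", {
  a1 <- tiny_task1_agent()
  a2 <- tiny_task2_agent()
  comp <- compose_q(a1, a2, "average", seed = 9)
  X <- qcompose:::uniform_sa_samples(10000, seed = 31)
  q_comp <- qcompose:::critic_forward(comp$critics[[1]], X)
  q1 <- qcompose:::critic_forward(a1$critics[[1]], X)
  q2 <- qcompose:::critic_forward(a2$critics[[1]], X)
  expect_equal(as.numeric(q_comp), as.numeric((q1 + q2) / 2), tolerance = 1e-12)
  mxc <- compose_q(a1, a2, "max", seed = 9)
  expect_equal(as.numeric(qcompose:::critic_forward(mxc$critics[[1]], X)),
               as.numeric(pmax(q1, q2)), tolerance = 1e-12)
})

test_that("a short training run improves the discounted return", {
  a2 <- tiny_task2_agent()
  expect_gt(mean(utils::tail(a2$epoch_disc_returns, 2)),
            a2$epoch_disc_returns[1])
  a1 <- tiny_task1_agent()
  expect_gt(mean(utils::tail(a1$epoch_disc_returns, 3)),
            a1$epoch_disc_returns[1])
})

test_that("a trained subtask agent solves its task at evaluation", {
  a1 <- tiny_task1_agent()
  env <- make_env(env_config("task1"), seed = 77)
  ev <- evaluate_agent(a1, env, n_episodes = 100, seed = 5)
  expect_gt(mean(attr(ev, "hit")), 0.9)
  expect_true(all(sapply(ev, nrow) <= a1$config$max_episode_len))
  # deterministic evaluation is reproducible
  ev2 <- evaluate_agent(a1, make_env(env_config("task1"), seed = 77),
                        n_episodes = 5, deterministic = TRUE, seed = 5)
  ev3 <- evaluate_agent(a1, make_env(env_config("task1"), seed = 77),
                        n_episodes = 5, deterministic = TRUE, seed = 5)
  expect_identical(ev2[[1]], ev3[[1]])
})

test_that("unit probing is deterministic and excludes dead units downstream", {
  a1 <- tiny_task1_agent()
  p1 <- probe_units(a1, n_samples = 10000, space_bins = 10, seed = 4)
  p2 <- probe_units(a1, n_samples = 10000, space_bins = 10, seed = 4)
  expect_identical(p1$space_map, p2$space_map)
  expect_identical(p1$dir_tuning, p2$dir_tuning)
  expect_equal(nrow(p1$units), sum(a1$config$hidden))
  expect_error(probe_units(a1, n_samples = 100), "10000")
})

test_that("ablation selects the requested units and persists in the agent", {
  a1 <- tiny_task1_agent()
  ids <- data.frame(subnet = 1L, layer = c(1L, 1L, 2L), index = c(1L, 5L, 3L))
  ab <- ablate(a1, ids, mode = "full")
  X <- qcompose:::uniform_sa_samples(500, seed = 1)
  fw <- qcompose:::mlp_forward(qcompose:::critic_nets(ab$critics[[1]])[[1]],
                               X, cache = TRUE)
  expect_true(all(fw$hs[[1]][, c(1, 5)] == 0))
  expect_true(all(fw$hs[[2]][, 3] == 0))
  ctrl <- ablate(a1, ids, mode = "control", seed = 2)
  expect_equal(nrow(ctrl$ablation$units), 3)
  expect_false(any(paste(ctrl$ablation$units$layer, ctrl$ablation$units$index)
                   %in% paste(ids$layer, ids$index)))
  half <- ablate(a1, ids, mode = "half", seed = 2)
  expect_equal(nrow(half$ablation$units), 2)
  expect_error(ablate(a1, data.frame(subnet = 1, layer = 9, index = 1)),
               "range")
})

test_that("control initialization checks mean-Q comparability", {
  a1 <- tiny_task1_agent()
  a2 <- tiny_task2_agent()
  ref <- compose_q(a1, a2, "average", seed = 3)
  a2c <- cached("t2c", {
    sac_train(make_env(env_config("task2", control_init_task2 = TRUE), 1),
              tiny_config("task2", 1L, epochs = 4L))
  })
  ci <- suppressWarnings(control_init(a1, a2c, reference = ref,
                                      n_check = 20000, seed = 5))
  chk <- attr(ci, "mean_q_check")
  expect_true(is.finite(chk["rel_diff"]))
  expect_equal(ci$composition$method, "control_init")
})

test_that("checkpoints survive a JSON round trip", {
  a1 <- tiny_task1_agent()
  f <- tempfile(fileext = ".json")
  save_agent(a1, f)
  back <- load_agent(f)
  S <- matrix(stats::rnorm(20), 5, 4)
  expect_equal(predict(a1, S), predict(back, S), tolerance = 1e-12)
  X <- qcompose:::uniform_sa_samples(100, seed = 2)
  expect_equal(qcompose:::critic_forward(a1$critics[[2]], X),
               qcompose:::critic_forward(back$critics[[2]], X),
               tolerance = 1e-12)
  unlink(f)
})

test_that("fitted objects print a readable summary", {
  a1 <- tiny_task1_agent()
  expect_output(print(a1), "Soft actor-critic")
  expect_output(print(a1), "alpha = 0.02")
  b <- arena_binning(5, c(0, 5), c(0, 5))
  tr <- data.frame(x = c(0.5, 1.5, 2.5), y = rep(0.5, 3), reward = c(0, 0, 1))
  vm <- estimate_state_values(tr, b, 0.95)
  expect_output(print(vm), "hit")
})
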
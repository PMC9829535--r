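test_that("trajectory generation is seed-deterministic and validated", {
  sp <- policy_spec("expert")
  t1 <- generate_trajectories(sp, "task1", 3, seed = 5)
  t2 <- generate_trajectories(sp, "task1", 3, seed = 5)
  expect_identical(t1, t2)
  expect_error(policy_spec("expert", speed = 0), "speed")
})

test_that("expert trials are shorter than naive trials", {
  ne <- sapply(generate_trajectories(policy_spec("expert"), "task1", 40,
                                     seed = 2), nrow)
  nn <- sapply(generate_trajectories(policy_spec("naive"), "task1", 40,
                                     seed = 2, trial_cap = 120), nrow)
  expect_lt(mean(ne), mean(nn))
})

test_that("the fixed-start variant starts on the left edge, 7 cm up", {
  sp <- policy_spec("expert", start = "fixed")
  trs <- generate_trajectories(sp, "task1", 5, seed = 3)
  for (tr in trs) {
    expect_equal(c(tr$x[1], tr$y[1]), c(0, 7))
  }
})

test_that("policy entropy orders stochastic above deterministic specs", {
  b <- arena_binning(10, c(0, 10), c(0, 10))
  h_sto <- policy_entropy(generate_trajectories(policy_spec("naive"),
                                                "task1", 15, seed = 4,
                                                trial_cap = 60),
                          b, window = 10)$mean
  h_det <- policy_entropy(generate_trajectories(
    policy_spec("expert", drift_gain = 0.95, dir_noise = 0.2),
    "task1", 15, seed = 4), b, window = 10)$mean
  expect_gt(h_sto, h_det)
})

test_that("task2 trials modulate lick rate by trial period", {
  trs <- generate_trajectories(policy_spec("expert"), "task2", 30, seed = 6)
  pre <- unlist(lapply(trs, function(tr) tr$lick[tr$t < 2]))
  resp <- unlist(lapply(trs, function(tr) tr$lick[tr$t >= 2 & tr$led == 1]))
  expect_gt(mean(resp), mean(pre))
})

test_that("session bundles carry ground truth and regenerate identically", {
  b1 <- generate_session("task1", "expert", n_units = 40, n_trials = 6,
                         seed = 11)
  b2 <- generate_session("task1", "expert", n_units = 40, n_trials = 6,
                         seed = 11)
  expect_identical(b1$activity, b2$activity)
  expect_identical(b1$units, b2$units)
  expect_true(all(table(b1$units$class) > 0))
  expect_false("mixed_composite" %in% b1$units$class)
  bc <- generate_session("composite", "expert", n_units = 40, n_trials = 6,
                         seed = 11)
  expect_true("mixed_composite" %in% bc$units$class)
  expect_error(neuron_specs(10, c(place = 0.5, untuned = 0.4)), "sum to 1")
})

test_that("estimated V maps recover the planted value structure", {
  b <- arena_binning(10, c(0, 10), c(0, 10))
  trs <- generate_trajectories(policy_spec("expert"), "task1", 80, seed = 13)
  vm <- estimate_state_values(trs, b, 0.99, reward_zone = c(3, 7, 3, 7))
  ctr <- bin_centers(b)
  va <- qcompose:::mouse_v_fun(ctr[, 1], ctr[, 2], 4)
  ok <- !is.na(vm$v)
  expect_gte(sum(ok), 60)
  expect_gte(stats::cor(vm$v[ok], va[ok]), 0.9)
})

test_that("pure-noise units yield no pseudo-EV", {
  b <- generate_session("task1", "expert", n_units = 30, n_trials = 25,
                        seed = 17,
                        fractions = c(untuned = 1))
  sv <- session_variables(b, 100)
  dm <- build_design_matrix(sv$vars, sv$duration, sample_rate = 100,
                            xlim = c(0, 10), ylim = c(0, 10))
  nf <- min(nrow(dm$X), nrow(b$activity))
  fit <- fit_glm(qcompose:::design_trim(dm, nf), b$activity[seq_len(nf), ])
  expect_lte(mean(fit$pseudo_ev), 0.02)
})
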
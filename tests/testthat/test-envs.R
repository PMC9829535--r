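test_that("task geometry follows the study layout and is validated", {
  c1 <- env_config("task1")
  expect_equal(c1$reward_zone, c(-0.4, 0.4, -0.4, 0.4))
  cc <- env_config("composite")
  expect_equal(cc$target_region, c(-0.05, 0.05, -1, -1 + 0.0031))
  expect_error(env_config("task1", lick_threshold = 0.2), "lick_threshold")
  expect_error(env_config("task1", arena_halfwidth = 0.3), "inside the arena")
  expect_error(env_config("task1", fixed_start = c(2, 0)), "fixed_start")
})

test_that("resets are deterministic per seed and respect start rules", {
  e1 <- make_env(env_config("task1"), seed = 42)
  p1 <- replicate(5, env_reset(e1)$position)
  e2 <- make_env(env_config("task1"), seed = 42)
  p2 <- replicate(5, env_reset(e2)$position)
  expect_identical(p1, p2)

  # starts never fall inside the reward zone
  e <- make_env(env_config("task1"), seed = 7)
  pos <- replicate(10000, env_reset(e)$position)
  inzone <- abs(pos[1, ]) <= 0.4 & abs(pos[2, ]) <= 0.4
  expect_equal(sum(inzone), 0)

  ef <- make_env(env_config("task1", fixed_start = c(-0.2, -0.98)), seed = 1)
  expect_equal(env_reset(ef)$position, c(-0.2, -0.98))

  e2d <- make_env(env_config("task2"), seed = 1)
  expect_equal(env_reset(e2d)$position, c(0, -0.98))
  e2c <- make_env(env_config("task2", control_init_task2 = TRUE), seed = 1)
  expect_equal(env_reset(e2c)$position, c(0, 0.98))
})

test_that("step dynamics implement the task rules", {
  # task1: entering the zone gives the reward and ends the episode
  e <- make_env(env_config("task1", fixed_start = c(0.45, 0)), seed = 1)
  env_reset(e)
  res <- env_step(e, c(-0.1, 0, 0))
  expect_equal(res$state$position, c(0.35, 0))
  expect_equal(res$reward, 1)
  expect_true(res$done)
  expect_error(env_step(e, c(0, 0, 0)), "finished")

  # a move that would cross the wall is rejected in that coordinate
  e <- make_env(env_config("task1", fixed_start = c(0.98, 0.6)), seed = 1)
  env_reset(e)
  res <- env_step(e, c(0.1, 0.05, 0))
  expect_equal(res$state$position, c(0.98, 0.65))

  # task2: lick above threshold is rewarded; movement is free but
  # irrelevant to the reward
  e2 <- make_env(env_config("task2"), seed = 1)
  env_reset(e2)
  res <- env_step(e2, c(0.1, 0.1, 0.09))
  expect_equal(res$state$position, c(0.1, -0.88))
  expect_true(res$info$lick_event)
  expect_equal(res$reward, 1)
  expect_true(res$done)
  # at exactly the threshold no event is counted
  e2 <- make_env(env_config("task2"), seed = 1)
  env_reset(e2)
  expect_false(env_step(e2, c(0, 0, 0.08))$info$lick_event)
  # licking away from the spout region earns nothing
  e2f <- make_env(env_config("task2"), seed = 1)
  env_reset(e2f)
  e2f$state$position <- c(0.5, 0)
  res_far <- env_step(e2f, c(0, 0, 0.09))
  expect_true(res_far$info$lick_event)
  expect_equal(res_far$reward, 0)
  expect_false(res_far$done)
})

test_that("composite reward needs target entry at a strictly earlier step", {
  cfg <- env_config("composite")
  e <- make_env(cfg, seed = 1)
  e$state <- list(position = c(0, -0.999), velocity = c(0, 0),
                  frozen = FALSE, step_index = 0L)
  e$done <- FALSE
  stopifnot(qcompose:::in_rect(0, -0.999, cfg$target_region))
  # lick while already inside but not yet frozen: entry this step, no reward
  res <- env_step(e, c(0, 0, 0.09))
  expect_equal(res$reward, 0)
  expect_true(res$state$frozen)
  # now frozen: movement inert, lick rewards
  res2 <- env_step(e, c(0.1, 0.1, 0.09))
  expect_equal(res2$state$position, c(0, -0.999))
  expect_equal(res2$reward, 1)
  expect_true(res2$done)
})

test_that("episodes truncate at the cap with zero reward", {
  e <- make_env(env_config("task1", fixed_start = c(0.9, 0.9),
                           max_episode_steps = 5), seed = 1)
  env_reset(e)
  for (k in 1:4) expect_false(env_step(e, c(0, 0.01, 0))$done)
  res <- env_step(e, c(0, 0.01, 0))
  expect_true(res$done)
  expect_true(res$info$truncated)
  expect_equal(res$reward, 0)
})

test_that("positions never leave the arena under random actions", {
  set.seed(11)
  e <- make_env(env_config("composite", max_episode_steps = 1000), seed = 3)
  n_checked <- 0
  worst <- 0
  while (n_checked < 100000) {
    env_reset(e)
    repeat {
      res <- env_step(e, c(stats::runif(2, -0.2, 0.2), stats::runif(1, 0, 0.05)))
      n_checked <- n_checked + 1
      worst <- max(worst, abs(res$state$position))
      if (res$done || n_checked %% 1000 == 0) break
    }
  }
  expect_lte(worst, 1)
})

test_that("altered reward pays by the side of zone entry", {
  ar <- list(axis = "x", high_side = "positive", high = 1, low = 0.1)
  e <- make_env(env_config("task1", fixed_start = c(0.45, 0),
                           altered_reward = ar), seed = 1)
  env_reset(e)
  expect_equal(env_step(e, c(-0.1, 0, 0))$reward, 1)
  e2 <- make_env(env_config("task1", fixed_start = c(-0.45, 0),
                            altered_reward = ar), seed = 1)
  env_reset(e2)
  expect_equal(env_step(e2, c(0.1, 0, 0))$reward, 0.1)
})

test_that("the identical-reward-zone variant replaces the composite target", {
  cc <- env_config("composite", identical_reward_zone = TRUE)
  expect_equal(cc$target_region, env_config("task1")$reward_zone)
  expect_error(env_config("task1", identical_reward_zone = TRUE), "composite")
  expect_output(print(env_config("composite")), "composite")
})
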
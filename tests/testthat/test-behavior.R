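# value / policy estimation from trajectories, checked against closed
# forms and a brute-force oracle

# brute-force oracle: explicit per-visit gamma^(T-t) accumulation
oracle_v <- function(trajectories, binning, gamma) {
  nb <- binning$n_bins^2
  sums <- numeric(nb); cnt <- numeric(nb)
  for (tr in trajectories) {
    if (sum(tr$reward) == 0) next
    Tend <- max(which(tr$reward > 0))
    for (t in seq_len(Tend)) {
      b <- bin_index(binning, tr$x[t], tr$y[t])
      sums[b] <- sums[b] + gamma^(Tend - t)
      cnt[b] <- cnt[b] + 1
    }
  }
  ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_)
}

# a scripted trajectory through given bin centers, rewarded at the end
path_traj <- function(binning, bins, hit = TRUE) {
  ctr <- bin_centers(binning)
  df <- data.frame(x = ctr[bins, 1], y = ctr[bins, 2], reward = 0)
  if (hit) df$reward[nrow(df)] <- 1
  df
}

test_that("state values equal the discounted-steps closed form", {
  b <- arena_binning(5, c(0, 5), c(0, 5))
  # bins walked in a straight line; reward at the 4th step
  tr <- path_traj(b, c(1, 2, 3, 4))
  vm <- estimate_state_values(tr, b, gamma = 0.95)
  expect_equal(vm$v[1], 0.95^3)   # 0.857375
  expect_equal(vm$v[2], 0.95^2)   # 0.9025
  expect_equal(vm$v[3], 0.95)
  expect_equal(vm$v[4], 1)        # terminal visit, gamma^0
  expect_true(all(is.na(vm$v[5:25])))

  # two visits to the same bin at T-t = 1 and 3 average their discounts
  tr2 <- path_traj(b, c(7, 12, 7, 8))
  vm2 <- estimate_state_values(tr2, b, gamma = 0.95)
  expect_equal(vm2$v[7], (0.95 + 0.95^3) / 2)  # 0.9036875

  # reward-zone bins are pinned at exactly 1
  zone <- c(2, 3, 2, 3)
  vm3 <- estimate_state_values(tr, b, gamma = 0.95, reward_zone = zone)
  ctr <- bin_centers(b)
  expect_true(all(vm3$v[qcompose:::in_rect(ctr[, 1], ctr[, 2], zone)] == 1))
})

test_that("miss trials are excluded from V and flagged", {
  b <- arena_binning(5, c(0, 5), c(0, 5))
  hit <- path_traj(b, c(1, 2, 3))
  miss <- path_traj(b, c(21, 22, 23), hit = FALSE)
  vm <- estimate_state_values(list(hit, miss), b, 0.9)
  expect_equal(vm$n_hit, 1L)
  expect_equal(vm$n_miss, 1L)
  expect_true(all(is.na(vm$v[21:23])))
  expect_error(estimate_state_values(list(miss), b, 0.9), NA)
  expect_true(all(is.na(estimate_state_values(list(miss), b, 0.9)$v)))
})

test_that("V and Q match the brute-force oracle on a 5x5 arena", {
  b <- arena_binning(5, c(0, 5), c(0, 5))
  set.seed(21)
  trs <- lapply(1:20, function(i) {
    path <- sample.int(25, sample(3:10, 1), replace = TRUE)
    path_traj(b, path, hit = i %% 4 != 0)
  })
  gamma <- 0.95
  vm <- estimate_state_values(trs, b, gamma)
  expect_equal(vm$v, oracle_v(trs, b, gamma))

  qm <- estimate_action_values(vm)
  # oracle Q: gamma * V(neighbor), same bin at edges and for no movement
  n <- 5
  for (bin in seq_len(25)) {
    ix <- (bin - 1) %/% n + 1; iy <- (bin - 1) %% n + 1
    for (k in 1:8) {
      ang <- (k - 1) * 45 * pi / 180
      nx <- ix + round(cos(ang)); ny <- iy + round(sin(ang))
      nb <- if (nx < 1 || nx > n || ny < 1 || ny > n) bin else (nx - 1) * n + ny
      expect_equal(unname(qm$q[bin, k]), gamma * vm$v[nb])
    }
    expect_equal(unname(qm$q[bin, 9]), gamma * vm$v[bin])
  }
})

test_that("V estimates are non-decreasing along a single hit trajectory", {
  b <- arena_binning(10, c(0, 10), c(0, 10))
  for (seed in 1:3) {
    tr <- generate_trajectories(policy_spec("expert"), "task1", 1, seed = seed)[[1]]
    vm <- estimate_state_values(tr, b, 0.99)
    Tend <- max(which(tr$reward > 0))
    path_bins <- bin_index(b, tr$x[seq_len(Tend)], tr$y[seq_len(Tend)])
    # compare first-visit values along the path: a bin visited later (and
    # only later) cannot have a smaller V than an earlier-only bin
    first_seen <- !duplicated(path_bins)
    v_path <- vm$v[path_bins[first_seen]]
    t_seen <- seq_len(Tend)[first_seen]
    single <- table(path_bins)[as.character(path_bins[first_seen])] == 1
    vv <- v_path[single]
    expect_true(all(diff(vv) >= -1e-12))
  }
})

test_that("policy fields combine movement vectors as vector sums", {
  b <- arena_binning(2, c(0, 2), c(0, 2))
  east <- list(seg(0.5, 0.5, 0.9, 0.5), seg(0.5, 0.4, 0.9, 0.4))
  pf <- policy_field(east, b, window = 1, still_threshold = 0.01)
  expect_equal(pf$vectors[1, ], c(1, 0))

  # equal and opposite movements cancel to a zero (flagged) resultant
  cancel <- list(seg(0.2, 0.5, 0.8, 0.5), seg(0.8, 0.5, 0.2, 0.5))
  pf2 <- policy_field(cancel, b, window = 1, still_threshold = 0.01)
  expect_equal(pf2$vectors[1, ], c(0, 0))
  expect_gt(pf2$counts[1], 0)

  # speeds 2:1 east:north give a resultant at atan2(1, 2)
  mix <- list(seg(0.1, 0.3, 0.9, 0.3), seg(0.5, 0.2, 0.5, 0.6))
  pf3 <- policy_field(mix, b, window = 1, still_threshold = 0.01)
  ang <- atan2(pf3$vectors[1, 2], pf3$vectors[1, 1])
  expect_equal(ang, atan2(0.4, 0.8))
})

test_that("policy entropy hits its analytic endpoints and bounds", {
  b <- arena_binning(2, c(0, 2), c(0, 2))
  east <- list(seg(0.5, 0.5, 0.9, 0.5), seg(0.5, 0.4, 0.9, 0.4))
  pe <- policy_entropy(east, b, window = 1, still_threshold = 0.01)
  expect_equal(pe$per_bin[1], 0)

  # equal speed in all 8 directions: maximum entropy ln 8
  angs <- (0:7) * pi / 4
  uni <- lapply(angs, function(a) {
    seg(0.5, 0.5, 0.5 + 0.3 * cos(a), 0.5 + 0.3 * sin(a))
  })
  pe2 <- policy_entropy(uni, b, window = 1, still_threshold = 0.01)
  expect_equal(pe2$per_bin[1], log(8), tolerance = 1e-12)

  two <- c(east, list(seg(0.5, 0.5, 0.5, 0.9), seg(0.4, 0.5, 0.4, 0.9)))
  pe3 <- policy_entropy(two, b, window = 1, still_threshold = 0.01)
  expect_equal(pe3$per_bin[1], log(2), tolerance = 1e-12)

  # bounds on generated data
  tr <- generate_trajectories(policy_spec("naive"), "task1", 5, seed = 5)
  pe4 <- policy_entropy(tr, arena_binning(10, c(0, 10), c(0, 10)), window = 10)
  h <- pe4$per_bin[!is.na(pe4$per_bin)]
  expect_true(all(h >= 0 & h <= log(8) + 1e-12))
})

test_that("cosine similarity compares policy fields bin by bin", {
  b <- arena_binning(2, c(0, 2), c(0, 2))
  east <- data.frame(x = c(0.5, 0.9), y = c(0.5, 0.5))
  west <- data.frame(x = c(0.9, 0.5), y = c(0.5, 0.5))
  north <- data.frame(x = c(0.5, 0.5), y = c(0.5, 0.9))
  fe <- policy_field(east, b, still_threshold = 0.01)
  fw <- policy_field(west, b, still_threshold = 0.01)
  fn <- policy_field(north, b, still_threshold = 0.01)
  expect_equal(cosine_similarity(fe, fe), 1)
  expect_equal(cosine_similarity(fe, fw), -1)
  expect_equal(cosine_similarity(fe, fn), 0)
  far <- data.frame(x = c(1.5, 1.9), y = c(1.5, 1.5))
  ff <- policy_field(far, b, still_threshold = 0.01)
  expect_error(cosine_similarity(fe, ff), "no spatial bin")
})

test_that("occupancy normalizes and recovers planted side biases", {
  b <- arena_binning(10, c(0, 10), c(0, 10))
  tr <- generate_trajectories(policy_spec("naive"), "task1", 5, seed = 2)
  occ <- state_occupancy(tr, b)
  expect_equal(sum(occ), 1, tolerance = 1e-12)

  two_bin <- data.frame(x = c(rep(0.5, 50), rep(9.5, 50)), y = rep(0.5, 100))
  occ2 <- state_occupancy(two_bin, b)
  expect_equal(occ2[bin_index(b, 0.5, 0.5)], 0.5)

  # planted 2:1 right:left bias recovered within the bootstrap interval
  set.seed(9)
  biased_session <- function() {
    n <- 300
    x <- ifelse(stats::runif(n) < 2 / 3, stats::runif(n, 5, 10),
                stats::runif(n, 0, 5))
    list(data.frame(x = x, y = stats::runif(n, 0, 10)))
  }
  sessions <- replicate(6, biased_session(), simplify = FALSE)
  res <- occupancy_ratio(sessions, b, axis = "x", high_side = "positive",
                         reference_sessions = sessions, n_boot = 300, seed = 4)
  expect_gt(res$ratio, 1.5)
  expect_lt(res$ratio, 2.7)
  expect_true(res$ci[1] <= res$ratio && res$ratio <= res$ci[2])
})

test_that("zone visitation is the fraction of episodes entering the zone", {
  zone <- c(4, 6, 0, 1)
  inside <- data.frame(x = c(1, 5), y = c(5, 0.5), reward = c(0, 0))
  outside <- data.frame(x = c(1, 2), y = c(5, 5), reward = c(0, 0))
  expect_equal(zone_visitation(list(inside, inside), zone), 1)
  expect_equal(zone_visitation(list(outside, outside), zone), 0)
  expect_equal(zone_visitation(list(inside, outside), zone), 0.5)
})

test_that("lick-task values discount time to the response period", {
  # hit trials: lick (reward) at sample 6 of an led-on trial
  mk_trial <- function(Tlen, lick_at) {
    df <- data.frame(t = (seq_len(Tlen) - 1) * 0.01, x = 5, y = 0.2,
                     lick = 0, reward = 0, led = 1)
    df$lick[lick_at] <- 1
    df$reward[lick_at] <- 1
    df
  }
  trs <- list(mk_trial(6, 6), mk_trial(4, 4))
  out <- estimate_lick_values(trs, gamma = 0.9)
  # V at within-trial sample 1 averages gamma^(T-1) over the two trials
  expect_equal(out$v_t[1], mean(c(0.9^5, 0.9^3)))
  expect_equal(out$v_t[4], mean(c(0.9^2, 0.9^0)))
  expect_gt(out$q["lick"], out$q["nolick"])
  expect_error(estimate_lick_values(list(mk_trial(3, 2)[-(1:3), ]), 0.9))
})
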
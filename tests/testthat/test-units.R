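test_that("selectivity index hits its endpoints and invariances", {
  one_hot <- c(1, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(selectivity_index(one_hot), 1)
  expect_equal(selectivity_index(rep(1, 8)), 0, tolerance = 1e-12)
  # angle doubling: equal mass at 0 and 180 degrees is fully selective
  opp <- c(1, 0, 0, 0, 1, 0, 0, 0)
  expect_equal(selectivity_index(opp), 1)
  # scale invariance and [0, 1] bounds on random tunings
  set.seed(4)
  M <- matrix(stats::runif(200), 25, 8)
  si <- selectivity_index(M)
  expect_equal(si, selectivity_index(10 * M))
  expect_true(all(si >= 0 & si <= 1))
  expect_error(selectivity_index(rep(0, 8)), "all-zero")
  expect_error(selectivity_index(c(-1, rep(1, 7))), "nonnegative")
})

test_that("distribution index is the normalized difference of fractions", {
  expect_equal(distribution_index(0.2, 0.2), 0)
  expect_equal(distribution_index(0.3, 0), 1)
  expect_equal(distribution_index(0, 0.3), -1)
  # antisymmetry, exactly
  set.seed(5)
  f1 <- stats::runif(50); f2 <- stats::runif(50)
  expect_identical(distribution_index(f1, f2), -distribution_index(f2, f1))
  expect_warning(out <- distribution_index(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("Benjamini-Hochberg mask matches the hand-worked procedure", {
  # m = 4, q = 0.05: thresholds 0.0125, 0.025, 0.0375, 0.05
  expect_equal(sum(fdr_adjust(c(0.01, 0.02, 0.03, 0.5), q = 0.05)), 3)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(fdr_adjust(rep(1, 10))))
  expect_true(all(fdr_adjust(rep(0, 10))))
  expect_identical(fdr_adjust(numeric(0)), logical(0))
})

test_that("FDR holds on all-null unit sets", {
  # noise maps against a structured value map: flagged fraction stays at
  # or below the nominal level
  set.seed(31)
  b <- arena_binning(10, c(0, 10), c(0, 10))
  ctr <- bin_centers(b)
  v <- stationary_value_map(b, c(5, 5), 4)
  reps <- replicate(20, {
    M <- matrix(stats::rnorm(150 * 100), 150, 100)
    mean(classify_v_like(M, v, shuffles = 200,
                         seed = sample.int(1e6, 1))$sig)
  })
  expect_lte(mean(reps), 0.05 + 0.02)
})

test_that("V-like classification separates matched from shuffled maps", {
  set.seed(8)
  b <- arena_binning(10, c(0, 10), c(0, 10))
  v <- stationary_value_map(b, c(5, 5), 4)
  # planted: noisy copies of the value map; controls: torus-shifted fields
  planted <- t(replicate(30, v + stats::rnorm(100, 0, 0.05)))
  ctr <- bin_centers(b)
  edge_fields <- t(replicate(30, {
    cx <- sample(c(0.5, 9.5), 1); cy <- stats::runif(1, 0, 10)
    exp(-((ctr[, 1] - cx)^2 + (ctr[, 2] - cy)^2) / 2) + stats::rnorm(100, 0, 0.05)
  }))
  cls <- classify_v_like(rbind(planted, edge_fields), v, shuffles = 500, seed = 3)
  expect_equal(cls$r[1], cor(planted[1, ], v))
  expect_gte(mean(cls$sig[1:30]), 0.95)
  expect_lte(mean(cls$sig[31:60]), 0.1)
  # self-correlation example: the map itself
  self <- classify_v_like(v, v, shuffles = 500, seed = 3)
  expect_equal(self$r, 1)
  expect_lte(self$p, 0.005)
})

test_that("Q-conjunctive classification recovers matched direction tuning", {
  set.seed(12)
  b <- arena_binning(10, c(0, 10), c(0, 10))
  v <- stationary_value_map(b, c(5, 5), 4)
  vm <- structure(list(v = v, binning = b, gamma = 0.99), class = "value_map")
  qm <- estimate_action_values(vm)
  ctr <- bin_centers(b)
  n_pos <- 25; n_neg <- 25
  mk_unit <- function(matched) {
    repeat {
      cx <- stats::runif(1, 0, 10); cy <- stats::runif(1, 0, 10)
      if (!qcompose:::in_rect(cx, cy, c(3, 7, 3, 7))) break
    }
    map <- exp(-((ctr[, 1] - cx)^2 + (ctr[, 2] - cy)^2) / (2 * 2^2))
    qloc <- qm$q[which.max(map), ]
    tun <- if (matched) qloc - min(qloc) else {
      # anti-matched: tuning rotated to the opposite directions
      qloc[c(5:8, 1:4, 9)] - min(qloc)
    }
    list(map = map, tun = tun + stats::rnorm(9, 0, 0.01))
  }
  units <- c(replicate(n_pos, mk_unit(TRUE), simplify = FALSE),
             replicate(n_neg, mk_unit(FALSE), simplify = FALSE))
  maps <- do.call(rbind, lapply(units, `[[`, "map"))
  tuns <- do.call(rbind, lapply(units, `[[`, "tun"))
  # null tunings: flat profiles with matched noise (the time-series
  # shuffle limit for these synthetic tunings)
  nulls <- function(s) {
    set.seed(1000 + s)
    matrix(stats::rnorm(nrow(tuns) * 9, mean(tuns), 0.05), nrow(tuns))
  }
  cls <- classify_q_conjunctive(maps, tuns, qm$q, shuffles = 400,
                                null_tunings = nulls)
  expect_gte(mean(cls$sig[1:n_pos]), 0.9)
  expect_lte(mean(cls$sig[n_pos + 1:n_neg]), 0.1)
  # uniform tuning: Pearson undefined, dot decides, no error
  uni <- classify_q_conjunctive(maps[1, , drop = FALSE],
                                rep(1, 9), qm$q, shuffles = 100,
                                null_tunings = function(s) {
                                  matrix(stats::rnorm(9, 1, 0.01), 1)
                                })
  expect_true(is.na(uni$r))
  expect_false(is.na(uni$p_dot))
})

test_that("lick-Q classification flags activated, not suppressed, units", {
  set.seed(14)
  Fn <- 600
  lick_frames <- sort(sample.int(Fn - 10, 25))
  m <- rep(0, Fn); m[outer(lick_frames, 0:5, "+")] <- 1
  act_on <- 0.5 * m + stats::rnorm(Fn, 0, 0.1)       # lick-activated
  act_off <- 0.5 * (1 - m) + stats::rnorm(Fn, 0, 0.1) # lick-suppressed
  act_flat <- stats::rnorm(Fn, 0.5, 0.1)              # invariant
  A <- cbind(replicate(10, 0.5 * m + stats::rnorm(Fn, 0, 0.1)),
             replicate(10, 0.5 * (1 - m) + stats::rnorm(Fn, 0, 0.1)),
             replicate(10, stats::rnorm(Fn, 0.5, 0.1)))
  cls <- classify_q_lick(A, lick_frames, q_lick = c(1, 0.93),
                         frame_rate = 5.67, shuffles = 300, seed = 2)
  expect_gte(mean(cls$sig[1:10]), 0.9)
  expect_equal(sum(cls$sig[11:20]), 0)
  expect_lte(mean(cls$sig[21:30]), 0.1)
  expect_error(classify_q_lick(A, integer(0), c(1, 0.9)), "no lick")
})

test_that("conjunctive chance level sits below matched-data fractions", {
  set.seed(16)
  b <- arena_binning(10, c(0, 10), c(0, 10))
  v <- stationary_value_map(b, c(5, 5), 4)
  vm <- structure(list(v = v, binning = b, gamma = 0.99), class = "value_map")
  qm <- estimate_action_values(vm)
  ctr <- bin_centers(b)
  state_maps <- t(replicate(40, {
    cx <- stats::runif(1, 0, 10); cy <- stats::runif(1, 0, 10)
    exp(-((ctr[, 1] - cx)^2 + (ctr[, 2] - cy)^2) / 8)
  }))
  action_tunings <- t(replicate(40, stats::runif(9)))
  ch <- chance_fraction_conjunctive(state_maps, action_tunings, qm$q,
                                    resamples = 300, shuffles = 200, seed = 5)
  expect_true(ch$chance >= 0 && ch$chance <= 1)
  expect_true(ch$ci[1] <= ch$chance && ch$chance <= ch$ci[2])
  expect_error(chance_fraction_conjunctive(state_maps[0, ], action_tunings,
                                           qm$q), "empty")
})

test_that("enrichment measures the side of space-map peaks", {
  b <- arena_binning(10, c(0, 10), c(0, 10))
  ctr <- bin_centers(b)
  mk_maps <- function(n, p_right) {
    t(replicate(n, {
      cx <- if (stats::runif(1) < p_right) stats::runif(1, 5.5, 10)
            else stats::runif(1, 0, 4.5)
      exp(-((ctr[, 1] - cx)^2 + (ctr[, 2] - 5)^2) / 4)
    }))
  }
  set.seed(18)
  all_right <- mk_maps(20, 1)
  expect_equal(enrichment_side(all_right, b, "x", "positive")$fraction, 1)
  planted <- mk_maps(200, 0.7)
  refs <- replicate(8, mk_maps(60, 0.5), simplify = FALSE)
  res <- enrichment_side(planted, b, "x", "positive", reference = refs,
                         n_boot = 400, seed = 2)
  expect_equal(res$fraction, 0.7, tolerance = 0.1)
  expect_lt(res$p, 0.05)
})

test_that("covariate control correlations behave at the extremes", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  out <- covariate_control_correlation(x, 2 * x + 1)
  expect_equal(out$r, 1)
  expect_warning(out2 <- covariate_control_correlation(rep(0.2, 4), x),
                 "constant")
  expect_true(is.na(out2$r))
  # independent series: |r| small in expectation
  set.seed(3)
  rs <- replicate(200, covariate_control_correlation(stats::runif(8),
                                                     stats::runif(8))$r)
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(covariate_control_correlation(1:2, 1:2), ">= 3")
})
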
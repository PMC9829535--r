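test_that("raised-cosine bases peak at 1, tile evenly, and span the stated supports", {
  ev <- build_basis("temporal_event")
  expect_equal(ev$n_bases, 6L)
  expect_equal(ev$support, c(-2, 2))
  rw <- build_basis("reward")
  expect_equal(rw$n_bases, 9L)
  expect_equal(rw$support, c(-2, 4))
  tt <- seq(-4, 6, by = 0.001)
  B <- eval_basis(rw, t = tt)
  expect_equal(apply(B, 2, max), rep(1, 9), tolerance = 1e-5)
  # interior sum approximately constant (perfect cos^2 tiling)
  interior <- tt > -1.5 & tt < 3.5
  s <- rowSums(B)[interior]
  expect_lt((max(s) - min(s)) / mean(s), 0.10)
  expect_error(build_basis("temporal_event", n_bases = 0), "positive")

  sp <- build_basis("spatial", xlim = c(0, 10), ylim = c(0, 10))
  expect_equal(sp$n_bases, 100L)
  vals <- eval_basis(sp, xy = sp$centers)
  expect_equal(diag(vals), rep(1, 100))
})

test_that("design matrix decomposes velocity by direction and checks inputs", {
  dur <- 60; rate <- 100
  n <- dur * rate
  vars <- list(object_pos = cbind(seq(0, 5, length.out = n), rep(5, n)),
               object_vel = cbind(rep(2, n), rep(0, n)),
               lick_onsets = c(10, 30))
  dm <- build_design_matrix(vars, dur, sample_rate = rate,
                            xlim = c(0, 10), ylim = c(0, 10))
  g <- dm$groups
  vel_vars <- unique(g$variable[grepl("object_vel", g$variable)])
  for (vv in vel_vars) {
    cols <- g$column[g$variable == vv]
    mx <- max(abs(dm$X[, cols]))
    if (vv == "object_vel_d0") expect_gt(mx, 0) else expect_equal(mx, 0)
  }
  # a single lick is supported only within +- 2 s (+ basis width) of onset
  cols <- g$column[g$variable == "lick_onsets"]
  on_frames <- which(rowSums(abs(dm$X[, cols])) > 1e-10)
  expect_true(all(abs(dm$frame_times[on_frames] - 10) < 4 |
                    abs(dm$frame_times[on_frames] - 30) < 4))
  expect_error(build_design_matrix(vars, dur, sample_rate = rate,
                                   required = c("object_pos", "reward_onsets")),
               "reward_onsets")
  expect_error(build_design_matrix(vars, dur + 5, sample_rate = rate),
               "mismatch")
})

test_that("downsampling a constant convolved signal stays constant", {
  dur <- 40; rate <- 100
  n <- dur * rate
  vars <- list(object_vel = cbind(rep(1.5, n), rep(0, n)))
  dm <- build_design_matrix(vars, dur, sample_rate = rate)
  cols <- dm$groups$column[dm$groups$variable == "object_vel_d0"]
  interior <- dm$frame_times > 5 & dm$frame_times < dur - 5
  for (cc in cols) {
    vals <- dm$X[interior, cc]
    expect_equal(max(vals) - min(vals), 0, tolerance = 1e-8 * max(abs(vals)))
  }
})

test_that("ridge fit matches a direct solve and is deterministic", {
  set.seed(41)
  n <- 300; P <- 12
  X <- matrix(stats::rnorm(n * P), n, P)
  w <- stats::rnorm(P)
  y <- X %*% w + stats::rnorm(n, 0, 0.5)
  fit <- fit_glm(X, y, folds = 5, lambdas = c(1))
  # independent oracle: closed-form ridge on centered data
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  w_direct <- solve(crossprod(Xc) + diag(1, P), crossprod(Xc, yc))
  expect_equal(as.numeric(fit$weights), as.numeric(w_direct), tolerance = 1e-8)
  fit2 <- fit_glm(X, y, folds = 5, lambdas = c(1))
  expect_identical(fit$weights, fit2$weights)
})

test_that("planted weights are recovered and noise gives no pseudo-EV", {
  set.seed(43)
  n <- 600; P <- 30
  X <- matrix(stats::rnorm(n * P), n, P)
  W <- matrix(stats::rnorm(P * 25), P, 25)
  sig <- X %*% W
  Y <- sig + matrix(stats::rnorm(n * 25, 0, apply(sig, 2, stats::sd) / 5),
                    n, 25, byrow = TRUE)
  fit <- fit_glm(X, Y, folds = 5)
  rr <- sapply(1:25, function(u) stats::cor(fit$weights[, u], W[, u]))
  expect_true(all(rr > 0.8))
  expect_true(all(fit$pseudo_ev > 0.8))

  noise <- matrix(stats::rnorm(n * 25), n, 25)
  fit0 <- fit_glm(X, noise, folds = 5)
  expect_lte(mean(fit0$pseudo_ev), 0.02)
})

test_that("response profiles marginalize to the planted variable", {
  # build a small session with one lick-only and one place-like unit
  dur <- 200; rate <- 100
  n <- dur * rate
  set.seed(47)
  pos <- cbind(stats::runif(n %/% 100, 0, 10)[rep(1:(n %/% 100), each = 100)],
               stats::runif(n %/% 100, 0, 10)[rep(1:(n %/% 100), each = 100)])
  licks <- sort(stats::runif(40, 5, dur - 5))
  vars <- list(object_pos = pos, lick_onsets = licks)
  dm <- build_design_matrix(vars, dur, sample_rate = rate,
                            xlim = c(0, 10), ylim = c(0, 10))
  fr <- nrow(dm$X)
  lick_frames <- pmin(floor(licks * dm$frame_rate) + 1, fr)
  lick_sig <- rep(0, fr); lick_sig[lick_frames] <- 1
  lick_sig <- as.numeric(stats::filter(lick_sig, 0.6, method = "recursive"))
  frame_pos <- pos[round(seq(1, n, length.out = fr)), ]
  place_sig <- exp(-((frame_pos[, 1] - 5)^2 + (frame_pos[, 2] - 5)^2) / 4)
  Y <- cbind(lick_sig + stats::rnorm(fr, 0, 0.05),
             place_sig + stats::rnorm(fr, 0, 0.05))
  fit <- fit_glm(dm, Y, folds = 5)

  lick_prof <- response_profile(fit, "lick_onsets")
  expect_gt(lick_prof[1, "lick"] - lick_prof[1, "nolick"],
            5 * abs(lick_prof[2, "lick"] - lick_prof[2, "nolick"]))
  space_prof <- response_profile(fit, "object_pos")
  # lick-only unit: flat space map relative to the place unit
  expect_lt(stats::sd(space_prof[1, ]), 0.3 * stats::sd(space_prof[2, ]))
  # place unit peaks at the planted center (bin 45/46/55/56 area)
  b <- arena_binning(10, c(0, 10), c(0, 10))
  pk <- bin_centers(b)[which.max(space_prof[2, ]), ]
  expect_lt(sqrt(sum((pk - c(5, 5))^2)), 1.5)
  expect_error(response_profile(fit, "joystick_vel"), "absent|unknown")
})
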
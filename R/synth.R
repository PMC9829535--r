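# Synthetic mouse-like sessions with known ground truth: trajectories under
# parameterized policies on a 10 x 10 cm arena (10-ms base rate),
# task-variable series, and calcium-like (deconvolved, nonnegative
# transient) unit activity at the imaging frame rate with planted tuning
# classes, so the whole analysis stack is testable without recordings.

MOUSE_DT <- 0.01            # 10-ms base sampling
MOUSE_ARENA <- c(0, 10)     # cm
MOUSE_ZONE <- c(3, 7, 3, 7) # 4 x 4 cm reward zone in the center
MOUSE_TARGET <- c(4.75, 5.25, 0, 0.016)  # bottom-middle composite target
MOUSE_GAMMA <- 0.99         # per 10 ms

#' Trajectory-generating policy specification
#'
#' The policy is a mixture: with probability \code{drift_gain} the step is
#' directed at the goal with wrapped-Gaussian angular noise
#' \code{dir_noise}; otherwise the direction is uniform.  Both knobs lower
#' the realized policy entropy as they move toward determinism.
#'
#' @param stage \code{"naive"} or \code{"expert"} (sets defaults).
#' @param drift_gain probability of a goal-directed step.
#' @param dir_noise angular noise s.d. (radians) of directed steps.
#' @param speed object speed in cm/s (> 0).
#' @param start \code{"random"} or \code{"fixed"}.
#' @param fixed_start start position for the deterministic-policy variant
#'   (default 7 cm from the bottom on the left edge).
#' @param lick_rate_on,lick_rate_off lick rates (Hz) during LED-on and
#'   LED-off periods.
#' @return a list of class \code{"policy_spec"}.
#' @export
policy_spec <- function(stage = c("expert", "naive"), drift_gain = NULL,
                        dir_noise = NULL, speed = NULL,
                        start = c("random", "fixed"),
                        fixed_start = c(0, 7),
                        lick_rate_on = NULL, lick_rate_off = 0.5) {
  stage <- match.arg(stage)
  start <- match.arg(start)
  def <- if (stage == "expert") {
    # expert mice keep a stochastic policy: goal-directed drift with
    # substantial angular spread
    list(drift_gain = 0.70, dir_noise = 0.9, speed = 4, lick_rate_on = 4)
  } else {
    list(drift_gain = 0.15, dir_noise = 2.0, speed = 2.5, lick_rate_on = 1)
  }
  if (is.null(drift_gain)) drift_gain <- def$drift_gain
  if (is.null(dir_noise)) dir_noise <- def$dir_noise
  if (is.null(speed)) speed <- def$speed
  if (is.null(lick_rate_on)) lick_rate_on <- def$lick_rate_on
  if (speed <= 0) stop("speed must be positive")
  structure(list(stage = stage, drift_gain = drift_gain,
                 dir_noise = dir_noise, speed = speed, start = start,
                 fixed_start = fixed_start, lick_rate_on = lick_rate_on,
                 lick_rate_off = lick_rate_off),
            class = "policy_spec")
}

rect_center <- function(rect) c(mean(rect[1:2]), mean(rect[3:4]))

# distance from a point to an axis-aligned rectangle (0 inside)
rect_dist <- function(x, y, rect) {
  dx <- pmax(rect[1] - x, 0, x - rect[2])
  dy <- pmax(rect[3] - y, 0, y - rect[4])
  sqrt(dx^2 + dy^2)
}

# analytic ground-truth state value: discounted steps-to-zone at full speed
mouse_v_fun <- function(x, y, speed, zone = MOUSE_ZONE) {
  steps <- rect_dist(x, y, zone) / (speed * MOUSE_DT)
  MOUSE_GAMMA^steps
}

# analytic Q over 8 directions + none: value of the 1-cm-displaced neighbor
mouse_q_profile <- function(x, y, speed, zone = MOUSE_ZONE) {
  ang <- DIR_ANGLES * pi / 180
  sapply(c(seq_along(ang), 9), function(k) {
    if (k <= 8) {
      nx <- pmin(pmax(x + cos(ang[k]), MOUSE_ARENA[1]), MOUSE_ARENA[2])
      ny <- pmin(pmax(y + sin(ang[k]), MOUSE_ARENA[1]), MOUSE_ARENA[2])
      MOUSE_GAMMA * mouse_v_fun(nx, ny, speed, zone)
    } else {
      MOUSE_GAMMA * mouse_v_fun(x, y, speed, zone)
    }
  })
}

ang_diff <- function(a, b) atan2(sin(a - b), cos(a - b))

# smooth heading dynamics: the heading is pulled toward the goal direction
# at a per-step rate set by drift_gain and diffuses with per-step noise set
# by dir_noise, so movement direction is persistent on the ~100-ms scale
# (as for a physical object moved by a joystick) while still exploring
sim_move_trial <- function(spec, goal_rect, freeze_in_target, trial_cap,
                           start_pos) {
  cap <- as.integer(trial_cap / MOUSE_DT)
  x <- numeric(cap + 1); y <- numeric(cap + 1)
  x[1] <- start_pos[1]; y[1] <- start_pos[2]
  goal <- rect_center(goal_rect)
  step_len <- spec$speed * MOUSE_DT
  pull <- 0.1 * spec$drift_gain
  hsd <- 0.12 * spec$dir_noise
  h <- stats::runif(1, -pi, pi)
  frozen <- FALSE
  i <- 1L
  while (i <= cap) {
    if (!frozen) {
      th_goal <- atan2(goal[2] - y[i], goal[1] - x[i])
      h <- h + pull * ang_diff(th_goal, h) + stats::rnorm(1, 0, hsd)
      x[i + 1] <- min(max(x[i] + step_len * cos(h), MOUSE_ARENA[1]), MOUSE_ARENA[2])
      y[i + 1] <- min(max(y[i] + step_len * sin(h), MOUSE_ARENA[1]), MOUSE_ARENA[2])
    } else {
      x[i + 1] <- x[i]; y[i + 1] <- y[i]
    }
    i <- i + 1L
    inside <- in_rect(x[i], y[i], goal_rect)
    if (inside) {
      if (freeze_in_target) frozen <- TRUE else break
    }
    if (frozen) break   # composite movement phase ends at target entry
  }
  list(x = x[seq_len(i)], y = y[seq_len(i)], frozen = frozen,
       reached = in_rect(x[i], y[i], goal_rect))
}

poisson_events <- function(n, rate) stats::runif(n) < rate * MOUSE_DT

pad_rows <- function(df, n_pad, led = 0) {
  if (n_pad <= 0) return(df)
  last <- df[nrow(df), ]
  pad <- last[rep(1, n_pad), ]
  pad$vx <- 0; pad$vy <- 0; pad$jx <- 0; pad$jy <- 0
  pad$lick <- 0; pad$reward <- 0; pad$led <- led
  rbind(df, pad)
}

#' Generate mouse-like trajectories
#'
#' Simulates 10-ms-step trials on the 10 x 10 cm arena.  Task 1 trials end
#' at reward-zone entry (hit) or at the 5-min cap (miss); Task 2 trials are
#' stationary licking trials with a 2-s delay before the response period;
#' composite trials require reaching the bottom-middle target (after which
#' the object is frozen) and then licking.  Hit trials are padded with a
#' 4-s reward-consumption period and a 2-s intertrial interval.
#'
#' @param spec a \code{\link{policy_spec}}.
#' @param task \code{"task1"}, \code{"task2"} or \code{"composite"}.
#' @param n_trials number of trials (>= 1).
#' @param seed RNG seed.
#' @param trial_cap trial cap in seconds (study: 5 min).
#' @return list of per-trial \code{data.frame}s with columns
#'   \code{t, x, y, vx, vy, jx, jy, lick, led, reward}.
#' @export
generate_trajectories <- function(spec, task = c("task1", "task2", "composite"),
                                  n_trials, seed = 0L, trial_cap = 300) {
  task <- match.arg(task)
  stopifnot(inherits(spec, "policy_spec"), n_trials >= 1)
  stream <- make_rng(seed)
  with_stream(stream, {
    lapply(seq_len(n_trials), function(tr) {
      if (task == "task2") {
        cap <- as.integer(trial_cap / MOUSE_DT)
        delay <- as.integer(2 / MOUSE_DT)
        lick <- poisson_events(cap, spec$lick_rate_on)
        lick[seq_len(delay)] <- poisson_events(delay, spec$lick_rate_off)
        first <- which(lick & seq_len(cap) > delay)[1]
        n <- if (is.na(first)) cap else first
        df <- data.frame(t = (seq_len(n) - 1) * MOUSE_DT,
                         x = 5, y = 0.2, vx = 0, vy = 0, jx = 0, jy = 0,
                         lick = as.numeric(lick[seq_len(n)]), led = 1,
                         reward = 0)
        if (!is.na(first)) {
          df$reward[n] <- 1
          df <- pad_rows(df, as.integer(6 / MOUSE_DT), led = 0)
        }
        df$t <- (seq_len(nrow(df)) - 1) * MOUSE_DT
        return(df)
      }
      goal <- if (task == "task1") MOUSE_ZONE else MOUSE_TARGET
      start <- if (spec$start == "fixed") spec$fixed_start else {
        repeat {
          p <- stats::runif(2, MOUSE_ARENA[1], MOUSE_ARENA[2])
          if (!in_rect(p[1], p[2], goal)) break
        }
        p
      }
      mv <- sim_move_trial(spec, goal,
                           freeze_in_target = (task == "composite"),
                           trial_cap = trial_cap, start_pos = start)
      n <- length(mv$x)
      df <- data.frame(t = (seq_len(n) - 1) * MOUSE_DT, x = mv$x, y = mv$y,
                       vx = c(0, diff(mv$x)) / MOUSE_DT,
                       vy = c(0, diff(mv$y)) / MOUSE_DT,
                       lick = as.numeric(poisson_events(n, spec$lick_rate_off)),
                       led = 1, reward = 0)
      # joystick velocity tracks the object loosely (motor gain + hand noise)
      df$jx <- df$vx + stats::rnorm(n, 0, spec$speed)
      df$jy <- df$vy + stats::rnorm(n, 0, spec$speed)
      hit <- FALSE
      if (task == "task1" && mv$reached) {
        hit <- TRUE
        df$reward[n] <- 1
      } else if (task == "composite" && mv$frozen) {
        # licking phase at the frozen target
        cap_left <- as.integer(trial_cap / MOUSE_DT) - n
        lick <- poisson_events(max(cap_left, 1), spec$lick_rate_on)
        first <- which(lick)[1]
        if (!is.na(first) && cap_left > 0) {
          add <- first
          ext <- df[rep(n, add), ]
          ext$vx <- 0; ext$vy <- 0; ext$jx <- 0; ext$jy <- 0
          ext$lick <- as.numeric(lick[seq_len(add)])
          ext$reward <- 0
          df <- rbind(df, ext)
          df$reward[nrow(df)] <- 1
          hit <- TRUE
        }
      }
      if (hit) df <- pad_rows(df, as.integer(6 / MOUSE_DT), led = 0)
      df$t <- (seq_len(nrow(df)) - 1) * MOUSE_DT
      df[, c("t", "x", "y", "vx", "vy", "jx", "jy", "lick", "led", "reward")]
    })
  })
}

#' Planted unit specifications
#'
#' @param n_units number of units.
#' @param fractions named class fractions summing to 1 (classes:
#'   \code{place, direction, conjunctive_q, v_like, lick, lick_q,
#'   mixed_composite, untuned}).
#' @param snr ratio of signal s.d. to additive noise s.d. at the frame
#'   level.  The default 5 emulates the activity-thresholded deconvolved
#'   traces that enter real analyses (units without clear transients are
#'   excluded upstream).
#' @param seed RNG seed.
#' @return data.frame of per-unit ground truth (class, field center/width,
#'   preferred direction, gain, region label).
#' @export
neuron_specs <- function(n_units, fractions, snr = 5, seed = 0L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("class fractions must sum to 1")
  classes <- names(fractions)
  counts <- floor(fractions * n_units)
  rem <- n_units - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  cls <- rep(classes, counts)
  regions <- c("M1", "M2", "S1", "RSC", "PPC")
  # class-dependent region enrichment (movement-Q in PPC/RSC, lick-Q in M2)
  region_probs <- list(
    conjunctive_q = c(0.12, 0.18, 0.10, 0.25, 0.35),
    v_like = c(0.12, 0.18, 0.10, 0.30, 0.30),
    lick_q = c(0.20, 0.45, 0.15, 0.10, 0.10),
    lick = c(0.25, 0.35, 0.20, 0.10, 0.10))
  stream <- make_rng(seed)
  with_stream(stream, {
    cls <- sample(cls)
    reg <- vapply(cls, function(cl) {
      pr <- region_probs[[cl]]
      if (is.null(pr)) pr <- rep(0.2, 5)
      sample(regions, 1, prob = pr)
    }, character(1))
    draw_center <- function(cl) {
      repeat {
        p <- stats::runif(2, MOUSE_ARENA[1], MOUSE_ARENA[2])
        # Q-conjunctive tuning is undefined inside the reward zone (flat
        # Q), so conjunctive fields are planted outside it
        if (cl != "conjunctive_q" || !in_rect(p[1], p[2], MOUSE_ZONE)) break
      }
      p
    }
    ctrs <- t(vapply(cls, draw_center, numeric(2)))
    data.frame(
      id = seq_len(n_units), class = cls, region = reg,
      cx = ctrs[, 1], cy = ctrs[, 2],
      # value-representing classes carry broad fields (network-like state
      # tuning); place fields are narrower
      sigma = ifelse(cls %in% c("conjunctive_q", "mixed_composite"),
                     stats::runif(n_units, 2.0, 2.8),
                     stats::runif(n_units, 1.0, 1.6)),
      pref_dir = sample(DIR_ANGLES, n_units, replace = TRUE),
      kappa = stats::runif(n_units, 2, 4),
      gain = stats::runif(n_units, 0.8, 1.2),
      snr = snr, stringsAsFactors = FALSE)
  })
}

#' Generate calcium-like activity with planted tuning
#'
#' Builds each unit's latent drive from its planted class (place: 2-D
#' Gaussian field; direction: von Mises over movement angle; v_like:
#' proportional to the analytic state value; conjunctive_q: field gated by
#' the local Q-matched direction profile; lick: lick-suppressed; lick_q:
#' lick-locked transients scaled by the lick value; mixed_composite: fields
#' at the arena center and bottom middle), convolves it with an
#' exponential transient kernel, averages within imaging frames and adds
#' Gaussian noise at 1/snr of the signal s.d.
#'
#' @param trajectories output of \code{\link{generate_trajectories}}.
#' @param specs a \code{\link{neuron_specs}} data.frame.
#' @param frame_rate imaging frame rate (Hz).
#' @param tau transient decay constant (s).
#' @param seed RNG seed.
#' @return list with \code{activity} (frames x units, nonnegative signal
#'   plus noise), \code{frame_times}, \code{labels} (= specs),
#'   \code{trial_frames} (frame index range per trial).
#' @export
generate_activity <- function(trajectories, specs, frame_rate = 5.67,
                              tau = 0.15, task = "task1", seed = 0L) {
  # value-tuned classes carry the Task 1 (center-zone) value structure in
  # every task: in the composite task these representations are retained
  # from subtask learning, which is what the classification stack tests
  goal_zone <- MOUSE_ZONE
  trs <- as_traj_list(trajectories)
  df <- do.call(rbind, trs)
  S <- nrow(df)
  frame_len <- 1 / (frame_rate * MOUSE_DT)
  fidx <- pmin(floor((seq_len(S) - 1) / frame_len) + 1, ceiling(S / frame_len))
  n_frames <- max(fidx)
  fcnt <- tabulate(fidx, n_frames)
  speed_ref <- stats::median(vapply(trs, function(tr) {
    max(sqrt(tr$vx^2 + tr$vy^2))
  }, numeric(1)))
  if (speed_ref <= 0) speed_ref <- 1

  sp <- sqrt(df$vx^2 + df$vy^2)
  move_ang <- atan2(df$vy, df$vx)
  moving <- sp > 0.5
  dbin <- ifelse(moving, (round(move_ang / (pi / 4)) %% 8) + 1L, 9L)
  vmap_here <- mouse_v_fun(df$x, df$y, speed_ref, zone = goal_zone)
  lick_idx <- which(df$lick > 0)
  # lick value: high when a lick can be rewarded (response period open /
  # frozen at the composite target), discounted before
  resp_open <- df$led == 1 & df$t >= 2
  at_target <- in_rect(df$x, df$y, MOUSE_TARGET)
  lick_value <- ifelse(resp_open | at_target, 1,
                       MOUSE_GAMMA^(pmax(2 - df$t, 0) / MOUSE_DT)) *
    ifelse(df$led == 1, 1, 0.2)

  a_decay <- exp(-MOUSE_DT / tau)
  kern <- function(x) as.numeric(stats::filter(x, a_decay, method = "recursive"))

  stream <- make_rng(seed)
  A <- matrix(0, n_frames, nrow(specs))
  sds <- numeric(nrow(specs))
  field <- function(cx, cy, sg) exp(-((df$x - cx)^2 + (df$y - cy)^2) / (2 * sg^2))
  for (u in seq_len(nrow(specs))) {
    s <- specs[u, ]
    lat <- switch(s$class,
      place = s$gain * field(s$cx, s$cy, s$sigma),
      v_like = s$gain * vmap_here,
      direction = {
        vm <- exp(s$kappa * cos(move_ang - s$pref_dir * pi / 180))
        s$gain * ifelse(moving, vm / exp(s$kappa), 0)
      },
      conjunctive_q = {
        qp <- mouse_q_profile(s$cx, s$cy, speed_ref, zone = goal_zone)
        w <- qp - min(qp)
        w <- if (max(w) > 0) w / max(w) else rep(1, 9)
        s$gain * field(s$cx, s$cy, s$sigma) * w[dbin]
      },
      lick = {   # lick-suppressed: tonic drive that pauses around licks
        drive <- rep(s$gain * 0.5, S)
        if (length(lick_idx)) {
          sup <- unique(as.integer(outer(lick_idx, 0:30, "+")))
          sup <- sup[sup <= S]
          drive[sup] <- 0
        }
        drive
      },
      lick_q = {
        x <- numeric(S)
        x[lick_idx] <- s$gain * lick_value[lick_idx]
        x * 30       # impulse height so transients dominate the kernel
      },
      mixed_composite = {
        s$gain * (field(5, 5, s$sigma) + field(5, 0.5, s$sigma))
      },
      untuned = numeric(S))
    sig <- kern(lat) * (1 - a_decay)   # unit-gain smoothing for sustained drive
    fr <- rowsum(sig, fidx)[, 1] / fcnt
    sds[u] <- stats::sd(fr)
    A[, u] <- fr
  }
  ref_sd <- if (any(sds > 0)) stats::median(sds[sds > 0]) else 1
  noise_sd <- pmax(sds, ref_sd) / specs$snr
  A <- A + with_stream(stream,
    matrix(stats::rnorm(n_frames * nrow(specs)), n_frames) *
      rep(noise_sd, each = n_frames))

  trial_len <- vapply(trs, nrow, integer(1))
  ends <- cumsum(trial_len)
  trial_frames <- cbind(start = fidx[c(1, utils::head(ends, -1) + 1)],
                        end = fidx[ends])
  list(activity = A, frame_times = (seq_len(n_frames) - 0.5) / frame_rate,
       labels = specs, trial_frames = trial_frames)
}

default_fractions <- function(task, stage) {
  if (task == "task2") {
    if (stage == "expert") {
      c(lick = 0.15, lick_q = 0.20, untuned = 0.65)
    } else c(lick = 0.15, lick_q = 0.10, untuned = 0.75)
  } else if (task == "task1") {
    if (stage == "expert") {
      c(place = 0.18, direction = 0.15, conjunctive_q = 0.14, v_like = 0.10,
        lick = 0.05, lick_q = 0.0, mixed_composite = 0, untuned = 0.38)
    } else {
      c(place = 0.18, direction = 0.15, conjunctive_q = 0.05, v_like = 0.04,
        lick = 0.05, lick_q = 0.0, mixed_composite = 0, untuned = 0.53)
    }
  } else {
    c(place = 0.14, direction = 0.12, conjunctive_q = 0.12, v_like = 0.08,
      lick = 0.05, lick_q = 0.10, mixed_composite = 0.10, untuned = 0.29)
  }
}

#' Generate a full synthetic session bundle
#'
#' One call producing trajectories, task-variable series and planted unit
#' activity for a task/stage combination, with defaults mirroring the
#' study's scales (Q-class fractions rise from naive to expert;
#' mixed-composite units exist only in composite-task bundles).
#' Regeneration from the same seed is bit-identical.
#'
#' @param task,stage task and learning stage.
#' @param n_units number of units (default 2000).
#' @param n_trials trials (task/stage-dependent default).
#' @param fractions optional class-fraction override.
#' @param snr generator signal-to-noise (default 3).
#' @param seed RNG seed.
#' @return an object of class \code{"session_bundle"}.
#' @export
generate_session <- function(task = c("task1", "task2", "composite"),
                             stage = c("expert", "naive"), n_units = 2000L,
                             n_trials = NULL, fractions = NULL, snr = 5,
                             seed = 0L) {
  task <- match.arg(task)
  stage <- match.arg(stage)
  if (is.null(n_trials)) {
    n_trials <- if (task == "task1" && stage == "naive") 25L else 150L
  }
  if (is.null(fractions)) fractions <- default_fractions(task, stage)
  spec <- policy_spec(stage)
  trs <- generate_trajectories(spec, task, n_trials, seed = seed,
                               trial_cap = if (stage == "naive") 120 else 300)
  specs <- neuron_specs(n_units, fractions, snr = snr, seed = seed + 1L)
  act <- generate_activity(trs, specs, task = task, seed = seed + 2L)
  structure(list(task = task, stage = stage, trajectories = trs,
                 activity = act$activity, frame_times = act$frame_times,
                 trial_frames = act$trial_frames, units = specs,
                 policy = spec, seed = seed),
            class = "session_bundle")
}

#' Task-variable time series of a session at a given sampling rate
#'
#' Upsamples the 10-ms base series (sample-and-hold for positions and
#' velocities; events mapped to their onset times) to the requested rate,
#' in the format expected by \code{\link{build_design_matrix}}.
#'
#' @param bundle a \code{\link{generate_session}} result.
#' @param sample_rate target rate in Hz (study: 2000).
#' @return list with \code{vars} (task-variable list), \code{duration}.
#' @export
session_variables <- function(bundle, sample_rate = 2000) {
  df <- do.call(rbind, bundle$trajectories)
  S <- nrow(df)
  t_sess <- (seq_len(S) - 1) * MOUSE_DT
  rep_k <- as.integer(round(sample_rate * MOUSE_DT))
  idx <- rep(seq_len(S), each = rep_k)
  trial_len <- vapply(bundle$trajectories, nrow, integer(1))
  onsets <- t_sess[c(1, utils::head(cumsum(trial_len), -1) + 1)]
  offsets <- t_sess[cumsum(trial_len)]
  vars <- list(
    trial_onsets = onsets,
    trial_offsets = offsets,
    lick_onsets = t_sess[df$lick > 0],
    reward_onsets = t_sess[df$reward > 0],
    object_pos = cbind(df$x[idx], df$y[idx]),
    object_vel = cbind(df$vx[idx], df$vy[idx]),
    joystick_vel = cbind(df$jx[idx], df$jy[idx]))
  if (bundle$task == "task2") {
    vars$object_pos <- NULL
    vars$object_vel <- NULL
  }
  list(vars = vars, duration = S * MOUSE_DT)
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("Synthetic %s session (%s stage)\n", x$task, x$stage))
  cat(sprintf("  %d trials, %d frames, %d units (seed %d)\n",
              length(x$trajectories), nrow(x$activity), ncol(x$activity),
              x$seed))
  cat("  planted classes:",
      paste(sprintf("%s=%d", names(table(x$units$class)),
                    table(x$units$class)), collapse = ", "), "\n")
  invisible(x)
}
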
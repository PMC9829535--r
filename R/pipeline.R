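# End-to-end orchestration: the agent-side experiment chain (pretrain ->
# compose -> fine-tune -> analyze) and the mouse-side synthetic chain
# (generate -> GLM -> classify -> compare), plus the experiment-plan
# runner that writes tabular outputs with a reproducibility manifest.

#' Training-scale profile
#'
#' Bundles the soft actor-critic sizes used by the experiment helpers.
#' \code{"full"} follows the study conditions (3 x 256 hidden units, 200
#' epochs, learning rate 1e-4, 6 seeds); \code{"reduced"} is the
#' desk-scale profile used by this package's tests and examples (2 x 48
#' hidden units, shorter pretraining at a higher learning rate, 40-epoch
#' composite fine-tuning at the study's 1e-4).  The composite fine-tuning
#' temperature is 0.005 and the subtask temperature 0.02 in both.
#'
#' @param scale \code{"reduced"} or \code{"full"}.
#' @return a named list of sizes and rates.
#' @export
train_profile <- function(scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(scale = scale, hidden = c(256L, 256L, 256L), batch_size = 256L,
         warmup = 1000L, replay = 1e6, lr_pretrain = 1e-4,
         lr_finetune = 1e-4, epochs_task1 = 200L, epochs_task2 = 200L,
         epochs_composite = 200L, steps_per_epoch = 300L,
         update_interval = 1L, alpha_subtask = 0.02,
         alpha_composite = 0.005, seeds = 1:6, early_epochs = 1:20)
  } else {
    list(scale = scale, hidden = c(48L, 48L), batch_size = 256L,
         warmup = 500L, replay = 50000, lr_pretrain = 1e-3,
         lr_finetune = 1e-4, epochs_task1 = 30L, epochs_task2 = 6L,
         epochs_composite = 50L, steps_per_epoch = 300L,
         update_interval = 2L, alpha_subtask = 0.02,
         alpha_composite = 0.005, seeds = 1:3, early_epochs = 1:50)
  }
}

profile_config <- function(profile, task, seed, alpha = NULL,
                           epochs = NULL, lr = NULL) {
  ft <- task == "composite"
  sac_config(
    alpha = if (!is.null(alpha)) alpha else
      if (ft) profile$alpha_composite else profile$alpha_subtask,
    epochs = if (!is.null(epochs)) epochs else
      switch(task, task1 = profile$epochs_task1,
             task2 = profile$epochs_task2, profile$epochs_composite),
    hidden = profile$hidden, batch_size = profile$batch_size,
    warmup_steps = profile$warmup, replay_size = profile$replay,
    lr = if (!is.null(lr)) lr else
      if (ft) profile$lr_finetune else profile$lr_pretrain,
    steps_per_epoch = profile$steps_per_epoch,
    # subtask pretraining always updates every step; the profile's
    # interval applies to composite fine-tuning
    update_interval = if (ft) profile$update_interval else 1L,
    seed = seed)
}

#' Pretrain a subtask agent
#'
#' @param task \code{"task1"} or \code{"task2"}.
#' @param seed training seed.
#' @param profile a \code{\link{train_profile}}.
#' @param alpha entropy temperature override (e.g. 0 for the deterministic
#'   pretraining variant of Task 1).
#' @param env_variant optional list of \code{\link{env_config}} overrides
#'   (e.g. \code{control_init_task2 = TRUE}).
#' @return a trained \code{"sac_agent"}.
#' @export
pretrain_subtask <- function(task, seed, profile = train_profile(),
                             alpha = NULL, env_variant = list()) {
  cfg <- profile_config(profile, task, seed, alpha = alpha)
  ec <- do.call(env_config, c(list(task = task), env_variant))
  sac_train(make_env(ec, seed = seed), cfg)
}

#' Fine-tune an agent on the composite task
#'
#' @param init composed checkpoint from \code{\link{compose_q}} /
#'   \code{\link{control_init}} (or NULL to learn from scratch).
#' @param seed training seed.
#' @param profile a \code{\link{train_profile}}.
#' @param env_variant \code{\link{env_config}} overrides (e.g.
#'   \code{identical_reward_zone = TRUE}).
#' @param epochs override of the fine-tuning length.
#' @return a trained \code{"sac_agent"}.
#' @export
finetune_composite <- function(init, seed, profile = train_profile(),
                               env_variant = list(), epochs = NULL) {
  cfg <- profile_config(profile, "composite", seed, epochs = epochs)
  ec <- do.call(env_config, c(list(task = "composite"), env_variant))
  sac_train(make_env(ec, seed = seed), cfg, init = init)
}

#' Mean return over the early fine-tuning epochs
#'
#' @param agent a trained \code{"sac_agent"}.
#' @param epochs epoch window (default the profile's early window 1..20).
#' @return scalar mean return.
#' @export
early_return <- function(agent, epochs = 1:20) {
  mean(agent$epoch_returns[epochs[epochs <= length(agent$epoch_returns)]])
}

#' Classify Q-representing hidden units of an agent
#'
#' Applies the unit-classification stack to the probed hidden-unit tuning
#' of the agent's critic: space maps against the action-averaged Q (V-like
#' class), direction tuning against the local Q distribution over movement
#' directions in each unit's top-5\% spatial bins (Q-conjunctive class),
#' and lick tuning against the Q(lick)/Q(no-lick) contrast with a
#' sample-relabeling null (lick-Q class).
#'
#' @param agent a \code{"sac_agent"} (subtask or composite).
#' @param n_samples probe samples.
#' @param n_bins spatial bins per axis for the probe.
#' @param shuffles shuffle draws for each null.
#' @param q FDR level.
#' @param seed RNG seed.
#' @return list with \code{units} (unit table with logical columns
#'   \code{v_like}, \code{q_conj}, \code{q_lick}, \code{q_move}),
#'   \code{probe}, \code{q_maps}, and the raw classification tables.
#' @export
classify_agent_units <- function(agent, n_samples = 100000L, n_bins = 40L,
                                 shuffles = 1000L, q = 0.05, seed = 0L) {
  probe <- probe_units(agent, n_samples = n_samples, space_bins = n_bins,
                       direction_bins = 8L, seed = seed,
                       lick_null = shuffles, dir_null = shuffles)
  qm <- agent_q_maps(agent, n_bins = n_bins)
  alive <- apply(probe$space_map, 1, function(m) stats::sd(m) > 0)

  vl <- classify_v_like(probe$space_map, qm$v, shuffles = shuffles, q = q,
                        seed = seed + 1L)
  dn <- probe$dir_null_tunings
  qc <- classify_q_conjunctive(probe$space_map, probe$dir_tuning,
                               qm$q_move[, 1:8, drop = FALSE],
                               shuffles = shuffles, q = q, seed = seed + 2L,
                               null_tunings = function(s) dn[, , s])
  # lick comodulation: observed dot of lick tuning with the Q(lick/no-lick)
  # pair versus the probe's sample-relabeling null
  qlv <- colMeans(qm$q_lick)          # mean Q over states: (no-lick, lick)
  obs_dot <- probe$lick_tuning[, 2] * qlv[2] + probe$lick_tuning[, 1] * qlv[1]
  null_dot <- probe$lick_null_on * qlv[2] + probe$lick_null_off * qlv[1]
  p_lick <- perm_p(rowSums(null_dot >= obs_dot), ncol(null_dot))
  ql_sig <- rep(FALSE, length(p_lick))
  ql_sig[alive] <- fdr_adjust(p_lick[alive], q)

  scr <- direction_tuned_screen(probe$dir_tuning,
                                function(s) dn[, , s], shuffles)
  units <- probe$units
  units$v_like <- vl$sig & alive
  units$q_conj <- qc$sig & alive & scr$tuned
  units$q_lick <- ql_sig
  units$q_move <- units$v_like | units$q_conj
  list(units = units, probe = probe, q_maps = qm,
       v_like = vl, q_conj = qc, p_lick = p_lick, alive = alive)
}

#' Analyze a synthetic mouse-like session end to end
#'
#' Runs the GLM encoding stage on the session's activity, derives tuning
#' profiles, estimates V/Q maps from the trajectories, applies the
#' Q-representation classifiers, and scores recovery against the planted
#' ground truth.
#'
#' @param bundle a \code{\link{generate_session}} result.
#' @param sample_rate task-variable rate fed to the design matrix.
#' @param shuffles shuffle draws per null.
#' @param folds GLM cross-validation folds.
#' @param q FDR level.
#' @param conj_screen_p p threshold of the direction-tunedness screen that
#'   defines the conjunctive pool.
#' @param subtask_maps for composite sessions: optional
#'   \code{list(task1 = , task2 = )} of per-bin subtask value vectors on
#'   the 10 x 10 binning; their average is the model's composed
#'   (action-averaged) composite Q map used for mixed-representation
#'   detection.  When absent, the session's own action-averaged Q map is
#'   used.
#' @param seed RNG seed.
#' @return list with \code{fit}, \code{profiles}, \code{value_map},
#'   \code{q_map}, \code{class_table} (per-unit flags + truth),
#'   \code{recovery} (per-class sensitivity/specificity).
#' @export
analyze_session <- function(bundle, sample_rate = 2000, shuffles = 1000L,
                            folds = 5L, q = 0.05, conj_screen_p = 0.2,
                            subtask_maps = NULL, seed = 0L) {
  stopifnot(inherits(bundle, "session_bundle"))
  sv <- session_variables(bundle, sample_rate)
  design <- build_design_matrix(sv$vars, sv$duration,
                                sample_rate = sample_rate,
                                frame_rate = 5.67,
                                xlim = MOUSE_ARENA, ylim = MOUSE_ARENA)
  nf <- min(nrow(design$X), nrow(bundle$activity))
  fit <- fit_glm(design_trim(design, nf), bundle$activity[seq_len(nf), ],
                 folds = folds)
  has_space <- bundle$task != "task2"
  profiles <- list(lick = response_profile(fit, "lick_onsets"))
  if (has_space) {
    profiles$space <- response_profile(fit, "object_pos")
    profiles$dir <- response_profile(fit, "object_vel")
  }

  binning <- arena_binning(10L, MOUSE_ARENA, MOUSE_ARENA)
  out <- list(fit = fit, profiles = profiles, binning = binning)
  units <- bundle$units
  truth <- units$class

  if (has_space) {
    zone <- if (bundle$task == "task1") MOUSE_ZONE else MOUSE_TARGET
    vm <- estimate_state_values(bundle$trajectories, binning, MOUSE_GAMMA,
                                reward_zone = zone)
    qmap <- estimate_action_values(vm)
    out$value_map <- vm
    out$q_map <- qmap
    # in the composite task, Q-subtask representations are retained, so
    # V-like and Q-conjunctive classification is referenced to the Task 1
    # value/Q maps when they are supplied
    if (bundle$task == "composite" && !is.null(subtask_maps)) {
      vm_ref <- structure(list(v = subtask_maps$task1, binning = binning,
                               gamma = MOUSE_GAMMA), class = "value_map")
      q_ref_map <- estimate_action_values(vm_ref)
    } else {
      vm_ref <- vm
      q_ref_map <- qmap
    }
    vl <- classify_v_like(profiles$space, vm_ref$v, shuffles = shuffles,
                          q = q, seed = seed + 1L)
    dt <- velocity_profile_null(fit, bundle$activity[seq_len(nf), ],
                                shuffles = shuffles, seed = seed + 5L)
    # the Q-conjunctive test applies to conjunctively tuned units only:
    # direction-modulated (shuffle screen on the profile spread) and
    # space-dominant (position group EV exceeding half the velocity EV)
    scr <- direction_tuned_screen(dt$tuning, dt$nulls, dt$shuffles,
                                  p_cut = conj_screen_p)
    ev_pos <- fit$group_ev["object_pos", ]
    vel_rows <- grep("^object_vel_", rownames(fit$group_ev))
    ev_vel <- colSums(pmax(fit$group_ev[vel_rows, , drop = FALSE], 0))
    conj_pool <- scr$tuned & ev_pos > 0.02 & ev_pos > 0.5 * ev_vel
    units$q_conj <- rep(FALSE, nrow(units))
    if (any(conj_pool)) {
      pool_nulls <- function(s) dt$nulls(s)[conj_pool, , drop = FALSE]
      qc <- classify_q_conjunctive(profiles$space[conj_pool, , drop = FALSE],
                                   dt$tuning[conj_pool, , drop = FALSE],
                                   q_ref_map$q, shuffles = dt$shuffles,
                                   q = q, seed = seed + 2L,
                                   null_tunings = pool_nulls)
      units$q_conj[conj_pool] <- qc$sig
      out$q_conj <- qc
    }
    units$v_like <- vl$sig
    out$v_like <- vl; out$dir_tuning <- dt$tuning
    out$conj_pool <- conj_pool
  }
  lick_frames <- lick_onset_frames(bundle)
  if (length(lick_frames)) {
    qlk <- estimate_lick_values(bundle$trajectories, MOUSE_GAMMA)
    nf <- nrow(bundle$activity)
    ql <- classify_q_lick(bundle$activity, lick_frames[lick_frames <= nf],
                          qlk$q, frame_rate = 5.67, shuffles = shuffles,
                          q = q, seed = seed + 3L)
    units$q_lick <- ql$sig
    out$q_lick <- ql
  }
  if (bundle$task == "composite" && has_space) {
    if (!is.null(subtask_maps)) {
      mean_q <- (subtask_maps$task1 + subtask_maps$task2) / 2
    } else {
      mean_q <- rowMeans(out$q_map$q, na.rm = TRUE)
      mean_q[is.nan(mean_q)] <- NA_real_
    }
    # mixed detection runs on space-encoding units (the analyzed pool)
    space_pool <- fit$group_ev["object_pos", ] > 0.02
    units$mixed <- rep(FALSE, nrow(units))
    if (any(space_pool)) {
      mx <- detect_mixed_composite(profiles$space[space_pool, , drop = FALSE],
                                   mean_q, shuffles = shuffles, q = q,
                                   seed = seed + 4L)
      units$mixed[space_pool] <- mx$sig
      out$mixed <- mx
      out$space_pool <- space_pool
    }
  }

  out$class_table <- units
  out$recovery <- recovery_scores(units, truth)
  out
}

design_trim <- function(design, n) {
  design$X <- design$X[seq_len(n), , drop = FALSE]
  design$frame_times <- design$frame_times[seq_len(n)]
  design
}

# frames x 9 direction-occupancy weights: time spent moving in each of the
# 8 directions (or not moving) within each imaging frame
direction_occupancy <- function(bundle, frame_rate = 5.67,
                                still_threshold = 0.5) {
  df <- do.call(rbind, bundle$trajectories)
  S <- nrow(df)
  frame_len <- 1 / (frame_rate * MOUSE_DT)
  fidx <- pmin(floor((seq_len(S) - 1) / frame_len) + 1, ceiling(S / frame_len))
  sp <- sqrt(df$vx^2 + df$vy^2)
  dbin <- ifelse(sp > still_threshold,
                 (round(atan2(df$vy, df$vx) / (pi / 4)) %% 8) + 1L, 9L)
  W <- matrix(0, max(fidx), 9)
  for (k in 1:9) W[, k] <- tabulate(fidx[dbin == k], max(fidx))
  W
}

lick_onset_frames <- function(bundle, frame_rate = 5.67) {
  df <- do.call(rbind, bundle$trajectories)
  t_sess <- (seq_len(nrow(df)) - 1) * MOUSE_DT
  unique(floor(t_sess[df$lick > 0] * frame_rate) + 1L)
}

recovery_scores <- function(units, truth) {
  pairs <- c(v_like = "v_like", q_conj = "conjunctive_q",
             q_lick = "lick_q", mixed = "mixed_composite")
  rows <- lapply(names(pairs), function(fl) {
    if (is.null(units[[fl]]) || !any(truth == pairs[fl])) return(NULL)
    pos <- truth == pairs[fl]
    data.frame(classifier = fl, class = pairs[fl],
               sensitivity = mean(units[[fl]][pos], na.rm = TRUE),
               specificity = mean(!units[[fl]][!pos], na.rm = TRUE),
               n_planted = sum(pos))
  })
  do.call(rbind, rows)
}

simple_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Define an experiment plan
#'
#' @param experiment one of \code{pretrain_subtasks, compose_average,
#'   compose_max, compose_control, scratch, ablation_full, ablation_half,
#'   ablation_control, entropy_on, entropy_off, identical_zone,
#'   synthetic_mouse_task1, synthetic_mouse_task2,
#'   synthetic_mouse_composite}.
#' @param seeds seeds to run.
#' @param scale \code{"reduced"} or \code{"full"}
#'   (\code{\link{train_profile}}).
#' @param out_dir output directory (created if needed).
#' @param n_units synthetic units (mouse experiments).
#' @param n_trials trials per synthetic session (NULL for the generator
#'   default).
#' @param sample_rate task-variable sampling rate fed to the GLM design
#'   (mouse experiments).
#' @param shuffles shuffle draws for classification stages.
#' @return a list of class \code{"experiment_plan"}.
#' @export
experiment_plan <- function(experiment, seeds = NULL,
                            scale = c("reduced", "full"),
                            out_dir = tempfile("qcompose_run_"),
                            n_units = 2000L, n_trials = NULL,
                            sample_rate = 2000, shuffles = 1000L) {
  scale <- match.arg(scale)
  profile <- train_profile(scale)
  if (is.null(seeds)) seeds <- profile$seeds
  structure(list(experiment = experiment, seeds = seeds, scale = scale,
                 profile = profile, out_dir = out_dir, n_units = n_units,
                 n_trials = n_trials, sample_rate = sample_rate,
                 shuffles = shuffles),
            class = "experiment_plan")
}

#' Run an experiment plan
#'
#' Executes the stage graph of the chosen experiment and writes
#' learning-curve CSVs, classification tables and a JSON manifest
#' (experiment, seeds, profile, config hash) to the plan's output
#' directory.
#'
#' @param plan an \code{\link{experiment_plan}}.
#' @return invisibly, a result list (also summarized on disk).
#' @export
run_experiment_plan <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  dir.create(plan$out_dir, recursive = TRUE, showWarnings = FALSE)
  pr <- plan$profile
  res <- list()
  ex <- plan$experiment

  if (grepl("^synthetic_mouse_", ex)) {
    task <- sub("^synthetic_mouse_", "", ex)
    for (seed in plan$seeds) {
      bundle <- generate_session(task, "expert", n_units = plan$n_units,
                                 n_trials = plan$n_trials, seed = seed)
      sm <- NULL
      if (task == "composite") {
        binning <- arena_binning(10L, MOUSE_ARENA, MOUSE_ARENA)
        tr1 <- generate_trajectories(policy_spec("expert"), "task1", 60,
                                     seed = seed + 500L)
        sm <- list(task1 = estimate_state_values(tr1, binning, MOUSE_GAMMA,
                                                 reward_zone = MOUSE_ZONE)$v,
                   task2 = stationary_value_map(binning, c(5, 0.2), 4))
      }
      an <- analyze_session(bundle, sample_rate = plan$sample_rate,
                            shuffles = plan$shuffles, subtask_maps = sm,
                            seed = seed)
      utils::write.csv(an$class_table,
                       file.path(plan$out_dir,
                                 sprintf("classification_seed%d.csv", seed)),
                       row.names = FALSE)
      utils::write.csv(an$recovery,
                       file.path(plan$out_dir,
                                 sprintf("recovery_seed%d.csv", seed)),
                       row.names = FALSE)
      res[[as.character(seed)]] <- an$recovery
    }
  } else if (ex == "pretrain_subtasks") {
    for (seed in plan$seeds) {
      a1 <- pretrain_subtask("task1", seed, pr)
      a2 <- pretrain_subtask("task2", seed, pr)
      utils::write.csv(
        data.frame(epoch = seq_along(a1$epoch_returns),
                   task1 = a1$epoch_returns,
                   task1_disc = a1$epoch_disc_returns),
        file.path(plan$out_dir, sprintf("pretrain_task1_seed%d.csv", seed)),
        row.names = FALSE)
      utils::write.csv(
        data.frame(epoch = seq_along(a2$epoch_returns),
                   task2 = a2$epoch_returns,
                   task2_disc = a2$epoch_disc_returns),
        file.path(plan$out_dir, sprintf("pretrain_task2_seed%d.csv", seed)),
        row.names = FALSE)
      res[[as.character(seed)]] <- list(task1 = a1, task2 = a2)
    }
  } else {
    curves <- list()
    for (seed in plan$seeds) {
      ag <- run_agent_chain(ex, seed, pr, shuffles = plan$shuffles)
      curves[[as.character(seed)]] <- ag$epoch_returns
      res[[as.character(seed)]] <- ag
    }
    cm <- do.call(cbind, curves)
    colnames(cm) <- paste0("seed", plan$seeds)
    utils::write.csv(data.frame(epoch = seq_len(nrow(cm)), cm),
                     file.path(plan$out_dir,
                               paste0("fig_learning_curves_", ex, ".csv")),
                     row.names = FALSE)
  }

  manifest <- list(experiment = ex, seeds = plan$seeds, scale = plan$scale,
                   profile = pr[setdiff(names(pr), "seeds")],
                   n_units = plan$n_units, shuffles = plan$shuffles,
                   config_hash = simple_hash(pr),
                   package_version = as.character(utils::packageVersion("qcompose")))
  jsonlite::write_json(manifest, file.path(plan$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

# one agent-side experiment chain for a single seed
run_agent_chain <- function(ex, seed, pr, shuffles = 1000L) {
  if (ex == "scratch") {
    return(finetune_composite(NULL, seed, pr))
  }
  alpha1 <- if (ex == "entropy_off") 0 else NULL
  a1 <- pretrain_subtask("task1", seed, pr, alpha = alpha1)
  a2 <- pretrain_subtask("task2", seed, pr,
                         env_variant = if (ex == "compose_control")
                           list(control_init_task2 = TRUE) else list())
  init <- switch(ex,
    compose_max = compose_q(a1, a2, "max", seed = seed + 100L),
    compose_control = control_init(a1, a2, seed = seed + 100L),
    compose_q(a1, a2, "average", seed = seed + 100L))
  if (grepl("^ablation_", ex)) {
    mode <- sub("^ablation_", "", ex)
    cl1 <- classify_agent_units(a1, n_samples = 20000L, shuffles = shuffles,
                                seed = seed + 200L)
    cl2 <- classify_agent_units(a2, n_samples = 20000L, shuffles = shuffles,
                                seed = seed + 201L)
    u1 <- cl1$units[cl1$units$q_move, c("subnet", "layer", "index")]
    u2 <- cl2$units[cl2$units$q_lick, c("subnet", "layer", "index")]
    u2$subnet <- 2L
    init <- ablate(init, rbind(u1, u2), mode = mode, seed = seed + 300L)
  }
  variant <- if (ex == "identical_zone") list(identical_reward_zone = TRUE)
             else list()
  finetune_composite(init, seed, pr, env_variant = variant)
}
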
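# Soft actor-critic with twin critics, squashed-Gaussian policy, and
# composition of pretrained subtask critics by averaging or maximum.

ACT_SCALE <- c(0.1, 0.1, 0.05)   # movement in [-0.1, 0.1], lick in [0, 0.1]
ACT_OFFSET <- c(0, 0, 0.05)
STATE_DIM <- 4L                  # (x, y, vx, vy)
ACT_DIM <- 3L                    # (dx, dy, lick)
LOGSTD_MIN <- -20
LOGSTD_MAX <- 2

#' Soft actor-critic training configuration
#'
#' Defaults follow the study conditions for the agents: 3 hidden layers of
#' 256 ReLU units in both actor and critics, discount 0.95, polyak 0.995,
#' Adam with learning rate 1e-4, replay size 1e6, 300 steps per epoch for
#' 200 epochs, and a per-task entropy temperature \code{alpha} (0.02 for the
#' stochastic subtask policies, 0 for the deterministic variant, 0.005 for
#' the composite task).
#'
#' @param alpha entropy temperature (>= 0).
#' @param gamma discount factor.
#' @param epochs,steps_per_epoch training length.
#' @param replay_size replay-buffer capacity.
#' @param polyak target-network averaging coefficient in (0, 1).
#' @param lr Adam learning rate for actor and critics.
#' @param hidden integer vector of hidden-layer widths.
#' @param batch_size minibatch size per gradient update.
#' @param update_interval environment steps between update rounds.
#' @param updates_per_interval gradient updates per round (defaults give one
#'   update per environment step).
#' @param warmup_steps steps of uniform-random actions before learning.
#' @param max_episode_len episode cap (should match the environment's).
#' @param seed integer; controls network initialization, exploration noise,
#'   replay sampling and the environment stream during training.
#' @return a list of class \code{"sac_config"}.
#' @export
sac_config <- function(alpha = 0.02, gamma = 0.95,
                       epochs = 200L, steps_per_epoch = 300L,
                       replay_size = 1e6, polyak = 0.995, lr = 1e-4,
                       hidden = c(256L, 256L, 256L),
                       batch_size = 256L, update_interval = 1L,
                       updates_per_interval = 1L,
                       warmup_steps = 1000L, max_episode_len = 300L,
                       seed = 0L) {
  if (alpha < 0) stop("alpha must be >= 0")
  stopifnot(polyak > 0, polyak < 1, gamma > 0, gamma < 1,
            epochs * steps_per_epoch > warmup_steps, batch_size >= 1)
  structure(list(alpha = alpha, gamma = gamma, epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 replay_size = as.integer(replay_size), polyak = polyak,
                 lr = lr, hidden = as.integer(hidden),
                 batch_size = as.integer(batch_size),
                 update_interval = as.integer(update_interval),
                 updates_per_interval = as.integer(updates_per_interval),
                 warmup_steps = as.integer(warmup_steps),
                 max_episode_len = as.integer(max_episode_len),
                 seed = as.integer(seed)),
            class = "sac_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# sample actions from the squashed-Gaussian policy; xi is the standard-normal
# reparameterization noise (n x ACT_DIM)
actor_sample <- function(actor, S, xi = NULL, deterministic = FALSE,
                         cache = FALSE) {
  fw <- mlp_forward(actor, S, cache = cache)
  out <- if (cache) fw$out else fw
  m <- ACT_DIM
  mu <- out[, 1:m, drop = FALSE]
  lsr <- out[, m + 1:m, drop = FALSE]
  ls <- pmin(pmax(lsr, LOGSTD_MIN), LOGSTD_MAX)
  if (deterministic) {
    u <- mu
  } else {
    if (is.null(xi)) xi <- matrix(stats::rnorm(nrow(S) * m), nrow(S), m)
    u <- mu + exp(ls) * xi
  }
  th <- tanh(u)
  a <- rep(ACT_OFFSET, each = nrow(S)) + rep(ACT_SCALE, each = nrow(S)) * th
  logp <- NULL
  if (!deterministic) {
    logp <- rowSums(-0.5 * xi^2 - ls - 0.5 * log(2 * pi)) -
      rowSums(2 * (log(2) - u - softplus(-2 * u)))
  }
  list(a = a, logp = logp, mu = mu, ls = ls, lsr = lsr, u = u, th = th,
       fw = if (cache) fw else NULL)
}

new_actor <- function(hidden) mlp_init(c(STATE_DIM, hidden, 2L * ACT_DIM))

new_critic <- function(hidden) {
  critic_single(mlp_init(c(STATE_DIM + ACT_DIM, hidden, 1L)))
}

replay_init <- function(cap) {
  list(S = matrix(0, cap, STATE_DIM), A = matrix(0, cap, ACT_DIM),
       R = numeric(cap), S2 = matrix(0, cap, STATE_DIM),
       D = numeric(cap), ptr = 0L, size = 0L, cap = as.integer(cap))
}

#' Train a soft actor-critic agent
#'
#' Two critics are trained independently against the soft Bellman target and
#' the minimum of the two is used in the policy-improvement step; target
#' networks track the online critics by polyak averaging; the optimizer is
#' Adam.  Passing a composed checkpoint as \code{init} fine-tunes it:
#' gradients flow into both subtask critic subnetworks through the combining
#' operator, and ablation masks persist.
#'
#' @param env an \code{"arena_env"} (its random stream is reseeded from
#'   \code{config$seed} so a run is fully determined by the config).
#' @param config a \code{\link{sac_config}}.
#' @param init optional \code{"sac_agent"} used as the starting point
#'   (e.g. the output of \code{\link{compose_q}}).
#' @param verbose print per-epoch mean returns.
#' @return an object of class \code{"sac_agent"} with elements
#'   \code{actor}, \code{critics}, \code{targets}, \code{config},
#'   \code{composition}, and \code{epoch_returns} (per-epoch mean episode
#'   return, the learning curve).
#' @export
sac_train <- function(env, config, init = NULL, verbose = FALSE) {
  stopifnot(inherits(env, "arena_env"), inherits(config, "sac_config"))
  stream <- make_rng(config$seed)
  env$rng <- make_rng(config$seed + 1000003L)

  if (is.null(init)) {
    with_stream(stream, {
      actor <- new_actor(config$hidden)
      q1 <- new_critic(config$hidden)
      q2 <- new_critic(config$hidden)
    })
    composition <- list(method = "none")
  } else {
    stopifnot(inherits(init, "sac_agent"))
    actor <- init$actor
    q1 <- init$critics[[1]]
    q2 <- init$critics[[2]]
    composition <- init$composition
  }
  t1 <- q1; t2 <- q2
  a_opt <- adam_init(net_params(actor))
  c_opt <- adam_init(c(critic_params(q1), critic_params(q2)))
  buf <- replay_init(config$replay_size)
  alpha <- config$alpha; gamma <- config$gamma

  do_update <- function() {
    n <- config$batch_size
    idx <- with_stream(stream, sample.int(buf$size, n, replace = TRUE))
    S <- buf$S[idx, , drop = FALSE]; A <- buf$A[idx, , drop = FALSE]
    R <- buf$R[idx]; S2 <- buf$S2[idx, , drop = FALSE]; D <- buf$D[idx]
    xi2 <- with_stream(stream, matrix(stats::rnorm(n * ACT_DIM), n, ACT_DIM))
    as2 <- actor_sample(actor, S2, xi = xi2)
    q1t <- critic_forward(t1, cbind(S2, as2$a))
    q2t <- critic_forward(t2, cbind(S2, as2$a))
    y <- R + gamma * (1 - D) * (pmin(q1t, q2t) - alpha * as2$logp)

    X <- cbind(S, A)
    f1 <- critic_forward(q1, X, cache = TRUE)
    f2 <- critic_forward(q2, X, cache = TRUE)
    e1 <- f1$out - y; e2 <- f2$out - y
    closs <- mean(e1^2) + mean(e2^2)
    if (!is.finite(closs)) stop("critic loss became non-finite; training aborted")
    bk1 <- critic_backward(q1, f1, matrix(2 * e1 / n))
    bk2 <- critic_backward(q2, f2, matrix(2 * e2 / n))
    st <- adam_step(c(critic_params(q1), critic_params(q2)),
                    c(critic_grads_flat(q1, bk1), critic_grads_flat(q2, bk2)),
                    c_opt, config$lr)
    c_opt <<- st$state
    np1 <- length(critic_params(q1))
    q1 <<- critic_set_params(q1, st$params[seq_len(np1)])
    q2 <<- critic_set_params(q2, st$params[np1 + seq_len(np1)])

    # actor update: maximize E[ min_i Q_i(s, a(s)) - alpha * log pi(a|s) ]
    xi <- with_stream(stream, matrix(stats::rnorm(n * ACT_DIM), n, ACT_DIM))
    as1 <- actor_sample(actor, S, xi = xi, cache = TRUE)
    Xa <- cbind(S, as1$a)
    g1 <- critic_forward(q1, Xa, cache = TRUE)
    g2 <- critic_forward(q2, Xa, cache = TRUE)
    w1 <- (g1$out <= g2$out) * 1
    dA1 <- critic_backward(q1, g1, matrix(-w1 / n), need_dX = TRUE)$dX
    dA2 <- critic_backward(q2, g2, matrix(-(1 - w1) / n), need_dX = TRUE)$dX
    dAenv <- (dA1 + dA2)[, STATE_DIM + 1:ACT_DIM, drop = FALSE]
    dlogp <- alpha / n
    du <- dlogp * 2 * as1$th +
      dAenv * rep(ACT_SCALE, each = n) * (1 - as1$th^2)
    dmu <- du
    dls <- du * (as1$u - as1$mu) - dlogp
    dlsr <- dls * (as1$lsr > LOGSTD_MIN & as1$lsr < LOGSTD_MAX)
    ga <- mlp_backward(actor, as1$fw, cbind(dmu, dlsr))
    st <- adam_step(net_params(actor), c(ga$gW, ga$gb), a_opt, config$lr)
    a_opt <<- st$state
    actor <<- net_set_params(actor, st$params)

    t1 <<- critic_set_params(t1, polyak_update(critic_params(t1),
                                               critic_params(q1), config$polyak))
    t2 <<- critic_set_params(t2, polyak_update(critic_params(t2),
                                               critic_params(q2), config$polyak))
    invisible(NULL)
  }

  epoch_returns <- rep(NA_real_, config$epochs)
  epoch_disc_returns <- rep(NA_real_, config$epochs)
  st <- env_reset(env)
  ep_ret <- 0
  ep_disc <- 0
  ep_len <- 0L
  total <- 0L
  for (epoch in seq_len(config$epochs)) {
    rets <- numeric(0)
    drets <- numeric(0)
    for (k in seq_len(config$steps_per_epoch)) {
      total <- total + 1L
      sv <- matrix(c(st$position, st$velocity), 1L)
      if (total <= config$warmup_steps) {
        act <- with_stream(stream, c(stats::runif(2, -0.1, 0.1),
                                     stats::runif(1, 0, 0.1)))
      } else {
        xi <- with_stream(stream, matrix(stats::rnorm(ACT_DIM), 1L))
        act <- as.numeric(actor_sample(actor, sv, xi = xi)$a)
      }
      res <- env_step(env, act)
      p <- buf$ptr %% buf$cap + 1L
      buf$S[p, ] <- sv
      buf$A[p, ] <- act
      buf$R[p] <- res$reward
      buf$S2[p, ] <- c(res$state$position, res$state$velocity)
      buf$D[p] <- as.numeric(res$done && !res$info$truncated)
      buf$ptr <- p; buf$size <- min(buf$size + 1L, buf$cap)
      ep_ret <- ep_ret + res$reward
      ep_len <- ep_len + 1L
      ep_disc <- ep_disc + gamma^(ep_len - 1L) * res$reward
      if (res$done) {
        rets <- c(rets, ep_ret)
        drets <- c(drets, ep_disc)
        ep_ret <- 0; ep_disc <- 0; ep_len <- 0L
        st <- env_reset(env)
      } else {
        st <- res$state
      }
      if (total > config$warmup_steps && buf$size >= config$batch_size &&
          total %% config$update_interval == 0L) {
        for (u in seq_len(config$updates_per_interval)) do_update()
      }
    }
    epoch_returns[epoch] <- if (length(rets)) mean(rets) else NA_real_
    epoch_disc_returns[epoch] <- if (length(drets)) mean(drets) else NA_real_
    if (verbose) {
      message(sprintf("epoch %d: mean return %.3f", epoch, epoch_returns[epoch]))
    }
  }
  # epochs in which no episode terminated inherit the previous epoch's value
  for (i in seq_along(epoch_returns)) {
    if (is.na(epoch_returns[i]) && i > 1) {
      epoch_returns[i] <- epoch_returns[i - 1]
      epoch_disc_returns[i] <- epoch_disc_returns[i - 1]
    }
  }
  epoch_returns[is.na(epoch_returns)] <- 0
  epoch_disc_returns[is.na(epoch_disc_returns)] <- 0

  structure(list(actor = actor, critics = list(q1, q2),
                 targets = list(t1, t2), config = config,
                 env_config = env$config, composition = composition,
                 epoch_returns = epoch_returns,
                 epoch_disc_returns = epoch_disc_returns),
            class = "sac_agent")
}

#' Compose two pretrained subtask critics into a composite agent
#'
#' The composite critic evaluates both subtask critic subnetworks on the
#' shared (state, action) input and combines their scalar outputs by the
#' elementwise mean (so that at initialization the composite Q is exactly
#' the arithmetic average of the two subtask Q functions) or by the
#' elementwise maximum.  Both members of the twin-critic pair are composed
#' pairwise.  The actor is freshly initialized; fine-tuning it against the
#' composed critic with \code{\link{sac_train}} lets gradients flow into
#' both subnetworks.
#'
#' @param ckpt1,ckpt2 trained \code{"sac_agent"} checkpoints with matching
#'   architecture (e.g. Task 1 and Task 2).
#' @param method \code{"average"} or \code{"max"}.
#' @param seed seed for the fresh actor's initialization.
#' @return an untrained composite \code{"sac_agent"}.
#' @export
compose_q <- function(ckpt1, ckpt2, method = c("average", "max"), seed = 0L) {
  method <- match.arg(method)
  stopifnot(inherits(ckpt1, "sac_agent"), inherits(ckpt2, "sac_agent"))
  if (!identical(ckpt1$config$hidden, ckpt2$config$hidden)) {
    stop("checkpoint architectures do not match")
  }
  nets1 <- lapply(ckpt1$critics, function(cr) critic_nets(cr)[[1]])
  nets2 <- lapply(ckpt2$critics, function(cr) critic_nets(cr)[[1]])
  critics <- list(critic_composite(nets1[[1]], nets2[[1]], method),
                  critic_composite(nets1[[2]], nets2[[2]], method))
  stream <- make_rng(seed)
  actor <- with_stream(stream, new_actor(ckpt1$config$hidden))
  structure(list(actor = actor, critics = critics, targets = critics,
                 config = ckpt1$config, env_config = NULL,
                 composition = list(method = method,
                                    sources = c("ckpt1", "ckpt2")),
                 epoch_returns = numeric(0)),
            class = "sac_agent")
}

#' Control-initialized composite agent
#'
#' Composes (by averaging) a Task 1 checkpoint with a checkpoint trained on
#' the modified Task 2 in which the agent sits at the top-middle of the
#' arena.  This construction keeps the mean composite Q over uniformly
#' sampled states and actions comparable to the genuine composite while
#' removing the useful Task 2 value structure.  When \code{reference} (a
#' genuine average-composed agent) is supplied, the mean-Q comparability is
#' probed on \code{n_check} uniform (s, a) samples and a warning recorded if
#' the two differ by more than 10\%.
#'
#' @param ckpt1 Task 1 checkpoint.
#' @param ckpt2_modified checkpoint trained on the \code{control_init_task2}
#'   environment variant.
#' @param reference optional average-composed \code{"sac_agent"}.
#' @param n_check number of uniform probe samples for the mean-Q check.
#' @param seed actor-initialization / probe seed.
#' @return a composite \code{"sac_agent"} with composition method
#'   \code{"control_init"}; attribute \code{"mean_q_check"} holds the probe.
#' @export
control_init <- function(ckpt1, ckpt2_modified, reference = NULL,
                         n_check = 100000L, seed = 0L) {
  ag <- compose_q(ckpt1, ckpt2_modified, method = "average", seed = seed)
  ag$composition$method <- "control_init"
  if (!is.null(reference)) {
    X <- uniform_sa_samples(n_check, seed + 7L)
    m_ctrl <- mean(critic_forward(ag$critics[[1]], X))
    m_ref <- mean(critic_forward(reference$critics[[1]], X))
    rel <- abs(m_ctrl - m_ref) / max(abs(m_ref), 1e-12)
    attr(ag, "mean_q_check") <- c(mean_q_control = m_ctrl,
                                  mean_q_reference = m_ref, rel_diff = rel)
    if (rel > 0.10) {
      warning(sprintf(
        "mean-Q comparability check failed: control %.4f vs reference %.4f (%.1f%% apart)",
        m_ctrl, m_ref, 100 * rel))
    }
  }
  ag
}

uniform_sa_samples <- function(n, seed) {
  stream <- make_rng(seed)
  with_stream(stream, cbind(
    stats::runif(n, -1, 1), stats::runif(n, -1, 1),
    stats::runif(n, -0.1, 0.1), stats::runif(n, -0.1, 0.1),
    stats::runif(n, -0.1, 0.1), stats::runif(n, -0.1, 0.1),
    stats::runif(n, 0, 0.1)))
}

total_hidden_units <- function(agent) {
  n_sub <- length(critic_nets(agent$critics[[1]]))
  n_sub * sum(agent$config$hidden)
}

#' Ablate hidden units of the Q networks
#'
#' Forces the activations of the selected hidden units to zero in the
#' forward pass of both twin critics (and their targets); the masks persist
#' through subsequent fine-tuning.  Units are identified by
#' \code{(subnet, layer, index)}: \code{subnet} is 1 for a plain critic or
#' the subtask-subnetwork number (1 or 2) of a composite critic.
#'
#' @param agent a \code{"sac_agent"}.
#' @param unit_ids data.frame with integer columns \code{subnet},
#'   \code{layer}, \code{index} (e.g. the Q-representing units found by
#'   \code{\link{classify_agent_units}}).
#' @param mode \code{"full"} ablates all listed units, \code{"half"} a
#'   random half, \code{"control"} an equal count of units drawn from the
#'   complement of the listed set.
#' @param seed RNG seed for the half/control draws.
#' @return the agent with ablation masks applied; \code{$ablation} records
#'   the ablated units.
#' @export
ablate <- function(agent, unit_ids, mode = c("full", "half", "control"),
                   seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(agent, "sac_agent"),
            all(c("subnet", "layer", "index") %in% names(unit_ids)))
  hidden <- agent$config$hidden
  n_sub <- length(critic_nets(agent$critics[[1]]))
  if (any(unit_ids$subnet < 1 | unit_ids$subnet > n_sub) ||
      any(unit_ids$layer < 1 | unit_ids$layer > length(hidden)) ||
      any(unit_ids$index < 1 | unit_ids$index > hidden[unit_ids$layer])) {
    stop("unit_ids outside the hidden-unit range of this agent")
  }
  if (nrow(unit_ids) > total_hidden_units(agent)) {
    stop("more units requested than exist")
  }
  all_units <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
    do.call(rbind, lapply(seq_along(hidden), function(l) {
      data.frame(subnet = s, layer = l, index = seq_len(hidden[l]))
    }))
  }))
  key <- function(df) paste(df$subnet, df$layer, df$index)
  stream <- make_rng(seed)
  sel <- switch(mode,
    full = unit_ids,
    half = with_stream(stream,
      unit_ids[sample.int(nrow(unit_ids), ceiling(nrow(unit_ids) / 2)), ]),
    control = {
      pool <- all_units[!(key(all_units) %in% key(unit_ids)), ]
      if (nrow(pool) < nrow(unit_ids)) stop("control pool smaller than ablation set")
      with_stream(stream, pool[sample.int(nrow(pool), nrow(unit_ids)), ])
    })
  masks <- lapply(seq_len(n_sub), function(s) {
    m <- lapply(hidden, function(w) rep(1, w))
    ss <- sel[sel$subnet == s, , drop = FALSE]
    for (i in seq_len(nrow(ss))) m[[ss$layer[i]]][ss$index[i]] <- 0
    m
  })
  apply_masks <- function(cr) {
    nets <- critic_nets(cr)
    for (s in seq_along(nets)) nets[[s]]$mask <- masks[[s]]
    critic_set_nets(cr, nets)
  }
  agent$critics <- lapply(agent$critics, apply_masks)
  agent$targets <- lapply(agent$targets, apply_masks)
  agent$ablation <- list(mode = mode, units = sel)
  agent
}

#' Probe hidden-unit tuning of the Q networks
#'
#' Feeds uniformly distributed random state and action inputs through the
#' first twin critic and records every hidden unit's post-activation output.
#' Space maps average unit activity on an \code{space_bins} x
#' \code{space_bins} grid of the arena; direction tuning averages activity
#' within 8 movement-angle sectors of the sampled action.
#'
#' @param agent a \code{"sac_agent"}.
#' @param n_samples number of uniform (state, action) samples (>= 10000).
#' @param space_bins spatial bins per axis (default 40).
#' @param direction_bins number of movement-direction sectors.
#' @param seed sampling seed.
#' @param lick_null if > 0, also compute that many null lick tunings per
#'   unit by randomly relabeling the probe samples as lick/no-lick with
#'   the true lick-event probability (the permutation null for lick
#'   comodulation tests).
#' @param dir_null if > 0, also compute that many null direction tunings
#'   per unit by randomly relabeling the probe samples' movement
#'   directions (the direction-shuffle null).
#' @return a list of class \code{"unit_probe"}: \code{units} (table of
#'   subnet/layer/index), \code{space_map} (units x bins^2, row-major in y
#'   within x), \code{dir_tuning} (units x direction_bins),
#'   \code{lick_tuning} (units x 2: no-lick, lick), plus the matching
#'   critic-output maps \code{q_space}, \code{q_dir}, \code{q_lick}, and
#'   (when requested) \code{lick_null_on} / \code{lick_null_off}
#'   (units x lick_null).
#' @export
probe_units <- function(agent, n_samples = 100000L, space_bins = 40L,
                        direction_bins = 8L, seed = 0L, lick_null = 0L,
                        dir_null = 0L) {
  stopifnot(n_samples >= 10000)
  X <- uniform_sa_samples(n_samples, seed)
  cr <- agent$critics[[1]]
  nets <- critic_nets(cr)
  hidden <- agent$config$hidden

  brk <- seq(-1, 1, length.out = space_bins + 1)
  bx <- pmin(pmax(findInterval(X[, 1], brk, rightmost.closed = TRUE), 1), space_bins)
  by <- pmin(pmax(findInterval(X[, 2], brk, rightmost.closed = TRUE), 1), space_bins)
  sbin <- (bx - 1L) * space_bins + by
  ang <- atan2(X[, 6], X[, 5])
  dbin <- (round(ang / (2 * pi / direction_bins)) %% direction_bins) + 1L
  lick_ev <- X[, 7] > 0.08

  units <- do.call(rbind, lapply(seq_along(nets), function(s) {
    do.call(rbind, lapply(seq_along(hidden), function(l) {
      data.frame(subnet = s, layer = l, index = seq_len(hidden[l]))
    }))
  }))
  n_units <- nrow(units)
  sp_sum <- matrix(0, space_bins^2, n_units)
  di_sum <- matrix(0, direction_bins, n_units)
  li_sum <- matrix(0, 2, n_units)
  sp_cnt <- tabulate(sbin, space_bins^2)
  di_cnt <- tabulate(dbin, direction_bins)
  li_cnt <- c(sum(!lick_ev), sum(lick_ev))
  q_sp <- numeric(space_bins^2); q_di <- numeric(direction_bins); q_li <- numeric(2)
  p_lick <- mean(lick_ev)
  null_stream <- make_rng(seed + 97L)
  ns_on <- if (lick_null > 0) matrix(0, n_units, lick_null) else NULL
  n_on <- numeric(lick_null)
  tot_sum <- numeric(n_units)
  ns_dir <- if (dir_null > 0) matrix(0, n_units, direction_bins * dir_null) else NULL
  n_dir <- numeric(direction_bins * dir_null)

  chunk <- 20000L
  starts <- seq(1L, n_samples, by = chunk)
  for (st in starts) {
    ii <- st:min(st + chunk - 1L, n_samples)
    Ac <- NULL
    for (s in seq_along(nets)) {
      fw <- mlp_forward(nets[[s]], X[ii, , drop = FALSE], cache = TRUE)
      Ac <- cbind(Ac, do.call(cbind, fw$hs))
      if (s == 1) qout <- fw$out else qout2 <- fw$out
    }
    qv <- if (length(nets) == 1) qout else {
      if (cr$op == "max") pmax(qout, qout2) else (qout + qout2) / 2
    }
    sp_sum <- sp_sum + rowsum_mat(Ac, sbin[ii], space_bins^2)
    di_sum <- di_sum + rowsum_mat(Ac, dbin[ii], direction_bins)
    li_sum <- li_sum + rowsum_mat(Ac, lick_ev[ii] + 1L, 2L)
    q_sp <- q_sp + rowsum_mat(qv, sbin[ii], space_bins^2)
    q_di <- q_di + rowsum_mat(qv, dbin[ii], direction_bins)
    q_li <- q_li + rowsum_mat(qv, lick_ev[ii] + 1L, 2L)
    if (lick_null > 0) {
      tot_sum <- tot_sum + colSums(Ac)
      for (ss in seq(1L, lick_null, by = 250L)) {
        kk <- ss:min(ss + 249L, lick_null)
        M <- with_stream(null_stream,
          (matrix(stats::runif(length(ii) * length(kk)),
                  length(ii)) < p_lick) * 1)
        ns_on[, kk] <- ns_on[, kk] + crossprod(Ac, M)
        n_on[kk] <- n_on[kk] + colSums(M)
      }
    }
    if (dir_null > 0) {
      len <- length(ii)
      for (s in seq_len(dir_null)) {
        lab <- with_stream(null_stream,
                           sample.int(direction_bins, len, replace = TRUE))
        I <- matrix(0, len, direction_bins)
        I[cbind(seq_len(len), lab)] <- 1
        cols <- (s - 1L) * direction_bins + seq_len(direction_bins)
        ns_dir[, cols] <- ns_dir[, cols] + crossprod(Ac, I)
        n_dir[cols] <- n_dir[cols] + colSums(I)
      }
    }
  }
  safe_div <- function(S, cnt) S / pmax(cnt, 1)
  lick_null_on <- lick_null_off <- NULL
  if (lick_null > 0) {
    lick_null_on <- sweep(ns_on, 2, pmax(n_on, 1), "/")
    lick_null_off <- sweep(matrix(tot_sum, n_units, lick_null) - ns_on, 2,
                           pmax(n_samples - n_on, 1), "/")
  }
  dir_null_tunings <- NULL
  if (dir_null > 0) {
    nt <- sweep(ns_dir, 2, pmax(n_dir, 1), "/")
    dir_null_tunings <- array(nt, c(n_units, direction_bins, dir_null))
  }
  structure(list(lick_null_on = lick_null_on, lick_null_off = lick_null_off,
                 dir_null_tunings = dir_null_tunings,
                 units = units,
                 space_map = t(safe_div(sp_sum, sp_cnt)),
                 dir_tuning = t(safe_div(di_sum, di_cnt)),
                 lick_tuning = t(safe_div(li_sum, li_cnt)),
                 q_space = as.numeric(safe_div(q_sp, sp_cnt)),
                 q_dir = as.numeric(safe_div(q_di, di_cnt)),
                 q_lick = as.numeric(safe_div(q_li, li_cnt)),
                 space_bins = space_bins, direction_bins = direction_bins),
            class = "unit_probe")
}

# rowsum over an index in 1..nbins with fixed output size
rowsum_mat <- function(M, idx, nbins) {
  M <- as.matrix(M)
  out <- matrix(0, nbins, ncol(M))
  rs <- rowsum(M, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Q maps of an agent's critic on a state/action grid
#'
#' Evaluates the (twin-minimum) critic on the centers of an
#' \code{n_bins} x \code{n_bins} grid with zero velocity, for 8 full-speed
#' movement directions plus no movement (at zero lick), and for lick versus
#' no lick (at no movement).
#'
#' @param agent a \code{"sac_agent"}.
#' @param n_bins spatial bins per axis.
#' @param subnet \code{NULL} for the full critic (composite operator applied)
#'   or a subnetwork number to read one subtask critic of a composite.
#' @return list with \code{q_move} (bins^2 x 9: 8 directions then none),
#'   \code{q_lick} (bins^2 x 2: no-lick, lick), \code{v} (action-averaged
#'   \code{q_move}), \code{centers}, \code{n_bins}.
#' @export
agent_q_maps <- function(agent, n_bins = 40L, subnet = NULL) {
  ctr <- seq(-1 + 1 / n_bins, 1 - 1 / n_bins, length.out = n_bins)
  grid <- as.matrix(expand.grid(y = ctr, x = ctr))[, c("x", "y")]
  nb2 <- n_bins^2
  angs <- (0:7) * pi / 4
  moves <- rbind(cbind(0.1 * cos(angs), 0.1 * sin(angs)), c(0, 0))
  fwd <- function(A) {
    X <- cbind(grid, 0, 0, matrix(A, nb2, length(A), byrow = TRUE))
    q <- lapply(agent$critics, function(cr) {
      if (!is.null(subnet) && cr$kind == "composite") {
        mlp_forward(cr$nets[[subnet]], X)
      } else critic_forward(cr, X)
    })
    pmin(q[[1]], q[[2]])
  }
  q_move <- sapply(seq_len(nrow(moves)), function(i) fwd(c(moves[i, ], 0)))
  q_lick <- cbind(fwd(c(0, 0, 0)), fwd(c(0, 0, 0.09)))
  list(q_move = q_move, q_lick = q_lick, v = rowMeans(q_move),
       centers = ctr, n_bins = n_bins)
}

#' Evaluate a trained agent
#'
#' Generates episodes by iterating the (frozen) policy from the
#' environment's initial states, until a reward is obtained (hit) or the
#' episode cap elapses (miss).
#'
#' @param agent a \code{"sac_agent"}.
#' @param env an \code{"arena_env"}.
#' @param n_episodes number of episodes (study default 3000).
#' @param deterministic if \code{TRUE}, use the mean action instead of
#'   sampling from the policy.
#' @param seed seed for the environment resets and policy noise.
#' @return a list of episode \code{data.frame}s
#'   (\code{t, x, y, dx, dy, lick, reward, done}) of class
#'   \code{"trajectory_set"}; attribute \code{"hit"} flags rewarded episodes.
#' @export
evaluate_agent <- function(agent, env, n_episodes = 3000L,
                           deterministic = FALSE, seed = 0L) {
  stream <- make_rng(seed + 13L)
  env$rng <- make_rng(seed)
  policy <- function(sv) {
    xi <- if (deterministic) NULL else
      with_stream(stream, matrix(stats::rnorm(ACT_DIM), 1L))
    as.numeric(actor_sample(agent$actor, matrix(sv, 1L), xi = xi,
                            deterministic = deterministic)$a)
  }
  eps <- vector("list", n_episodes)
  hit <- logical(n_episodes)
  for (i in seq_len(n_episodes)) {
    tr <- run_episode(env, policy)
    eps[[i]] <- tr
    hit[i] <- sum(tr$reward) > 0
  }
  structure(eps, class = "trajectory_set", hit = hit,
            task = env$config$task, halfwidth = env$config$arena_halfwidth)
}

#' @export
print.sac_agent <- function(x, ...) {
  cat("Soft actor-critic agent\n")
  cat(sprintf("  hidden layers: %s; alpha = %g; gamma = %g\n",
              paste(x$config$hidden, collapse = "x"),
              x$config$alpha, x$config$gamma))
  cat(sprintf("  composition: %s\n", x$composition$method))
  if (length(x$epoch_returns)) {
    cat(sprintf("  trained %d epochs; final mean return %.3f\n",
                length(x$epoch_returns), utils::tail(x$epoch_returns, 1)))
  } else cat("  untrained (no epochs run)\n")
  if (!is.null(x$ablation)) {
    cat(sprintf("  ablation: %s (%d units)\n", x$ablation$mode,
                nrow(x$ablation$units)))
  }
  invisible(x)
}

#' @export
plot.sac_agent <- function(x, ...) {
  graphics::plot(seq_along(x$epoch_returns), x$epoch_returns, type = "l",
                 xlab = "epoch", ylab = "mean episode return", ...)
  invisible(x)
}

#' Action of the policy at given states
#'
#' @param object a \code{"sac_agent"}.
#' @param states numeric vector \code{c(x, y, vx, vy)} or a matrix of rows.
#' @param deterministic use the policy mean (default) or sample.
#' @param seed noise seed when sampling.
#' @param ... unused.
#' @return a matrix of actions \code{(dx, dy, lick)}.
#' @export
predict.sac_agent <- function(object, states, deterministic = TRUE,
                              seed = 0L, ...) {
  S <- if (is.null(dim(states))) matrix(states, 1L) else as.matrix(states)
  xi <- NULL
  if (!deterministic) {
    stream <- make_rng(seed)
    xi <- with_stream(stream, matrix(stats::rnorm(nrow(S) * ACT_DIM),
                                     nrow(S), ACT_DIM))
  }
  out <- actor_sample(object$actor, S, xi = xi,
                      deterministic = deterministic)$a
  colnames(out) <- c("dx", "dy", "lick")
  out
}
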
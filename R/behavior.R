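# Behavioral value and policy estimation from trajectories, for agents
# (step-indexed episodes on the [-1,1]^2 arena) and mouse-like data
# (10-ms-sampled trials on a 10 x 10 cm arena).  Values follow the
# terminal-reward simplification V(s) = E[gamma^(T-t)] with the reward-zone
# value pinned at 1, and Q(s,a) = gamma * V(neighbor(s,a)) on the binned
# arena.

#' Arena binning
#'
#' @param n_bins bins per axis (10 for value/policy analyses, 40 for
#'   network-unit tuning).
#' @param xlim,ylim arena extent.
#' @return an object of class \code{"arena_binning"}.
#' @export
arena_binning <- function(n_bins = 10L, xlim = c(-1, 1), ylim = xlim) {
  stopifnot(n_bins >= 2, diff(xlim) > 0, diff(ylim) > 0)
  structure(list(n_bins = as.integer(n_bins), xlim = xlim, ylim = ylim),
            class = "arena_binning")
}

#' Bin index of positions
#'
#' Bins are numbered 1..n_bins^2, x-major (all y bins of the first x column
#' first); positions on the upper edges fall in the last bin.
#'
#' @param binning an \code{\link{arena_binning}}.
#' @param x,y coordinates.
#' @return integer bin indices (NA outside the arena).
#' @export
bin_index <- function(binning, x, y) {
  n <- binning$n_bins
  bx <- floor((x - binning$xlim[1]) / diff(binning$xlim) * n) + 1L
  by <- floor((y - binning$ylim[1]) / diff(binning$ylim) * n) + 1L
  bx[x == binning$xlim[2]] <- n
  by[y == binning$ylim[2]] <- n
  ok <- bx >= 1L & bx <= n & by >= 1L & by <= n
  out <- rep(NA_integer_, length(x))
  out[ok] <- (bx[ok] - 1L) * n + by[ok]
  out
}

#' Bin centers
#' @param binning an \code{\link{arena_binning}}.
#' @return a (n_bins^2 x 2) matrix of bin-center coordinates, in bin order.
#' @export
bin_centers <- function(binning) {
  n <- binning$n_bins
  cx <- binning$xlim[1] + (seq_len(n) - 0.5) * diff(binning$xlim) / n
  cy <- binning$ylim[1] + (seq_len(n) - 0.5) * diff(binning$ylim) / n
  cbind(x = rep(cx, each = n), y = rep(cy, times = n))
}

as_traj_list <- function(trajectories) {
  if (is.data.frame(trajectories)) list(trajectories) else trajectories
}

traj_is_hit <- function(tr) "reward" %in% names(tr) && sum(tr$reward) > 0

#' Estimate the state-value map from trajectories
#'
#' For every visit at time t of a rewarded (hit) trajectory ending at time
#' T, the visit contributes gamma^(T - t); V of a bin is the mean over all
#' its visits.  Time is measured in samples (rows), so gamma is the
#' per-sample discount (0.95 per step for agents, 0.99 per 10 ms for
#' mouse-like data).  Miss trials carry no terminal reward and are excluded
#' (recorded in the result).  Bins whose center lies in \code{reward_zone}
#' are set to 1 exactly.
#'
#' @param trajectories a trajectory \code{data.frame} (columns
#'   \code{x, y, reward}) or a list of them.
#' @param binning an \code{\link{arena_binning}}.
#' @param gamma per-sample discount in (0, 1).
#' @param reward_zone optional \code{c(xmin, xmax, ymin, ymax)}.
#' @return an object of class \code{"value_map"}: \code{v} (length
#'   n_bins^2, NA where unvisited), \code{visits}, \code{binning},
#'   \code{gamma}, \code{n_hit}, \code{n_miss}.
#' @export
estimate_state_values <- function(trajectories, binning, gamma,
                                  reward_zone = NULL) {
  stopifnot(gamma > 0, gamma < 1, inherits(binning, "arena_binning"))
  trs <- as_traj_list(trajectories)
  if (!length(trs)) stop("at least one trajectory is required")
  nb <- binning$n_bins^2
  sums <- numeric(nb); cnt <- numeric(nb)
  n_hit <- 0L; n_miss <- 0L
  for (tr in trs) {
    if (!traj_is_hit(tr)) { n_miss <- n_miss + 1L; next }
    n_hit <- n_hit + 1L
    Tend <- max(which(tr$reward > 0))
    tt <- seq_len(Tend)
    b <- bin_index(binning, tr$x[tt], tr$y[tt])
    w <- gamma^(Tend - tt)
    ok <- !is.na(b)
    sums <- sums + rowsum_vec(w[ok], b[ok], nb)
    cnt <- cnt + tabulate(b[ok], nb)
  }
  v <- ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_)
  if (!is.null(reward_zone)) {
    ctr <- bin_centers(binning)
    inz <- in_rect(ctr[, 1], ctr[, 2], reward_zone)
    v[inz] <- 1
  }
  structure(list(v = v, visits = cnt, binning = binning, gamma = gamma,
                 reward_zone = reward_zone, n_hit = n_hit, n_miss = n_miss),
            class = "value_map")
}

rowsum_vec <- function(x, idx, nbins) {
  out <- numeric(nbins)
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs))] <- rs
  out
}

# direction labels: 8 sectors counterclockwise from east, plus no movement
DIR_ANGLES <- (0:7) * 45
DIR_LABELS <- c(paste0("d", DIR_ANGLES), "none")

#' Derive the action-value map from a state-value map
#'
#' Q(s, a) = gamma * V(s') where s' is the adjacent bin in the direction of
#' a (8 directions, 45 degrees apart); for the no-movement action, or when
#' the movement would exit the arena, s' is the same bin.  Q is NA where
#' the needed V is undefined (unvisited).
#'
#' @param value_map a \code{\link{estimate_state_values}} result.
#' @return an object of class \code{"q_map"}: matrix \code{q}
#'   (n_bins^2 x 9, columns \code{d0,...,d315,none}), plus the binning and
#'   gamma.
#' @export
estimate_action_values <- function(value_map) {
  stopifnot(inherits(value_map, "value_map"))
  b <- value_map$binning
  n <- b$n_bins
  gamma <- value_map$gamma
  v <- value_map$v
  q <- matrix(NA_real_, n^2, 9, dimnames = list(NULL, DIR_LABELS))
  ix <- rep(seq_len(n), each = n)
  iy <- rep(seq_len(n), times = n)
  for (k in 1:8) {
    ang <- DIR_ANGLES[k] * pi / 180
    sx <- round(cos(ang)); sy <- round(sin(ang))
    nx <- ix + sx; ny <- iy + sy
    inside <- nx >= 1 & nx <= n & ny >= 1 & ny <= n
    nbin <- ifelse(inside, (nx - 1L) * n + ny, seq_len(n^2))
    q[, k] <- gamma * v[nbin]
  }
  q[, 9] <- gamma * v
  structure(list(q = q, binning = b, gamma = gamma), class = "q_map")
}

# movement vectors over a window of rows within each trajectory
movement_vectors <- function(tr, window = 1L) {
  n <- nrow(tr)
  if (n <= window) return(NULL)
  i0 <- seq(1L, n - window, by = window)
  data.frame(x = tr$x[i0], y = tr$y[i0],
             vx = tr$x[i0 + window] - tr$x[i0],
             vy = tr$y[i0 + window] - tr$y[i0])
}

#' Policy field from trajectories
#'
#' In each spatial bin, the preferred action is the vectorial sum of all
#' movement vectors observed there, normalized to a unit vector; the action
#' probability distribution over the 8 directions is the speed-weighted
#' direction histogram normalized to sum to 1.  Movements slower than
#' \code{still_threshold} (per window) count as no movement and contribute
#' to neither.
#'
#' @param trajectories trajectory data.frame(s).
#' @param binning an \code{\link{arena_binning}}.
#' @param window samples per movement vector (1 for per-step agent data,
#'   10 for 100-ms vectors on 10-ms mouse-like data).
#' @param still_threshold displacement below which a movement counts as
#'   "no movement" (default 0.05 in arena units, i.e. 0.05 cm per 100 ms on
#'   the mouse arena).
#' @return an object of class \code{"policy_field"}: \code{vectors}
#'   (n_bins^2 x 2 unit vectors; zero where unvisited or cancelled),
#'   \code{pi} (n_bins^2 x 8 direction distribution, rows of NA where
#'   unvisited), \code{resultant} (unnormalized sums), \code{counts}.
#' @export
policy_field <- function(trajectories, binning, window = 1L,
                         still_threshold = 0.05) {
  trs <- as_traj_list(trajectories)
  mv <- do.call(rbind, lapply(trs, movement_vectors, window = window))
  if (is.null(mv) || !nrow(mv)) stop("no movement vectors available")
  nb <- binning$n_bins^2
  b <- bin_index(binning, mv$x, mv$y)
  sp <- sqrt(mv$vx^2 + mv$vy^2)
  moving <- sp >= still_threshold & !is.na(b)
  res <- cbind(rowsum_vec(mv$vx[moving], b[moving], nb),
               rowsum_vec(mv$vy[moving], b[moving], nb))
  counts <- tabulate(b[!is.na(b)], nb)
  len <- sqrt(rowSums(res^2))
  vectors <- res / ifelse(len > 0, len, 1)
  dk <- (round(atan2(mv$vy[moving], mv$vx[moving]) / (pi / 4)) %% 8) + 1L
  pi_mat <- matrix(0, nb, 8, dimnames = list(NULL, paste0("d", DIR_ANGLES)))
  for (k in 1:8) {
    pi_mat[, k] <- rowsum_vec(sp[moving][dk == k], b[moving][dk == k], nb)
  }
  tot <- rowSums(pi_mat)
  pi_mat <- pi_mat / ifelse(tot > 0, tot, 1)
  pi_mat[tot == 0, ] <- NA_real_
  structure(list(vectors = vectors, pi = pi_mat, resultant = res,
                 counts = counts, binning = binning),
            class = "policy_field")
}

#' Policy entropy per spatial bin
#'
#' Shannon entropy (natural log) of the 8-direction action distribution in
#' each visited bin; the session value is the mean over visited bins.
#'
#' @param x a \code{\link{policy_field}}, or trajectories (then
#'   \code{binning}/\code{...} are passed to \code{policy_field}).
#' @param binning required when \code{x} is not a policy field.
#' @param ... passed to \code{\link{policy_field}}.
#' @return list with \code{per_bin} (NA where unvisited) and \code{mean}.
#' @export
policy_entropy <- function(x, binning = NULL, ...) {
  pf <- if (inherits(x, "policy_field")) x else policy_field(x, binning, ...)
  p <- pf$pi
  h <- -rowSums(ifelse(is.na(p) | p == 0, 0, p * log(p)))
  h[apply(p, 1, function(r) all(is.na(r)))] <- NA_real_
  list(per_bin = h, mean = mean(h, na.rm = TRUE))
}

#' Cosine similarity between two policy fields
#'
#' Per-bin dot product of the two resultant vectors divided by the product
#' of their lengths, averaged over bins with movement in both fields.
#'
#' @param fieldA,fieldB \code{\link{policy_field}} objects on the same
#'   binning.
#' @return mean cosine similarity (scalar).
#' @export
cosine_similarity <- function(fieldA, fieldB) {
  stopifnot(inherits(fieldA, "policy_field"), inherits(fieldB, "policy_field"),
            fieldA$binning$n_bins == fieldB$binning$n_bins)
  la <- sqrt(rowSums(fieldA$resultant^2))
  lb <- sqrt(rowSums(fieldB$resultant^2))
  ok <- la > 0 & lb > 0
  if (!any(ok)) stop("no spatial bin is visited in both fields")
  dots <- rowSums(fieldA$resultant * fieldB$resultant)
  mean(dots[ok] / (la[ok] * lb[ok]))
}

#' State occupancy
#'
#' @param trajectories trajectory data.frame(s).
#' @param binning an \code{\link{arena_binning}}.
#' @return occupancy probabilities per bin (sums to 1).
#' @export
state_occupancy <- function(trajectories, binning) {
  trs <- as_traj_list(trajectories)
  b <- unlist(lapply(trs, function(tr) bin_index(binning, tr$x, tr$y)))
  b <- b[!is.na(b)]
  if (!length(b)) stop("no in-arena samples")
  tabulate(b, binning$n_bins^2) / length(b)
}

side_mask <- function(binning, axis, side) {
  ctr <- bin_centers(binning)
  coord <- if (axis == "x") ctr[, 1] else ctr[, 2]
  mid <- mean(if (axis == "x") binning$xlim else binning$ylim)
  if (side == "positive") coord > mid else coord < mid
}

#' Occupancy ratio between two sides of the arena
#'
#' Ratio of total occupancy on the high-reward side to the low-reward side
#' (arena halves along \code{axis}).  A bootstrap null is built by
#' resampling the supplied reference sessions with replacement and
#' recomputing the mean ratio.
#'
#' @param sessions list of trajectory sets (one per session), each a list
#'   of trajectory data.frames.
#' @param binning an \code{\link{arena_binning}}.
#' @param axis \code{"x"} or \code{"y"}; \code{high_side}
#'   \code{"positive"} or \code{"negative"}.
#' @param high_side which half counts as the high-reward side.
#' @param reference_sessions optional list of reference sessions for the
#'   bootstrap null.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return list with \code{ratio} (mean over sessions), \code{per_session},
#'   and (when references are given) \code{null} and \code{ci}.
#' @export
occupancy_ratio <- function(sessions, binning, axis = "x",
                            high_side = "positive",
                            reference_sessions = NULL, n_boot = 1000L,
                            seed = 0L) {
  hi <- side_mask(binning, axis, high_side)
  lo <- side_mask(binning, axis,
                  if (high_side == "positive") "negative" else "positive")
  one <- function(sess) {
    occ <- state_occupancy(sess, binning)
    den <- sum(occ[lo])
    if (den == 0) return(NA_real_)
    sum(occ[hi]) / den
  }
  per <- vapply(sessions, one, numeric(1))
  out <- list(ratio = mean(per, na.rm = TRUE), per_session = per)
  if (!is.null(reference_sessions)) {
    ref <- vapply(reference_sessions, one, numeric(1))
    stream <- make_rng(seed)
    null <- with_stream(stream, replicate(n_boot, {
      mean(ref[sample.int(length(ref), replace = TRUE)], na.rm = TRUE)
    }))
    out$null <- null
    out$ci <- stats::quantile(null, c(0.025, 0.975), na.rm = TRUE)
  }
  out
}

#' Zone visitation probability
#'
#' Fraction of trajectories entering (or, for agent episodes with logged
#' actions on the [-1, 1]^2 arena, touching) the given rectangle at least
#' once.  Touching means the wall-projected candidate position of a step
#' lies in the zone, matching the environment's goal-contact rule.
#'
#' @param trajectories trajectory data.frame(s).
#' @param zone \code{c(xmin, xmax, ymin, ymax)}.
#' @return scalar in [0, 1].
#' @export
zone_visitation <- function(trajectories, zone) {
  trs <- as_traj_list(trajectories)
  mean(vapply(trs, function(tr) {
    hit <- any(in_rect(tr$x, tr$y, zone))
    if (!hit && all(c("dx", "dy") %in% names(tr)) &&
        all(abs(tr$x) <= 1) && all(abs(tr$y) <= 1)) {
      cx <- pmin(pmax(tr$x + tr$dx, -1), 1)
      cy <- pmin(pmax(tr$y + tr$dy, -1), 1)
      hit <- any(in_rect(cx, cy, zone))
    }
    hit
  }, logical(1)))
}

#' Value map of a stationary goal
#'
#' Discounted-steps value surface toward a fixed point: each bin's value
#' is gamma raised to the number of movement steps needed to reach the
#' point at the given speed.  Used e.g. as the spatial value map of the
#' stationary lick task when composing subtask maps.
#'
#' @param binning an \code{\link{arena_binning}}.
#' @param pos goal position \code{c(x, y)}.
#' @param speed movement speed (arena units/s).
#' @param gamma per-sample discount; \code{dt} sample interval (s).
#' @param dt sample interval in seconds.
#' @return numeric vector of per-bin values.
#' @export
stationary_value_map <- function(binning, pos, speed, gamma = 0.99,
                                 dt = 0.01) {
  ctr <- bin_centers(binning)
  d <- sqrt((ctr[, 1] - pos[1])^2 + (ctr[, 2] - pos[2])^2)
  gamma^(d / (speed * dt))
}

#' Time-resolved values for the lick task
#'
#' For trials with a single terminal reward triggered by licking, V at time
#' t within the trial is the mean of gamma^(T - t) over hit trials still
#' running at t.  The lick/no-lick action values come from a one-step
#' lookahead: Q(lick) is the mean immediate outcome of observed licks plus
#' discounted continuation, and Q(no lick) = gamma * V(next).
#'
#' @param trajectories trial data.frames with columns \code{lick} (0/1
#'   events) and \code{reward}.
#' @param gamma per-sample discount.
#' @return list with \code{v_t} (value by within-trial sample),
#'   \code{q} (named c(lick, nolick)).
#' @export
estimate_lick_values <- function(trajectories, gamma) {
  trs <- as_traj_list(trajectories)
  hits <- Filter(traj_is_hit, trs)
  if (!length(hits)) stop("no hit trials")
  Tmax <- max(vapply(hits, nrow, integer(1)))
  num <- numeric(Tmax); den <- numeric(Tmax)
  lick_out <- c()
  for (tr in hits) {
    Tend <- max(which(tr$reward > 0))
    tt <- seq_len(Tend)
    num[tt] <- num[tt] + gamma^(Tend - tt)
    den[tt] <- den[tt] + 1
    li <- which(tr$lick > 0 & seq_len(nrow(tr)) <= Tend)
    if (length(li)) lick_out <- c(lick_out, tr$reward[li])
  }
  v_t <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  v_next <- c(v_t[-1], 1)
  q_nolick <- gamma * mean(v_next, na.rm = TRUE)
  q_lick <- if (length(lick_out)) mean(lick_out) + gamma * q_nolick * mean(lick_out == 0)
            else NA_real_
  list(v_t = v_t, q = c(lick = q_lick, nolick = q_nolick))
}

#' @export
print.value_map <- function(x, ...) {
  cat(sprintf("Value map on a %d x %d arena (gamma = %g)\n",
              x$binning$n_bins, x$binning$n_bins, x$gamma))
  cat(sprintf("  %d hit / %d miss trajectories; %d of %d bins visited\n",
              x$n_hit, x$n_miss, sum(x$visits > 0), length(x$v)))
  cat(sprintf("  V range: [%.3f, %.3f]\n", min(x$v, na.rm = TRUE),
              max(x$v, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.value_map <- function(x, ...) {
  n <- x$binning$n_bins
  graphics::image(matrix(x$v, n, n), xlab = "x", ylab = "y",
                  main = "state-value map", ...)
  invisible(x)
}
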
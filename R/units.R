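# Classification of Q-representing units from tuning profiles (GLM-derived
# for mouse-like data, probe-derived for network hidden units), with
# shuffle nulls, add-one permutation p-values, and Benjamini-Hochberg FDR;
# plus selectivity / distribution indices, chance levels, enrichment and
# covariate controls.

perm_p <- function(null_geq_obs, n_null) (1 + null_geq_obs) / (1 + n_null)

row_standardize <- function(M) {
  mu <- rowMeans(M)
  s <- sqrt(rowSums((M - mu)^2))
  list(Z = (M - mu) / ifelse(s > 0, s, 1), ok = s > 0)
}

#' Benjamini-Hochberg significance mask
#'
#' @param p_values numeric p-values in [0, 1].
#' @param q FDR level.
#' @return logical vector: which hypotheses are rejected at FDR q.
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(logical(0))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Classify V-like units from space maps
#'
#' A unit's space map is compared with the state-value map by Pearson
#' correlation; the null shuffles the unit's spatial map relative to the
#' value map (position shuffle) \code{shuffles} times, and the one-tailed
#' add-one permutation p-value is FDR-corrected across units.  For square
#' maps the shuffle is a random two-dimensional circular (torus) shift,
#' which preserves the map's spatial smoothness; otherwise a full bin
#' permutation is used.
#'
#' @param space_maps units x bins matrix (or a single map).
#' @param v_map numeric value per bin (NA bins are dropped).
#' @param shuffles number of position shuffles.
#' @param q FDR level.
#' @param seed shuffle seed.
#' @return data.frame with \code{r}, \code{p}, \code{sig} per unit.
#' @export
classify_v_like <- function(space_maps, v_map, shuffles = 1000L, q = 0.05,
                            seed = 0L) {
  M <- if (is.null(dim(space_maps))) matrix(space_maps, 1) else as.matrix(space_maps)
  B_all <- length(v_map)
  n_side <- round(sqrt(B_all))
  keep <- which(!is.na(v_map))
  v <- v_map[keep]
  vc <- v - mean(v)
  vz <- vc / sqrt(sum(vc^2))
  r_with_v <- function(Mk) {    # Mk: units x length(keep)
    zs <- row_standardize(Mk)
    r <- as.numeric(zs$Z %*% vz)
    r[!zs$ok] <- NA_real_
    r
  }
  obs <- r_with_v(M[, keep, drop = FALSE])
  stream <- make_rng(seed)
  thr <- ifelse(is.na(obs), Inf, obs)
  geq <- numeric(nrow(M))
  if (n_side * n_side == B_all && n_side > 1) {
    ix <- (keep - 1) %/% n_side
    iy <- (keep - 1) %% n_side
    sh <- with_stream(stream, cbind(sample.int(n_side, shuffles, TRUE) - 1L,
                                    sample.int(n_side, shuffles, TRUE) - 1L))
    sh[rowSums(sh) == 0, 1] <- 1L     # exclude the identity shift
    for (s in seq_len(shuffles)) {
      src <- ((ix + sh[s, 1]) %% n_side) * n_side + ((iy + sh[s, 2]) %% n_side) + 1
      cmp <- r_with_v(M[, src, drop = FALSE]) >= thr
      geq <- geq + ifelse(is.na(cmp), FALSE, cmp)
    }
  } else {
    for (s in seq_len(shuffles)) {
      src <- with_stream(stream, sample.int(B_all))[keep]
      cmp <- r_with_v(M[, src, drop = FALSE]) >= thr
      geq <- geq + ifelse(is.na(cmp), FALSE, cmp)
    }
  }
  p <- perm_p(geq, shuffles)
  p[is.na(obs)] <- NA_real_
  sig <- rep(FALSE, length(p))
  ok <- !is.na(p)
  sig[ok] <- fdr_adjust(p[ok], q)
  data.frame(r = obs, p = p, sig = sig)
}

# reference Q vector of each unit: Q averaged over its top-5% space-map
# bins, weighted by the normalized activity in those bins
unit_q_reference <- function(space_maps, q_mat, top_quantile = 0.95,
                             min_bins = 2L) {
  M <- as.matrix(space_maps)
  out <- matrix(NA_real_, nrow(M), ncol(q_mat))
  usable <- logical(nrow(M))
  # only bins with a fully defined Q row can enter the reference
  q_ok <- which(rowSums(is.na(q_mat)) == 0)
  if (length(q_ok) < min_bins) return(list(q_ref = out, usable = usable))
  for (u in seq_len(nrow(M))) {
    m <- M[u, q_ok]
    thr <- stats::quantile(m, top_quantile, na.rm = TRUE, names = FALSE)
    idx <- q_ok[which(m >= thr & !is.na(m))]
    if (length(idx) < min_bins) {
      idx <- q_ok[order(m, decreasing = TRUE)[seq_len(min_bins)]]
    }
    w <- M[u, idx] - min(0, min(M[u, idx]))
    if (sum(w) <= 0) w <- rep(1, length(idx))
    w <- w / sum(w)
    out[u, ] <- colSums(q_mat[idx, , drop = FALSE] * w)
    usable[u] <- TRUE
  }
  list(q_ref = out, usable = usable)
}

#' Classify Q-conjunctive units
#'
#' For units with conjunctive space and direction tuning: the unit's
#' direction tuning is compared with the local Q distribution over actions
#' in its top-5\% space-map bins (Q weighted by the normalized activity in
#' those bins), by Pearson correlation AND by dot product; a unit is
#' labeled when either metric survives FDR.  The null distribution comes
#' from shuffled direction tunings: either supplied via
#' \code{null_tunings} (recomputed tunings under movement-direction
#' time-series shuffling, the study's scheme) or, as a fallback, from
#' permuting the direction labels of the observed tuning.
#'
#' @param space_maps units x bins.
#' @param dir_tunings units x n_actions direction tuning (e.g. 9: 8
#'   directions plus no movement).
#' @param q_mat bins x n_actions action-value map.
#' @param null_tunings optional function(s) returning the s-th shuffled
#'   tuning matrix (units x n_actions), or a list of such matrices.
#' @param shuffles,q,seed as in \code{\link{classify_v_like}}.
#' @return data.frame with \code{r}, \code{p_pearson}, \code{dot},
#'   \code{p_dot}, \code{sig} per unit.
#' @export
classify_q_conjunctive <- function(space_maps, dir_tunings, q_mat,
                                   shuffles = 1000L, q = 0.05, seed = 0L,
                                   null_tunings = NULL) {
  Tn <- if (is.null(dim(dir_tunings))) matrix(dir_tunings, 1) else as.matrix(dir_tunings)
  ref <- unit_q_reference(space_maps, as.matrix(q_mat))
  K <- ncol(Tn)
  U <- nrow(Tn)
  stream <- make_rng(seed)
  if (is.null(null_tunings)) {
    perms <- with_stream(stream,
      matrix(replicate(shuffles, sample.int(K)), K, shuffles))
    null_fun <- function(s) Tn[, perms[, s], drop = FALSE]
  } else if (is.list(null_tunings)) {
    shuffles <- length(null_tunings)
    null_fun <- function(s) null_tunings[[s]]
  } else {
    null_fun <- null_tunings
  }

  zs <- row_standardize(Tn)
  qz <- row_standardize(ref$q_ref)
  # dot product on the mean-centered tuning: keeps the magnitude of the
  # direction modulation while discarding the unit's overall activity
  # level (whose estimation noise is common to all directions)
  cdot <- function(M) rowSums((M - rowMeans(M)) * ref$q_ref)
  obs_r <- rowSums(zs$Z * qz$Z)
  obs_dot <- cdot(Tn)
  thr_r <- ifelse(is.finite(obs_r), obs_r, Inf)
  thr_d <- ifelse(is.finite(obs_dot), obs_dot, Inf)
  null_geq_r <- numeric(U); null_geq_d <- numeric(U)
  for (s in seq_len(shuffles)) {
    Ns <- null_fun(s)
    nz <- row_standardize(Ns)
    null_geq_r <- null_geq_r + (rowSums(nz$Z * qz$Z) >= thr_r)
    null_geq_d <- null_geq_d + (cdot(Ns) >= thr_d)
  }
  p_r <- perm_p(null_geq_r, shuffles)
  p_d <- perm_p(null_geq_d, shuffles)
  const <- !zs$ok | !qz$ok          # Pearson undefined: dot product decides
  p_r[const] <- NA_real_
  obs_r[const] <- NA_real_
  p_r[!ref$usable] <- NA_real_
  p_d[!ref$usable] <- NA_real_
  sig_r <- rep(FALSE, U); sig_d <- rep(FALSE, U)
  sig_r[!is.na(p_r)] <- fdr_adjust(p_r[!is.na(p_r)], q)
  sig_d[!is.na(p_d)] <- fdr_adjust(p_d[!is.na(p_d)], q)
  data.frame(r = obs_r, p_pearson = p_r, dot = obs_dot, p_dot = p_d,
             sig = sig_r | sig_d)
}

#' Direction-tunedness screen
#'
#' Tests whether a unit's direction tuning is modulated at all: the spread
#' (s.d. across the 8 movement directions) of the observed tuning is
#' compared with the spread under the shuffle null.
#'
#' @param tuning units x n_actions observed tuning.
#' @param null_fun function(s) returning the s-th null tuning matrix.
#' @param shuffles number of nulls.
#' @param dirs columns counted as movement directions (default 1:8).
#' @param p_cut screening p threshold.
#' @return list with \code{p} and logical \code{tuned}.
#' @export
direction_tuned_screen <- function(tuning, null_fun, shuffles, dirs = 1:8,
                                   p_cut = 0.05) {
  row_sd <- function(M) {
    M <- as.matrix(M)[, dirs, drop = FALSE]
    sqrt(rowSums((M - rowMeans(M))^2) / (length(dirs) - 1))
  }
  obs <- row_sd(tuning)
  geq <- numeric(length(obs))
  for (s in seq_len(shuffles)) {
    geq <- geq + (row_sd(null_fun(s)) >= obs)
  }
  p <- perm_p(geq, shuffles)
  list(p = p, tuned = p < p_cut)
}

#' Empirical direction tuning and its time-series-shuffle null
#'
#' Direction tuning by direction-occupancy-weighted averaging: each
#' frame's activity is attributed to the movement directions occupied
#' during that frame (from the base-rate movement samples), giving a
#' units x 9 tuning (8 directions + no movement).  Null tunings recompute
#' the same quantity after circularly shifting the occupancy series
#' against the activity, which preserves both autocorrelations while
#' breaking their relationship (the movement-direction shuffle).
#'
#' @param activity frames x units.
#' @param occupancy frames x 9 direction-occupancy weights (e.g. time
#'   spent moving in each direction within the frame).
#' @param shuffles number of circular-shift nulls.
#' @param seed RNG seed.
#' @return list with \code{tuning} (units x 9), \code{nulls} (a
#'   function(s) computing the s-th null tuning on demand) and
#'   \code{shuffles}.
#' @export
direction_tuning_empirical <- function(activity, occupancy, shuffles = 1000L,
                                       seed = 0L) {
  A <- as.matrix(activity)
  W <- as.matrix(occupancy)
  Fn <- nrow(A)
  stopifnot(nrow(W) == Fn)
  cs <- colSums(W)
  tune_of <- function(Ws) sweep(crossprod(A, Ws), 2, pmax(cs, 1e-12), "/")
  tuning <- tune_of(W)
  stream <- make_rng(seed)
  shifts <- with_stream(stream, sample.int(Fn - 1L, shuffles, replace = TRUE))
  nulls <- function(s) {
    idx <- ((seq_len(Fn) - 1L + shifts[s]) %% Fn) + 1L
    tune_of(W[idx, , drop = FALSE])
  }
  list(tuning = tuning, nulls = nulls, shuffles = shuffles)
}

#' Classify lick-Q units from activity traces
#'
#' Lick tuning (mean activity in the second after lick onsets versus all
#' other frames) is compared with the Q(lick)/Q(no-lick) pair by Pearson
#' correlation and dot product; the null shuffles the lick-onset time
#' series by random circular shifts, preserving its autocorrelation.
#'
#' @param activity frames x units.
#' @param lick_frames integer frame indices of lick onsets.
#' @param q_lick numeric \code{c(lick, nolick)} action values (a per-unit
#'   2-column matrix is also accepted, e.g. from top-bin weighting).
#' @param frame_rate frames per second (to span the 1-s response window).
#' @param shuffles,q,seed as above.
#' @return data.frame with \code{tuning_lick}, \code{tuning_nolick},
#'   \code{dot}, \code{p_dot}, \code{r}, \code{p_pearson}, \code{sig}.
#' @export
classify_q_lick <- function(activity, lick_frames, q_lick, frame_rate = 5.67,
                            shuffles = 1000L, q = 0.05, seed = 0L) {
  A <- as.matrix(activity)
  Fn <- nrow(A); U <- ncol(A)
  if (!length(lick_frames)) stop("no lick events")
  win <- max(1L, round(frame_rate))
  mask_from <- function(onsets) {
    idx <- unique(as.integer(outer(onsets, 0:(win - 1L), "+")))
    idx <- idx[idx >= 1 & idx <= Fn]
    m <- rep(0, Fn); m[idx] <- 1; m
  }
  m_obs <- mask_from(lick_frames)
  if (all(m_obs == 1) || all(m_obs == 0)) stop("degenerate lick mask")
  tune <- function(m) {
    on <- crossprod(A, m) / sum(m)
    off <- crossprod(A, 1 - m) / sum(1 - m)
    cbind(on, off)
  }
  Qm <- if (is.null(dim(q_lick))) {
    matrix(q_lick, U, 2, byrow = TRUE)
  } else as.matrix(q_lick)
  stat <- function(Tu) {
    dq <- Qm[, 1] - Qm[, 2]
    list(dot = Tu[, 1] * Qm[, 1] + Tu[, 2] * Qm[, 2],
         r = sign((Tu[, 1] - Tu[, 2]) * dq) * (abs(dq) > 0) *
           (abs(Tu[, 1] - Tu[, 2]) > 0))
  }
  T0 <- tune(m_obs)
  s0 <- stat(T0)
  stream <- make_rng(seed)
  shifts <- with_stream(stream, sample.int(Fn - 1L, shuffles, replace = TRUE))
  # all null masks at once: one matrix product across shuffles
  Msk <- vapply(shifts, function(s) {
    mask_from(((lick_frames - 1L + s) %% Fn) + 1L)
  }, numeric(Fn))
  n_on <- colSums(Msk)
  SUMS <- crossprod(A, Msk)                              # U x shuffles
  ON <- sweep(SUMS, 2, n_on, "/")
  OFF <- sweep(matrix(colSums(A), U, shuffles) - SUMS, 2, Fn - n_on, "/")
  dq <- Qm[, 1] - Qm[, 2]
  null_dot <- ON * Qm[, 1] + OFF * Qm[, 2]
  null_r <- sign((ON - OFF) * dq) * (abs(ON - OFF) > 0) * (abs(dq) > 0)
  p_d <- perm_p(rowSums(null_dot >= s0$dot), shuffles)
  p_r <- perm_p(rowSums(null_r >= s0$r), shuffles)
  sig <- fdr_adjust(p_d, q) | fdr_adjust(p_r, q)
  data.frame(tuning_lick = T0[, 1], tuning_nolick = T0[, 2],
             dot = s0$dot, p_dot = p_d, r = s0$r, p_pearson = p_r, sig = sig)
}

#' Chance level for conjunctive Q coding
#'
#' Pairs independently sampled state-coding space maps with action-coding
#' direction tunings and measures how often such random pairings would be
#' classified as Q-conjunctive.
#'
#' @param state_maps space maps of state-coding units (units x bins).
#' @param action_tunings direction tunings of action-coding units
#'   (units x n_actions).
#' @param q_mat bins x n_actions action-value map.
#' @param resamples number of random pairings (default 1000).
#' @param shuffles,q,seed as above.
#' @return list with \code{chance} (mean classified fraction),
#'   \code{ci} (2.5/97.5 binomial bootstrap percentiles), \code{n_pairs}.
#' @export
chance_fraction_conjunctive <- function(state_maps, action_tunings, q_mat,
                                        resamples = 1000L, shuffles = 1000L,
                                        q = 0.05, seed = 0L) {
  Sm <- as.matrix(state_maps); At <- as.matrix(action_tunings)
  if (!nrow(Sm) || !nrow(At)) stop("empty coder pools")
  stream <- make_rng(seed)
  ii <- with_stream(stream, sample.int(nrow(Sm), resamples, replace = TRUE))
  jj <- with_stream(stream, sample.int(nrow(At), resamples, replace = TRUE))
  cls <- classify_q_conjunctive(Sm[ii, , drop = FALSE], At[jj, , drop = FALSE],
                                q_mat, shuffles = shuffles, q = q,
                                seed = seed + 1L)
  hits <- cls$sig
  boot <- with_stream(stream, replicate(1000, {
    mean(hits[sample.int(length(hits), replace = TRUE)])
  }))
  list(chance = mean(hits), ci = stats::quantile(boot, c(0.025, 0.975)),
       n_pairs = resamples)
}

#' Detect mixed composite-Q units
#'
#' Correlates each unit's space map with the action-averaged composite Q
#' map against a position-shuffle null (as \code{\link{classify_v_like}},
#' with the composite map as reference).
#'
#' @inheritParams classify_v_like
#' @param mean_q_map action-averaged composite Q per bin.
#' @return data.frame with \code{r}, \code{p}, \code{sig}.
#' @export
detect_mixed_composite <- function(space_maps, mean_q_map, shuffles = 1000L,
                                   q = 0.05, seed = 0L) {
  classify_v_like(space_maps, mean_q_map, shuffles = shuffles, q = q,
                  seed = seed)
}

#' Chance fraction under uniformly distributed place fields
#'
#' Simulates units whose space tuning is a single raised-cosine place field
#' (the GLM spatial basis shape) centered uniformly at random in the arena,
#' and runs the mixed-composite detection on them; the classified fraction
#' is the chance level under the uniform-place-field assumption.
#'
#' @param mean_q_map action-averaged composite Q per bin (length n_bins^2).
#' @param binning the \code{\link{arena_binning}} of the map.
#' @param n_sim simulated units.
#' @param width_factor field width as a multiple of the 10x10 grid spacing.
#' @param shuffles,q,seed as above.
#' @return list with \code{chance} and the simulated classification table.
#' @export
uniform_place_field_chance <- function(mean_q_map, binning, n_sim = 1000L,
                                       width_factor = 1.5, shuffles = 1000L,
                                       q = 0.05, seed = 0L) {
  ctr <- bin_centers(binning)
  w <- width_factor * diff(binning$xlim) / 10
  stream <- make_rng(seed)
  cx <- with_stream(stream, stats::runif(n_sim, binning$xlim[1], binning$xlim[2]))
  cy <- with_stream(stream, stats::runif(n_sim, binning$ylim[1], binning$ylim[2]))
  maps <- raised_cosine(outer(cx, ctr[, 1], "-"), w) *
    raised_cosine(outer(cy, ctr[, 2], "-"), w)
  cls <- detect_mixed_composite(maps, mean_q_map, shuffles = shuffles, q = q,
                                seed = seed + 1L)
  list(chance = mean(cls$sig, na.rm = TRUE), table = cls)
}

#' Direction selectivity index
#'
#' SI = 1 - circular variance with angle doubling:
#' \eqn{SI = || \sum_k r_k e^{i 2 \theta_k} || / \sum_k r_k}.
#' One-hot tuning gives 1; uniform tuning gives 0; equal mass at opposite
#' directions still gives 1 (doubling maps them to the same phase).
#'
#' @param r_k nonnegative responses per direction (vector, or units x
#'   directions matrix).
#' @param angles_deg direction angles in degrees (default the 8 standard
#'   directions; extra tuning entries such as a trailing no-movement level
#'   are not allowed here).
#' @return SI scalar or vector.
#' @export
selectivity_index <- function(r_k, angles_deg = DIR_ANGLES) {
  M <- if (is.null(dim(r_k))) matrix(r_k, 1) else as.matrix(r_k)
  if (ncol(M) != length(angles_deg)) stop("tuning/angle length mismatch")
  if (any(M < 0)) stop("r_k must be nonnegative")
  tot <- rowSums(M)
  if (any(tot == 0)) stop("all-zero tuning: SI undefined")
  th <- angles_deg * pi / 180
  re <- as.numeric(M %*% cos(2 * th))
  im <- as.numeric(M %*% sin(2 * th))
  si <- sqrt(re^2 + im^2) / tot
  if (is.null(dim(r_k))) si[1] else si
}

#' Dedicated-versus-distributed index
#'
#' \eqn{(f_1 - f_2) / (f_1 + f_2)}: 1 when a representation lives only in
#' the first subnetwork/region, -1 only in the second, 0 when evenly
#' distributed.
#'
#' @param f1,f2 nonnegative fractions.
#' @return index in [-1, 1]; NA (with a warning) when both are zero.
#' @export
distribution_index <- function(f1, f2) {
  if (any(f1 < 0 | f2 < 0)) stop("fractions must be nonnegative")
  out <- (f1 - f2) / (f1 + f2)
  if (any(f1 + f2 == 0)) {
    warning("distribution index undefined where both fractions are zero")
    out[f1 + f2 == 0] <- NA_real_
  }
  out
}

#' Enrichment of space-map peaks on the high-reward side
#'
#' Fraction of units whose space-map peak falls on the high-reward half of
#' the arena, with a null built by resampling reference-condition subjects
#' with replacement.  Peak ties resolve to the first bin in map order
#' (recorded in the result).
#'
#' @param space_maps units x bins matrix from the altered-reward condition.
#' @param binning the map's \code{\link{arena_binning}}.
#' @param axis,high_side which half is the high-reward side.
#' @param reference list of reference-subject space-map matrices.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return list with \code{fraction}, \code{p} (one-tailed vs the null),
#'   \code{null}, \code{n_ties}.
#' @export
enrichment_side <- function(space_maps, binning, axis = "x",
                            high_side = "positive", reference = NULL,
                            n_boot = 1000L, seed = 0L) {
  hi <- side_mask(binning, axis, high_side)
  frac_high <- function(M) {
    M <- as.matrix(M)
    peaks <- apply(M, 1, which.max)
    mean(hi[peaks])
  }
  M <- as.matrix(space_maps)
  n_ties <- sum(apply(M, 1, function(m) sum(m == max(m)) > 1))
  obs <- frac_high(M)
  out <- list(fraction = obs, n_ties = n_ties)
  if (!is.null(reference)) {
    ref <- vapply(reference, frac_high, numeric(1))
    stream <- make_rng(seed)
    null <- with_stream(stream, replicate(n_boot, {
      mean(ref[sample.int(length(ref), replace = TRUE)])
    }))
    out$null <- null
    out$p <- perm_p(sum(null >= obs), n_boot)
  }
  out
}

#' Session-by-session covariate control correlation
#'
#' Pearson correlation (two-tailed) between a per-session fraction of
#' classified units and a per-session behavioral covariate (e.g. traveled
#' distance, lick frequency), to check that classification fractions do
#' not merely track movement statistics.
#'
#' @param per_session_fractions,per_session_covariate numeric vectors
#'   (>= 3 sessions).
#' @return list with \code{r}, \code{p}, \code{n}; NA with a warning for
#'   constant series.
#' @export
covariate_control_correlation <- function(per_session_fractions,
                                          per_session_covariate) {
  x <- per_session_fractions; y <- per_session_covariate
  if (length(x) < 3 || length(x) != length(y)) {
    stop("need >= 3 paired sessions")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant series: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
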
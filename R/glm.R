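# Encoding models of unit activity from task variables: raised-cosine
# bases, design-matrix construction at the task-variable sampling rate with
# downsampling to the imaging frame rate, ridge-regularized fitting with
# nested cross-validation shared across units, and marginalized response
# profiles.

#' Raised-cosine basis set
#'
#' Temporal kinds use one-dimensional raised cosines
#' \eqn{b_j(t) = 0.5 (1 + cos(\pi (t - c_j) / w))} for \eqn{|t - c_j| < w},
#' with centers evenly spaced over the support and width \eqn{w} equal to
#' twice the center spacing (perfect tiling: the interior sum is constant).
#' The spatial kind is a 10 x 10 grid of separable two-dimensional raised
#' cosines with width 1.5x the grid spacing.
#'
#' Defaults per kind: \code{temporal_event} and \code{velocity_direction}
#' use 6 bases over [-2, 2] s; \code{reward} uses 9 bases over [-2, 4] s;
#' \code{spatial} uses 100 bases over the arena.
#'
#' @param kind basis kind.
#' @param n_bases number of bases (per axis^2 for spatial).
#' @param support \code{c(lo, hi)} in seconds (temporal kinds).
#' @param xlim,ylim arena extent (spatial kind).
#' @return an object of class \code{"basis_set"}.
#' @export
build_basis <- function(kind = c("temporal_event", "velocity_direction",
                                 "reward", "spatial"),
                        n_bases = NULL, support = NULL,
                        xlim = c(-1, 1), ylim = xlim) {
  kind <- match.arg(kind)
  if (kind == "spatial") {
    if (is.null(n_bases)) n_bases <- 100L
    n_side <- as.integer(round(sqrt(n_bases)))
    if (n_side^2 != n_bases) stop("spatial n_bases must be a perfect square")
    if (n_bases <= 0) stop("n_bases must be positive")
    dx <- diff(xlim) / n_side
    dy <- diff(ylim) / n_side
    cx <- xlim[1] + (seq_len(n_side) - 0.5) * dx
    cy <- ylim[1] + (seq_len(n_side) - 0.5) * dy
    centers <- cbind(x = rep(cx, each = n_side), y = rep(cy, times = n_side))
    return(structure(list(kind = kind, n_bases = n_bases, n_side = n_side,
                          centers = centers, width = c(1.5 * dx, 1.5 * dy),
                          xlim = xlim, ylim = ylim),
                     class = "basis_set"))
  }
  if (is.null(n_bases)) n_bases <- if (kind == "reward") 9L else 6L
  if (is.null(support)) support <- if (kind == "reward") c(-2, 4) else c(-2, 2)
  if (n_bases <= 0) stop("n_bases must be positive")
  centers <- seq(support[1], support[2], length.out = n_bases)
  width <- 2 * diff(centers[1:2])
  structure(list(kind = kind, n_bases = as.integer(n_bases),
                 support = support, centers = centers, width = width),
            class = "basis_set")
}

raised_cosine <- function(u, width) {
  ifelse(abs(u) < width, 0.5 * (1 + cos(pi * u / width)), 0)
}

#' Evaluate a basis set
#'
#' @param basis a \code{\link{build_basis}} result.
#' @param t times in seconds (temporal kinds).
#' @param xy a two-column matrix of positions (spatial kind).
#' @return matrix of basis values (length(t) or nrow(xy)) x n_bases.
#' @export
eval_basis <- function(basis, t = NULL, xy = NULL) {
  if (basis$kind == "spatial") {
    stopifnot(!is.null(xy))
    xy <- as.matrix(xy)
    bx <- outer(xy[, 1], basis$centers[, 1], "-")
    by <- outer(xy[, 2], basis$centers[, 2], "-")
    raised_cosine(bx, basis$width[1]) * raised_cosine(by, basis$width[2])
  } else {
    stopifnot(!is.null(t))
    sapply(seq_len(basis$n_bases), function(j) {
      raised_cosine(t - basis$centers[j], basis$width)
    })
  }
}

# causal+anticausal convolution of a sampled signal with each basis of a
# temporal basis set, preserving alignment: output[i] = sum_j x[i - l] b(l/rate)
conv_basis <- function(x, basis, rate) {
  n <- length(x)
  lags <- seq(floor((basis$centers[1] - basis$width) * rate),
              ceiling((basis$centers[basis$n_bases] + basis$width) * rate))
  K <- eval_basis(basis, t = lags / rate)
  nk <- length(lags)
  m <- stats::nextn(n + nk)
  fx <- stats::fft(c(x, numeric(m - n)))
  out <- matrix(0, n, basis$n_bases)
  for (j in seq_len(basis$n_bases)) {
    fk <- stats::fft(c(K[, j], numeric(m - nk)))
    y <- Re(stats::fft(fx * fk, inverse = TRUE)) / m
    # linear conv z[t] = sum_m x[t - m + 1] K[m]; the lag-l term sits at
    # t = i - lags[1], so out[i] = z[i - lags[1]]
    out[, j] <- y[seq_len(n) - lags[1]]
  }
  out
}

#' Build a GLM design matrix from task variables
#'
#' Event variables (trial onset/offset, lick onsets, reward onsets) enter as
#' 0/1 impulse trains; object and joystick velocity are decomposed into 8
#' direction channels carrying movement amplitude; object position is
#' one-hot on the 10 x 10 arena and expanded through the spatial bases.
#' Temporal predictors are convolved with their bases at the task-variable
#' sampling rate and then downsampled by averaging within each imaging
#' frame.
#'
#' @param vars a list with (any subset of) elements:
#'   \code{trial_onsets}, \code{trial_offsets}, \code{lick_onsets},
#'   \code{reward_onsets} (times in seconds); \code{object_pos} (T x 2),
#'   \code{object_vel}, \code{joystick_vel} (T x 2, units/s), sampled at
#'   \code{sample_rate}.
#' @param duration session length in seconds.
#' @param sample_rate task-variable sampling rate in Hz (study: 2000).
#' @param frame_rate imaging frame rate in Hz (study: ~5.67).
#' @param required variable groups that must be present (error otherwise);
#'   defaults to those supplied.
#' @param xlim,ylim arena extent for the spatial bases.
#' @return an object of class \code{"design_matrix"}: \code{X} (frames x
#'   predictors), \code{groups} (data.frame column/variable/basis),
#'   \code{bases}, \code{frame_times}, \code{frame_rate},
#'   \code{meta} (reference amplitudes for response profiles).
#' @export
build_design_matrix <- function(vars, duration, sample_rate = 2000,
                                frame_rate = 5.67, required = NULL,
                                xlim = c(-1, 1), ylim = xlim) {
  n <- as.integer(round(duration * sample_rate))
  if (!is.null(vars$object_pos) && nrow(vars$object_pos) != n) {
    stop("sampling-rate mismatch: object_pos has ", nrow(vars$object_pos),
         " rows but duration*sample_rate = ", n)
  }
  if (!is.null(required)) {
    missing <- setdiff(required, names(vars))
    if (length(missing)) {
      stop("missing task-variable groups: ", paste(missing, collapse = ", "))
    }
  }
  frame_len <- sample_rate / frame_rate
  frame_of <- pmin(floor((seq_len(n) - 1) / frame_len) + 1,
                   ceiling(n / frame_len))
  n_frames <- max(frame_of)
  frame_cnt <- tabulate(frame_of, n_frames)
  downsample <- function(M) rowsum(M, frame_of) / frame_cnt

  ev_basis <- build_basis("temporal_event")
  rw_basis <- build_basis("reward")
  sp_basis <- build_basis("spatial", xlim = xlim, ylim = ylim)
  bases <- list(event = ev_basis, reward = rw_basis, spatial = sp_basis)

  impulse <- function(times) {
    x <- numeric(n)
    idx <- pmin(pmax(round(times * sample_rate) + 1, 1), n)
    x[idx] <- 1
    x
  }
  vel_channels <- function(V) {
    sp <- sqrt(V[, 1]^2 + V[, 2]^2)
    ang <- atan2(V[, 2], V[, 1])
    dk <- (round(ang / (pi / 4)) %% 8) + 1L
    ch <- matrix(0, n, 8)
    moving <- sp > 0
    for (k in 1:8) {
      sel <- moving & dk == k
      ch[sel, k] <- sp[sel]
    }
    ch
  }

  cols <- list(); groups <- list(); meta <- list()
  add_group <- function(name, M, basis_idx) {
    cols[[length(cols) + 1]] <<- M
    groups[[length(groups) + 1]] <<- data.frame(
      variable = name, basis = basis_idx, stringsAsFactors = FALSE)
  }
  add_temporal <- function(name, x, basis) {
    C <- conv_basis(x, basis, sample_rate)
    add_group(name, downsample(C), seq_len(basis$n_bases))
  }

  for (ev in c("trial_onsets", "trial_offsets", "lick_onsets")) {
    if (!is.null(vars[[ev]])) add_temporal(ev, impulse(vars[[ev]]), ev_basis)
  }
  if (!is.null(vars$reward_onsets)) {
    add_temporal("reward_onsets", impulse(vars$reward_onsets), rw_basis)
  }
  for (vv in c("object_vel", "joystick_vel")) {
    if (!is.null(vars[[vv]])) {
      ch <- vel_channels(as.matrix(vars[[vv]]))
      sp <- sqrt(vars[[vv]][, 1]^2 + vars[[vv]][, 2]^2)
      meta[[paste0(vv, "_ref_amplitude")]] <- mean(sp[sp > 0])
      for (k in 1:8) {
        add_temporal(sprintf("%s_d%d", vv, (k - 1) * 45), ch[, k], ev_basis)
      }
    }
  }
  if (!is.null(vars$object_pos)) {
    # evaluate and frame-average the spatial bases in row blocks: the
    # full samples x 100 expansion would not fit in memory at 2000 Hz
    acc <- matrix(0, n_frames, sp_basis$n_bases)
    blk <- 50000L
    for (st in seq(1L, n, by = blk)) {
      ii <- st:min(st + blk - 1L, n)
      Pb <- eval_basis(sp_basis, xy = vars$object_pos[ii, , drop = FALSE])
      acc <- acc + rowsum_mat(Pb, frame_of[ii], n_frames)
    }
    add_group("object_pos", acc / frame_cnt, seq_len(sp_basis$n_bases))
  }
  if (!length(cols)) stop("no task variables supplied")

  X <- do.call(cbind, cols)
  groups <- do.call(rbind, groups)
  groups$column <- seq_len(nrow(groups))
  structure(list(X = X, groups = groups, bases = bases,
                 frame_times = (seq_len(n_frames) - 0.5) / frame_rate,
                 frame_rate = frame_rate, sample_rate = sample_rate,
                 meta = meta),
            class = "design_matrix")
}

# contiguous-block fold assignment over frames
block_folds <- function(n, folds) {
  cut(seq_len(n), breaks = folds, labels = FALSE)
}

#' Fit ridge-regularized encoding models
#'
#' Fits an identity-link Gaussian encoding model to each unit's deconvolved
#' activity trace with ridge regularization.  The penalty is chosen per
#' outer fold by nested cross-validation on the training blocks; folds are
#' contiguous frame blocks to respect temporal autocorrelation.  The
#' pseudo-explained variance is
#' \code{1 - SSE(model) / SSE(intercept-only)} on held-out frames, averaged
#' over folds.  All units share the design, so the expensive factorizations
#' are computed once per (fold, lambda) and reused across units.
#'
#' @param design a \code{\link{build_design_matrix}} result (or a plain
#'   numeric matrix).
#' @param activity frames x units activity matrix (or a single trace).
#' @param folds number of cross-validation folds (>= 3).
#' @param lambdas candidate ridge penalties.
#' @param seed reserved for API stability (the fold assignment is
#'   deterministic).
#' @return an object of class \code{"encoding_fit"}: \code{weights}
#'   (predictors x units, refit on all data at the median selected
#'   penalty), \code{intercept}, \code{pseudo_ev} (per unit),
#'   \code{group_ev} (variables x units: pseudo-EV of each variable's
#'   partial prediction), \code{lambda} (per fold), \code{groups}.
#' @export
fit_glm <- function(design, activity, folds = 5L,
                    lambdas = 10^seq(-1, 4, by = 1), seed = 0L) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(activity)
  if (nrow(Y) != nrow(X)) stop("activity length does not match design rows")
  if (!all(is.finite(Y))) stop("activity contains non-finite values")
  if (folds < 3) stop("need at least 3 folds")
  n <- nrow(X); P <- ncol(X); U <- ncol(Y)
  # center once; ridge then needs no penalized intercept
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  fid <- block_folds(n, folds)

  XtX_f <- lapply(seq_len(folds), function(f) crossprod(Xc[fid == f, , drop = FALSE]))
  XtY_f <- lapply(seq_len(folds), function(f) {
    crossprod(Xc[fid == f, , drop = FALSE], Yc[fid == f, , drop = FALSE])
  })
  XtX_all <- Reduce(`+`, XtX_f)
  XtY_all <- Reduce(`+`, XtY_f)

  solve_ridge <- function(A, B, lam) {
    R <- chol(A + diag(lam, P))
    backsolve(R, backsolve(R, B, transpose = TRUE))
  }

  sse <- function(res) colSums(res^2)
  ev_fold <- matrix(0, folds, U)
  lambda_idx <- matrix(0L, folds, U)   # per-unit penalty per outer fold
  for (f in seq_len(folds)) {
    tr <- seq_len(folds)[-f]
    A_tr <- XtX_all - XtX_f[[f]]
    B_tr <- XtY_all - XtY_f[[f]]
    # inner CV over the training blocks, per candidate penalty
    inner_err <- matrix(0, length(lambdas), U)
    for (g in tr) {
      A_in <- A_tr - XtX_f[[g]]
      B_in <- B_tr - XtY_f[[g]]
      Xg <- Xc[fid == g, , drop = FALSE]; Yg <- Yc[fid == g, , drop = FALSE]
      for (li in seq_along(lambdas)) {
        W <- solve_ridge(A_in, B_in, lambdas[li])
        inner_err[li, ] <- inner_err[li, ] + sse(Yg - Xg %*% W)
      }
    }
    best <- apply(inner_err, 2, which.min)
    lambda_idx[f, ] <- best
    Xf <- Xc[fid == f, , drop = FALSE]; Yf <- Yc[fid == f, , drop = FALSE]
    for (li in unique(best)) {
      uu <- which(best == li)
      W <- solve_ridge(A_tr, B_tr[, uu, drop = FALSE], lambdas[li])
      ev_fold[f, uu] <- 1 - sse(Yf[, uu, drop = FALSE] - Xf %*% W) /
        pmax(sse(Yf[, uu, drop = FALSE]), 1e-12)
    }
  }
  pseudo_ev <- colMeans(ev_fold)

  # final refit on all data at each unit's median selected penalty
  lam_unit <- apply(lambda_idx, 2, function(ix) as.integer(stats::median(ix)))
  W <- matrix(0, P, U)
  for (li in unique(lam_unit)) {
    uu <- which(lam_unit == li)
    W[, uu] <- solve_ridge(XtX_all, XtY_all[, uu, drop = FALSE], lambdas[li])
  }
  intercept <- ym - as.numeric(crossprod(W, xm))

  # per-variable contribution: in-sample EV of the partial prediction
  vars <- unique(if (inherits(design, "design_matrix")) design$groups$variable
                 else "all")
  groups <- if (inherits(design, "design_matrix")) design$groups
            else data.frame(variable = "all", column = seq_len(P))
  group_ev <- matrix(NA_real_, length(vars), U, dimnames = list(vars, NULL))
  for (vi in seq_along(vars)) {
    cc <- groups$column[groups$variable == vars[vi]]
    pred <- Xc[, cc, drop = FALSE] %*% W[cc, , drop = FALSE]
    group_ev[vi, ] <- 1 - colSums((Yc - pred)^2) / pmax(colSums(Yc^2), 1e-12)
  }

  structure(list(weights = W, intercept = intercept, pseudo_ev = pseudo_ev,
                 group_ev = group_ev, lambda = lambdas[lam_unit],
                 lambdas = lambdas, lam_unit_idx = lam_unit,
                 Xc = Xc, XtX = XtX_all,
                 folds = folds, groups = groups,
                 design_meta = if (inherits(design, "design_matrix"))
                   design[c("bases", "meta", "frame_rate", "sample_rate")] else NULL,
                 xm = xm, ym = ym),
            class = "encoding_fit")
}

#' Marginalized response profile of fitted units
#'
#' Model-predicted response as a function of one task variable with all
#' other predictor groups held at their session means.
#'
#' @param fit an \code{\link{fit_glm}} result built from a
#'   \code{design_matrix}.
#' @param variable one of \code{"object_pos"} (10 x 10 space map),
#'   \code{"object_vel"} or \code{"joystick_vel"} (tuning over 8 directions
#'   plus a no-movement level), \code{"lick_onsets"} (lick vs no-lick pair).
#' @return a units x levels matrix: 100 columns for space, 9
#'   (\code{d0..d315, none}) for velocity, 2 (\code{lick, nolick}) for lick.
#' @export
response_profile <- function(fit, variable) {
  stopifnot(inherits(fit, "encoding_fit"))
  if (is.null(fit$design_meta)) stop("fit was not built from a design_matrix")
  g <- fit$groups
  base_resp <- fit$ym  # prediction with every predictor at its session mean
  if (variable == "object_pos") {
    cc <- g$column[g$variable == "object_pos"]
    if (!length(cc)) stop("unknown or absent variable: ", variable)
    sp <- fit$design_meta$bases$spatial
    ctr <- bin_centers(arena_binning(sp$n_side, sp$xlim, sp$ylim))
    B <- eval_basis(sp, xy = ctr)             # bins x n_bases
    Bc <- sweep(B, 2, fit$xm[cc])
    prof <- Bc %*% fit$weights[cc, , drop = FALSE]  # bins x units
    return(t(prof) + rep(base_resp, each = 1))
  }
  if (variable %in% c("object_vel", "joystick_vel")) {
    ref <- fit$design_meta$meta[[paste0(variable, "_ref_amplitude")]]
    if (is.null(ref)) stop("unknown or absent variable: ", variable)
    ev <- fit$design_meta$bases$event
    # sustained movement at the reference amplitude: predictor level is the
    # amplitude times the basis mass (equal across bases by construction)
    # sustained input of amplitude A yields predictor level A * rate * int b dt
    mass <- sum(eval_basis(ev, t = seq(ev$centers[1] - ev$width,
                                       ev$centers[1] + ev$width, by = 0.01))[, 1]) *
      0.01 * fit$design_meta$sample_rate
    # direction channels are mutually exclusive: the level-k response sets
    # channel k to the sustained reference amplitude and all others to 0
    zero_all <- 0
    for (nm in sprintf("%s_d%d", variable, (0:7) * 45)) {
      cc <- g$column[g$variable == nm]
      zero_all <- zero_all +
        as.numeric(crossprod(fit$weights[cc, , drop = FALSE], -fit$xm[cc]))
    }
    out <- matrix(NA_real_, ncol(fit$weights), 9,
                  dimnames = list(NULL, DIR_LABELS))
    for (k in 1:8) {
      cc <- g$column[g$variable == sprintf("%s_d%d", variable, (k - 1) * 45)]
      out[, k] <- base_resp + zero_all +
        ref * mass * colSums(fit$weights[cc, , drop = FALSE])
    }
    out[, 9] <- base_resp + zero_all
    return(out)
  }
  if (variable == "velocity_levels") {
    # internal: the P x 9 linear functional L such that the direction
    # profile is ym + t(L) %*% weights (used for shuffle nulls)
    ref <- fit$design_meta$meta$object_vel_ref_amplitude
    ev <- fit$design_meta$bases$event
    mass <- sum(eval_basis(ev, t = seq(ev$centers[1] - ev$width,
                                       ev$centers[1] + ev$width, by = 0.01))[, 1]) *
      0.01 * fit$design_meta$sample_rate
    L <- matrix(0, nrow(fit$weights), 9)
    for (k in 1:8) {
      cc <- g$column[g$variable == sprintf("object_vel_d%d", (k - 1) * 45)]
      L[cc, k] <- ref * mass
    }
    for (k in 1:9) {
      for (kk in 1:8) {
        cc <- g$column[g$variable == sprintf("object_vel_d%d", (kk - 1) * 45)]
        L[cc, k] <- L[cc, k] - fit$xm[cc]
      }
    }
    return(L)
  }
  if (variable == "lick_onsets") {
    cc <- g$column[g$variable == "lick_onsets"]
    if (!length(cc)) stop("unknown or absent variable: ", variable)
    ev <- fit$design_meta$bases$event
    # response to one lick: reconstructed temporal kernel averaged over the
    # second after the onset, on top of the no-lick baseline
    tt <- seq(0, 1, by = 1 / fit$design_meta$frame_rate)
    Bk <- eval_basis(ev, t = tt)
    lv_on <- colMeans(Bk) - fit$xm[cc]
    lv_off <- -fit$xm[cc]
    on <- base_resp + as.numeric(crossprod(fit$weights[cc, , drop = FALSE], lv_on))
    off <- base_resp + as.numeric(crossprod(fit$weights[cc, , drop = FALSE], lv_off))
    return(cbind(lick = on, nolick = off))
  }
  stop("unknown variable: ", variable)
}

#' Shuffle null for GLM direction profiles
#'
#' The fitted direction profile is a fixed linear functional of the
#' activity trace (given the design and each unit's selected ridge
#' penalty), so null profiles can be generated by applying the same
#' functional to surrogate traces.  The surrogates follow the
#' Freedman-Lane scheme for the movement-direction shuffle: each unit's
#' activity is decomposed into its reduced-model prediction (all
#' predictors except the object-velocity group) plus residuals, and the
#' residuals are circularly shifted against the design.  This preserves
#' the unit's relationship to position, events and its autocorrelation
#' while destroying any direction dependence.
#'
#' @param fit an \code{\link{fit_glm}} result built from a
#'   \code{design_matrix} containing \code{object_vel}.
#' @param activity the frames x units activity matrix used in the fit.
#' @param shuffles number of null profiles.
#' @param seed RNG seed.
#' @return list with \code{tuning} (units x 9 observed profile, equal to
#'   \code{response_profile(fit, "object_vel")}), \code{nulls}
#'   (function(s) giving the s-th null profile matrix), \code{shuffles}.
#' @export
velocity_profile_null <- function(fit, activity, shuffles = 1000L, seed = 0L) {
  stopifnot(inherits(fit, "encoding_fit"))
  Y <- as.matrix(activity)
  Fn <- nrow(fit$Xc)
  if (nrow(Y) != Fn) stop("activity does not match the fitted design")
  Yc <- sweep(Y, 2, fit$ym)
  L <- response_profile(fit, "velocity_levels")
  P <- nrow(L)
  vel_cols <- fit$groups$column[grepl("^object_vel_", fit$groups$variable)]
  red_cols <- setdiff(seq_len(P), vel_cols)
  lam_groups <- split(seq_len(ncol(Y)), fit$lam_unit_idx)
  Ms <- list(); Yhat_red <- matrix(0, Fn, ncol(Y))
  for (li in names(lam_groups)) {
    lam <- fit$lambdas[as.integer(li)]
    uu <- lam_groups[[li]]
    R <- chol(fit$XtX + diag(lam, P))
    Ms[[li]] <- fit$Xc %*% backsolve(R, backsolve(R, L, transpose = TRUE))
    Xr <- fit$Xc[, red_cols, drop = FALSE]
    Rr <- chol(fit$XtX[red_cols, red_cols] + diag(lam, length(red_cols)))
    Br <- backsolve(Rr, backsolve(Rr, crossprod(Xr, Yc[, uu, drop = FALSE]),
                                  transpose = TRUE))
    Yhat_red[, uu] <- Xr %*% Br
  }
  E <- Yc - Yhat_red
  base <- matrix(0, ncol(Y), 9)   # profile part from the reduced prediction
  for (li in names(lam_groups)) {
    uu <- lam_groups[[li]]
    base[uu, ] <- t(crossprod(Ms[[li]], Yhat_red[, uu, drop = FALSE]))
  }
  stream <- make_rng(seed)
  shifts <- with_stream(stream, sample.int(Fn - 1L, shuffles, replace = TRUE))
  nulls <- function(s) {
    idx <- ((seq_len(Fn) - 1L + shifts[s]) %% Fn) + 1L
    out <- base
    for (li in names(lam_groups)) {
      uu <- lam_groups[[li]]
      out[uu, ] <- out[uu, ] + t(crossprod(Ms[[li]], E[idx, uu, drop = FALSE]))
    }
    out + fit$ym
  }
  list(tuning = response_profile(fit, "object_vel"), nulls = nulls,
       shuffles = shuffles)
}
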
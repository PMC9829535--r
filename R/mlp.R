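# Multilayer-perceptron machinery used by the soft actor-critic trainer.
# Dense layers with ReLU hidden activations and a linear output, batched as
# rows; manual reverse-mode gradients so that gradients can also be taken
# with respect to the *inputs* (needed for the actor update through the
# critic) and routed through composite critics and ablation masks.

mlp_init <- function(sizes, gain = 1) {
  # sizes: c(n_in, hidden..., n_out)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- gain / sqrt(sizes[l])
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes, mask = NULL)
}

# mask: list (one per hidden layer) of multipliers (0 = ablated unit), or NULL
mlp_forward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  hs <- if (cache) vector("list", L) else NULL
  H <- X
  ones <- rep(1, nrow(X))
  for (l in seq_len(L)) {
    # affine layer via the augmented product [H 1] [W; b]
    Z <- cbind(H, ones) %*% rbind(net$W[[l]], net$b[[l]])
    if (l < L) {
      H <- Z * (Z > 0)
      if (!is.null(net$mask)) H <- H * rep(net$mask[[l]], each = nrow(H))
      if (cache) hs[[l]] <- H
    } else {
      H <- Z
    }
  }
  if (cache) list(out = H, hs = hs, X = X) else H
}

# dY: gradient of the loss wrt the network output (n x n_out)
# returns parameter gradients and (optionally) gradient wrt the input rows
mlp_backward <- function(net, fw, dY, need_dX = FALSE) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  D <- dY
  for (l in rev(seq_len(L))) {
    Hprev <- if (l == 1L) fw$X else fw$hs[[l - 1L]]
    gW[[l]] <- crossprod(Hprev, D)
    gb[[l]] <- colSums(D)
    if (l > 1L || need_dX) {
      D <- D %*% t(net$W[[l]])
      if (l > 1L) {
        act <- fw$hs[[l - 1L]]
        D <- D * (act > 0)
        # masked units pass no gradient (activation forced to 0)
        if (!is.null(net$mask)) D <- D * rep(net$mask[[l - 1L]], each = nrow(D))
      }
    }
  }
  list(gW = gW, gb = gb, dX = if (need_dX) D else NULL)
}

# ---- critics: single MLP or a composition of two frozen-architecture nets

critic_single <- function(net) {
  structure(list(kind = "single", net = net), class = "qc_critic")
}

critic_composite <- function(net1, net2, op = c("average", "max")) {
  op <- match.arg(op)
  if (!identical(net1$sizes, net2$sizes)) stop("critic architecture mismatch")
  structure(list(kind = "composite", op = op, nets = list(net1, net2)),
            class = "qc_critic")
}

critic_forward <- function(cr, X, cache = FALSE) {
  if (cr$kind == "single") {
    fw <- mlp_forward(cr$net, X, cache = cache)
    if (cache) list(out = fw$out, sub = list(fw)) else fw
  } else {
    f1 <- mlp_forward(cr$nets[[1]], X, cache = cache)
    f2 <- mlp_forward(cr$nets[[2]], X, cache = cache)
    o1 <- if (cache) f1$out else f1
    o2 <- if (cache) f2$out else f2
    out <- switch(cr$op,
                  average = (o1 + o2) / 2,
                  max = pmax(o1, o2))
    if (cache) list(out = out, sub = list(f1, f2), o1 = o1, o2 = o2) else out
  }
}

# gradients flow into both subnetworks through the combining operator
critic_backward <- function(cr, fw, dY, need_dX = FALSE) {
  if (cr$kind == "single") {
    g <- mlp_backward(cr$net, fw$sub[[1]], dY, need_dX = need_dX)
    list(grads = list(g), dX = g$dX)
  } else {
    if (cr$op == "average") {
      d1 <- dY / 2; d2 <- dY / 2
    } else {
      w1 <- (fw$o1 >= fw$o2) * 1
      d1 <- dY * w1; d2 <- dY * (1 - w1)
    }
    g1 <- mlp_backward(cr$nets[[1]], fw$sub[[1]], d1, need_dX = need_dX)
    g2 <- mlp_backward(cr$nets[[2]], fw$sub[[2]], d2, need_dX = need_dX)
    dX <- if (need_dX) g1$dX + g2$dX else NULL
    list(grads = list(g1, g2), dX = dX)
  }
}

critic_nets <- function(cr) if (cr$kind == "single") list(cr$net) else cr$nets

critic_set_nets <- function(cr, nets) {
  if (cr$kind == "single") cr$net <- nets[[1]] else cr$nets <- nets
  cr
}

# ---- flat parameter access (used by Adam and polyak updates)

net_params <- function(net) c(net$W, net$b)

net_set_params <- function(net, p) {
  L <- length(net$W)
  net$W <- p[seq_len(L)]
  net$b <- p[L + seq_len(L)]
  net
}

critic_params <- function(cr) unlist(lapply(critic_nets(cr), net_params), recursive = FALSE)

critic_set_params <- function(cr, p) {
  nets <- critic_nets(cr)
  k <- 0L
  for (i in seq_along(nets)) {
    np <- length(net_params(nets[[i]]))
    nets[[i]] <- net_set_params(nets[[i]], p[k + seq_len(np)])
    k <- k + np
  }
  critic_set_nets(cr, nets)
}

critic_grads_flat <- function(cr, bk) {
  unlist(lapply(bk$grads, function(g) c(g$gW, g$gb)), recursive = FALSE)
}

# ---- Adam optimizer over a flat list of arrays; the moment vectors are
# kept as single concatenated vectors so one update is a handful of
# vectorized operations regardless of how many weight arrays exist

adam_init <- function(params) {
  n <- sum(vapply(params, length, numeric(1)))
  list(m = numeric(n), v = numeric(n), t = 0L,
       skeleton = lapply(params, dim),
       lens = vapply(params, length, numeric(1)))
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  pv <- unlist(params, use.names = FALSE)
  gv <- unlist(grads, use.names = FALSE)
  state$m <- beta1 * state$m + (1 - beta1) * gv
  state$v <- beta2 * state$v + (1 - beta2) * gv * gv
  pv <- pv - lr * (state$m / c1) / (sqrt(state$v / c2) + eps)
  ends <- cumsum(state$lens)
  starts <- c(1, utils::head(ends, -1) + 1)
  for (i in seq_along(params)) {
    x <- pv[starts[i]:ends[i]]
    dm <- state$skeleton[[i]]
    params[[i]] <- if (is.null(dm)) x else matrix(x, dm[1], dm[2])
  }
  list(params = params, state = state)
}

polyak_update <- function(target_params, online_params, polyak) {
  for (i in seq_along(target_params)) {
    target_params[[i]] <- polyak * target_params[[i]] +
      (1 - polyak) * online_params[[i]]
  }
  target_params
}
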
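# Minimal dense-network engine: forward/backward passes with ReLU, sigmoid
# or linear activations, inverted dropout, batch normalization (pre-
# activation), and Adam / RMSProp updates. Everything operates on plain
# matrices; callers own the RNG state (wrap in with_seed_()).
#
# A "net" is list(input_dim, layers = list(<layer>...)) where each layer has
# W (fan_in x fan_out), b (fan_out), act, dropout rate, and when batchnorm is
# on: gamma, beta, run_mean, run_var.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

nn_new <- function(input_dim, widths, acts,
                   dropout = rep(0, length(widths)),
                   batchnorm = rep(FALSE, length(widths)),
                   init = "he_uniform", init_sd = 0.05) {
  stopifnot(length(widths) == length(acts),
            length(widths) == length(dropout),
            length(widths) == length(batchnorm))
  if (!init %in% c("he_uniform", "random_normal"))
    dn_stop(sprintf("unknown initializer '%s'", init), "unknown_init")
  layers <- vector("list", length(widths))
  fan_in <- input_dim
  for (l in seq_along(widths)) {
    fan_out <- widths[l]
    W <- if (init == "he_uniform") {
      limit <- sqrt(6 / fan_in)
      matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
    } else {
      matrix(stats::rnorm(fan_in * fan_out, 0, init_sd), fan_in, fan_out)
    }
    layer <- list(W = W, b = rep(0, fan_out), act = acts[l],
                  dropout = dropout[l], batchnorm = batchnorm[l])
    if (batchnorm[l]) {
      layer$gamma <- rep(1, fan_out)
      layer$beta <- rep(0, fan_out)
      layer$run_mean <- rep(0, fan_out)
      layer$run_var <- rep(1, fan_out)
    }
    layers[[l]] <- layer
    fan_in <- fan_out
  }
  list(input_dim = input_dim, layers = layers)
}

nn_activate <- function(Z, act) {
  switch(act,
         relu = pmax(Z, 0),
         sigmoid = 1 / (1 + exp(-Z)),
         linear = Z,
         dn_stop(sprintf("unknown activation '%s'", act), "unknown_activation"))
}

# Forward pass. training = TRUE activates dropout and batch statistics
# (updating running estimates in the returned net); training = FALSE uses
# running batch-norm statistics and no dropout.
nn_forward <- function(net, X, training = FALSE) {
  if (ncol(X) != net$input_dim)
    dn_stop(sprintf("input width %d does not match network input %d",
                    ncol(X), net$input_dim), "width_mismatch")
  n <- nrow(X)
  A <- X
  caches <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- A %*% ly$W
    Z <- add_rowwise(Z, ly$b)
    cache <- list(A_prev = A)
    if (ly$batchnorm) {
      if (training && n > 1L) {
        mu <- colMeans(Z)
        Zc <- add_rowwise(Z, -mu)
        v <- colMeans(Zc * Zc)
        net$layers[[l]]$run_mean <- BN_MOMENTUM * ly$run_mean + (1 - BN_MOMENTUM) * mu
        net$layers[[l]]$run_var <- BN_MOMENTUM * ly$run_var + (1 - BN_MOMENTUM) * v
      } else {
        mu <- ly$run_mean
        v <- ly$run_var
        Zc <- add_rowwise(Z, -mu)
      }
      inv_std <- 1 / sqrt(v + BN_EPS)
      Zh <- mul_rowwise(Zc, inv_std)
      Z <- add_rowwise(mul_rowwise(Zh, ly$gamma), ly$beta)
      cache$Zh <- Zh
      cache$inv_std <- inv_std
    }
    A <- nn_activate(Z, ly$act)
    cache$out <- A
    if (training && ly$dropout > 0) {
      keep <- 1 - ly$dropout
      mask <- matrix((stats::runif(length(A)) < keep) / keep, n)
      A <- A * mask
      cache$mask <- mask
    }
    caches[[l]] <- cache
  }
  list(out = A, caches = caches, net = net)
}

# Backward pass: dOut is the loss gradient w.r.t. the (post-dropout) network
# output. Returns per-layer parameter gradients and the gradient w.r.t. the
# network input (needed to chain critic gradients into the generator).
nn_backward <- function(net, caches, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    cache <- caches[[l]]
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    dZ <- switch(ly$act,
                 relu = dA * (cache$out > 0),
                 sigmoid = dA * cache$out * (1 - cache$out),
                 linear = dA)
    g <- list()
    if (ly$batchnorm) {
      n <- nrow(dZ)
      Zh <- cache$Zh
      g$gamma <- colSums(dZ * Zh)
      g$beta <- colSums(dZ)
      dZh <- mul_rowwise(dZ, ly$gamma)
      s1 <- colSums(dZh)
      s2 <- colSums(dZh * Zh)
      dZ <- mul_rowwise(n * dZh - rep(s1, each = n) - Zh * rep(s2, each = n),
                        cache$inv_std / n)
    }
    g$W <- crossprod(cache$A_prev, dZ)
    g$b <- colSums(dZ)
    grads[[l]] <- g
    dA <- tcrossprod(dZ, ly$W)
  }
  list(grads = grads, dX = dA)
}

grad_add <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  for (l in seq_along(g1)) for (p in names(g1[[l]]))
    g1[[l]][[p]] <- g1[[l]][[p]] + g2[[l]][[p]]
  g1
}

nn_param_names <- function(layer)
  intersect(c("W", "b", "gamma", "beta"), names(layer))

opt_init <- function(net, kind = c("adam", "rmsprop")) {
  kind <- match.arg(kind)
  state <- list(kind = kind, t = 0L, slots = vector("list", length(net$layers)))
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    sl <- list()
    for (p in nn_param_names(ly)) {
      z <- ly[[p]] * 0
      sl[[p]] <- if (kind == "adam") list(m = z, v = z) else list(cache = z)
    }
    state$slots[[l]] <- sl
  }
  state
}

# One optimizer step; returns list(net, state). Adam uses the cited
# algorithm's published defaults (beta1 0.9, beta2 0.999, eps 1e-8);
# RMSProp uses rho 0.9, eps 1e-8.
opt_step <- function(net, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, rho = 0.9, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (l in seq_along(net$layers)) {
    for (p in names(grads[[l]])) {
      g <- grads[[l]][[p]]
      sl <- state$slots[[l]][[p]]
      if (state$kind == "adam") {
        sl$m <- beta1 * sl$m + (1 - beta1) * g
        sl$v <- beta2 * sl$v + (1 - beta2) * g * g
        mhat <- sl$m / (1 - beta1^t)
        vhat <- sl$v / (1 - beta2^t)
        net$layers[[l]][[p]] <- net$layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      } else {
        sl$cache <- rho * sl$cache + (1 - rho) * g * g
        net$layers[[l]][[p]] <- net$layers[[l]][[p]] - lr * g / (sqrt(sl$cache) + eps)
      }
      state$slots[[l]][[p]] <- sl
    }
  }
  list(net = net, state = state)
}

# Clip every parameter of a net to [-bound, bound] (WGAN Lipschitz
# constraint on the critic).
nn_clip <- function(net, bound) {
  for (l in seq_along(net$layers))
    for (p in nn_param_names(net$layers[[l]]))
      net$layers[[l]][[p]] <- pmin(pmax(net$layers[[l]][[p]], -bound), bound)
  net
}

nn_max_abs_param <- function(net) {
  m <- 0
  for (l in seq_along(net$layers))
    for (p in nn_param_names(net$layers[[l]]))
      m <- max(m, max(abs(net$layers[[l]][[p]])))
  m
}
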
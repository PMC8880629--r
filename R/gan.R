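#' Configuration for GAN / WGAN tabular augmentation
#'
#' Describes the generator and critic used to synthesize 25-dimensional
#' formulation rows (21 features + 4 profile points on the unit scale). The
#' generator maps 100-dimensional standard-normal noise through six hidden
#' layers (500, 250, 200, 150, 100, 50 nodes, batch normalization on every
#' hidden layer) to a sigmoid output; the critic has four hidden layers
#' (150, 120, 100, 50 nodes) with dropout 0.1 on the first two and a linear
#' scalar output. Training follows the weight-clipped Wasserstein recipe:
#' RMSProp with learning rate 5e-5, clip bound 0.01, and 5 critic updates
#' per generator update.
#'
#' @param data_dim width of the real data rows (25 for SRMT).
#' @param noise_dim generator input width.
#' @param generator_hidden,critic_hidden hidden-layer widths.
#' @param clip_bound critic weights are clipped to `[-clip_bound,
#'   clip_bound]` after every critic update (Lipschitz constraint).
#' @param critic_steps critic updates per generator update.
#' @param iterations number of generator updates.
#' @param batch_size minibatch size for both networks.
#' @param learning_rate RMSProp step size.
#' @param critic_dropout dropout rates for the first hidden layers of the
#'   critic/discriminator.
#' @param seed RNG seed covering initialization and the whole training run.
#' @return An object of class `wgan_config`.
#' @export
wgan_config <- function(data_dim = 25, noise_dim = 100,
                        generator_hidden = c(500, 250, 200, 150, 100, 50),
                        critic_hidden = c(150, 120, 100, 50),
                        clip_bound = 0.01, critic_steps = 5,
                        iterations = 5000, batch_size = 64,
                        learning_rate = 5e-5,
                        critic_dropout = c(0.1, 0.1), seed = 1) {
  if (clip_bound <= 0) dn_stop("clip_bound must be positive", "bad_clip")
  if (critic_steps < 1 || iterations < 1 || batch_size < 1)
    dn_stop("critic_steps, iterations and batch_size must be >= 1",
            "bad_count")
  structure(list(data_dim = as.integer(data_dim),
                 noise_dim = as.integer(noise_dim),
                 generator_hidden = as.integer(generator_hidden),
                 critic_hidden = as.integer(critic_hidden),
                 clip_bound = clip_bound,
                 critic_steps = as.integer(critic_steps),
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 critic_dropout = critic_dropout, seed = seed),
            class = "wgan_config")
}

gan_build_nets <- function(cfg, critic_output) {
  ng <- length(cfg$generator_hidden)
  G <- nn_new(cfg$noise_dim,
              widths = c(cfg$generator_hidden, cfg$data_dim),
              acts = c(rep("relu", ng), "sigmoid"),
              batchnorm = c(rep(TRUE, ng), FALSE),
              init = "he_uniform")
  nc <- length(cfg$critic_hidden)
  cd <- rep(0, nc)
  cd[seq_along(cfg$critic_dropout)] <- cfg$critic_dropout
  C <- nn_new(cfg$data_dim,
              widths = c(cfg$critic_hidden, 1L),
              acts = c(rep("relu", nc), critic_output),
              dropout = c(cd, 0),
              init = "he_uniform")
  list(G = G, C = C)
}

check_real <- function(real, cfg) {
  real <- as.matrix(real)
  if (ncol(real) != cfg$data_dim)
    dn_stop(sprintf("real data width %d does not match data_dim %d",
                    ncol(real), cfg$data_dim), "width_mismatch")
  if (nrow(real) < cfg$batch_size)
    dn_stop("need at least batch_size real samples", "too_few_rows")
  if (min(real) < -1e-9 || max(real) > 1 + 1e-9)
    dn_stop("real data must be normalized to [0, 1]", "unnormalized")
  real
}

#' Train a weight-clipped Wasserstein GAN on tabular rows
#'
#' Alternates `critic_steps` critic updates (ascending the difference of
#' mean critic scores on real versus generated batches, then clipping every
#' critic parameter to the clip bound) with one generator update (ascending
#' the mean critic score of its samples), both via RMSProp. The critic's
#' real-minus-fake score difference estimates the Wasserstein distance
#' between the data and generator distributions; unlike the vanilla GAN
#' loss it keeps gradients informative and discourages mode collapse.
#'
#' @param real n x data_dim matrix on the unit scale.
#' @param cfg a [wgan_config()].
#' @return An object of class `gan_generator` (fields `net`, `noise_dim`,
#'   `data_dim`, `kind`, and per-iteration `history` of the critic's
#'   real-minus-fake score gap).
#' @export
train_wgan <- function(real, cfg) {
  stopifnot(inherits(cfg, "wgan_config"))
  real <- check_real(real, cfg)
  n <- nrow(real)
  nb <- cfg$batch_size
  history <- numeric(cfg$iterations)
  with_seed_(cfg$seed, {
    nets <- gan_build_nets(cfg, critic_output = "linear")
    G <- nets$G; C <- nets$C
    sG <- opt_init(G, "rmsprop")
    sC <- opt_init(C, "rmsprop")
    for (it in seq_len(cfg$iterations)) {
      gap <- 0
      for (s in seq_len(cfg$critic_steps)) {
        Xr <- real[sample.int(n, nb), , drop = FALSE]
        Z <- matrix(stats::rnorm(nb * cfg$noise_dim), nb)
        fwG <- nn_forward(G, Z, training = TRUE)
        G <- fwG$net  # batch-norm running stats advance
        Xf <- fwG$out
        fr <- nn_forward(C, Xr, training = TRUE)
        ff <- nn_forward(C, Xf, training = TRUE)
        gap <- mean(fr$out) - mean(ff$out)
        # minimize mean(C(fake)) - mean(C(real))
        gr <- nn_backward(C, fr$caches, matrix(-1 / nb, nb, 1))
        gf <- nn_backward(C, ff$caches, matrix(1 / nb, nb, 1))
        st <- opt_step(C, grad_add(gr$grads, gf$grads), sC, cfg$learning_rate)
        C <- nn_clip(st$net, cfg$clip_bound)
        sC <- st$state
      }
      Z <- matrix(stats::rnorm(nb * cfg$noise_dim), nb)
      fwG <- nn_forward(G, Z, training = TRUE)
      G <- fwG$net
      fc <- nn_forward(C, fwG$out, training = TRUE)
      # minimize -mean(C(fake))
      bc <- nn_backward(C, fc$caches, matrix(-1 / nb, nb, 1))
      bg <- nn_backward(G, fwG$caches, bc$dX)
      st <- opt_step(G, bg$grads, sG, cfg$learning_rate)
      G <- st$net
      sG <- st$state
      history[it] <- gap
    }
  })
  structure(list(net = G, critic = C, noise_dim = cfg$noise_dim,
                 data_dim = cfg$data_dim, kind = "wgan", history = history),
            class = "gan_generator")
}

#' Train a vanilla GAN (mode-collapse baseline)
#'
#' Same architectures as [train_wgan()] but with a sigmoid discriminator
#' trained under binary cross-entropy and a non-saturating generator loss,
#' optimized with Adam. Serves as the baseline whose generated samples tend
#' to concentrate (mode collapse), diagnosed with [project_2d()].
#'
#' @param real n x data_dim matrix on the unit scale.
#' @param cfg a [wgan_config()]; `clip_bound` is ignored and
#'   `critic_steps` is the number of discriminator updates per generator
#'   update (1 for the classic protocol).
#' @param learning_rate Adam step size for both networks.
#' @return A `gan_generator` with `kind = "gan"`; `history` holds the
#'   discriminator loss per iteration.
#' @export
train_gan <- function(real, cfg, learning_rate = 2e-4) {
  stopifnot(inherits(cfg, "wgan_config"))
  real <- check_real(real, cfg)
  n <- nrow(real)
  nb <- cfg$batch_size
  eps <- 1e-7
  history <- numeric(cfg$iterations)
  with_seed_(cfg$seed, {
    nets <- gan_build_nets(cfg, critic_output = "sigmoid")
    G <- nets$G; D <- nets$C
    sG <- opt_init(G, "adam")
    sD <- opt_init(D, "adam")
    for (it in seq_len(cfg$iterations)) {
      dloss <- 0
      for (s in seq_len(cfg$critic_steps)) {
        Xr <- real[sample.int(n, nb), , drop = FALSE]
        Z <- matrix(stats::rnorm(nb * cfg$noise_dim), nb)
        fwG <- nn_forward(G, Z, training = TRUE)
        G <- fwG$net
        fr <- nn_forward(D, Xr, training = TRUE)
        ff <- nn_forward(D, fwG$out, training = TRUE)
        pr <- pmin(pmax(fr$out, eps), 1 - eps)
        pf <- pmin(pmax(ff$out, eps), 1 - eps)
        dloss <- -mean(log(pr)) - mean(log(1 - pf))
        gr <- nn_backward(D, fr$caches, -1 / (nb * pr))
        gf <- nn_backward(D, ff$caches, 1 / (nb * (1 - pf)))
        st <- opt_step(D, grad_add(gr$grads, gf$grads), sD, learning_rate,
                       beta1 = 0.5)
        D <- st$net
        sD <- st$state
      }
      Z <- matrix(stats::rnorm(nb * cfg$noise_dim), nb)
      fwG <- nn_forward(G, Z, training = TRUE)
      G <- fwG$net
      fd <- nn_forward(D, fwG$out, training = TRUE)
      pf <- pmin(pmax(fd$out, eps), 1 - eps)
      bd <- nn_backward(D, fd$caches, -1 / (nb * pf))  # non-saturating loss
      bg <- nn_backward(G, fwG$caches, bd$dX)
      st <- opt_step(G, bg$grads, sG, learning_rate, beta1 = 0.5)
      G <- st$net
      sG <- st$state
      history[it] <- dloss
    }
  })
  structure(list(net = G, critic = D, noise_dim = cfg$noise_dim,
                 data_dim = cfg$data_dim, kind = "gan", history = history),
            class = "gan_generator")
}

#' @export
print.gan_generator <- function(x, ...) {
  cat(sprintf("<gan_generator %s> noise %d -> data %d; trained %d iterations\n",
              x$kind, x$noise_dim, x$data_dim, length(x$history)))
  invisible(x)
}

#' Sample rows from a trained generator
#'
#' Draws standard-normal noise and passes it through the generator in
#' inference mode (batch-norm running statistics, no dropout); the sigmoid
#' output keeps every value in (0, 1).
#'
#' @param generator a `gan_generator`.
#' @param n number of rows (0 gives an empty matrix).
#' @param seed RNG seed.
#' @return n x data_dim matrix.
#' @export
generate_samples <- function(generator, n, seed = 1) {
  stopifnot(inherits(generator, "gan_generator"))
  if (n == 0L) return(matrix(numeric(0), 0L, generator$data_dim))
  with_seed_(seed, {
    Z <- matrix(stats::rnorm(n * generator$noise_dim), n)
    nn_forward(generator$net, Z, training = FALSE)$out
  })
}

#' 2-D PCA projection diagnostic for mode collapse
#'
#' Fits a 2-component PCA on the real rows only and projects both sets onto
#' it, giving the scatter coordinates used to inspect how generated samples
#' occupy the data space. The dispersion ratio — trace of the generated
#' scores' covariance over trace of the real scores' covariance — is a
#' scalar collapse diagnostic: near 0 means the generator concentrated on
#' few points, near 1 means it matched the real spread.
#'
#' @param real,generated matrices of matching width.
#' @return List with `real` and `generated` n x 2 score matrices and
#'   `dispersion_ratio`.
#' @export
project_2d <- function(real, generated) {
  real <- as.matrix(real)
  generated <- as.matrix(generated)
  if (ncol(real) != ncol(generated))
    dn_stop("real and generated must have matching widths", "width_mismatch")
  if (nrow(real) < 3L)
    dn_stop("need at least 3 real rows", "too_few_rows")
  pm <- fit_pca(real)
  R2 <- pca_transform(pm, real, 2L)
  G2 <- pca_transform(pm, generated, 2L)
  ratio <- sum(diag(stats::cov(G2))) / sum(diag(stats::cov(R2)))
  list(real = R2, generated = G2, dispersion_ratio = ratio)
}
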
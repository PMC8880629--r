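# Shared fixtures, all built in code.

# Per-class counts of the original 105-row SRMT training data.
original_class_counts <- c(5L, 4L, 7L, 8L, 9L, 13L, 20L, 15L, 9L, 15L)

# The ten published example profiles for the cumulative-release check:
# five valid (non-decreasing) and five physically impossible.
valid_profiles <- rbind(
  c(0.070, 0.234, 0.824, 0.855),
  c(0.302, 0.575, 0.785, 0.910),
  c(0.100, 0.386, 0.934, 0.942),
  c(0.214, 0.305, 0.409, 0.441),
  c(0.131, 0.328, 0.455, 0.497))
invalid_profiles <- rbind(
  c(0.244, 0.513, 0.798, 0.718),
  c(0.365, 0.316, 0.580, 0.575),
  c(0.358, 0.469, 0.728, 0.696),
  c(0.368, 0.271, 0.572, 0.571),
  c(0.453, 0.248, 0.688, 0.652))

# A tiny raw dataset with known values.
tiny_ds <- function(n = 6, p = 3, q = 1, seed = 1) {
  withr::with_seed(seed, {
    formulation_dataset(matrix(runif(n * p, 0, 10), n, p),
                        matrix(runif(n * q, 0, 100), n, q))
  })
}

# A 25-column dataset whose rows carry prescribed class labels (for
# oversampling-contract tests); labels are returned as an attribute.
labeled_rows <- function(counts, seed = 1) {
  n <- sum(counts)
  labels <- rep(seq_along(counts) - 1L, counts)
  withr::with_seed(seed, {
    X <- matrix(runif(n * 21), n, 21)
    # targets: monotone profiles whose final value falls in the label's bin
    y4 <- (labels + runif(n, 0.05, 0.95)) / 10
    Y <- t(vapply(y4, function(v) sort(runif(4, 0, v)), numeric(4)))
    Y[, 4] <- y4
    ds <- formulation_dataset(X, Y, normalized = TRUE, target_scale = 100)
    attr(ds, "labels") <- labels
    ds
  })
}

# Two well-separated 25-dimensional clusters on the unit scale: the toy
# bimodal distribution for mode-collapse diagnostics.
bimodal_real <- function(n = 200, sd = 0.02, seed = 42) {
  centers <- rep(c(0.25, 0.75), each = n / 2)
  withr::with_seed(seed,
    pmin(pmax(matrix(rnorm(n * 25, centers, sd), n, 25), 0), 1))
}

# Small-architecture GAN config for desk-scale experiments.
toy_gan_config <- function(iterations, seed, learning_rate = 5e-5,
                           clip_bound = 0.01, critic_steps = 5) {
  wgan_config(data_dim = 25, noise_dim = 8,
              generator_hidden = c(32, 32), critic_hidden = c(32, 32),
              iterations = iterations, batch_size = 64,
              learning_rate = learning_rate, clip_bound = clip_bound,
              critic_steps = critic_steps, seed = seed)
}

# Fraction of generated rows nearest each of the two toy modes.
mode_shares <- function(samples) {
  hi <- mean(rowMeans(samples) > 0.5)
  c(lo = 1 - hi, hi = hi)
}
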
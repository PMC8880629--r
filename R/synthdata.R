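#' Configuration for the synthetic formulation-data generators
#'
#' @param n_samples number of formulations to generate (>= 10).
#' @param n_latent number of latent formulation factors behind the OFDF
#'   feature block structure (default 5, the dimensionality the scree elbow
#'   should recover).
#' @param noise_sd measurement-noise standard deviation on the unit target
#'   scale (also scales feature noise). Default 0.02, i.e. about 2 s on the
#'   disintegration-time scale and 2 percentage points of dissolution,
#'   typical assay repeatability.
#' @param imbalance_profile per-class proportions over the 10 binned
#'   final-dissolution labels (SRMT). Defaults to the class frequencies of
#'   the original 105-sample training data: counts
#'   (5, 4, 7, 8, 9, 13, 20, 15, 9, 15) / 105.
#' @param seed RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_samples, n_latent = 5, noise_sd = 0.02,
                         imbalance_profile =
                           c(5, 4, 7, 8, 9, 13, 20, 15, 9, 15) / 105,
                         seed = 1) {
  if (n_samples < 10) dn_stop("n_samples must be >= 10", "bad_config")
  if (n_latent < 1 || n_latent >= 21)
    dn_stop("n_latent must be in 1..20", "bad_config")
  if (noise_sd < 0) dn_stop("noise_sd must be non-negative", "bad_config")
  if (length(imbalance_profile) != 10 ||
      abs(sum(imbalance_profile) - 1) > 1e-8 || any(imbalance_profile < 0))
    dn_stop("imbalance_profile must be 10 non-negative proportions summing to 1",
            "bad_config")
  structure(list(n_samples = as.integer(n_samples),
                 n_latent = as.integer(n_latent),
                 noise_sd = noise_sd,
                 imbalance_profile = imbalance_profile, seed = seed),
            class = "synth_config")
}

# Fixed OFDF loading design: 24 features in n_latent blocks, block sizes
# chosen so that (after per-column min-max scaling) the eigenvalue scree of
# the feature covariance is flat-to-concave early and drops into its floor
# at component n_latent, making the elbow land there. For the default 5
# factors the sizes are (6, 6, 6, 5, 1).
ofdf_block_sizes <- function(k) {
  if (k == 5L) return(c(6L, 6L, 6L, 5L, 1L))
  w <- c(seq(k, 2, length.out = k - 1), 0.6)
  base <- floor(w / sum(w) * 24)
  base[base < 1] <- 1L
  while (sum(base) > 24) base[which.max(base)] <- base[which.max(base)] - 1L
  while (sum(base) < 24) base[which.max(w - base / 24)] <- base[which.max(w - base / 24)] + 1L
  as.integer(base)
}

ofdf_feature_names <- c(
  "molecular_weight", "xlogp3", "hbond_donors", "hbond_acceptors",
  "rotatable_bonds", "tpsa", "heavy_atoms", "complexity", "logs",
  "film_former_code", "secondary_polymer_code", "plasticizer_code",
  "surfactant_code", "sweetener_code", "flavor_code", "disintegrant_code",
  "filler_code", "colorant_code",
  "weight_mg", "thickness_um", "tensile_strength", "elongation_pct",
  "folding_endurance", "drug_content_pct")

#' Generate a synthetic OFDF-structured dataset
#'
#' Emulates the statistical shape of an oral-film formulation table:
#' 24 numeric features driven by `n_latent` independent latent formulation
#' factors through a fixed block-loading design (producing the strongly
#' correlated feature pairs typical of such data, and a covariance scree
#' whose elbow sits at `n_latent`), plus one disintegration-time target in
#' seconds on a 0-100 s scale, a smooth bounded nonlinear function of the
#' latent factors with additive noise. With `noise_sd = 0` the feature
#' matrix has exact rank `n_latent`.
#'
#' Targets are raw seconds; run [normalize_dataset()] with
#' `target_scale = 100` before training.
#'
#' @param cfg a [synth_config()].
#' @return A [formulation_dataset()] with 24 features and 1 target.
#' @export
gen_ofdf <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_samples
  k <- cfg$n_latent
  sizes <- ofdf_block_sizes(k)
  factor_of <- rep(seq_len(k), sizes)
  # fixed per-column affine placement and loading signs (deterministic
  # design, independent of the seed, so the spectral shape is stable)
  centers <- rep(c(200, 3, 8, 60, 40, 120), length.out = 24)
  scales <- rep(c(50, 1.5, 2, 12, 8, 25), length.out = 24)
  signs <- rep(c(1, 1, 1, -1), length.out = 24)
  with_seed_(cfg$seed, {
    U <- matrix(stats::runif(n * k), n, k)
    E <- matrix(stats::rnorm(n * 24, 0, cfg$noise_sd), n, 24)
    X <- matrix(0, n, 24)
    for (j in seq_len(24))
      X[, j] <- centers[j] + scales[j] * (signs[j] * U[, factor_of[j]] + E[, j])
    u <- function(f) U[, min(f, k)]
    g <- (1.2 * u(1) + 0.9 * u(2)^2 +
            0.6 * stats::plogis(4 * (u(3) - 0.5)) +
            0.4 * u(4) * u(5) + 0.3 * u(5)) / 3.4
    y01 <- pmin(pmax(0.1 + 0.8 * g + stats::rnorm(n, 0, cfg$noise_sd), 0), 1)
    formulation_dataset(X, matrix(100 * y01, ncol = 1),
                        feature_names = ofdf_feature_names,
                        target_names = "disintegration_time_s")
  })
}

srmt_feature_names <- c(
  "molecular_weight", "xlogp3", "hbond_donors", "hbond_acceptors",
  "rotatable_bonds", "tpsa", "heavy_atoms", "complexity", "logs",
  "matrix_former_code", "polymer_grade_code", "binder_code", "filler_code",
  "lubricant_code", "glidant_code", "surfactant_code",
  "release_modifier_code", "coating_code",
  "granulation_process", "diameter_mm", "hardness_n")

# Largest-remainder apportionment of n samples to the profile's 10 classes.
class_quotas <- function(n, profile) {
  raw <- n * profile
  q <- floor(raw)
  rem <- n - sum(q)
  if (rem > 0) {
    extra <- order(raw - q, decreasing = TRUE)[seq_len(rem)]
    q[extra] <- q[extra] + 1
  }
  as.integer(q)
}

#' Generate a synthetic SRMT-structured dataset
#'
#' Emulates a sustained-release tablet table: each formulation carries
#' Weibull release kinetics
#' \eqn{F(t) = F_{max} (1 - \exp(-(t/\tau)^\beta))}
#' with \eqn{F_{max} \in [0.3, 1]}, scale \eqn{\tau \in [1.2, 30]} h and
#' shape \eqn{\beta \in [0.6, 2.5]}, evaluated at 2, 4, 6 and 8 h to give a
#' monotone cumulative dissolution profile (percent scale). Assay noise is
#' added and the profile re-sorted, so every generated profile satisfies
#' the cumulative constraint. The binned final-dissolution label
#' (`floor(10 F(8h))`) follows `imbalance_profile` exactly: kinetic
#' parameters are rejection-sampled per class quota and the noisy 8-hour
#' value is kept inside its class bin.
#'
#' The 21 features mix descriptor-like columns, excipient codes and
#' process parameters; several are informative transforms of the kinetic
#' parameters (hardness and solubility track \eqn{\tau}, granulation and
#' XlogP3 track \eqn{\beta}, the surfactant code tracks \eqn{F_{max}}), so
#' the profiles are learnable from the features.
#'
#' @param cfg a [synth_config()].
#' @return A [formulation_dataset()] with 21 features and 4 targets
#'   (percent cumulative dissolution at 2, 4, 6, 8 h).
#' @export
gen_srmt <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_samples
  quotas <- class_quotas(n, cfg$imbalance_profile)
  tpts <- c(2, 4, 6, 8)
  with_seed_(cfg$seed, {
    need <- quotas
    fmax <- tau <- beta <- numeric(0)
    labs <- integer(0)
    rounds <- 0L
    while (sum(need) > 0 && rounds < 500L) {
      rounds <- rounds + 1L
      m <- max(200L, 4L * sum(need))
      fm <- stats::runif(m, 0.3, 1)
      tu <- exp(stats::runif(m, log(1.2), log(30)))
      be <- stats::runif(m, 0.6, 2.5)
      f8 <- fm * (1 - exp(-(8 / tu)^be))
      lb <- pmin(floor(10 * f8), 9)
      for (i in seq_len(m)) {
        cl <- lb[i] + 1L
        if (need[cl] > 0L) {
          need[cl] <- need[cl] - 1L
          fmax <- c(fmax, fm[i]); tau <- c(tau, tu[i]); beta <- c(beta, be[i])
          labs <- c(labs, lb[i])
          if (sum(need) == 0L) break
        }
      }
    }
    if (sum(need) > 0)
      dn_stop("rejection sampling failed to fill class quotas", "bad_config")
    # profiles (percent), noisy but monotone and label-preserving
    Y <- t(vapply(seq_len(n), function(i)
      100 * fmax[i] * (1 - exp(-(tpts / tau[i])^beta[i])), numeric(4)))
    Y <- Y + matrix(stats::rnorm(n * 4, 0, 100 * cfg$noise_sd), n, 4)
    Y <- t(apply(Y, 1, sort))
    lo <- 10 * labs
    hi <- 10 * (labs + 1) - 1e-6
    Y[, 4] <- pmin(pmax(Y[, 4], lo), hi)
    for (j in 3:1) Y[, j] <- pmin(Y[, j], Y[, j + 1])
    Y <- pmin(pmax(Y, 0), 100)
    # features linked to the kinetics
    lt <- log(tau)
    ns <- cfg$noise_sd / 0.02  # noise multiplier relative to the default
    z <- function(s) stats::rnorm(n, 0, s * ns)
    X <- cbind(
      molecular_weight = 250 + 40 * lt + z(20),
      xlogp3 = 1 + 0.8 * beta + z(0.4),
      hbond_donors = 2 + 0.6 * fmax * 4 + z(0.5),
      hbond_acceptors = 5 + 0.4 * lt + z(0.8),
      rotatable_bonds = 5 + z(1.5),
      tpsa = 80 + 6 * lt + z(8),
      heavy_atoms = 25 + 3 * lt + z(2),
      complexity = 300 + 60 * lt + z(40),
      logs = -2 - 1.1 * lt - 0.4 * beta + z(0.3),
      matrix_former_code = sample(1:5, n, replace = TRUE),
      polymer_grade_code = 1 + floor(3 * pmin((lt - log(1.2)) / (log(30) - log(1.2)), 0.999)),
      binder_code = sample(1:4, n, replace = TRUE),
      filler_code = sample(1:5, n, replace = TRUE),
      lubricant_code = sample(1:3, n, replace = TRUE),
      glidant_code = sample(1:3, n, replace = TRUE),
      surfactant_code = 1 + floor(7.99 * (fmax - 0.3) / 0.7),
      release_modifier_code = 1 + floor(3.99 * pmin((beta - 0.6) / 1.9, 0.999)),
      coating_code = sample(1:4, n, replace = TRUE),
      granulation_process = stats::rbinom(n, 1, stats::plogis(2 * (beta - 1.5))),
      diameter_mm = 7 + 2 * stats::runif(n),
      hardness_n = 50 + 12 * lt + z(2))
    colnames(X) <- srmt_feature_names
    ds <- formulation_dataset(X, Y,
                              feature_names = srmt_feature_names,
                              target_names = paste0("dissolution_pct_", tpts, "h"))
    # underlying release kinetics, kept for diagnostics and oracle checks
    attr(ds, "kinetics") <- data.frame(fmax = fmax, tau = tau, beta = beta,
                                       label = labs)
    ds
  })
}
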
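#' Fit a full principal component decomposition
#'
#' Eigendecomposition of the covariance matrix of the (column-centered)
#' training features. The full orthonormal basis is retained; choosing how
#' many components to keep is deferred to [select_elbow()] /
#' [cumulative_variance()], so validation and test data can later be
#' projected with exactly the training-fitted mean and axes.
#'
#' @param train_features numeric matrix with at least 2 rows.
#' @return An object of class `pca_model` with fields `mean` (per-feature
#'   mean), `components` (p x p orthonormal matrix, columns are axes) and
#'   `eigenvalues` (non-increasing, clipped at 0).
#' @export
fit_pca <- function(train_features) {
  X <- as.matrix(train_features)
  if (nrow(X) < 2L)
    dn_stop("PCA requires at least 2 samples", "too_few_rows")
  mu <- colMeans(X)
  S <- stats::cov(X)
  e <- eigen(S, symmetric = TRUE)
  ev <- e$values
  ev[ev < 0 & ev > -1e-12] <- 0
  if (any(ev < 0)) ev <- pmax(ev, 0)  # numerical guard for larger jitter
  structure(list(mean = mu, components = e$vectors, eigenvalues = ev),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d features; leading eigenvalues: %s\n",
              length(x$mean),
              paste(signif(utils::head(x$eigenvalues, 5), 3), collapse = ", ")))
  invisible(x)
}

#' Automatic elbow selection on a scree curve
#'
#' Locates the scree-plot elbow as the interior index maximizing the discrete
#' second-order difference of the eigenvalue sequence (the point where the
#' slope softens most sharply). Ties break toward the smallest index; a
#' curve with no positive curvature (e.g. all eigenvalues equal, or exactly
#' linear decay) has no elbow and yields `k = 1`. The choice is invariant to
#' rescaling all eigenvalues by a positive constant.
#'
#' @param eigenvalues non-increasing numeric vector, length >= 3.
#' @return Integer component count `k`.
#' @export
select_elbow <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  n <- length(ev)
  if (n < 3L)
    dn_stop("elbow selection needs at least 3 eigenvalues", "too_few_values")
  if (is.unsorted(rev(ev) - 1e-12 * max(abs(ev), 1)))
    dn_stop("eigenvalues must be non-increasing", "not_sorted")
  i <- 2:(n - 1L)
  d2 <- ev[i - 1L] - 2 * ev[i] + ev[i + 1L]
  tol <- 1e-10 * max(abs(ev), .Machine$double.xmin)
  if (max(d2) <= tol) return(1L)
  as.integer(i[which.max(d2)])
}

#' Cumulative percentage of variance
#'
#' Running fraction of total variance explained by the leading components.
#'
#' @param eigenvalues non-negative numeric vector with positive sum.
#' @return Non-decreasing vector of fractions ending at 1.
#' @export
cumulative_variance <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  if (any(ev < 0))
    dn_stop("eigenvalues must be non-negative", "negative_eigenvalue")
  if (sum(ev) <= 0)
    dn_stop("eigenvalues are all zero", "zero_variance")
  cumsum(ev) / sum(ev)
}

#' Project features onto leading principal components
#'
#' Centers `features` by the training-fitted mean and returns scores on the
#' first `k` components. Applying this to validation/test data with a model
#' fitted on the training part keeps preprocessing leakage-free.
#'
#' @param model a [fit_pca()] model.
#' @param features matrix with the fitted feature width.
#' @param k number of components, `1 <= k <= n_features`.
#' @return n x k score matrix.
#' @export
pca_transform <- function(model, features, k) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(features)
  p <- length(model$mean)
  if (ncol(X) != p)
    dn_stop(sprintf("feature width %d does not match fitted width %d",
                    ncol(X), p), "width_mismatch")
  if (k < 1L || k > p)
    dn_stop(sprintf("k = %d out of range 1..%d", k, p), "bad_k")
  add_rowwise(X, -model$mean) %*% model$components[, seq_len(k), drop = FALSE]
}

#' Pearson correlation matrix with constant-column convention
#'
#' Symmetric matrix of pairwise correlations with unit diagonal. Constant
#' columns have undefined correlation; they are reported as 0 off-diagonal
#' with a warning, which is the convention used when plotting
#' before/after-PCA correlation structure.
#'
#' @param features numeric matrix.
#' @return Symmetric matrix in `[-1, 1]` with unit diagonal.
#' @export
correlation_matrix <- function(features) {
  X <- as.matrix(features)
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0
  if (any(const))
    dn_warn(sprintf("constant column(s) assigned zero correlation: %s",
                    paste(which(const), collapse = ", ")), "constant_column")
  C <- suppressWarnings(stats::cor(X))
  C[const, ] <- 0
  C[, const] <- 0
  diag(C) <- 1
  C
}
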
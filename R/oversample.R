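#' Bin final dissolution values into 10 integer classes
#'
#' Multiplies the 8-hour cumulative dissolution fraction by 10 and drops
#' the decimal part, yielding labels 0..9 for class-based oversampling of
#' the otherwise continuous targets. A value of exactly 1.0 is clipped to
#' label 9 so that no 11th class appears.
#'
#' @param targets n x 4 matrix of profiles on the unit scale, or a numeric
#'   vector of final values.
#' @return Integer vector of labels in 0..9.
#' @export
bin_final_dissolution <- function(targets) {
  v <- if (is.matrix(targets)) targets[, ncol(targets)] else as.numeric(targets)
  if (any(v < 0 | v > 1))
    dn_stop("final dissolution values must lie in [0, 1]", "out_of_range")
  pmin(as.integer(floor(10 * v)), 9L)
}

#' Test the cumulative (monotone non-decreasing) release constraint
#'
#' Cumulative dissolution cannot decrease over time, so a physically valid
#' 4-point profile must be non-decreasing; ties are allowed.
#'
#' @param profile numeric vector of 4 cumulative release values.
#' @return `TRUE` iff the profile is non-decreasing.
#' @export
is_cumulative <- function(profile) {
  v <- as.numeric(profile)
  if (length(v) != 4L || !all(is.finite(v)))
    dn_stop("profile must be 4 finite values", "bad_profile")
  all(diff(v) >= 0)
}

#' Remove generated samples violating the cumulative constraint
#'
#' Applied to generator output (rows of concatenated features and profile,
#' profile in the last 4 columns): keeps only rows whose profile passes
#' [is_cumulative()], preserving order. Idempotent.
#'
#' @param samples numeric matrix whose last 4 columns are the profile.
#' @return List with `kept` (the surviving rows) and `n_removed`.
#' @export
filter_cumulative <- function(samples) {
  samples <- as.matrix(samples)
  if (ncol(samples) < 4L)
    dn_stop("samples must have at least 4 (profile) columns", "bad_shape")
  prof <- samples[, ncol(samples) - 3:0, drop = FALSE]
  ok <- apply(prof, 1, function(v) all(diff(v) >= 0))
  list(kept = samples[ok, , drop = FALSE], n_removed = sum(!ok))
}

# Euclidean nearest neighbours of row i within matrix M (excluding i),
# returning up to k indices.
knn_indices <- function(M, i, k, pool = seq_len(nrow(M))) {
  pool <- setdiff(pool, i)
  d <- sqrt(colSums((t(M[pool, , drop = FALSE]) - M[i, ])^2))
  pool[order(d)][seq_len(min(k, length(pool)))]
}

#' Oversample minority classes of a binned formulation dataset
#'
#' Balances the classes produced by [bin_final_dissolution()] by appending
#' synthetic rows. Interpolation operates on the concatenated
#' `[features, targets]` vector (25 columns for SRMT) so each synthetic row
#' carries both a formulation and a profile; all original rows are kept
#' verbatim, in order, ahead of the synthetic rows.
#'
#' * `ros` duplicates randomly drawn minority rows until every class
#'   reaches the majority count (exact balance).
#' * `smote` interpolates between a minority row and one of its k nearest
#'   same-class neighbours, `new = x + u (x_nn - x)`, u ~ U(0, 1)
#'   (exact balance).
#' * `adasyn` allocates synthetic counts per minority row in proportion to
#'   the share of other-class points among its k nearest neighbours in the
#'   full data, so harder regions get more synthesis (near balance; totals
#'   are data-dependent through rounding).
#'
#' The neighbour count k (default 5) is reduced to class size minus one for
#' classes too small to supply 5 neighbours.
#'
#' @param ds a [formulation_dataset()] (any consistent scale; normally the
#'   normalized training part).
#' @param labels integer class labels aligned with the rows.
#' @param method `"ros"`, `"smote"` or `"adasyn"`.
#' @param seed RNG seed.
#' @param k neighbour count for the interpolating methods.
#' @return A [formulation_dataset()] whose `provenance` marks synthetic
#'   rows with the method name.
#' @export
oversample <- function(ds, labels, method = c("ros", "smote", "adasyn"),
                       seed = 1, k = 5) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "formulation_dataset"))
  if (length(labels) != n_samples(ds))
    dn_stop("labels must align with dataset rows", "length_mismatch")
  M <- cbind(ds$features, ds$targets)
  counts <- table(labels)
  n_max <- max(counts)
  classes <- names(counts)
  if (method %in% c("smote", "adasyn") &&
      any(counts < n_max & counts < 2))
    dn_stop("classes with a single sample cannot be interpolated",
            "class_too_small")
  new_rows <- NULL
  with_seed_(seed, {
    for (cl in classes) {
      idx <- which(labels == as.numeric(cl))
      need <- n_max - length(idx)
      if (need == 0) next
      if (method == "ros") {
        picks <- idx[sample.int(length(idx), need, replace = TRUE)]
        new_rows <- rbind(new_rows, M[picks, , drop = FALSE])
      } else if (method == "smote") {
        kc <- min(k, length(idx) - 1L)
        base <- idx[sample.int(length(idx), need, replace = TRUE)]
        for (b in base) {
          nn <- knn_indices(M, b, kc, pool = idx)
          nb <- nn[sample.int(length(nn), 1L)]
          u <- stats::runif(1)
          new_rows <- rbind(new_rows, M[b, ] + u * (M[nb, ] - M[b, ]))
        }
      } else {  # adasyn
        kc <- min(k, nrow(M) - 1L)
        r <- vapply(idx, function(i) {
          nn <- knn_indices(M, i, kc)
          mean(labels[nn] != as.numeric(cl))
        }, numeric(1))
        if (sum(r) == 0) r <- rep(1, length(idx))
        g <- round(r / sum(r) * need)
        kcl <- min(k, length(idx) - 1L)
        for (j in seq_along(idx)) {
          if (g[j] == 0) next
          nn <- knn_indices(M, idx[j], kcl, pool = idx)
          for (s in seq_len(g[j])) {
            nb <- nn[sample.int(length(nn), 1L)]
            u <- stats::runif(1)
            new_rows <- rbind(new_rows,
                              M[idx[j], ] + u * (M[nb, ] - M[idx[j], ]))
          }
        }
      }
    }
  })
  if (is.null(new_rows)) return(ds)
  p <- ncol(ds$features)
  formulation_dataset(
    rbind(ds$features, new_rows[, seq_len(p), drop = FALSE]),
    rbind(ds$targets, new_rows[, -seq_len(p), drop = FALSE]),
    ds$feature_names, ds$target_names,
    bounds = ds$bounds, target_scale = ds$target_scale,
    normalized = ds$normalized,
    provenance = c(ds$provenance, rep(method, nrow(new_rows))))
}
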
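#' Within-threshold accuracy for disintegration time
#'
#' Fraction of predictions whose absolute error is within `threshold`
#' seconds of the observed disintegration time. The 10 s default is about
#' 10% of the full observation scale, the conventional success criterion
#' for this assay; an error of exactly 10 s counts as a success.
#'
#' @param predicted,actual numeric vectors in seconds (denormalized).
#' @param threshold success threshold in seconds.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_ofdf <- function(predicted, actual, threshold = 10) {
  if (length(predicted) != length(actual))
    dn_stop("predicted and actual must have equal length", "length_mismatch")
  if (length(predicted) == 0L)
    dn_stop("empty input", "empty_input")
  mean(abs(predicted - actual) <= threshold)
}

#' f2 similarity factor between two dissolution profiles
#'
#' The FDA-recommended similarity factor
#' \deqn{f_2 = 50 \log_{10}\left(100 \left[1 + \tfrac{1}{n}\sum_t (R_t - T_t)^2\right]^{-1/2}\right)}
#' computed over the n sampling times on the percent (0-100) scale.
#' Identical profiles give exactly 100; a uniform 10-percentage-point
#' difference gives about 50, the conventional similarity cutoff. The
#' factor is symmetric in its arguments and decreases as any single
#' pointwise difference grows.
#'
#' @param reference,test numeric profiles of equal length on the percent
#'   scale.
#' @return The f2 value (at most 100).
#' @export
f2_similarity <- function(reference, test) {
  if (length(reference) != length(test))
    dn_stop("profiles must have equal length", "length_mismatch")
  d <- reference - test
  50 * log10(100 / sqrt(1 + mean(d * d)))
}

#' f2-based accuracy for dissolution-profile prediction
#'
#' Fraction of samples whose predicted 4-point profile has
#' `f2(actual, predicted) >= cutoff`. The f2 value is compared unrounded:
#' a uniform 10-point error (f2 = 49.89...) fails the default cutoff of 50.
#'
#' @param predicted,actual n x 4 matrices on the percent scale.
#' @param cutoff similarity threshold (boundary counts as success).
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_srmt <- function(predicted, actual, cutoff = 50) {
  predicted <- as.matrix(predicted)
  actual <- as.matrix(actual)
  if (!all(dim(predicted) == dim(actual)))
    dn_stop("predicted and actual must have equal shape", "shape_mismatch")
  f2s <- vapply(seq_len(nrow(actual)), function(i)
    f2_similarity(actual[i, ], predicted[i, ]), numeric(1))
  mean(f2s >= cutoff)
}

#' Root-mean-square error (pooled over all entries)
#' @param predicted,actual numeric vectors or matrices of equal shape.
#' @return Non-negative scalar.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    dn_stop("predicted and actual must have equal shape", "shape_mismatch")
  sqrt(mean((predicted - actual)^2))
}

#' Mean absolute error (pooled over all entries)
#' @param predicted,actual numeric vectors or matrices of equal shape.
#' @return Non-negative scalar; always `<=` [rmse()] on the same input.
#' @export
mae <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    dn_stop("predicted and actual must have equal shape", "shape_mismatch")
  mean(abs(predicted - actual))
}

#' Full evaluation report for one data part
#'
#' Accuracy is computed on the denormalized scale (seconds for
#' disintegration time, percent for dissolution), while RMSE and MAE stay
#' on the normalized unit scale, matching how the two conventions are
#' usually reported side by side.
#'
#' @param predicted,actual matrices on the normalized `[0, 1]` scale.
#' @param kind `"ofdf"` (within-10-second criterion on 1 target) or
#'   `"srmt"` (f2 >= 50 criterion on 4 targets).
#' @param target_scale full-scale value used for denormalization.
#' @param threshold seconds threshold for `"ofdf"`.
#' @param cutoff f2 cutoff for `"srmt"`.
#' @return An object of class `eval_report` with fields `accuracy`, `rmse`,
#'   `mae` and `per_sample` (absolute error in seconds for OFDF, f2 for
#'   SRMT).
#' @export
eval_report <- function(predicted, actual, kind = c("ofdf", "srmt"),
                        target_scale = 100, threshold = 10, cutoff = 50) {
  kind <- match.arg(kind)
  predicted <- as.matrix(predicted)
  actual <- as.matrix(actual)
  if (!all(dim(predicted) == dim(actual)))
    dn_stop("predicted and actual must have equal shape", "shape_mismatch")
  pd <- denormalize_target(predicted, target_scale)
  ad <- denormalize_target(actual, target_scale)
  if (kind == "ofdf") {
    acc <- accuracy_ofdf(as.vector(pd), as.vector(ad), threshold)
    per <- abs(as.vector(pd) - as.vector(ad))
  } else {
    acc <- accuracy_srmt(pd, ad, cutoff)
    per <- vapply(seq_len(nrow(ad)), function(i)
      f2_similarity(ad[i, ], pd[i, ]), numeric(1))
  }
  structure(list(kind = kind, accuracy = acc,
                 rmse = rmse(predicted, actual), mae = mae(predicted, actual),
                 per_sample = per, n = nrow(actual)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s> n = %d | accuracy %.1f%% | RMSE %.4f | MAE %.4f\n",
              x$kind, x$n, 100 * x$accuracy, x$rmse, x$mae))
  invisible(x)
}
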
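#' Formulation dataset container
#'
#' The universal tabular container of the package: a numeric feature matrix
#' (molecular descriptors, encoded excipient types, process parameters) and a
#' numeric target matrix (1 column for OFDF disintegration time, 4 ordered
#' columns for SRMT cumulative dissolution). Targets are stored raw (seconds
#' or percent) until [normalize_dataset()] maps them to the unit scale.
#'
#' @param features numeric matrix, one row per formulation.
#' @param targets numeric matrix with the same number of rows.
#' @param feature_names,target_names optional character vectors of column
#'   names; defaults are taken from the matrices or generated.
#' @param bounds per-feature normalization bounds (2 x p matrix with rows
#'   `min` and `max`), or `NULL` before normalization.
#' @param target_scale full-scale value of the targets (100 s for OFDF,
#'   100 % for SRMT), `NA` before normalization.
#' @param normalized logical flag; `TRUE` once [normalize_dataset()] ran.
#' @param provenance character vector labelling each row's origin
#'   (`"original"`, `"ros"`, `"smote"`, `"adasyn"`, `"gan"`, `"wgan"`).
#' @return An object of class `formulation_dataset`.
#' @export
formulation_dataset <- function(features, targets,
                                feature_names = NULL, target_names = NULL,
                                bounds = NULL, target_scale = NA_real_,
                                normalized = FALSE, provenance = NULL) {
  features <- as.matrix(features)
  targets <- as.matrix(targets)
  if (!is.numeric(features) || !is.numeric(targets))
    dn_stop("features and targets must be numeric", "non_numeric")
  if (nrow(features) != nrow(targets))
    dn_stop("features and targets must have equal row counts", "row_mismatch")
  feature_names <- feature_names %||% colnames(features) %||%
    paste0("x", seq_len(ncol(features)))
  target_names <- target_names %||% colnames(targets) %||%
    paste0("y", seq_len(ncol(targets)))
  colnames(features) <- feature_names
  colnames(targets) <- target_names
  if (!is.null(provenance) && length(provenance) != nrow(features))
    dn_stop("provenance must have one entry per row", "row_mismatch")
  structure(list(features = features, targets = targets,
                 feature_names = feature_names, target_names = target_names,
                 bounds = bounds, target_scale = target_scale,
                 normalized = normalized,
                 provenance = provenance %||% rep("original", nrow(features))),
            class = "formulation_dataset")
}

#' @export
print.formulation_dataset <- function(x, ...) {
  cat(sprintf("<formulation_dataset> %d samples, %d features, %d target%s (%s)\n",
              nrow(x$features), ncol(x$features), ncol(x$targets),
              if (ncol(x$targets) == 1L) "" else "s",
              if (x$normalized) "normalized" else "raw units"))
  invisible(x)
}

#' @export
dim.formulation_dataset <- function(x) dim(x$features)

n_samples <- function(ds) nrow(ds$features)

# Row subset preserving all metadata.
ds_slice <- function(ds, idx) {
  formulation_dataset(ds$features[idx, , drop = FALSE],
                      ds$targets[idx, , drop = FALSE],
                      ds$feature_names, ds$target_names,
                      bounds = ds$bounds, target_scale = ds$target_scale,
                      normalized = ds$normalized,
                      provenance = ds$provenance[idx])
}

#' Load a formulation dataset from CSV
#'
#' Reads a headered CSV whose columns are partitioned features-then-targets.
#' Values are stored raw; no scaling is applied until [normalize_dataset()].
#'
#' @param path path to a CSV file (RFC-4180, header row).
#' @param n_features,n_targets expected column split; the file must contain
#'   exactly `n_features + n_targets` columns.
#' @return A [formulation_dataset()].
#' @export
load_dataset <- function(path, n_features, n_targets) {
  if (!file.exists(path))
    dn_stop(sprintf("dataset file not found: %s", path), "missing_file")
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  expected <- n_features + n_targets
  if (ncol(df) != expected)
    dn_stop(sprintf("expected %d columns (%d features + %d targets), found %d",
                    expected, n_features, n_targets, ncol(df)),
            "column_mismatch")
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad))
    dn_stop(sprintf("non-numeric entries in column(s): %s",
                    paste(bad, collapse = ", ")), "non_numeric")
  m <- as.matrix(df)
  formulation_dataset(m[, seq_len(n_features), drop = FALSE],
                      m[, n_features + seq_len(n_targets), drop = FALSE])
}

#' Normalize a formulation dataset
#'
#' Targets are divided by their full-scale value (100 for seconds on a
#' 0-100 s scale or percent dissolution), mapping them to `[0, 1]`. Features
#' are min-max scaled per column. When `bounds` is supplied (the training
#' part's bounds) those are applied unchanged, keeping validation/test
#' preprocessing leakage-free; otherwise bounds are computed from `ds` and
#' recorded for denormalization.
#'
#' A constant feature column (max equal to min) is mapped to 0 with a
#' warning.
#'
#' @param ds a [formulation_dataset()] in raw units.
#' @param target_scale positive full-scale target value.
#' @param bounds optional 2 x p matrix (rows `min`, `max`) from a reference
#'   (training) dataset.
#' @return A normalized [formulation_dataset()] carrying its bounds.
#' @export
normalize_dataset <- function(ds, target_scale, bounds = NULL) {
  stopifnot(inherits(ds, "formulation_dataset"))
  if (!is.numeric(target_scale) || length(target_scale) != 1L ||
      target_scale <= 0)
    dn_stop("target_scale must be a positive scalar", "bad_scale")
  X <- ds$features
  if (is.null(bounds)) {
    bounds <- rbind(min = apply(X, 2, min), max = apply(X, 2, max))
    colnames(bounds) <- ds$feature_names
  }
  rng <- bounds["max", ] - bounds["min", ]
  const <- rng == 0
  if (any(const)) {
    dn_warn(sprintf("constant feature column(s) mapped to 0: %s",
                    paste(ds$feature_names[const], collapse = ", ")),
            "constant_column")
    rng[const] <- 1  # avoid 0/0; centered value is 0 below
  }
  Xn <- add_rowwise(X, -bounds["min", ])
  Xn <- mul_rowwise(Xn, 1 / rng)
  Xn[, const] <- 0
  formulation_dataset(Xn, ds$targets / target_scale,
                      ds$feature_names, ds$target_names,
                      bounds = bounds, target_scale = target_scale,
                      normalized = TRUE, provenance = ds$provenance)
}

#' Map normalized targets back to original units
#'
#' Inverse of the target scaling in [normalize_dataset()]:
#' `denormalize_target(y / s, s)` recovers `y` to floating tolerance.
#'
#' @param values numeric vector or matrix on the unit scale.
#' @param target_scale the full-scale value used to normalize.
#' @return values multiplied by `target_scale`.
#' @export
denormalize_target <- function(values, target_scale) {
  if (!all(is.finite(values)))
    dn_stop("values must be finite", "non_finite")
  values * target_scale
}

#' Split a dataset into train / validation / test
#'
#' Either a seeded uniform random split into exact part sizes, or an explicit
#' index partition (to reuse published split indices when available). Parts
#' are row-disjoint and exhaustive.
#'
#' @param ds a [formulation_dataset()].
#' @param sizes integer vector `c(n_train, n_val, n_test)` summing to the
#'   sample count (ignored when `indices` is given).
#' @param seed RNG seed for the random split.
#' @param indices optional list with integer components `train`,
#'   `validation`, `test` forming a partition of `1:n`.
#' @return A list of class `formulation_split` with elements `train`,
#'   `validation`, `test` (each a [formulation_dataset()]) and `indices`.
#' @export
split_dataset <- function(ds, sizes = NULL, seed = 1, indices = NULL) {
  stopifnot(inherits(ds, "formulation_dataset"))
  n <- n_samples(ds)
  if (is.null(indices)) {
    if (is.null(sizes) || length(sizes) != 3L)
      dn_stop("sizes must be c(n_train, n_val, n_test)", "bad_sizes")
    if (sum(sizes) != n)
      dn_stop(sprintf("sizes sum to %d but the dataset has %d samples",
                      sum(sizes), n), "size_mismatch")
    perm <- with_seed_(seed, sample.int(n))
    indices <- list(train = sort(perm[seq_len(sizes[1])]),
                    validation = sort(perm[sizes[1] + seq_len(sizes[2])]),
                    test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
  } else {
    all_idx <- sort(c(indices$train, indices$validation, indices$test))
    if (!identical(all_idx, seq_len(n)))
      dn_stop("indices must partition 1:n_samples", "bad_indices")
  }
  structure(list(train = ds_slice(ds, indices$train),
                 validation = ds_slice(ds, indices$validation),
                 test = ds_slice(ds, indices$test),
                 indices = indices),
            class = "formulation_split")
}

#' @export
print.formulation_split <- function(x, ...) {
  cat(sprintf("<formulation_split> train %d / validation %d / test %d\n",
              n_samples(x$train), n_samples(x$validation), n_samples(x$test)))
  invisible(x)
}
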
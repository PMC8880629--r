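#' Parameter and update accounting for all architecture presets
#'
#' Reproduces the bookkeeping used to compare the network designs: the
#' per-layer trainable-parameter tables and totals of all five presets, the
#' parameter saving of the PCA-reduced OFDF network relative to the raw
#' 24-input version, and the total optimizer updates of the standard
#' training protocols (baselines: batch size 1 for 900 / 2600 epochs;
#' proposed: batch size 32 for 800 / 2000 epochs on 91 / 105 training
#' rows).
#'
#' @return A list with `tables` (named list of per-layer data frames),
#'   `totals` (named integer vector), `pca_param_saving`, and `updates`.
#' @export
audit_params <- function() {
  presets <- c("ofdf_existing", "ofdf_proposed", "ofdf_proposed_pca",
               "srmt_existing", "srmt_proposed")
  tables <- lapply(presets, function(p) param_table(preset_spec(p)))
  names(tables) <- presets
  totals <- vapply(tables, function(t) sum(t$params), integer(1))
  list(tables = tables,
       totals = totals,
       pca_param_saving = totals[["ofdf_proposed"]] - totals[["ofdf_proposed_pca"]],
       updates = c(ofdf_existing = count_updates(91, 1, 900),
                   ofdf_proposed = count_updates(91, 32, 800),
                   srmt_existing = count_updates(105, 1, 2600)))
}

# Normalize the three split parts leakage-free: bounds fitted on train only.
normalize_split <- function(split, target_scale) {
  train <- normalize_dataset(split$train, target_scale)
  list(train = train,
       validation = normalize_dataset(split$validation, target_scale,
                                      bounds = train$bounds),
       test = normalize_dataset(split$test, target_scale,
                                bounds = train$bounds),
       indices = split$indices)
}

write_manifest <- function(out_dir, info) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  info$r_version <- R.version.string
  info$package_version <- as.character(utils::packageVersion("dissolvenet"))
  jsonlite::write_json(info, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

report_list <- function(reports)
  lapply(reports, function(r) list(accuracy = r$accuracy, rmse = r$rmse,
                                   mae = r$mae, n = r$n))

#' Run the disintegration-time pipeline end to end
#'
#' Splits the data, min-max normalizes with training-set bounds
#' (disintegration time divided by its 100 s full scale), fits PCA on the
#' training features, projects all parts onto the leading components, trains
#' the proposed three-hidden-layer network (50, 25, 16; dropout 0.05 on the
#' first hidden layer; Adam, learning rate 0.01, 800 epochs, batch 32) and
#' evaluates the within-10-second accuracy plus RMSE/MAE on every part.
#'
#' @param ds a raw [formulation_dataset()] (24 features, 1 target in
#'   seconds); defaults to a synthetic 131-sample dataset from
#'   [gen_ofdf()].
#' @param sizes train/validation/test sizes (default 91/20/20).
#' @param use_pca apply the PCA reduction (`FALSE` trains on the raw 24
#'   features).
#' @param n_components number of components, or `"auto"` for the scree
#'   elbow from [select_elbow()]. Default 5.
#' @param epochs,learning_rate,batch_size training protocol.
#' @param seed master seed; derives the split, initialization and training
#'   streams.
#' @param out_dir optional directory for artifacts (scree CSV, correlation
#'   matrices before/after PCA, training history, reports and a manifest).
#' @return A list of class `ofdf_run` with the three `eval_report`s, the
#'   trained model, the PCA model, `k`, parameter and update counts.
#' @export
run_ofdf <- function(ds = NULL, sizes = c(91, 20, 20), use_pca = TRUE,
                     n_components = 5, epochs = 800, learning_rate = 0.01,
                     batch_size = 32, seed = 1, out_dir = NULL) {
  if (is.null(ds))
    ds <- gen_ofdf(synth_config(n_samples = sum(sizes),
                                seed = child_seed(seed, 1)))
  split <- split_dataset(ds, sizes, seed = child_seed(seed, 2))
  parts <- normalize_split(split, target_scale = 100)
  pca <- fit_pca(parts$train$features)
  if (use_pca) {
    k <- if (identical(n_components, "auto"))
      select_elbow(pca$eigenvalues) else as.integer(n_components)
    feats <- lapply(parts[c("train", "validation", "test")],
                    function(p) pca_transform(pca, p$features, k))
  } else {
    k <- ncol(parts$train$features)
    feats <- lapply(parts[c("train", "validation", "test")],
                    function(p) p$features)
  }
  spec <- mlp_spec(k, c(50, 25, 16), 1, dropout = list(`1` = 0.05))
  model <- build_mlp(spec, seed = child_seed(seed, 3))
  cfg <- train_config(learning_rate = learning_rate, epochs = epochs,
                      batch_size = batch_size, seed = child_seed(seed, 4))
  model <- train_mlp(model,
                     list(features = feats$train,
                          targets = parts$train$targets), cfg)
  reports <- lapply(c(train = "train", validation = "validation",
                      test = "test"), function(p)
    eval_report(predict(model, feats[[p]]), parts[[p]]$targets,
                kind = "ofdf", target_scale = 100))
  out <- structure(list(reports = reports, model = model, pca = pca, k = k,
                        spec = spec,
                        param_count = count_trainable_params(spec),
                        n_updates = model$n_updates,
                        history = model$history, bounds = parts$train$bounds,
                        split_indices = parts$indices, seed = seed),
                   class = "ofdf_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(component = seq_along(pca$eigenvalues),
                                eigenvalue = pca$eigenvalues,
                                cpv = cumulative_variance(pca$eigenvalues)),
                     file.path(out_dir, "scree.csv"), row.names = FALSE)
    utils::write.csv(correlation_matrix(parts$train$features),
                     file.path(out_dir, "correlation_before_pca.csv"))
    utils::write.csv(correlation_matrix(
      pca_transform(pca, parts$train$features, k)),
      file.path(out_dir, "correlation_after_pca.csv"))
    utils::write.csv(data.frame(epoch = seq_along(model$history),
                                loss = model$history),
                     file.path(out_dir, "history.csv"), row.names = FALSE)
    write_manifest(out_dir, list(
      pipeline = "ofdf", seed = seed, sizes = sizes, use_pca = use_pca,
      k = k, epochs = epochs, learning_rate = learning_rate,
      batch_size = batch_size, param_count = out$param_count,
      n_updates = out$n_updates, reports = report_list(reports)))
  }
  out
}

#' @export
print.ofdf_run <- function(x, ...) {
  cat(sprintf("<ofdf_run> k = %d components, %s parameters, %d updates\n",
              x$k, format(x$param_count, big.mark = ","), x$n_updates))
  for (p in names(x$reports)) { cat(sprintf("  %-10s ", p)); print(x$reports[[p]]) }
  invisible(x)
}

# Augment a normalized SRMT training part; returns the augmented dataset
# plus generation bookkeeping.
augment_training <- function(train, method, seed, wgan = NULL,
                             n_candidates = 2000, oversample_k = 5) {
  info <- list(n_original = n_samples(train), n_generated = 0L,
               n_removed = 0L)
  if (method == "none") return(list(train = train, info = info))
  if (method %in% c("ros", "smote", "adasyn")) {
    labels <- bin_final_dissolution(train$targets)
    aug <- oversample(train, labels, method, seed = seed, k = oversample_k)
    info$n_generated <- n_samples(aug) - n_samples(train)
    return(list(train = aug, info = info))
  }
  # gan / wgan: learn the joint [features, profile] distribution
  M <- cbind(train$features, train$targets)
  cfg <- wgan %||% wgan_config(data_dim = ncol(M), seed = child_seed(seed, 7))
  gen <- if (method == "wgan") train_wgan(M, cfg) else {
    cfg$critic_steps <- 1L
    train_gan(M, cfg)
  }
  raw <- generate_samples(gen, n_candidates, seed = child_seed(seed, 8))
  flt <- filter_cumulative(raw)
  info$n_generated <- nrow(flt$kept)
  info$n_removed <- flt$n_removed
  p <- ncol(train$features)
  aug <- formulation_dataset(
    rbind(train$features, flt$kept[, seq_len(p), drop = FALSE]),
    rbind(train$targets, flt$kept[, -seq_len(p), drop = FALSE]),
    train$feature_names, train$target_names,
    bounds = train$bounds, target_scale = train$target_scale,
    normalized = TRUE,
    provenance = c(train$provenance, rep(method, nrow(flt$kept))))
  list(train = aug, info = info, generator = gen)
}

#' Run the dissolution-profile pipeline end to end
#'
#' Splits the data, normalizes leakage-free (percent dissolution divided by
#' 100), augments the training part only — by label-binned oversampling
#' (`ros` / `smote` / `adasyn`), by GAN or weight-clipped WGAN generation of
#' joint `[features, profile]` rows followed by the cumulative-release
#' validity filter, or not at all (`none`) — then trains the proposed
#' five-hidden-layer multi-output network (150, 130, 100, 50, 30; dropout
#' 0.1 on the first two hidden layers; random-normal initialization; Adam,
#' learning rate 0.001, 2000 epochs, batch 32) and evaluates f2-based
#' accuracy plus RMSE/MAE. Training metrics are reported on the original
#' (unaugmented) training rows so runs with different augmentation are
#' comparable; validation and test rows are never touched by augmentation.
#'
#' @param ds a raw [formulation_dataset()] (21 features, 4 percent
#'   targets); defaults to a synthetic 145-sample dataset from
#'   [gen_srmt()].
#' @param sizes train/validation/test sizes (default 105/20/20).
#' @param method augmentation method.
#' @param epochs,learning_rate,batch_size training protocol.
#' @param wgan optional [wgan_config()] override for `gan` / `wgan`.
#' @param n_candidates generator draws before filtering.
#' @param seed master seed.
#' @param out_dir optional artifact directory (augmented training CSV with
#'   provenance column, 2-D projection coordinates for generated rows,
#'   history, reports, manifest).
#' @return A list of class `srmt_run` with the three `eval_report`s, the
#'   model, augmentation bookkeeping, and (for `gan`/`wgan`) the generator
#'   and its 2-D projection diagnostic.
#' @export
run_srmt <- function(ds = NULL, sizes = c(105, 20, 20),
                     method = c("wgan", "none", "ros", "smote", "adasyn", "gan"),
                     epochs = 2000, learning_rate = 0.001, batch_size = 32,
                     wgan = NULL, n_candidates = 2000, seed = 1,
                     out_dir = NULL) {
  method <- match.arg(method)
  if (is.null(ds))
    ds <- gen_srmt(synth_config(n_samples = sum(sizes),
                                seed = child_seed(seed, 1)))
  split <- split_dataset(ds, sizes, seed = child_seed(seed, 2))
  parts <- normalize_split(split, target_scale = 100)
  aug <- augment_training(parts$train, method, seed = child_seed(seed, 5),
                          wgan = wgan, n_candidates = n_candidates)
  spec <- preset_spec("srmt_proposed")
  model <- build_mlp(spec, seed = child_seed(seed, 3))
  cfg <- train_config(learning_rate = learning_rate, epochs = epochs,
                      batch_size = batch_size, seed = child_seed(seed, 4))
  model <- train_mlp(model, aug$train, cfg)
  eval_parts <- list(train = parts$train, validation = parts$validation,
                     test = parts$test)
  reports <- lapply(eval_parts, function(p)
    eval_report(predict(model, p$features), p$targets,
                kind = "srmt", target_scale = 100))
  proj <- NULL
  if (!is.null(aug$generator) && aug$info$n_generated >= 3) {
    M <- cbind(parts$train$features, parts$train$targets)
    gen_rows <- cbind(aug$train$features, aug$train$targets)
    gen_rows <- gen_rows[aug$train$provenance != "original", , drop = FALSE]
    proj <- project_2d(M, gen_rows)
  }
  out <- structure(list(reports = reports, model = model, method = method,
                        augmentation = aug$info, generator = aug$generator,
                        projection = proj, spec = spec,
                        param_count = count_trainable_params(spec),
                        n_updates = model$n_updates,
                        n_train_rows = n_samples(aug$train),
                        history = model$history, bounds = parts$train$bounds,
                        split_indices = parts$indices, seed = seed),
                   class = "srmt_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    aug_df <- data.frame(aug$train$features, aug$train$targets,
                         provenance = aug$train$provenance,
                         check.names = FALSE)
    utils::write.csv(aug_df, file.path(out_dir, "augmented_train.csv"),
                     row.names = FALSE)
    if (!is.null(proj)) {
      coords <- rbind(data.frame(pc1 = proj$real[, 1], pc2 = proj$real[, 2],
                                 set = "real"),
                      data.frame(pc1 = proj$generated[, 1],
                                 pc2 = proj$generated[, 2], set = "generated"))
      utils::write.csv(coords, file.path(out_dir, "projection_2d.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(data.frame(epoch = seq_along(model$history),
                                loss = model$history),
                     file.path(out_dir, "history.csv"), row.names = FALSE)
    write_manifest(out_dir, list(
      pipeline = "srmt", seed = seed, sizes = sizes, method = method,
      epochs = epochs, learning_rate = learning_rate,
      batch_size = batch_size, n_candidates = n_candidates,
      augmentation = aug$info, param_count = out$param_count,
      n_updates = out$n_updates,
      dispersion_ratio = if (!is.null(proj)) proj$dispersion_ratio else NULL,
      reports = report_list(reports)))
  }
  out
}

#' @export
print.srmt_run <- function(x, ...) {
  cat(sprintf("<srmt_run %s> %d training rows (%d generated, %d filtered out), %s parameters\n",
              x$method, x$n_train_rows, x$augmentation$n_generated,
              x$augmentation$n_removed, format(x$param_count, big.mark = ",")))
  for (p in names(x$reports)) { cat(sprintf("  %-10s ", p)); print(x$reports[[p]]) }
  invisible(x)
}
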
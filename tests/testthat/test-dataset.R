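test_that("load_dataset partitions columns and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(matrix(seq_len(3 * 25), 3, 25))
  names(df) <- c(paste0("f", 1:24), "disintegration_time_s")
  write.csv(df, path, row.names = FALSE)
  ds <- load_dataset(path, n_features = 24, n_targets = 1)
  expect_identical(dim(ds$features), c(3L, 24L))
  expect_identical(dim(ds$targets), c(3L, 1L))

  expect_error(load_dataset(path, n_features = 19, n_targets = 1),
               class = "dissolvenet_error_column_mismatch")
  expect_error(load_dataset(file.path(tempdir(), "nope.csv"), 24, 1),
               class = "dissolvenet_error_missing_file")

  bad <- withr::local_tempfile(fileext = ".csv")
  df$f3[2] <- "oops"
  write.csv(df, bad, row.names = FALSE)
  expect_error(load_dataset(bad, 24, 1),
               class = "dissolvenet_error_non_numeric")
})

test_that("targets are stored raw until normalization divides by full scale", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = c(1, 2), b = c(3, 4), y = c(35, 85.5)),
            path, row.names = FALSE)
  ds <- load_dataset(path, 2, 1)
  expect_equal(as.vector(ds$targets), c(35, 85.5))
  nds <- normalize_dataset(ds, target_scale = 100)
  expect_equal(as.vector(nds$targets), c(0.35, 0.855))
})

test_that("normalization min-max scales features and handles constant columns", {
  ds <- formulation_dataset(cbind(x1 = c(0, 5, 10), x2 = c(2, 2, 2)),
                            matrix(c(10, 20, 30), ncol = 1))
  expect_warning(nds <- normalize_dataset(ds, 100),
                 class = "dissolvenet_warning_constant_column")
  expect_equal(nds$features[, "x1"], c(0, 0.5, 1))
  expect_equal(nds$features[, "x2"], c(0, 0, 0))
  expect_true(all(nds$features >= 0 & nds$features <= 1))
  expect_true(all(nds$targets >= 0 & nds$targets <= 1))
})

test_that("training-set bounds transfer to held-out parts without refitting", {
  tr <- formulation_dataset(matrix(c(0, 10, 5), 3, 1),
                            matrix(c(1, 2, 3), 3, 1))
  te <- formulation_dataset(matrix(c(2.5, 7.5), 2, 1), matrix(c(4, 5), 2, 1))
  ntr <- normalize_dataset(tr, 100)
  nte <- normalize_dataset(te, 100, bounds = ntr$bounds)
  expect_equal(as.vector(nte$features), c(0.25, 0.75))
})

test_that("target normalization round-trips within 1e-9", {
  withr::with_seed(7, {
    y <- matrix(runif(100, 0, 100), ncol = 1)
    back <- denormalize_target(y / 100, 100)
    expect_lt(max(abs(back - y)), 1e-9)
  })
  expect_identical(denormalize_target(0.35, 100), 35)
  expect_identical(denormalize_target(0, 100), 0)
  expect_error(denormalize_target(c(0.1, NaN), 100),
               class = "dissolvenet_error_non_finite")
})

test_that("random splits have exact sizes, disjoint parts, and are seeded", {
  for (case in list(list(n = 131, sizes = c(91, 20, 20)),
                    list(n = 145, sizes = c(105, 20, 20)))) {
    ds <- withr::with_seed(3, formulation_dataset(
      matrix(runif(case$n * 4), case$n), matrix(runif(case$n), ncol = 1)))
    sp <- split_dataset(ds, case$sizes, seed = 11)
    expect_equal(vapply(sp[c("train", "validation", "test")], function(d)
      nrow(d$features), numeric(1)), case$sizes, ignore_attr = TRUE)
    all_idx <- unlist(sp$indices)
    expect_setequal(all_idx, seq_len(case$n))
    expect_equal(length(all_idx), case$n)  # no index appears twice
    sp2 <- split_dataset(ds, case$sizes, seed = 11)
    expect_identical(sp$indices, sp2$indices)
  }
  ds <- tiny_ds(n = 10)
  expect_error(split_dataset(ds, c(5, 3, 3), seed = 1),
               class = "dissolvenet_error_size_mismatch")
})

test_that("explicit index lists are honoured and validated", {
  ds <- tiny_ds(n = 6)
  idx <- list(train = c(1L, 3L, 5L), validation = c(2L, 6L), test = 4L)
  sp <- split_dataset(ds, indices = idx)
  expect_equal(sp$train$features, ds$features[c(1, 3, 5), , drop = FALSE])
  expect_error(split_dataset(ds, indices = list(train = 1:3, validation = 3:4,
                                                test = 5:6)),
               class = "dissolvenet_error_bad_indices")
})
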
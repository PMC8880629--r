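test_that("final-dissolution binning floors into 10 classes with 1.0 clipped", {
  expect_identical(bin_final_dissolution(0.855), 8L)
  expect_identical(bin_final_dissolution(0), 0L)
  expect_identical(bin_final_dissolution(1), 9L)
  expect_identical(bin_final_dissolution(cbind(0.1, 0.2, 0.3, 0.39)), 3L)
  expect_error(bin_final_dissolution(1.2),
               class = "dissolvenet_error_out_of_range")
})

test_that("cumulative check accepts the five valid published profiles", {
  for (i in 1:5) {
    expect_true(is_cumulative(valid_profiles[i, ]))
    expect_false(is_cumulative(invalid_profiles[i, ]))
  }
  expect_true(is_cumulative(c(0.5, 0.5, 0.5, 0.5)))  # ties allowed
  expect_error(is_cumulative(c(0.1, NA, 0.3, 0.4)),
               class = "dissolvenet_error_bad_profile")
})

test_that("the validity filter keeps 5 of the 10 example profiles, idempotently", {
  feats <- matrix(0.5, 10, 21)
  samples <- cbind(feats, rbind(valid_profiles, invalid_profiles))
  # interleave to check order preservation
  ord <- c(1, 6, 2, 7, 3, 8, 4, 9, 5, 10)
  samples <- samples[ord, ]
  fl <- filter_cumulative(samples)
  expect_identical(nrow(fl$kept), 5L)
  expect_identical(fl$n_removed, 5L)
  expect_equal(fl$kept[, 22:25], valid_profiles, ignore_attr = TRUE)
  fl2 <- filter_cumulative(fl$kept)
  expect_identical(fl2$kept, fl$kept)
  expect_identical(fl2$n_removed, 0L)
  all_ok <- filter_cumulative(cbind(feats[1:5, ], valid_profiles))
  expect_identical(all_ok$n_removed, 0L)
})

test_that("ROS and SMOTE balance the published class counts to 200 rows", {
  ds <- labeled_rows(original_class_counts)
  labels <- attr(ds, "labels")
  expect_identical(sum(original_class_counts), 105L)
  for (method in c("ros", "smote")) {
    aug <- oversample(ds, labels, method, seed = 5)
    expect_identical(nrow(aug$features),
                     10L * max(original_class_counts))  # 200
    # every class reaches the majority count
    new_labels <- bin_final_dissolution(aug$targets)
    expect_true(all(table(new_labels) == max(original_class_counts)))
    # original rows preserved verbatim, in order, ahead of synthetic rows
    expect_identical(aug$features[1:105, ], ds$features)
    expect_identical(aug$targets[1:105, ], ds$targets)
    expect_identical(unique(aug$provenance[106:200]), method)
  }
})

test_that("ADASYN reaches near-balance", {
  ds <- labeled_rows(original_class_counts)
  aug <- oversample(ds, attr(ds, "labels"), "adasyn", seed = 5)
  n_bal <- 10L * max(original_class_counts)
  expect_gte(nrow(aug$features), round(0.9 * n_bal))
  expect_lte(nrow(aug$features), round(1.1 * n_bal))
  expect_identical(aug$features[1:105, ], ds$features)
})

test_that("SMOTE rows interpolate within their own class bin", {
  ds <- labeled_rows(original_class_counts)
  aug <- oversample(ds, attr(ds, "labels"), "smote", seed = 11)
  synth <- aug$targets[aug$provenance == "smote", , drop = FALSE]
  # convex combinations of same-class rows keep a monotone profile shape
  expect_true(all(apply(synth, 1, function(v) all(diff(v) >= -1e-9))))
})

test_that("balanced input is returned unchanged and errors are classed", {
  ds <- labeled_rows(rep(5L, 10))
  aug <- oversample(ds, attr(ds, "labels"), "ros", seed = 1)
  expect_identical(aug$features, ds$features)
  expect_identical(nrow(aug$features), 50L)
  expect_error(oversample(ds, attr(ds, "labels"), "bogus"))
  one <- labeled_rows(c(1L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L))
  expect_error(oversample(one, attr(one, "labels"), "smote", seed = 1),
               class = "dissolvenet_error_class_too_small")
})

test_that("oversampling is deterministic per seed", {
  ds <- labeled_rows(original_class_counts)
  labels <- attr(ds, "labels")
  a <- oversample(ds, labels, "smote", seed = 8)
  b <- oversample(ds, labels, "smote", seed = 8)
  expect_identical(a$features, b$features)
  c_ <- oversample(ds, labels, "smote", seed = 9)
  expect_false(identical(a$features, c_$features))
})
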
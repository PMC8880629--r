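# Expected per-layer parameter counts follow fan_in * fan_out + fan_out.
published_layer_counts <- list(
  ofdf_existing = c(0, 1250, rep(2550, 9), 51),
  ofdf_proposed = c(0, 1250, 1275, 416, 17),
  ofdf_proposed_pca = c(0, 300, 1275, 416, 17),
  srmt_existing = c(0, 660, rep(930, 8), 124),
  srmt_proposed = c(0, 3300, 19630, 13100, 5050, 1530, 124))

test_that("preset architectures reproduce every per-layer parameter entry", {
  for (nm in names(published_layer_counts)) {
    tab <- param_table(preset_spec(nm))
    expect_equal(tab$params, published_layer_counts[[nm]],
                 ignore_attr = TRUE, label = nm)
  }
  totals <- vapply(names(published_layer_counts),
                   function(nm) count_trainable_params(preset_spec(nm)),
                   integer(1))
  expect_identical(unname(totals), c(24251L, 2958L, 2008L, 8224L, 42734L))
  # dimensionality reduction 24 -> 5 saves 19 x 50 weights
  expect_identical(totals[["ofdf_proposed"]] - totals[["ofdf_proposed_pca"]],
                   950L)
  expect_error(preset_spec("unknown"),
               class = "dissolvenet_error_unknown_preset")
})

test_that("preset shapes match their published descriptions", {
  s <- preset_spec("ofdf_proposed_pca")
  expect_identical(s$input_dim, 5L)
  expect_identical(c(s$hidden, s$output_dim), c(50L, 25L, 16L, 1L))
  expect_equal(s$dropout, c(0.05, 0, 0))
  s2 <- preset_spec("srmt_proposed")
  expect_identical(c(s2$hidden, s2$output_dim),
                   c(150L, 130L, 100L, 50L, 30L, 4L))
  expect_equal(s2$dropout, c(0.1, 0.1, 0, 0, 0))
  expect_identical(s2$weight_init, "random_normal")
})

test_that("update accounting uses the ceiling batch convention", {
  expect_identical(count_updates(91, 32, 800), 2400L)
  expect_identical(count_updates(32, 32, 1), 1L)
  expect_identical(count_updates(91, 1, 900), 81900L)
  expect_identical(count_updates(105, 1, 2600), 273000L)
  expect_error(count_updates(0, 32, 10), class = "dissolvenet_error_bad_count")
})

test_that("a degenerate one-weight network counts 2 parameters", {
  expect_identical(count_trainable_params(mlp_spec(1, integer(0), 1)), 2L)
})

test_that("initialization: zero biases, He-uniform bounds, seed determinism", {
  spec <- mlp_spec(10, c(50, 20), 1)
  for (seed in 1:5) {
    m <- build_mlp(spec, seed = seed)
    for (ly in m$net$layers) expect_true(all(ly$b == 0))
    # layer 2 has fan_in 50: all weights within +-sqrt(6/50)
    expect_lte(max(abs(m$net$layers[[2]]$W)), sqrt(6 / 50))
    expect_lte(max(abs(m$net$layers[[1]]$W)), sqrt(6 / 10))
  }
  expect_identical(build_mlp(spec, seed = 42)$net,
                   build_mlp(spec, seed = 42)$net)
  # normal init stays near zero at sd 0.05
  mn <- build_mlp(mlp_spec(30, c(40), 2, weight_init = "random_normal"), 1)
  expect_lt(sd(mn$net$layers[[1]]$W), 0.07)
  expect_error(build_mlp(mlp_spec(2, 3, 1, weight_init = "bogus"), 1),
               class = "dissolvenet_error_unknown_init")
})

# Finite-difference check of the backpropagated gradients, including a
# batch-normalized layer (dropout off; loss is then deterministic in the
# parameters for a fixed batch).
numeric_grad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

test_that("backpropagation matches finite differences", {
  set.seed(31)
  X <- matrix(runif(8 * 3), 8, 3)
  Y <- matrix(runif(8 * 2), 8, 2)
  net <- dissolvenet:::nn_new(3, widths = c(5, 4, 2),
                              acts = c("relu", "relu", "sigmoid"),
                              batchnorm = c(FALSE, TRUE, FALSE))
  loss_at <- function(net) {
    P <- dissolvenet:::nn_forward(net, X, training = TRUE)$out
    mean((P - Y)^2)
  }
  fw <- dissolvenet:::nn_forward(net, X, training = TRUE)
  E <- fw$out - Y
  bw <- dissolvenet:::nn_backward(net, fw$caches, 2 * E / length(E))
  for (l in seq_along(net$layers)) {
    for (p in names(bw$grads[[l]])) {
      f <- function(v) {
        n2 <- net
        n2$layers[[l]][[p]][] <- v
        loss_at(n2)
      }
      num <- numeric_grad(f, as.vector(net$layers[[l]][[p]]))
      expect_equal(as.vector(bw$grads[[l]][[p]]), num, tolerance = 1e-5,
                   label = sprintf("layer %d %s", l, p))
    }
  }
})

test_that("training fits a constant target and counts its updates", {
  spec <- mlp_spec(4, c(16, 8), 1)
  model <- build_mlp(spec, seed = 1)
  withr::with_seed(2, {
    data <- list(features = matrix(runif(30 * 4), 30, 4),
                 targets = matrix(0.6, 30, 1))
  })
  cfg <- train_config(learning_rate = 0.01, epochs = 500, batch_size = 8,
                      seed = 3)
  model <- train_mlp(model, data, cfg)
  expect_length(model$history, 500)
  expect_lt(tail(model$history, 1), 1e-3)
  expect_identical(model$n_updates, count_updates(30, 8, 500))
  p <- predict(model, data$features)
  expect_true(all(p > 0 & p < 1))
  expect_lt(max(abs(p - 0.6)), 0.05)
})

test_that("training validates its preconditions", {
  model <- build_mlp(mlp_spec(3, c(4), 1), 1)
  data <- list(features = matrix(runif(12), 4, 3),
               targets = matrix(runif(4), 4, 1))
  expect_error(train_config(epochs = 0), class = "dissolvenet_error_bad_epochs")
  expect_error(
    train_mlp(model, list(features = data$features[, 1:2],
                          targets = data$targets),
              train_config(epochs = 1)),
    class = "dissolvenet_error_width_mismatch")
  expect_error(
    train_mlp(model, list(features = data$features,
                          targets = data$targets * 50),
              train_config(epochs = 1)),
    class = "dissolvenet_error_unnormalized_targets")
})

test_that("training is reproducible and inference deterministic", {
  spec <- mlp_spec(3, c(8, 8), 1)  # no dropout
  data <- withr::with_seed(4, list(features = matrix(runif(60), 20, 3),
                                   targets = matrix(runif(20), 20, 1)))
  cfg <- train_config(epochs = 30, batch_size = 8, seed = 9)
  m1 <- train_mlp(build_mlp(spec, 7), data, cfg)
  m2 <- train_mlp(build_mlp(spec, 7), data, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$net, m2$net)
  p1 <- predict(m1, data$features)
  expect_identical(p1, predict(m1, data$features))
  # dropout used in training does not perturb inference
  specd <- mlp_spec(3, c(8, 8), 1, dropout = list(`1` = 0.3))
  md <- train_mlp(build_mlp(specd, 7), data, cfg)
  expect_identical(predict(md, data$features), predict(md, data$features))
})

test_that("multi-output networks emit one column per target", {
  model <- build_mlp(preset_spec("srmt_proposed"), 1)
  p <- predict(model, matrix(runif(2 * 21), 2, 21))
  expect_identical(dim(p), c(2L, 4L))
  expect_true(all(p > 0 & p < 1))
})
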
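#' Declarative specification of a fully-connected network
#'
#' Describes an MLP completely enough to build it and to count its trainable
#' parameters: input width, hidden widths, output width, activations,
#' dropout placement and weight initializer. Dropout applies to hidden
#' layers only.
#'
#' @param input_dim input feature count.
#' @param hidden integer vector of hidden-layer widths (may be empty).
#' @param output_dim output width (1 for OFDF, 4 for SRMT).
#' @param hidden_activation,output_activation activation names
#'   (`"relu"`, `"sigmoid"`, `"linear"`).
#' @param dropout named list mapping hidden-layer index (1-based, as string
#'   or number) to a rate in `[0, 1)`.
#' @param weight_init `"he_uniform"` (U(-sqrt(6/fan_in), +sqrt(6/fan_in))) or
#'   `"random_normal"` (N(0, `init_sd`^2)). Biases are always zero.
#' @param init_sd standard deviation for `"random_normal"`.
#' @return An object of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim, hidden, output_dim,
                     hidden_activation = "relu", output_activation = "sigmoid",
                     dropout = list(), weight_init = "he_uniform",
                     init_sd = 0.05) {
  widths <- c(hidden, output_dim)
  if (any(widths <= 0) || input_dim <= 0)
    dn_stop("all layer widths must be positive", "bad_width")
  dr <- rep(0, length(hidden))
  if (length(dropout)) {
    idx <- as.integer(names(dropout) %||% seq_along(dropout))
    rates <- as.numeric(unlist(dropout))
    if (any(idx < 1L | idx > length(hidden)))
      dn_stop("dropout applies to hidden layers only", "bad_dropout")
    if (any(rates < 0 | rates >= 1))
      dn_stop("dropout rates must lie in [0, 1)", "bad_dropout")
    dr[idx] <- rates
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 output_dim = as.integer(output_dim),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 dropout = dr, weight_init = weight_init, init_sd = init_sd),
            class = "mlp_spec")
}

#' @export
print.mlp_spec <- function(x, ...) {
  cat(sprintf("<mlp_spec> %d -> [%s] -> %d (%s/%s, init %s), %s parameters\n",
              x$input_dim, paste(x$hidden, collapse = ", "), x$output_dim,
              x$hidden_activation, x$output_activation, x$weight_init,
              format(count_trainable_params(x), big.mark = ",")))
  invisible(x)
}

#' Named architecture presets
#'
#' The five network architectures studied for the two prediction problems:
#'
#' * `ofdf_existing`: 24 -> ten hidden layers of 50 -> 1 (the prior
#'   baseline for disintegration time).
#' * `ofdf_proposed`: 24 -> 50, 25, 16 -> 1, dropout 0.05 on hidden layer 1.
#' * `ofdf_proposed_pca`: the same network on the 5-dimensional PCA
#'   representation.
#' * `srmt_existing`: 21 -> nine hidden layers of 30 -> 4.
#' * `srmt_proposed`: 21 -> 150, 130, 100, 50, 30 -> 4, dropout 0.1 on
#'   hidden layers 1 and 2, random-normal weight initialization.
#'
#' All use ReLU hidden activations and a sigmoid output (targets live on the
#' unit scale).
#'
#' @param name preset name.
#' @return An [mlp_spec()].
#' @export
preset_spec <- function(name) {
  switch(name,
    ofdf_existing = mlp_spec(24, rep(50, 10), 1),
    ofdf_proposed = mlp_spec(24, c(50, 25, 16), 1, dropout = list(`1` = 0.05)),
    ofdf_proposed_pca = mlp_spec(5, c(50, 25, 16), 1, dropout = list(`1` = 0.05)),
    srmt_existing = mlp_spec(21, rep(30, 9), 4),
    srmt_proposed = mlp_spec(21, c(150, 130, 100, 50, 30), 4,
                             dropout = list(`1` = 0.1, `2` = 0.1),
                             weight_init = "random_normal"),
    dn_stop(sprintf("unknown preset '%s'", name), "unknown_preset"))
}

#' Per-layer trainable-parameter table
#'
#' One row per layer (input row included with 0), counting
#' `fan_in * fan_out + fan_out` weights plus biases per dense layer.
#' Dropout contributes no parameters.
#'
#' @param spec an [mlp_spec()].
#' @return data.frame with columns `layer`, `shape`, `params`.
#' @export
param_table <- function(spec) {
  stopifnot(inherits(spec, "mlp_spec"))
  widths <- c(spec$hidden, spec$output_dim)
  fan_in <- c(spec$input_dim, widths[-length(widths)])
  params <- fan_in * widths + widths
  nh <- length(spec$hidden)
  labels <- c("Input",
              if (nh) paste("Hidden layer", seq_len(nh)),
              "Output")
  data.frame(layer = labels,
             shape = c(spec$input_dim, widths),
             params = c(0L, as.integer(params)),
             stringsAsFactors = FALSE)
}

#' Total trainable parameters of a network
#'
#' @param spec an [mlp_spec()].
#' @return Integer parameter count.
#' @export
count_trainable_params <- function(spec) {
  sum(param_table(spec)$params)
}

#' Total optimizer updates of a training run
#'
#' One update per batch; the final partial batch is used, so an epoch has
#' `ceiling(n_train / batch_size)` updates.
#'
#' @param n_train,batch_size,epochs positive integers.
#' @return Integer update count `epochs * ceiling(n_train / batch_size)`.
#' @export
count_updates <- function(n_train, batch_size, epochs) {
  if (n_train <= 0 || batch_size <= 0 || epochs <= 0)
    dn_stop("n_train, batch_size and epochs must be positive", "bad_count")
  as.integer(epochs) * as.integer(ceiling(n_train / batch_size))
}

#' Training configuration
#'
#' @param optimizer optimizer name (only `"adam"` is implemented for the
#'   prediction networks).
#' @param learning_rate positive step size (0.01 for the OFDF runs, 0.001
#'   for SRMT).
#' @param loss loss name (`"mse"`).
#' @param epochs number of passes over the training data (>= 1).
#' @param batch_size samples per update (>= 1); the last batch may be
#'   partial.
#' @param seed RNG seed covering shuffling and dropout masks.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 0.01,
                         loss = "mse", epochs = 800, batch_size = 32,
                         seed = 1) {
  if (epochs < 1L) dn_stop("epochs must be >= 1", "bad_epochs")
  if (batch_size < 1L) dn_stop("batch_size must be >= 1", "bad_batch")
  if (learning_rate <= 0) dn_stop("learning_rate must be positive", "bad_lr")
  if (optimizer != "adam")
    dn_stop(sprintf("unknown optimizer '%s'", optimizer), "unknown_optimizer")
  if (loss != "mse")
    dn_stop(sprintf("unknown loss '%s'", loss), "unknown_loss")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 loss = loss, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed),
            class = "train_config")
}

#' Build an (untrained) network from a specification
#'
#' Weights are drawn from the spec's initializer under the given seed;
#' biases start at exactly zero. The same seed always reproduces the same
#' parameters bit for bit.
#'
#' @param spec an [mlp_spec()].
#' @param seed RNG seed for initialization.
#' @return An object of class `mlp_model`.
#' @export
build_mlp <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "mlp_spec"))
  nh <- length(spec$hidden)
  net <- with_seed_(seed, nn_new(
    spec$input_dim,
    widths = c(spec$hidden, spec$output_dim),
    acts = c(rep(spec$hidden_activation, nh), spec$output_activation),
    dropout = c(spec$dropout, 0),
    init = spec$weight_init, init_sd = spec$init_sd))
  structure(list(spec = spec, net = net, history = numeric(0),
                 n_updates = 0L, trained = FALSE),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d -> [%s] -> %d; %s; %d updates performed\n",
              x$spec$input_dim, paste(x$spec$hidden, collapse = ", "),
              x$spec$output_dim,
              if (x$trained) "trained" else "untrained", x$n_updates))
  invisible(x)
}

#' Train a network by mini-batch gradient descent
#'
#' Mean-squared-error loss with the Adam optimizer. Each epoch reshuffles
#' the training rows; batches of `batch_size` (final batch partial) each
#' trigger one parameter update, so a run performs exactly
#' [count_updates()] steps. Dropout is active only here, never at
#' prediction time. Targets must already be on the unit scale.
#'
#' @param model an [build_mlp()] model.
#' @param data a [formulation_dataset()] (normalized) or a list with
#'   elements `features` and `targets`.
#' @param cfg a [train_config()].
#' @return The trained `mlp_model`, with per-epoch `history` (mean training
#'   loss) and the update counter.
#' @export
train_mlp <- function(model, data, cfg) {
  stopifnot(inherits(model, "mlp_model"), inherits(cfg, "train_config"))
  X <- as.matrix(data$features)
  Y <- as.matrix(data$targets)
  if (ncol(X) != model$spec$input_dim)
    dn_stop(sprintf("feature width %d does not match model input %d",
                    ncol(X), model$spec$input_dim), "width_mismatch")
  if (ncol(Y) != model$spec$output_dim)
    dn_stop("target width does not match model output", "width_mismatch")
  if (min(Y) < -1e-9 || max(Y) > 1 + 1e-9)
    dn_stop("targets must be normalized to [0, 1] before training",
            "unnormalized_targets")
  n <- nrow(X)
  net <- model$net
  state <- opt_init(net, "adam")
  history <- numeric(cfg$epochs)
  n_updates <- model$n_updates
  with_seed_(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      sse <- 0
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        fw <- nn_forward(net, X[idx, , drop = FALSE], training = TRUE)
        net <- fw$net
        P <- fw$out
        E <- P - Y[idx, , drop = FALSE]
        loss <- mean(E * E)
        if (!is.finite(loss))
          dn_stop(sprintf("non-finite training loss at epoch %d", epoch),
                  "non_finite_loss")
        bw <- nn_backward(net, fw$caches, 2 * E / length(E))
        st <- opt_step(net, bw$grads, state, cfg$learning_rate)
        net <- st$net
        state <- st$state
        n_updates <- n_updates + 1L
        sse <- sse + sum(E * E)
      }
      history[epoch] <- sse / (n * ncol(Y))
    }
  })
  model$net <- net
  model$history <- c(model$history, history)
  model$n_updates <- n_updates
  model$trained <- TRUE
  model
}

#' Predict with a trained network
#'
#' Deterministic forward pass with dropout disabled; sigmoid outputs lie
#' strictly in (0, 1) on the unit target scale.
#'
#' @param object an `mlp_model`.
#' @param features numeric matrix with the model's input width.
#' @param ... unused.
#' @return n x output_dim matrix of predictions.
#' @export
predict.mlp_model <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != object$spec$input_dim)
    dn_stop(sprintf("feature width %d does not match model input %d",
                    ncol(X), object$spec$input_dim), "width_mismatch")
  nn_forward(object$net, X, training = FALSE)$out
}
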
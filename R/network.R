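#' Training hyper-parameters for the per-item network
#'
#' The studied grid is patience in \{10, 100\} epochs, dropout in
#' \{0.20, 0.25, 0.50\}, and batch mode full-batch / mini-batch of 8 /
#' stochastic (batch size 1).  `max_epochs` caps training when the
#' early-stopping patience never triggers.
#'
#' @param patience_epochs consecutive epochs without improvement of the
#'   (smoothed) training loss tolerated before training halts; >= 1.
#' @param dropout_rate dropout probability in `[0, 1)`, applied after
#'   every hidden layer.
#' @param batch_mode `"full"`, `"mini8"`, or `"stochastic"`.
#' @param max_epochs hard epoch cap (>= patience_epochs).
#' @param validation_fraction held-out fraction used for early stopping
#'   and the reported per-item accuracy, in (0, 1).
#' @param learning_rate Adam step size.
#' @param n_starts independent initializations per item; the fit with
#'   the best held-out loss is kept (deep narrow stacks are sensitive
#'   to initialization).
#' @param seed integer RNG seed for split, init, shuffling, dropout.
#' @return A `hyper_params` list.
#' @export
hyper_params <- function(patience_epochs = 10L, dropout_rate = 0.25,
                         batch_mode = c("mini8", "full", "stochastic"),
                         max_epochs = 1000L, validation_fraction = 0.2,
                         learning_rate = 3e-3, n_starts = 2L, seed = 1L) {
  batch_mode <- match.arg(batch_mode)
  hp <- list(patience_epochs = as.integer(patience_epochs),
             dropout_rate = dropout_rate,
             batch_mode = batch_mode,
             max_epochs = as.integer(max_epochs),
             validation_fraction = validation_fraction,
             learning_rate = learning_rate,
             n_starts = as.integer(n_starts),
             seed = as.integer(seed))
  if (hp$n_starts < 1L) stop("n_starts must be >= 1")
  if (hp$patience_epochs < 1L) stop("patience_epochs must be >= 1")
  if (hp$max_epochs < hp$patience_epochs) {
    stop("max_epochs must be >= patience_epochs")
  }
  if (hp$dropout_rate < 0 || hp$dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)")
  }
  if (hp$validation_fraction <= 0 || hp$validation_fraction >= 1) {
    stop("validation_fraction must lie in (0, 1)")
  }
  hp
}

batch_size_for <- function(batch_mode, n_train) {
  switch(batch_mode,
         full = n_train,
         mini8 = 8L,
         stochastic = 1L)
}

#' Build the network architecture for a given input width
#'
#' The architecture has 15 hidden layers in three groups of five: the
#' first five layers are twice as wide as the input, the middle five as
#' wide as the input, and the last five half as wide (floored, clamped
#' at 1).  Hidden activation is ReLU; the output is a 4-unit softmax,
#' one unit per Likert score.  During the imputation loop the input
#' width starts at the 12 CCPT indices and grows by one merged item per
#' iteration.
#'
#' @param n_inputs number of input features (>= 1).
#' @param dropout_rate dropout probability carried in the returned
#'   description.
#' @return A `network_spec` list with fields `n_inputs`, `hidden_widths`
#'   (15 integers), `n_outputs` (4), `hidden_activation`,
#'   `output_activation`, `dropout_rate`.
#' @examples
#' build_network_spec(12)$hidden_widths
#' @export
build_network_spec <- function(n_inputs, dropout_rate = 0.25) {
  if (!is.numeric(n_inputs) || n_inputs < 1) {
    stop("n_inputs must be >= 1")
  }
  n <- as.integer(n_inputs)
  widths <- c(rep(2L * n, 5L), rep(n, 5L), rep(max(1L, n %/% 2L), 5L))
  structure(list(n_inputs = n,
                 hidden_widths = widths,
                 n_outputs = 4L,
                 hidden_activation = "relu",
                 output_activation = "softmax",
                 dropout_rate = dropout_rate),
            class = "network_spec")
}

# stratified train/validation split: each class keeps ~ (1-frac) in
# training; falls back to a plain random split when any class has < 2 rows
split_validation <- function(targets, fraction) {
  n <- length(targets)
  counts <- table(targets)
  val <- integer(0)
  if (all(counts >= 2L)) {
    for (cl in names(counts)) {
      rows <- which(targets == as.integer(cl))
      k <- max(1L, round(fraction * length(rows)))
      k <- min(k, length(rows) - 1L)  # keep at least one row in training
      val <- c(val, sample(rows, k))
    }
  } else {
    k <- max(1L, round(fraction * n))
    k <- min(k, n - 1L)
    val <- sample.int(n, k)
  }
  sort(val)
}

#' Train the per-item imputation network
#'
#' Fits the deep network of [build_network_spec()] to predict one
#' ordinal item (scores 0--3) from a complete feature matrix.  Rows are
#' split into training and validation sets (stratified by score when
#' every observed score has at least two rows); weights are updated by
#' Adam on categorical cross-entropy with the batch size implied by
#' `hp$batch_mode`, and training halts when the (smoothed) training
#' loss has not improved for `hp$patience_epochs` consecutive epochs
#' (or at `hp$max_epochs`).  The returned weights are the snapshot with
#' the best held-out loss, and the reported `validation_accuracy` is
#' computed on rows never used for weight updates.
#'
#' Deep narrow stacks of this shape are delicate to optimize on small
#' samples; the trainer uses orthogonal initialization, gradient
#' clipping, step-size decay, a curriculum ramp of the dropout rate,
#' and a weight moving average (see the methods vignette), and fits
#' `hp$n_starts` independent starts keeping the best held-out loss.
#'
#' Columns listed in `standardize_cols` (the continuous CCPT indices)
#' are standardized with statistics fitted on the training rows only;
#' ordinal item columns are fed as raw 0--3 scores.
#'
#' If all targets share a single value the item is degenerate and a
#' constant model with validation accuracy 1 is returned without
#' training.
#'
#' @param features complete numeric matrix (no `NA`), one row per
#'   participant.
#' @param targets integer vector of scores in `{0,1,2,3}`, one per row.
#' @param hp a [hyper_params()] list.
#' @param standardize_cols integer indices of columns to standardize
#'   (default: none).
#' @return A `trained_item_model` with fields `spec`, `weights`,
#'   `biases`, `center`/`scale_` (standardization), `constant_class`,
#'   `validation_accuracy`, `epochs_run`.
#' @export
train_item_model <- function(features, targets, hp = hyper_params(),
                             standardize_cols = integer(0)) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("features must have no missing entries")
  if (nrow(features) != length(targets)) {
    stop("features row count must equal length(targets)")
  }
  if (nrow(features) < 8L) {
    stop("insufficient data: need at least 8 rows, got ", nrow(features))
  }
  targets <- as.integer(targets)
  if (anyNA(targets) || any(targets < 0L | targets > 3L)) {
    stop("targets must lie in {0,1,2,3}")
  }

  spec <- build_network_spec(ncol(features), hp$dropout_rate)
  if (length(unique(targets)) == 1L) {
    return(structure(list(spec = spec, weights = NULL, biases = NULL,
                          center = NULL, scale_ = NULL,
                          standardize_cols = integer(0),
                          constant_class = targets[1L],
                          validation_accuracy = 1.0, epochs_run = 0L),
                     class = "trained_item_model"))
  }

  set.seed(hp$seed)
  val_idx <- split_validation(targets, hp$validation_fraction)
  train_idx <- setdiff(seq_len(nrow(features)), val_idx)

  center <- rep(0, ncol(features))
  scale_ <- rep(1, ncol(features))
  if (length(standardize_cols) > 0L) {
    center[standardize_cols] <-
      colMeans(features[train_idx, standardize_cols, drop = FALSE])
    s <- apply(features[train_idx, standardize_cols, drop = FALSE], 2, sd)
    s[!is.finite(s) | s == 0] <- 1
    scale_[standardize_cols] <- s
  }
  x <- sweep(sweep(features, 2, center, "-"), 2, scale_, "/")

  # deep narrow stacks are sensitive to initialization: train from
  # `n_starts` seeds and keep the fit with the best held-out loss
  fit <- NULL
  for (attempt in seq_len(hp$n_starts) - 1L) {
    cand <- .mlp_train_cpp(
      x[train_idx, , drop = FALSE], targets[train_idx],
      x[val_idx, , drop = FALSE], targets[val_idx],
      spec$hidden_widths, hp$dropout_rate,
      batch_size_for(hp$batch_mode, length(train_idx)),
      hp$max_epochs, hp$patience_epochs, hp$learning_rate,
      as.integer((hp$seed + attempt * 977L) %% .Machine$integer.max)
    )
    if (is.null(fit) || cand$validation_loss < fit$validation_loss) {
      fit <- cand
    }
  }
  structure(list(spec = spec, weights = fit$weights, biases = fit$biases,
                 center = center, scale_ = scale_,
                 standardize_cols = standardize_cols,
                 constant_class = NULL,
                 validation_accuracy = fit$validation_accuracy,
                 epochs_run = fit$epochs_run),
            class = "trained_item_model")
}

#' Predict ordinal scores from a trained item model
#'
#' Returns, per row, the score whose softmax probability is maximal;
#' ties break toward the lower score.
#'
#' @param model a `trained_item_model`.
#' @param features complete numeric matrix with
#'   `model$spec$n_inputs` columns.
#' @return Integer vector of scores in `{0,1,2,3}`.
#' @export
predict_item <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$spec$n_inputs) {
    stop("feature column count ", ncol(features),
         " does not match model input width ", model$spec$n_inputs)
  }
  if (anyNA(features)) stop("features must have no missing entries")
  if (!is.null(model$constant_class)) {
    return(rep(model$constant_class, nrow(features)))
  }
  x <- sweep(sweep(features, 2, model$center, "-"), 2, model$scale_, "/")
  probs <- .mlp_predict_cpp(model$weights, model$biases, x)
  # which.max returns the first maximum -> ties resolve to the lower score
  as.integer(apply(probs, 1L, which.max)) - 1L
}

#' Softmax class probabilities from a trained item model
#' @keywords internal
predict_item_probs <- function(model, features) {
  features <- as.matrix(features)
  if (!is.null(model$constant_class)) {
    probs <- matrix(0, nrow(features), 4L)
    probs[, model$constant_class + 1L] <- 1
    return(probs)
  }
  x <- sweep(sweep(features, 2, model$center, "-"), 2, model$scale_, "/")
  .mlp_predict_cpp(model$weights, model$biases, x)
}
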
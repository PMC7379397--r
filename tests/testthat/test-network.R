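test_that("network widths follow the 2n/n/n-half rule for any input", {
  s12 <- build_network_spec(12)
  expect_equal(s12$hidden_widths,
               c(rep(24L, 5), rep(12L, 5), rep(6L, 5)))
  expect_equal(s12$n_outputs, 4L)
  expect_equal(s12$hidden_activation, "relu")
  expect_equal(s12$output_activation, "softmax")

  expect_equal(build_network_spec(13)$hidden_widths[11:15], rep(6L, 5))
  s118 <- build_network_spec(118)
  expect_equal(unique(s118$hidden_widths[1:5]), 236L)
  expect_equal(unique(s118$hidden_widths[6:10]), 118L)
  expect_equal(unique(s118$hidden_widths[11:15]), 59L)
  # widths hold across the whole growth range of the loop
  for (n in c(12, 13, 50, 117, 118)) {
    w <- build_network_spec(n)$hidden_widths
    expect_equal(w, c(rep(2L * n, 5), rep(n, 5), rep(max(1L, n %/% 2L), 5)))
  }
  expect_equal(build_network_spec(1)$hidden_widths[11:15], rep(1L, 5))
  expect_error(build_network_spec(0), "n_inputs")
})

test_that("a constant item yields a constant model with accuracy 1", {
  x <- matrix(rnorm(20 * 12), 20, 12)
  m <- train_item_model(x, rep(2L, 20), quick_hp())
  expect_equal(m$validation_accuracy, 1.0)
  expect_equal(m$epochs_run, 0L)
  expect_equal(predict_item(m, x), rep(2L, 20))
})

test_that("training errors on bad inputs", {
  x <- matrix(rnorm(20 * 4), 20, 4)
  y <- sample(0:3, 20, replace = TRUE)
  xm <- x; xm[3, 2] <- NA
  expect_error(train_item_model(xm, y, quick_hp()), "missing")
  expect_error(train_item_model(x[1:5, ], y[1:5], quick_hp()),
               "at least 8 rows")
  expect_error(train_item_model(x, y + 4L, quick_hp()), "0,1,2,3")
  expect_error(hyper_params(patience_epochs = 0), "patience")
  expect_error(hyper_params(dropout_rate = 1), "dropout")
  expect_error(hyper_params(max_epochs = 5, patience_epochs = 10),
               "max_epochs")
})

test_that("a noise-free threshold rule is recovered almost perfectly", {
  set.seed(42)
  n <- 400
  x <- matrix(rnorm(n * 12), n, 12)
  cuts <- c(-0.7, 0, 0.7)
  # deterministic rule with a margin around the thresholds, so the
  # boundary is identifiable from a finite sample
  repeat {
    bad <- vapply(x[, 3], function(v) any(abs(v - cuts) < 0.15), logical(1))
    if (!any(bad)) break
    x[bad, 3] <- rnorm(sum(bad))
  }
  y <- as.integer(cut(x[, 3], c(-Inf, cuts, Inf))) - 1L
  hp <- hyper_params(patience_epochs = 50, dropout_rate = 0,
                     batch_mode = "mini8", max_epochs = 600,
                     learning_rate = 0.01, n_starts = 3, seed = 7)
  m <- train_item_model(x, y, hp, standardize_cols = 1:12)
  expect_gte(m$validation_accuracy, 0.95)
  # rule-lookup oracle: predictions on the training rows must match the
  # exact rule for almost every row
  oracle <- as.integer(cut(x[, 3], c(-Inf, cuts, Inf))) - 1L
  expect_gte(mean(predict_item(m, x) == oracle), 0.95)
})

test_that("permuted targets score at chance on a balanced problem", {
  set.seed(9)
  n <- 400
  x <- matrix(rnorm(n * 12), n, 12)
  y <- sample(rep(0:3, n / 4))
  hp <- hyper_params(patience_epochs = 10, dropout_rate = 0,
                     batch_mode = "mini8", max_epochs = 100, seed = 3)
  m <- train_item_model(x, y, hp, standardize_cols = 1:12)
  se <- sqrt(0.25 * 0.75 / 80)  # 80 validation rows
  expect_lt(abs(m$validation_accuracy - 0.25), 3 * se)
})

test_that("training and prediction are deterministic given the seed", {
  set.seed(5)
  x <- matrix(rnorm(120 * 6), 120, 6)
  y <- sample(0:3, 120, replace = TRUE)
  hp <- hyper_params(patience_epochs = 3, dropout_rate = 0.25,
                     max_epochs = 40, seed = 13)
  m1 <- train_item_model(x, y, hp, standardize_cols = 1:6)
  m2 <- train_item_model(x, y, hp, standardize_cols = 1:6)
  expect_identical(m1$validation_accuracy, m2$validation_accuracy)
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict_item(m1, x), predict_item(m2, x))
})

test_that("early stopping respects the epoch cap and the patience hook", {
  set.seed(5)
  x <- matrix(rnorm(100 * 4), 100, 4)
  y <- sample(0:3, 100, replace = TRUE)
  hp <- hyper_params(patience_epochs = 2, dropout_rate = 0,
                     max_epochs = 25, seed = 1)
  m <- train_item_model(x, y, hp)
  expect_lte(m$epochs_run, 25L)
  # patience = max_epochs (never triggers early): runs to the cap
  hp2 <- hyper_params(patience_epochs = 30, dropout_rate = 0,
                      max_epochs = 30, seed = 1)
  m2 <- train_item_model(x, y, hp2)
  expect_equal(m2$epochs_run, 30L)
})

test_that("predictions are valid scores and ties break to the lower one", {
  set.seed(6)
  x <- matrix(rnorm(60 * 5), 60, 5)
  y <- sample(0:3, 60, replace = TRUE)
  m <- train_item_model(x, y, quick_hp())
  p <- predict_item(m, x)
  expect_true(all(p %in% 0:3))
  expect_error(predict_item(m, x[, 1:3]), "column")
  # zeroed parameters give a uniform softmax; the tie rule picks 0
  m0 <- m
  m0$weights <- lapply(m0$weights, function(w) w * 0)
  m0$biases <- lapply(m0$biases, function(b) b * 0)
  expect_equal(predict_item(m0, x), rep(0L, nrow(x)))
  probs <- scaleimpute:::predict_item_probs(m0, x)
  expect_equal(unname(probs), matrix(0.25, nrow(x), 4), tolerance = 1e-12)
})

test_that("harder planted items never score above easier ones on average", {
  reg <- tiny_registry(4)
  accs <- sapply(1:3, function(s) {
    coh <- planted_cohort(250, s, lams = c(5, 1.5, 0.6, 0), reg)
    hp <- hyper_params(patience_epochs = 5, dropout_rate = 0.25,
                       max_epochs = 150, n_starts = 1, seed = s * 7)
    sapply(seq_len(4), function(j) {
      hp$seed <- s * 7 + j
      train_item_model(coh$ccpt, coh$items[, j], hp,
                       standardize_cols = 1:12)$validation_accuracy
    })
  })
  mean_acc <- rowMeans(accs)
  se <- sqrt(mean_acc * (1 - mean_acc) / (3 * 50))
  # non-increasing in SNR up to one standard error
  expect_true(all(diff(mean_acc) <= se[-1] + 1e-9))
})
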
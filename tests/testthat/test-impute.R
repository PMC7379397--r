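masked_fixture <- function(n = 40, n_items = 6, rate = 0.2, seed = 3) {
  reg <- tiny_registry(n_items)
  coh <- generate_cohort(reg, cohort_config(n_case = n / 2,
                                            n_control = n / 2,
                                            seed = seed))
  list(registry = reg, complete = coh,
       masked = random_mask(coh, reg, rate, seed + 100))
}

test_that("mean imputation rounds the observed mean into the score range", {
  x <- masked_fixture()
  coh <- x$masked
  coh$items[, 1] <- c(0L, 1L, 3L, NA, rep(0L, 36))
  filled <- mean_impute(coh)
  expect_equal(unname(filled$items[4, 1]), 0L)  # mean 4/39 rounds to 0
  coh$items[1:4, 1] <- c(0L, 1L, 3L, NA)
  coh$items[5:40, 1] <- NA_integer_
  expect_equal(unname(mean_impute(coh)$items[4, 1]), 1L)  # mean 4/3 -> 1
  coh$items[, 2] <- c(3L, 3L, rep(NA_integer_, 38))
  expect_equal(unique(unname(mean_impute(coh)$items[3:40, 2])), 3L)
  # complete cohort: identity
  expect_identical(mean_impute(x$complete)$items, x$complete$items)
  # all-missing item: error naming it
  coh$items[, 3] <- NA_integer_
  expect_error(mean_impute(coh), colnames(coh$items)[3])
})

test_that("interpolation fills within scale by position", {
  reg <- tiny_registry(6)
  items <- matrix(NA_integer_, 3, 6, dimnames = list(NULL, reg$item_id))
  items[1, ] <- c(0L, NA, 2L, 2L, 2L, 2L)   # midpoint 0-2 -> 1
  items[2, ] <- c(NA, 2L, 2L, 2L, 2L, 2L)   # leading edge extends
  items[3, ] <- c(1L, 1L, 1L, 1L, 1L, 1L)   # complete row untouched
  coh <- cohort_table(c("A", "B", "C"), c("CASE", "CONTROL", "CASE"),
                      matrix(0, 3, 12), items, reg)
  out <- interpolate_impute(coh, reg)
  expect_equal(unname(out$items[1, 2]), 1L)
  expect_equal(unname(out$items[2, 1]), 2L)
  expect_identical(out$items[3, ], items[3, ])
  expect_equal(count_missing(out), 0L)
})

test_that("interpolation falls back to item means for empty scale rows", {
  reg <- tiny_registry(6)
  items <- matrix(2L, 4, 6, dimnames = list(NULL, reg$item_id))
  items[1, ] <- NA_integer_
  coh <- cohort_table(sprintf("P%d", 1:4),
                      rep(c("CASE", "CONTROL"), 2),
                      matrix(0, 4, 12), items, reg)
  out <- interpolate_impute(coh, reg)
  expect_equal(unname(out$items[1, ]), rep(2L, 6))
})

test_that("multiple imputation preserves observed cells in every table", {
  x <- masked_fixture()
  out <- multiple_impute(x$masked, m = 3, seed = 5)
  expect_length(out, 3)
  obs <- !is.na(x$masked$items)
  for (tab in out) {
    expect_equal(count_missing(tab), 0L)
    expect_identical(tab$items[obs], x$masked$items[obs])
  }
  expect_error(multiple_impute(x$masked, m = 1), "m must be >= 2")
  # complete input: all tables identical to it
  out2 <- multiple_impute(x$complete, m = 2, seed = 5)
  expect_identical(out2[[1]]$items, x$complete$items)
  expect_identical(out2[[2]]$items, x$complete$items)
})

test_that("chained equations recover a perfectly collinear item", {
  reg <- tiny_registry(4)
  set.seed(8)
  n <- 80
  base <- sample(0:3, n, replace = TRUE)
  items <- cbind(base, base, sample(0:3, n, TRUE), sample(0:3, n, TRUE))
  colnames(items) <- reg$item_id
  storage.mode(items) <- "integer"
  coh <- cohort_table(sprintf("P%d", 1:n),
                      rep(c("CASE", "CONTROL"), n / 2),
                      matrix(rnorm(n * 12), n, 12), items, reg)
  mis_rows <- 1:20
  coh$items[mis_rows, 2] <- NA_integer_
  out <- multiple_impute(coh, m = 3, seed = 9)
  agree <- sapply(out, function(tab) {
    mean(tab$items[mis_rows, 2] == base[mis_rows])
  })
  expect_true(all(agree >= 0.9))
})

test_that("tier assignment splits the order into floored thirds", {
  ord107 <- build_default_registry()$item_id
  t107 <- assign_tiers(ord107)
  expect_equal(unname(table(t107)[c("TOP", "INTERMEDIATE", "BOTTOM")]),
               c(35L, 37L, 35L), ignore_attr = TRUE)
  expect_equal(unname(t107[ord107[1]]), "TOP")
  expect_equal(unname(t107[ord107[107]]), "BOTTOM")
  t6 <- assign_tiers(paste0("i", 1:6))
  expect_equal(unname(table(t6)[c("TOP", "INTERMEDIATE", "BOTTOM")]),
               c(2L, 2L, 2L), ignore_attr = TRUE)
  t7 <- assign_tiers(paste0("i", 1:7))
  expect_equal(unname(table(t7)[c("TOP", "INTERMEDIATE", "BOTTOM")]),
               c(2L, 3L, 2L), ignore_attr = TRUE)
  expect_error(assign_tiers(character(0)), "non-empty")
})

test_that("the loop on a complete cohort is an identity with a full order", {
  x <- masked_fixture(n = 30, n_items = 5, rate = 0)
  res <- run_iterative_imputation(x$complete, x$registry, quick_hp())
  expect_identical(res$completed_cohort$items, x$complete$items)
  expect_setequal(res$imputation_order, x$registry$item_id)
  expect_true(all(vapply(res$records, `[[`, numeric(1),
                         "n_cells_imputed") == 0))
})

test_that("greedy selection maximizes candidate accuracy every iteration", {
  x <- masked_fixture(n = 40, n_items = 5, rate = 0.15)
  res <- run_iterative_imputation(x$masked, x$registry, quick_hp())
  for (r in res$records) {
    if (!r$deferred) {
      expect_equal(r$selected_accuracy, max(r$candidate_accuracies))
    }
    expect_equal(r$n_features, 12L + r$iteration - 1L)
  }
  expect_equal(count_missing(res$completed_cohort), 0L)
  obs <- !is.na(x$masked$items)
  expect_identical(res$completed_cohort$items[obs], x$masked$items[obs])
})

test_that("a noise-free planted item is selected first", {
  reg <- tiny_registry(6)
  set.seed(17)
  n <- 200
  ccpt <- matrix(rnorm(n * 12), n, 12)
  items <- sapply(1:6, function(j) sample(0:3, n, replace = TRUE))
  # item 4 is a deterministic threshold of CCPT index 2
  items[, 4] <- as.integer(cut(ccpt[, 2], c(-Inf, -0.7, 0, 0.7, Inf))) - 1L
  colnames(items) <- reg$item_id
  coh <- cohort_table(sprintf("P%d", 1:n),
                      rep(c("CASE", "CONTROL"), n / 2),
                      ccpt, items, reg)
  coh <- random_mask(coh, reg, rate = 0.1, seed = 18)
  hp <- hyper_params(patience_epochs = 10, dropout_rate = 0,
                     max_epochs = 150, learning_rate = 0.01,
                     n_starts = 1, seed = 19)
  res <- run_iterative_imputation(coh, reg, hp)
  expect_equal(res$imputation_order[1], reg$item_id[4])
  expect_gt(res$records[[1]]$selected_accuracy,
            max(res$records[[1]]$candidate_accuracies[-4]) + 0.2)
})

test_that("sparse items defer to the end or abort per policy", {
  x <- masked_fixture(n = 30, n_items = 5, rate = 0)
  coh <- x$complete
  coh$items[1:25, 3] <- NA_integer_  # 5 observed rows only
  res <- run_iterative_imputation(coh, x$registry, quick_hp())
  expect_equal(res$imputation_order[5], x$registry$item_id[3])
  expect_true(res$records[[5]]$deferred)
  expect_equal(count_missing(res$completed_cohort), 0L)
  expect_error(
    run_iterative_imputation(coh, x$registry, quick_hp(),
                             imputation_options(sparse_item_policy = "error")),
    "fewer than 8")
})

test_that("ODD exclusion drops flagged items from the loop", {
  full_reg <- build_default_registry()
  ids <- full_reg$item_id[full_reg$scale == "SNAP_P" &
                            full_reg$position %in% 16:21]
  reg <- registry_subset(full_reg, item_ids = ids)  # 3 ODD of 6
  coh <- generate_cohort(reg, cohort_config(n_case = 20, n_control = 20,
                                            seed = 23))
  coh <- random_mask(coh, reg, 0.1, 24)
  res <- run_iterative_imputation(coh, reg, quick_hp(),
                                  imputation_options(exclude_odd_items = TRUE))
  expect_setequal(res$imputation_order,
                  reg$item_id[!reg$is_odd_item])
  expect_equal(ncol(res$completed_cohort$items), 3L)
})

test_that("the loop is deterministic given the seed", {
  x <- masked_fixture(n = 30, n_items = 4, rate = 0.15)
  r1 <- run_iterative_imputation(x$masked, x$registry, quick_hp(5))
  r2 <- run_iterative_imputation(x$masked, x$registry, quick_hp(5))
  expect_identical(r1$completed_cohort$items, r2$completed_cohort$items)
  expect_identical(r1$imputation_order, r2$imputation_order)
})

test_that("network imputation reconstructs held-back cells far better
           than mean imputation", {
  reg <- registry_subset(build_default_registry(), n_items = 15)
  for (s in 1:3) {
    coh <- generate_cohort(reg, cohort_config(n_case = 150, n_control = 150,
                                              effect_sizes = 1.5, seed = s))
    mis <- random_mask(coh, reg, rate = 0.08, seed = s + 50)
    hp <- hyper_params(patience_epochs = 3, dropout_rate = 0.25,
                       max_epochs = 60, n_starts = 1, seed = s)
    imp <- run_iterative_imputation(mis, reg, hp)
    mask <- is.na(mis$items)
    dnn_cell <- mean(imp$completed_cohort$items[mask] == coh$items[mask])
    mean_cell <- mean(mean_impute(mis)$items[mask] == coh$items[mask])
    expect_gt(dnn_cell, mean_cell + 0.1)
  }
})
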
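#' Options for the iterative imputation loop
#'
#' @param exclude_odd_items drop items flagged as oppositional-defiant
#'   (ODD) screening items before the loop (sensitivity analysis).
#' @param track_classification run the downstream two-group SVM
#'   classification after each iteration and record its 10-fold mean
#'   accuracy in the iteration record.
#' @param sparse_item_policy what to do with items having fewer than 8
#'   observed responses: `"skip_to_last"` imputes them after all
#'   evaluable items (flagged `deferred` in their record), `"error"`
#'   aborts.
#' @param candidate_subsample optional integer: evaluate at most this
#'   many randomly chosen remaining items per iteration (`NULL` = all;
#'   a desk-scale control, off by default).
#' @param classification_folds folds used when `track_classification`.
#' @return An options list for [run_iterative_imputation()].
#' @export
imputation_options <- function(exclude_odd_items = FALSE,
                               track_classification = FALSE,
                               sparse_item_policy = c("skip_to_last",
                                                      "error"),
                               candidate_subsample = NULL,
                               classification_folds = 10L) {
  list(exclude_odd_items = exclude_odd_items,
       track_classification = track_classification,
       sparse_item_policy = match.arg(sparse_item_policy),
       candidate_subsample = candidate_subsample,
       classification_folds = as.integer(classification_folds))
}

# deterministic per-(iteration, candidate) seed derived from the base seed
derive_seed <- function(base, iteration, j) {
  as.integer((as.numeric(base) + 104729 * iteration + 7919 * j) %%
               .Machine$integer.max)
}

#' Greedy iterative deep-network imputation
#'
#' Implements the iterative loop at the core of the package.  The
#' feature set starts as the 12 complete CCPT indices.  At each
#' iteration, every remaining item is scored: a deep network
#' ([train_item_model()]) is fitted on the participants whose response
#' to that item is observed, and its held-out accuracy recorded.  The
#' item with the highest accuracy is selected (ties break by canonical
#' registry order), its missing cells are filled with the model's
#' predictions, the completed column is appended to the feature set,
#' and the loop repeats until no items remain.  Imputed values of
#' merged items feed all subsequent models; the input width at
#' iteration k is therefore 12 + (k - 1).
#'
#' The imputation order that emerges ranks items by how predictable
#' (and, on clinical data, how discriminating) they are.
#'
#' @param cohort a `cohort_table`; CCPT indices must be complete.
#' @param registry the `item_registry`.
#' @param hp [hyper_params()] controlling each per-item network.
#' @param options [imputation_options()].
#' @return An `imputation_result` list: `completed_cohort` (no missing
#'   cells), `imputation_order` (item ids in selection order),
#'   `records` (one per iteration: candidate accuracies, selected item
#'   and accuracy, cells imputed, optional classification accuracy,
#'   elapsed seconds), and `tiers` (TOP/INTERMEDIATE/BOTTOM per item).
#' @export
run_iterative_imputation <- function(cohort, registry,
                                     hp = hyper_params(),
                                     options = imputation_options()) {
  validate_registry(registry)
  validate_cohort(cohort, registry)
  reg <- registry[registry$item_id %in% colnames(cohort$items), ,
                  drop = FALSE]
  if (options$exclude_odd_items) {
    reg <- reg[!reg$is_odd_item, , drop = FALSE]
  }
  item_ids <- reg$item_id  # canonical order
  items <- cohort$items[, item_ids, drop = FALSE]
  n <- n_participants(cohort)

  observed_counts <- colSums(!is.na(items))
  sparse <- names(observed_counts)[observed_counts < 8L]
  if (length(sparse) > 0L && options$sparse_item_policy == "error") {
    stop("items with fewer than 8 observed responses: ",
         paste(sparse, collapse = ", "))
  }
  evaluable <- setdiff(item_ids, sparse)

  features <- cohort$ccpt
  std_cols <- seq_len(N_CCPT)  # CCPT block is standardized; items raw
  remaining <- evaluable
  order_out <- character(0)
  records <- list()
  iter <- 0L

  while (length(remaining) > 0L) {
    iter <- iter + 1L
    t0 <- proc.time()[["elapsed"]]
    candidates <- remaining
    if (!is.null(options$candidate_subsample) &&
        length(candidates) > options$candidate_subsample) {
      set.seed(derive_seed(hp$seed, iter, 0L))
      candidates <- sample(candidates, options$candidate_subsample)
      candidates <- item_ids[item_ids %in% candidates]  # canonical order
    }
    accs <- rep(NA_real_, length(candidates))
    names(accs) <- candidates
    models <- vector("list", length(candidates))
    names(models) <- candidates
    for (j in seq_along(candidates)) {
      id <- candidates[j]
      obs <- which(!is.na(items[, id]))
      hp_j <- hp
      hp_j$seed <- derive_seed(hp$seed, iter, j)
      models[[id]] <- train_item_model(features[obs, , drop = FALSE],
                                       items[obs, id], hp_j,
                                       standardize_cols = std_cols)
      accs[id] <- models[[id]]$validation_accuracy
    }
    sel <- candidates[which.max(accs)]  # first max -> canonical tie-break
    mis <- which(is.na(items[, sel]))
    if (length(mis) > 0L) {
      items[mis, sel] <- predict_item(models[[sel]],
                                      features[mis, , drop = FALSE])
    }
    features <- cbind(features, items[, sel, drop = FALSE])
    remaining <- setdiff(remaining, sel)
    order_out <- c(order_out, sel)

    cls_acc <- NA_real_
    if (isTRUE(options$track_classification)) {
      run <- classify_groups(features, cohort$group,
                             n_folds = options$classification_folds,
                             seed = derive_seed(hp$seed, iter, 999L))
      cls_acc <- run$mean_accuracy
    }
    records[[iter]] <- list(
      iteration = iter,
      selected_item = sel,
      n_features = ncol(features) - 1L,
      candidate_accuracies = accs,
      selected_accuracy = unname(accs[sel]),
      n_cells_imputed = length(mis),
      classification_accuracy = cls_acc,
      deferred = FALSE,
      elapsed_seconds = proc.time()[["elapsed"]] - t0
    )
  }

  # sparse items: imputed after all evaluable items, from their observed
  # mean (a network cannot be honestly validated on < 8 rows)
  for (id in sparse) {
    iter <- iter + 1L
    t0 <- proc.time()[["elapsed"]]
    mis <- which(is.na(items[, id]))
    obs_vals <- items[!is.na(items[, id]), id]
    fill <- if (length(obs_vals) > 0L) {
      round_half_up_clamp(mean(obs_vals))
    } else 0L
    if (length(mis) > 0L) items[mis, id] <- fill
    features <- cbind(features, items[, id, drop = FALSE])
    order_out <- c(order_out, id)
    records[[iter]] <- list(
      iteration = iter, selected_item = id,
      n_features = ncol(features) - 1L,
      candidate_accuracies = stats::setNames(numeric(0), character(0)),
      selected_accuracy = NA_real_,
      n_cells_imputed = length(mis),
      classification_accuracy = NA_real_,
      deferred = TRUE,
      elapsed_seconds = proc.time()[["elapsed"]] - t0
    )
  }

  completed <- cohort
  completed$items[, item_ids] <- items[, item_ids]
  if (options$exclude_odd_items) {
    keep <- reg$item_id
    completed$items <- completed$items[, keep, drop = FALSE]
  }
  structure(list(completed_cohort = completed,
                 imputation_order = order_out,
                 records = records,
                 tiers = assign_tiers(order_out)),
            class = "imputation_result")
}

#' Assign imputation-order tiers
#'
#' Splits an imputation order into thirds: the first `floor(N/3)` items
#' selected are TOP, the last `floor(N/3)` are BOTTOM, and the
#' remainder INTERMEDIATE.  For the full 107-item registry this yields
#' tiers of 35 / 37 / 35 items.
#'
#' @param imputation_order character vector of item ids in selection
#'   order.
#' @return Named character vector mapping item id to
#'   `"TOP"`/`"INTERMEDIATE"`/`"BOTTOM"`.
#' @export
assign_tiers <- function(imputation_order) {
  n <- length(imputation_order)
  if (n == 0L) stop("imputation order must be non-empty")
  k <- n %/% 3L
  tier <- rep("INTERMEDIATE", n)
  if (k > 0L) {
    tier[seq_len(k)] <- "TOP"
    tier[seq.int(n - k + 1L, n)] <- "BOTTOM"
  }
  stats::setNames(tier, imputation_order)
}

round_half_up_clamp <- function(x) {
  as.integer(pmin(3L, pmax(0L, floor(x + 0.5))))
}

#' Mean imputation baseline
#'
#' Fills each missing cell with the item's observed mean, rounded to
#' the nearest integer score (halves round up) and clamped to 0--3.
#'
#' @param cohort a `cohort_table`.
#' @return The completed cohort.
#' @export
mean_impute <- function(cohort) {
  items <- cohort$items
  for (j in seq_len(ncol(items))) {
    mis <- is.na(items[, j])
    if (!any(mis)) next
    obs <- items[!mis, j]
    if (length(obs) == 0L) {
      stop("item ", colnames(items)[j], " has no observed values")
    }
    items[mis, j] <- round_half_up_clamp(mean(obs))
  }
  cohort$items <- items
  cohort
}

#' Within-scale positional interpolation baseline
#'
#' For each participant and scale, missing cells are filled by linear
#' interpolation over item position between the nearest observed
#' neighbours (nearest-value extension at the ends), rounded to the
#' nearest score.  A participant with no observed item on a scale falls
#' back to the per-item observed means for that scale.
#'
#' @param cohort a `cohort_table`.
#' @param registry the `item_registry` (supplies scale and position).
#' @return The completed cohort.
#' @export
interpolate_impute <- function(cohort, registry) {
  validate_registry(registry)
  reg <- registry[registry$item_id %in% colnames(cohort$items), ,
                  drop = FALSE]
  items <- cohort$items
  col_means <- colMeans(items, na.rm = TRUE)
  for (sc in unique(reg$scale)) {
    ids <- reg$item_id[reg$scale == sc]
    ids <- ids[order(reg$position[match(ids, reg$item_id)])]
    pos <- reg$position[match(ids, reg$item_id)]
    block <- items[, ids, drop = FALSE]
    for (i in seq_len(nrow(block))) {
      row <- block[i, ]
      mis <- is.na(row)
      if (!any(mis)) next
      if (all(mis)) {
        block[i, ] <- round_half_up_clamp(col_means[ids])
        next
      }
      filled <- stats::approx(pos[!mis], row[!mis], xout = pos,
                              method = "linear", rule = 2)$y
      block[i, mis] <- round_half_up_clamp(filled[mis])
    }
    items[, ids] <- block
  }
  cohort$items <- items
  cohort
}

#' Chained-equations multiple imputation baseline
#'
#' Stochastic-regression chained equations: missing cells are
#' initialized by [mean_impute()]; then, cycling through the items in
#' canonical order for `n_cycles` rounds, each item is regressed
#' (rank-tolerant least squares) on all other columns (CCPT indices and
#' the other items, current completions included) using the rows where
#' it was observed, and its missing cells are redrawn as the linear
#' prediction plus Gaussian residual noise, rounded and clamped to
#' 0--3.  Repeating with independent noise streams yields `m` plausible
#' completed tables; observed cells are identical across all of them.
#'
#' @param cohort a `cohort_table`.
#' @param m number of imputed tables (>= 2).
#' @param seed integer RNG seed.
#' @param n_cycles chained-equation cycles per table.
#' @return List of `m` completed `cohort_table`s.
#' @export
multiple_impute <- function(cohort, m = 5L, seed = 1L, n_cycles = 10L) {
  if (m < 2L) stop("m must be >= 2")
  n <- n_participants(cohort)
  items0 <- cohort$items
  miss_mask <- is.na(items0)
  base <- mean_impute(cohort)
  out <- vector("list", m)
  for (d in seq_len(m)) {
    set.seed(as.integer((as.numeric(seed) + 7717 * d) %%
                          .Machine$integer.max))
    items <- base$items
    for (cycle in seq_len(n_cycles)) {
      for (j in seq_len(ncol(items))) {
        mis <- miss_mask[, j]
        if (!any(mis)) next
        others <- cbind(1, cohort$ccpt, items[, -j, drop = FALSE])
        y <- items0[, j]
        obs <- !is.na(y)
        fit <- stats::lm.fit(others[obs, , drop = FALSE], y[obs])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        sigma <- sqrt(sum(fit$residuals^2) /
                        max(1L, fit$df.residual))
        if (!is.finite(sigma)) sigma <- 0
        pred <- drop(others[mis, , drop = FALSE] %*% beta) +
          rnorm(sum(mis), sd = sigma)
        items[mis, j] <- round_half_up_clamp(pred)
      }
    }
    ci <- cohort
    ci$items <- items
    out[[d]] <- ci
  }
  out
}
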
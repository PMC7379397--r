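#' Tier composition report
#'
#' Cross-tabulates the imputation-order tiers (TOP / INTERMEDIATE /
#' BOTTOM) against scale, informant, and symptom domain, and lists each
#' item's selection rank and held-out accuracy.  On clinical data the
#' TOP tier collects the most discriminating items (e.g.
#' teacher-reported oppositional behaviours), the BOTTOM tier the least.
#'
#' @param result an `imputation_result` from
#'   [run_iterative_imputation()].
#' @param registry the `item_registry`.
#' @return A `tier_report`: `tier_sizes`, `composition` (data frame of
#'   tier x scale x informant x domain counts), `items` (per-item rank,
#'   tier, accuracy).
#' @export
build_tier_report <- function(result, registry) {
  validate_registry(registry)
  ord <- result$imputation_order
  tiers <- result$tiers
  reg <- registry[match(ord, registry$item_id), , drop = FALSE]
  sel_acc <- vapply(result$records, function(r) {
    if (is.null(r$selected_accuracy)) NA_real_ else r$selected_accuracy
  }, numeric(1))
  items <- data.frame(rank = seq_along(ord),
                      item_id = ord,
                      scale = reg$scale,
                      informant = reg$informant,
                      domain = reg$domain,
                      tier = unname(tiers[ord]),
                      selected_accuracy = sel_acc,
                      stringsAsFactors = FALSE)
  comp <- as.data.frame(table(tier = items$tier, scale = items$scale,
                              informant = items$informant,
                              domain = items$domain),
                        stringsAsFactors = FALSE)
  names(comp)[names(comp) == "Freq"] <- "n_items"
  tier_sizes <- vapply(c("TOP", "INTERMEDIATE", "BOTTOM"),
                       function(t) sum(items$tier == t), integer(1))
  structure(list(tier_sizes = tier_sizes, composition = comp,
                 items = items),
            class = "tier_report")
}

#' @export
print.tier_report <- function(x, ...) {
  cat("Imputation-order tier report\n")
  cat(sprintf("  tiers: TOP %d / INTERMEDIATE %d / BOTTOM %d\n",
              x$tier_sizes[["TOP"]], x$tier_sizes[["INTERMEDIATE"]],
              x$tier_sizes[["BOTTOM"]]))
  top <- x$items[x$items$tier == "TOP", ]
  cat("  TOP-tier domains:\n")
  print(table(top$domain, top$informant))
  invisible(x)
}

#' Compare two imputation orders
#'
#' Restricted to the items shared by both orders, reports the Spearman
#' rank correlation of the selection ranks and the number of shared
#' items whose tier assignment differs.  Supports the ODD-exclusion
#' sensitivity analysis (rerunning the loop without oppositional items
#' and checking the shared ordering is preserved).
#'
#' @param order_a,order_b character vectors of item ids in selection
#'   order.
#' @return List with `spearman_rho`, `n_shared`, `n_tier_changes`.
#' @export
compare_orders <- function(order_a, order_b) {
  shared <- intersect(order_a, order_b)
  if (length(shared) == 0L) {
    stop("orders share no items")
  }
  ra <- match(shared, order_a)
  rb <- match(shared, order_b)
  rho <- if (length(shared) >= 2L) {
    stats::cor(ra, rb, method = "spearman")
  } else NA_real_
  # tiers recomputed on the restriction so both sides are comparable
  ta <- assign_tiers(order_a[sort(ra)])
  tb <- assign_tiers(order_b[sort(rb)])
  n_changes <- sum(ta[shared] != tb[shared])
  list(spearman_rho = rho, n_shared = length(shared),
       n_tier_changes = n_changes)
}

#' Run the full imputation workflow
#'
#' Orchestrates simulate (when the cohort source is synthetic) ->
#' impute -> evaluate -> report, writing all artifacts into
#' `output_dir`: the input cohort CSV, the completed cohort CSV, the
#' per-iteration records JSON (network methods only), the evaluation
#' JSON, the tier report CSV, a frozen copy of the resolved
#' configuration, and a log with per-iteration timings.
#'
#' @param config list with fields: either `cohort_path` or
#'   `cohort_config` + `missingness` (see [cohort_config()],
#'   [missingness_pattern()]); `registry` (default full 107-item
#'   registry); `n_items` optional registry subset size; `method` one
#'   of `"dnn"`, `"mean"`, `"interpolate"`, `"mice"`; `hyperparams`
#'   ([hyper_params()]); `exclude_odd`, `track_classification`
#'   logicals; `evaluate` logical (default TRUE); `output_dir`; `seed`.
#' @return Invisibly, a list with the in-memory results
#'   (`cohort`, `completed`, `result`, `report`, `evaluation`).
#' @export
run_pipeline <- function(config) {
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config$output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  method <- match.arg(config$method, c("dnn", "mean", "interpolate",
                                       "mice"))
  registry <- if (is.null(config$registry)) build_default_registry() else
    config$registry
  if (!is.null(config$n_items)) {
    registry <- registry_subset(registry, n_items = config$n_items)
  }

  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }

  sources <- c(!is.null(config$cohort_path), !is.null(config$cohort_config))
  if (sum(sources) != 1L) {
    stop("exactly one cohort source (cohort_path or cohort_config) required")
  }
  if (!is.null(config$cohort_path)) {
    cohort <- load_cohort(config$cohort_path, registry)
    log_line("loaded cohort from %s (%d participants)",
             config$cohort_path, n_participants(cohort))
  } else {
    cfg <- config$cohort_config
    cohort <- generate_cohort(registry, cfg)
    pat <- config$missingness
    if (!is.null(pat)) cohort <- apply_missingness(cohort, registry, pat)
    log_line("simulated cohort: %d participants, %d missing cells",
             n_participants(cohort), count_missing(cohort))
  }
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  hp <- if (is.null(config$hyperparams)) hyper_params(seed = seed) else
    config$hyperparams
  opts <- imputation_options(
    exclude_odd_items = isTRUE(config$exclude_odd),
    track_classification = isTRUE(config$track_classification)
  )

  result <- NULL
  report <- NULL
  if (method == "dnn") {
    result <- run_iterative_imputation(cohort, registry, hp, opts)
    completed <- result$completed_cohort
    rec_json <- lapply(result$records, function(r) {
      r$candidate_accuracies <- as.list(r$candidate_accuracies)
      r
    })
    jsonlite::write_json(rec_json, file.path(out_dir, "iterations.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report <- build_tier_report(result, registry)
    write.csv(report$items, file.path(out_dir, "imputation_order.csv"),
              row.names = FALSE)
    for (r in result$records) {
      log_line("iteration %d: selected %s acc=%.4f cells=%d %.2fs",
               r$iteration, r$selected_item,
               ifelse(is.na(r$selected_accuracy), -1,
                      r$selected_accuracy),
               r$n_cells_imputed, r$elapsed_seconds)
    }
  } else if (method == "mean") {
    completed <- mean_impute(cohort)
  } else if (method == "interpolate") {
    completed <- interpolate_impute(cohort, registry)
  } else {
    completed <- multiple_impute(cohort, m = 2L, seed = seed)[[1L]]
  }
  write_cohort(completed, file.path(out_dir, "completed.csv"))
  log_line("method %s: %d cells imputed, %d remaining missing",
           method, count_missing(cohort), count_missing(completed))

  evaluation <- NULL
  if (!identical(config$evaluate, FALSE)) {
    evaluation <- tryCatch(
      evaluate_imputation(cohort, completed, registry, seed = seed),
      error = function(e) {
        log_line("evaluation skipped: %s", conditionMessage(e))
        NULL
      })
    if (!is.null(evaluation)) {
      jsonlite::write_json(
        list(reference = list(
               fold_accuracies = evaluation$reference_run$fold_accuracies,
               mean = evaluation$reference_run$mean_accuracy,
               sd = evaluation$reference_run$sd_accuracy,
               formatted = sprintf("%.4f ± %.4f",
                                   evaluation$reference_run$mean_accuracy,
                                   evaluation$reference_run$sd_accuracy)),
             imputed = list(
               fold_accuracies = evaluation$imputed_run$fold_accuracies,
               mean = evaluation$imputed_run$mean_accuracy,
               sd = evaluation$imputed_run$sd_accuracy,
               formatted = sprintf("%.4f ± %.4f",
                                   evaluation$imputed_run$mean_accuracy,
                                   evaluation$imputed_run$sd_accuracy)),
             t_statistic = evaluation$t_statistic,
             p_value = evaluation$p_value),
        file.path(out_dir, "evaluation.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  frozen <- config
  frozen$registry <- NULL
  frozen$seed <- seed
  frozen$method <- method
  jsonlite::write_json(frozen, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(cohort = cohort, completed = completed, result = result,
                 report = report, evaluation = evaluation))
}
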
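#' @useDynLib scaleimpute, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd predict pt quantile
#' @importFrom utils read.csv write.csv
NULL

N_CCPT <- 12L
ccpt_colnames <- function() sprintf("ccpt_%02d", seq_len(N_CCPT))

#' Construct a cohort table
#'
#' A cohort table holds one row per participant: a binary diagnostic
#' label (CASE/CONTROL), 12 always-complete continuous attention-test
#' (CCPT) indices, and the ordinal item responses (0--3, `NA` = missing)
#' for the registry items.
#'
#' @param participant_id character vector of unique ids.
#' @param group character/factor of `"CASE"`/`"CONTROL"` labels.
#' @param ccpt numeric matrix, one row per participant, 12 columns; no
#'   missing values allowed.
#' @param items integer matrix, one row per participant, one column per
#'   registry item (named by item id); entries in `{0,1,2,3}` or `NA`.
#' @param registry the `item_registry` the item columns refer to.
#' @return A `cohort_table` object.
#' @export
cohort_table <- function(participant_id, group, ccpt, items, registry) {
  validate_registry(registry)
  ccpt <- as.matrix(ccpt)
  items <- as.matrix(items)
  storage.mode(items) <- "integer"
  colnames(ccpt) <- ccpt_colnames()
  cohort <- structure(
    list(participant_id = as.character(participant_id),
         group = factor(as.character(group), levels = c("CASE", "CONTROL")),
         ccpt = ccpt,
         items = items),
    class = "cohort_table"
  )
  validate_cohort(cohort, registry)
  cohort
}

#' Validate a cohort table against a registry
#'
#' @param cohort a `cohort_table`.
#' @param registry an `item_registry`.
#' @return The cohort, invisibly.
#' @export
validate_cohort <- function(cohort, registry) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- length(cohort$participant_id)
  if (anyDuplicated(cohort$participant_id)) {
    stop("participant ids must be unique")
  }
  if (any(is.na(cohort$group))) {
    stop("group labels must be CASE or CONTROL")
  }
  if (nrow(cohort$ccpt) != n || nrow(cohort$items) != n) {
    stop("ccpt/items row counts disagree with participant count")
  }
  if (ncol(cohort$ccpt) != N_CCPT) {
    stop("expected ", N_CCPT, " CCPT index columns, got ", ncol(cohort$ccpt))
  }
  if (anyNA(cohort$ccpt)) {
    stop("CCPT indices must be complete (no missing entries)")
  }
  unknown <- setdiff(colnames(cohort$items), registry$item_id)
  if (length(unknown) > 0L) {
    stop("item columns not in registry: ", paste(unknown, collapse = ", "))
  }
  vals <- cohort$items[!is.na(cohort$items)]
  if (length(vals) > 0L && (any(vals < 0L) || any(vals > 3L))) {
    stop("item responses must lie in {0,1,2,3}")
  }
  invisible(cohort)
}

#' @export
print.cohort_table <- function(x, ...) {
  n <- length(x$participant_id)
  cat(sprintf("<cohort_table: %d participants (%d CASE / %d CONTROL), %d items, %d missing cells>\n",
              n, sum(x$group == "CASE"), sum(x$group == "CONTROL"),
              ncol(x$items), count_missing(x)))
  invisible(x)
}

n_participants <- function(cohort) length(cohort$participant_id)

#' Count missing item cells
#'
#' @param cohort a `cohort_table`.
#' @return Integer count of missing (NA) item responses.
#' @export
count_missing <- function(cohort) {
  sum(is.na(cohort$items))
}

#' Load a cohort from CSV
#'
#' Expects a header row and columns `participant_id`, `group`,
#' `ccpt_01`..`ccpt_12`, then one column per registry item (named by item
#' id).  Empty cells or `NA` in item columns denote missing responses;
#' CCPT cells must be complete and item values must lie in `{0,1,2,3}`.
#'
#' @param path CSV file path.
#' @param registry the `item_registry` describing the item columns.
#' @return A `cohort_table`.
#' @export
load_cohort <- function(path, registry) {
  validate_registry(registry)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 na.strings = c("", "NA"))
  needed <- c("participant_id", "group", ccpt_colnames())
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  item_cols <- intersect(registry$item_id, names(df))
  if (length(item_cols) == 0L) {
    stop("cohort CSV contains no registry item columns")
  }
  bad_group <- !df$group %in% c("CASE", "CONTROL")
  if (any(bad_group)) {
    stop("invalid group label in row ", which(bad_group)[1L])
  }
  ccpt_df <- df[, ccpt_colnames(), drop = FALSE]
  for (j in ccpt_colnames()) {
    if (is.character(ccpt_df[[j]])) stop("CCPT columns must be numeric")
    ccpt_df[[j]] <- as.numeric(ccpt_df[[j]])  # zero-row columns read as logical
  }
  ccpt <- as.matrix(ccpt_df)
  if (anyNA(ccpt)) {
    bad <- which(is.na(ccpt), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing CCPT value at row %d, column %s",
                 bad[1L], ccpt_colnames()[bad[2L]]))
  }
  items <- matrix(NA_integer_, nrow(df), length(item_cols),
                  dimnames = list(NULL, item_cols))
  for (j in item_cols) {
    v <- df[[j]]
    if (is.character(v)) {
      suppressWarnings(v_num <- as.numeric(v))
      if (any(is.na(v_num) & !is.na(v))) {
        stop(sprintf("non-numeric item value at row %d, column %s",
                     which(is.na(v_num) & !is.na(v))[1L], j))
      }
      v <- v_num
    }
    bad <- !is.na(v) & (!v %in% c(0, 1, 2, 3))
    if (any(bad)) {
      stop(sprintf("item value out of range {0,1,2,3} at row %d, column %s",
                   which(bad)[1L], j))
    }
    items[, j] <- as.integer(v)
  }
  cohort_table(df$participant_id, df$group, ccpt, items, registry)
}

#' Write a cohort to CSV
#'
#' Missing item cells are serialized as `NA`; [load_cohort()] on the
#' result reproduces the cohort exactly, including the missingness mask.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(participant_id = cohort$participant_id,
                   group = as.character(cohort$group),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(cohort$ccpt, check.names = FALSE),
              as.data.frame(cohort$items, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Extract the complete-case reference subset
#'
#' The reference subset is the set of participants with every item
#' response observed across all scales; it serves as the comparison
#' standard for the effectiveness evaluation.
#'
#' @param cohort a `cohort_table`.
#' @return Character vector of participant ids (possibly empty).
#' @export
extract_reference_subset <- function(cohort) {
  complete <- rowSums(is.na(cohort$items)) == 0L
  cohort$participant_id[complete]
}

#' Subset a cohort by participant row index
#' @keywords internal
cohort_rows <- function(cohort, idx) {
  structure(
    list(participant_id = cohort$participant_id[idx],
         group = cohort$group[idx],
         ccpt = cohort$ccpt[idx, , drop = FALSE],
         items = cohort$items[idx, , drop = FALSE]),
    class = "cohort_table"
  )
}

#' Full numeric feature matrix (CCPT indices + item columns)
#' @keywords internal
cohort_feature_matrix <- function(cohort) {
  cbind(cohort$ccpt, cohort$items)
}
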
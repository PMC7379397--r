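#' Build the default 107-item registry
#'
#' Constructs the canonical registry of the four ADHD rating scales used
#' throughout the package: the parent and teacher SNAP-IV forms (26 items
#' each), the Conners' Parent Rating Scale - Revised: Short form (CPRS,
#' 27 items) and the Conners' Teacher Rating Scale - Revised: Short form
#' (CTRS, 28 items), 107 items in total.  Every item is scored on a
#' 4-point Likert scale (0--3).
#'
#' Canonical order is SNAP_P 1--26, SNAP_T 1--26, CPRS 1--27, CTRS 1--28;
#' this ordering is the global tie-break used by the imputation engine.
#'
#' Symptom domains follow the scale structure: SNAP positions 1--9 are
#' inattention, 10--18 hyperactivity/impulsivity, 19--26 oppositional
#' (the ODD items).  On the Conners' short forms the oppositional
#' positions are 2, 6, 11, 16, 20, 24 (CPRS) and 2, 6, 10, 15, 20 (CTRS);
#' the remaining Conners positions are assigned to the subscale families
#' (cognitive problems/inattention, hyperactivity/impulsivity, ADHD index)
#' by a fixed synthetic block assignment -- the published short forms do
#' not enumerate a per-item mapping, and no computation in this package
#' depends on these labels beyond reporting.
#'
#' @return An `item_registry`: a data frame with one row per item and
#'   columns `item_id`, `scale`, `informant`, `position`, `domain`,
#'   `is_odd_item`, in canonical order.
#' @examples
#' reg <- build_default_registry()
#' table(reg$scale)
#' @export
build_default_registry <- function() {
  snap_domain <- function(pos) {
    ifelse(pos <= 9, "inattention",
           ifelse(pos <= 18, "hyperactivity_impulsivity", "oppositional"))
  }
  snap_p <- data.frame(
    item_id = sprintf("snap_p_%02d", 1:26),
    scale = "SNAP_P", informant = "parent", position = 1:26,
    domain = snap_domain(1:26), is_odd_item = 1:26 >= 19,
    stringsAsFactors = FALSE
  )
  snap_t <- data.frame(
    item_id = sprintf("snap_t_%02d", 1:26),
    scale = "SNAP_T", informant = "teacher", position = 1:26,
    domain = snap_domain(1:26), is_odd_item = 1:26 >= 19,
    stringsAsFactors = FALSE
  )
  conners <- function(scale, informant, n_items, odd_pos) {
    pos <- seq_len(n_items)
    odd <- pos %in% odd_pos
    domain <- character(n_items)
    domain[odd] <- "oppositional"
    # non-ODD positions split into three consecutive subscale blocks
    non_odd <- pos[!odd]
    k <- length(non_odd)
    thirds <- rep(c("cognitive_inattention", "hyperactivity_impulsivity",
                    "adhd_index"),
                  c(ceiling(k / 3), ceiling(k / 3),
                    k - 2L * ceiling(k / 3)))
    domain[!odd] <- thirds
    data.frame(
      item_id = sprintf("%s_%02d", tolower(scale), pos),
      scale = scale, informant = informant, position = pos,
      domain = domain, is_odd_item = odd, stringsAsFactors = FALSE
    )
  }
  reg <- rbind(
    snap_p, snap_t,
    conners("CPRS", "parent", 27, c(2, 6, 11, 16, 20, 24)),
    conners("CTRS", "teacher", 28, c(2, 6, 10, 15, 20))
  )
  rownames(reg) <- NULL
  class(reg) <- c("item_registry", "data.frame")
  reg
}

#' Validate an item registry
#'
#' @param registry object to validate.
#' @return The registry, invisibly, after checking structure.
#' @keywords internal
validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry))
  needed <- c("item_id", "scale", "informant", "position", "domain",
              "is_odd_item")
  missing_cols <- setdiff(needed, names(registry))
  if (length(missing_cols) > 0L) {
    stop("registry lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(registry$item_id)) {
    stop("registry item_id values must be unique")
  }
  invisible(registry)
}

#' Restrict a registry to a subset of items
#'
#' Keeps canonical order.  Used for desk-scale runs and tests.
#'
#' @param registry an `item_registry`.
#' @param item_ids character vector of item ids to keep, or `NULL`.
#' @param n_items alternatively, keep the first `n_items` items in
#'   canonical order.
#' @return The restricted registry.
#' @export
registry_subset <- function(registry, item_ids = NULL, n_items = NULL) {
  validate_registry(registry)
  if (!is.null(item_ids)) {
    unknown <- setdiff(item_ids, registry$item_id)
    if (length(unknown) > 0L) {
      stop("unknown item ids: ", paste(unknown, collapse = ", "))
    }
    out <- registry[registry$item_id %in% item_ids, , drop = FALSE]
  } else if (!is.null(n_items)) {
    stopifnot(n_items >= 1L, n_items <= nrow(registry))
    out <- registry[seq_len(n_items), , drop = FALSE]
  } else {
    out <- registry
  }
  rownames(out) <- NULL
  class(out) <- c("item_registry", "data.frame")
  out
}

#' Write a registry to JSON
#'
#' @param registry an `item_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  jsonlite::write_json(as.data.frame(registry), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Read a registry from JSON
#'
#' @param path JSON file written by [write_registry()].
#' @return An `item_registry`.
#' @export
read_registry <- function(path) {
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- as.data.frame(reg, stringsAsFactors = FALSE)
  reg$position <- as.integer(reg$position)
  reg$is_odd_item <- as.logical(reg$is_odd_item)
  class(reg) <- c("item_registry", "data.frame")
  validate_registry(reg)
  reg
}
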
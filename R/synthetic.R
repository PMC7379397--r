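#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a two-group (CASE/CONTROL) clinical cohort with
#' latent-trait-driven ordinal item responses and correlated continuous
#' attention-test indices.  Each participant draws one unit-variance
#' latent trait per symptom domain, shifted in the CASE group by the
#' domain's standardized effect size.  Parent and teacher informants see
#' correlated views of each domain trait.  An item's latent response is
#' `loading * trait + noise`, cut at three fixed thresholds into the
#' 0--3 score; each CCPT index is a noisy weighted combination of the
#' domain traits.
#'
#' Defaults reflect a strongly separated clinical phenotype (standardized
#' group difference 1.5 on every symptom domain), moderate informant
#' agreement (0.7), item loadings spread over U(0.5, 1.5) so that some
#' items are highly trait-saturated and some near-noise, and cutpoints
#' (0.5, 1.5, 2.5) that put most control responses at 0 (symptom scales
#' are right-skewed in typically developing samples).
#'
#' @param n_case,n_control group sizes (each >= 2).
#' @param effect_sizes named numeric vector of standardized CASE-CONTROL
#'   latent mean differences per domain; a single unnamed value is
#'   recycled to all five domains.
#' @param item_loading_range length-2 numeric, uniform range for item
#'   loadings on their domain trait.
#' @param ordinal_cutpoints three strictly increasing thresholds mapping
#'   the latent response to scores 0--3.
#' @param ccpt_loading strength of the CCPT indices' dependence on the
#'   domain traits.
#' @param noise_sd standard deviation of item-level and index-level
#'   noise (> 0).
#' @param informant_cor correlation between parent and teacher views of
#'   the same domain trait, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_case = 200, n_control = 200,
                          effect_sizes = 1.5,
                          item_loading_range = c(0.5, 1.5),
                          ordinal_cutpoints = c(0.5, 1.5, 2.5),
                          ccpt_loading = 0.8,
                          noise_sd = 1,
                          informant_cor = 0.7,
                          seed = 1L) {
  domains <- c("inattention", "hyperactivity_impulsivity", "oppositional",
               "cognitive_inattention", "adhd_index")
  if (is.null(names(effect_sizes))) {
    stopifnot(length(effect_sizes) == 1L)
    effect_sizes <- stats::setNames(rep(effect_sizes, length(domains)),
                                    domains)
  } else {
    missing_d <- setdiff(domains, names(effect_sizes))
    effect_sizes[missing_d] <- 0
    effect_sizes <- effect_sizes[domains]
  }
  cfg <- list(n_case = as.integer(n_case),
              n_control = as.integer(n_control),
              effect_sizes = effect_sizes,
              item_loading_range = item_loading_range,
              ordinal_cutpoints = ordinal_cutpoints,
              ccpt_loading = ccpt_loading,
              noise_sd = noise_sd,
              informant_cor = informant_cor,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_case < 2L || cfg$n_control < 2L) {
    stop("n_case and n_control must both be >= 2")
  }
  if (length(cfg$ordinal_cutpoints) != 3L ||
      any(diff(cfg$ordinal_cutpoints) <= 0)) {
    stop("ordinal_cutpoints must be 3 strictly increasing values")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (length(cfg$item_loading_range) != 2L ||
      cfg$item_loading_range[1L] > cfg$item_loading_range[2L]) {
    stop("item_loading_range must be (low, high) with low <= high")
  }
  if (cfg$informant_cor < 0 || cfg$informant_cor > 1) {
    stop("informant_cor must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Generate a complete synthetic cohort
#'
#' Draws a complete (no missing cells) two-group cohort under the latent
#' trait model described in [cohort_config()].  Deterministic given
#' `config$seed`.
#'
#' @param registry an `item_registry` (items to simulate).
#' @param config a `cohort_config`.
#' @return A complete `cohort_table`.
#' @export
generate_cohort <- function(registry, config = cohort_config()) {
  validate_registry(registry)
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_case + config$n_control
  group <- c(rep("CASE", config$n_case), rep("CONTROL", config$n_control))
  domains <- names(config$effect_sizes)
  shift <- ifelse(group == "CASE", 1, 0)

  # common domain traits: unit variance, CASE mean = effect size
  common <- sapply(domains, function(d) {
    shift * config$effect_sizes[[d]] + rnorm(n)
  })
  # informant views: same mean shift, correlated with the common trait
  r <- config$informant_cor
  view <- function(d) {
    shift * config$effect_sizes[[d]] +
      sqrt(r) * (common[, d] - shift * config$effect_sizes[[d]]) +
      sqrt(1 - r) * rnorm(n)
  }
  views <- list(parent = sapply(domains, view),
                teacher = sapply(domains, view))

  loadings <- runif(nrow(registry), config$item_loading_range[1L],
                    config$item_loading_range[2L])
  items <- matrix(NA_integer_, n, nrow(registry),
                  dimnames = list(NULL, registry$item_id))
  for (j in seq_len(nrow(registry))) {
    trait <- views[[registry$informant[j]]][, registry$domain[j]]
    latent <- loadings[j] * trait + rnorm(n, sd = config$noise_sd)
    items[, j] <- as.integer(findInterval(latent, config$ordinal_cutpoints))
  }

  # each index loads on a random convex combination of the common traits
  ccpt <- matrix(0, n, N_CCPT)
  for (k in seq_len(N_CCPT)) {
    w <- runif(length(domains))
    w <- w / sum(w)
    ccpt[, k] <- config$ccpt_loading * drop(common %*% w) +
      rnorm(n, sd = config$noise_sd)
  }

  cohort_table(sprintf("P%04d", seq_len(n)), group, ccpt, items, registry)
}

#' Missingness pattern for a synthetic cohort
#'
#' Missingness has two layers, mirroring the dominant pattern of
#' multi-informant questionnaire studies: a participant may lack an
#' entire scale (the informant never returned that form), and surviving
#' cells may be missing individually.  Both layers are missing completely
#' at random by default; `mar_group_factor` multiplies the CASE group's
#' block probabilities (capped at 1) to stress-test a missing-at-random
#' departure.
#'
#' Default block probabilities follow the completion rates of a large
#' two-site ADHD cohort: parent SNAP 64.5% complete, teacher SNAP 47.1%,
#' parent Conners 81.6%, teacher Conners 59.8%.
#'
#' @param block_probs named numeric vector: probability a participant
#'   lacks each entire scale; a single unnamed value recycles to all
#'   scales.
#' @param item_mcar_rate probability that a cell surviving the block
#'   layer is individually missing.
#' @param mar_group_factor multiplier on CASE block probabilities
#'   (1 = MCAR).
#' @param seed integer RNG seed (independent of the cohort seed, so one
#'   cohort can receive several masks).
#' @return A `missingness_pattern` list.
#' @export
missingness_pattern <- function(block_probs = c(SNAP_P = 0.355,
                                                SNAP_T = 0.529,
                                                CPRS = 0.184,
                                                CTRS = 0.402),
                                item_mcar_rate = 0.01,
                                mar_group_factor = 1,
                                seed = 1L) {
  pat <- list(block_probs = block_probs,
              item_mcar_rate = item_mcar_rate,
              mar_group_factor = mar_group_factor,
              seed = as.integer(seed))
  validate_missingness_pattern(pat)
  pat
}

validate_missingness_pattern <- function(pat) {
  probs <- c(pat$block_probs, pat$item_mcar_rate)
  if (any(probs < 0) || any(probs > 1)) {
    stop("missingness probabilities must lie in [0, 1]")
  }
  if (pat$mar_group_factor < 0) stop("mar_group_factor must be >= 0")
  invisible(pat)
}

#' Apply a missingness pattern to a complete cohort
#'
#' Blanks whole scales per participant with the pattern's block
#' probabilities, then blanks surviving cells with the item-level rate.
#' CCPT indices are never blanked and observed values are never altered.
#' Deterministic given `pattern$seed`.
#'
#' @param cohort a `cohort_table` (normally complete).
#' @param registry the `item_registry` describing the item columns.
#' @param pattern a `missingness_pattern`.
#' @return The cohort with missing cells introduced.
#' @export
apply_missingness <- function(cohort, registry, pattern) {
  validate_registry(registry)
  validate_missingness_pattern(pattern)
  set.seed(pattern$seed)
  n <- n_participants(cohort)
  items <- cohort$items
  scales <- unique(registry$scale)
  bp <- pattern$block_probs
  if (is.null(names(bp))) {
    stopifnot(length(bp) == 1L)
    bp <- stats::setNames(rep(bp, length(scales)), scales)
  }
  for (sc in scales) {
    p <- if (sc %in% names(bp)) bp[[sc]] else 0
    p_row <- ifelse(cohort$group == "CASE",
                    pmin(1, p * pattern$mar_group_factor), p)
    drop_row <- runif(n) < p_row
    cols <- intersect(registry$item_id[registry$scale == sc],
                      colnames(items))
    items[drop_row, cols] <- NA_integer_
  }
  if (pattern$item_mcar_rate > 0) {
    surv <- !is.na(items)
    blank <- matrix(runif(length(items)) < pattern$item_mcar_rate,
                    nrow(items))
    items[surv & blank] <- NA_integer_
  }
  cohort$items <- items
  cohort
}
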
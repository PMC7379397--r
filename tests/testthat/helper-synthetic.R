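# Shared builders for planted-signal cohorts and fast hyper-parameters.

# Items with matched marginals: every item is an ordinal cut of a
# unit-variance latent, so held-out accuracy differences reflect the
# planted signal-to-noise (loading), not marginal skew.  Item j loads
# on CCPT index (j %% 12) + 1.
planted_cohort <- function(n, seed, lams, registry,
                           cuts = qnorm(c(0.25, 0.5, 0.75))) {
  stopifnot(length(lams) == nrow(registry))
  set.seed(seed)
  ccpt <- matrix(rnorm(n * 12), n, 12)
  items <- sapply(seq_along(lams), function(j) {
    lam <- lams[j]
    as.integer(findInterval((lam * ccpt[, j %% 12 + 1] + rnorm(n)) /
                              sqrt(lam^2 + 1), cuts))
  })
  colnames(items) <- registry$item_id
  cohort_table(sprintf("P%04d", seq_len(n)),
               rep(c("CASE", "CONTROL"), length.out = n),
               ccpt, items, registry)
}

# a small registry subset for fast loops
tiny_registry <- function(n_items = 6) {
  registry_subset(build_default_registry(), n_items = n_items)
}

# fast hyper-parameters for plumbing-level tests where per-item model
# quality is irrelevant
quick_hp <- function(seed = 1L) {
  hyper_params(patience_epochs = 2, dropout_rate = 0, batch_mode = "mini8",
               max_epochs = 15, n_starts = 1, seed = seed)
}

# random mask helper
random_mask <- function(cohort, registry, rate, seed) {
  apply_missingness(cohort, registry,
                    missingness_pattern(block_probs = 0,
                                        item_mcar_rate = rate,
                                        seed = seed))
}
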
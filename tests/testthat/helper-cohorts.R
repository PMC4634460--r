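# Shared, lazily computed fixtures. Everything is generated in code from
# fixed seeds; the cache only avoids recomputing within one test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# A small study-like cohort reused across test files.
small_cohort <- function() {
  cached("small_cohort", generate_cohort(cohort_config(n_subjects = 8, seed = 101)))
}

small_features <- function() {
  cached("small_features", extract_cohort_features(small_cohort()))
}

# Null screens: raw p-value matrices from cohorts with zero stress effect.
# Each replicate is an independent small cohort (12 subjects) screened with
# the unpaired Mann-Whitney over all 14 features x 3 comparisons.
null_screen_pvals <- function(n_rep = 120) {
  cached(sprintf("null_screens_%d", n_rep), {
    lapply(seq_len(n_rep), function(r) {
      cohort <- generate_cohort(cohort_config(
        n_subjects = 12, seed = 5000 + r, stages = heat_stress_stages(effect = 0),
        paired = FALSE  # exchangeable records: the iid null the tests assume
      ))
      scr <- screen_features(extract_cohort_features(cohort))
      m <- as.matrix(scr[, c("p_e1", "p_e2", "p_e3")])
      rownames(m) <- scr$feature
      m
    })
  })
}
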
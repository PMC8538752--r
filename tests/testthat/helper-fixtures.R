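# Shared fixtures, memoized so expensive cohorts are built once per run.
.fixtures <- new.env(parent = emptyenv())

# A reduced-resolution configuration for tests that exercise structure
# rather than the full 36,001-point study grid.
smallConfig <- function(...) {
  args <- utils::modifyList(
    list(n_preterm = 8, n_term = 6, grid = c(0.5, 9.5, 9001)),
    list(...))
  do.call(cohortConfig, args)
}

# The frozen default-fixture cohort: study-sized defaults, seed 1,
# aligned, binned and total-area normalized.
defaultBinnedFixture <- function() {
  if (is.null(.fixtures$default_binned)) {
    cfg <- cohortConfig(seed = 1)
    x <- suppressWarnings(alignSpectra(simulateCohort(cfg)))
    .fixtures$default_binned <- normalizeTotalArea(binSpectra(x))
  }
  .fixtures$default_binned
}

# Deterministic well-separated two-group feature matrix (not spectra)
# for classifier-level tests.
separableFeatures <- function(n_pos = 8, n_neg = 8, p = 4, shift = 6,
                              seed = 7) {
  set.seed(seed)
  y <- rep(c("preterm", "term"), c(n_pos, n_neg))
  x <- matrix(stats::rnorm((n_pos + n_neg) * p), n_pos + n_neg, p)
  x[y == "preterm", 1] <- x[y == "preterm", 1] + shift
  list(x = x, y = y)
}
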
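# Shared fixtures, built once per test run.

# small default cohort reused by several files
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(20, seed = 42)
    cache
  }
})

small_features <- function() {
  coh <- small_cohort()
  assemble_feature_table(coh$covariates, coh$concentrations)
}

# noise-free single-subject model parameters used by NCA oracles
base_params <- function() {
  list(dose = 2e7, cl = 16500, v = 30000, ka = 1.2, tlag = 3)
}

# independent brute-force trapezoid (index loop, no vectorization)
trapezoid_oracle <- function(t, y) {
  s <- 0
  for (i in 2:length(t)) s <- s + (t[i] - t[i - 1]) * (y[i] + y[i - 1]) / 2
  s
}
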
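# A default 200-participant cohort processed once and shared across test
# files (simulation is the expensive step; the measures and epoch summaries
# are reused by the cohort-property, reference-curve and acceptance tests).
.cohort_cache <- new.env(parent = emptyenv())

default_cohort_measures <- function() {
  if (is.null(.cohort_cache$measures)) {
    sessions <- simulate_cohort(cohort_config(), "pushball")
    .cohort_cache$measures <- extract_measures(sessions)
  }
  .cohort_cache$measures
}

default_cohort_epochs <- function() {
  if (is.null(.cohort_cache$epochs)) {
    .cohort_cache$epochs <- extract_epochs(default_cohort_measures())
  }
  .cohort_cache$epochs
}
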
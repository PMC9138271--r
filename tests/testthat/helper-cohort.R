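# Shared synthetic-cohort fixtures, built once per test run. The default
# cohort (42 + 44 subjects, balanced 10-minute recordings) takes on the order
# of two minutes to simulate and analyse, so it is memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Full default cohort with per-subject stage MI and the subject feature table.
default_cohort_analysis <- function() {
  memoise_fixture("default_cohort", function() {
    cohort <- generate_cohort(cohort_spec(seed = 20260901))
    smis <- lapply(cohort$subjects$id, function(id) {
      dec <- split_bands(antialias_and_detrend(cohort$recordings[[id]]))
      stage_mi(dec, cohort$hypnograms[[id]])
    })
    names(smis) <- cohort$subjects$id
    features <- subject_feature_table(smis, cohort$subjects)
    list(cohort = cohort, stage_mi = smis, features = features)
  })
}

# Window-level MI features for a subset of the default cohort's subjects
# (both groups represented), for the classification-harness checks.
cohort_window_features <- function(n_per_group = 3) {
  memoise_fixture("window_features", function() {
    ca <- default_cohort_analysis()
    cohort <- ca$cohort
    ids <- c(head(cohort$subjects$id[cohort$subjects$rdi <= 15], n_per_group),
             head(cohort$subjects$id[cohort$subjects$rdi > 15], n_per_group))
    do.call(rbind, lapply(ids, function(id) {
      dec <- split_bands(antialias_and_detrend(cohort$recordings[[id]]))
      window_feature_table(dec, cohort$hypnograms[[id]])
    }))
  })
}

# Uniform-stage coupling profile helper.
flat_profile <- function(pair, m) {
  coupling_profile(pair, stats::setNames(rep(m, 5), c("W", "N1", "N2", "N3", "REM")))
}

theta_gamma_bands <- function() {
  b <- default_bands()
  b[b$name %in% c("theta", "gamma"), ]
}
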
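# The replicate recovery batch shared by the recovery, calibration and
# range tests (expensive; computed once per test run).
acceptance_recovery <- function() {
  if (is.null(.fit_cache$recovery)) {
    .fit_cache$recovery <- recovery_study(n_reps = 20, seed = 101)
  }
  .fit_cache$recovery
}
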
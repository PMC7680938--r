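# The desk-scale experiment used by the acceptance tests: 20 replicates
# of the full scenario grid (source errors, rates 0-50%, both schemes) at
# reduced scale (6 chromosomes, 500 markers, 50 QTL, cohorts of 300),
# paired across scenarios by shared founders.  Memoised: it is by far the
# most expensive computation in the suite, so it runs once and several
# acceptance properties are checked against the same run.

get_toy_experiment <- function() {
  if (is.null(.fixture_env$toy_experiment)) {
    spec <- experiment_spec("toy", rates = c(0, 0.2), n_reps = 2)
    .fixture_env$toy_experiment <- run_experiment(spec, seed = 77)
  }
  .fixture_env$toy_experiment
}

acceptance_experiment <- function() {
  if (is.null(.fixture_env$acc_experiment)) {
    .fixture_env$acc_experiment <-
      run_experiment(experiment_spec("reduced"), seed = 42)
  }
  .fixture_env$acc_experiment
}
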
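# Small in-code fixtures shared across tests.

toy_count_matrix <- function(values, features = NULL, samples = NULL,
                             normalized = "raw") {
  features <- features %||% sprintf("f%d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  count_matrix(values, normalized = normalized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A deterministic small cohort for pipeline-level tests (shared so the
# ~15 s generation cost is paid once per test run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- simulation_params(n_samples = 20, n_tfs = 6, n_peaks = 120,
                                  n_genes = 80, features_per_chrom = 50,
                                  seed = 101)
      truth <- simulate_truth(params)
      cohort <- simulate_cohort(truth)
      cache <<- list(params = params, truth = truth, cohort = cohort)
    }
    cache
  }
})
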
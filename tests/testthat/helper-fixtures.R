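## Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

## A small but complete cohort reused across module tests.
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(
      sim_config(n_genes = 40, ase_sites = 80, n_clusters = 20, seed = 42))
  }
  .fixture_env$cohort
}

## A minimal paired design without simulation overhead.
toy_design <- function(n_ind = 10) {
  ind <- sprintf("i%02d", seq_len(n_ind))
  data.frame(sample_id = paste0(rep(ind, each = 2), "_", c(70, 80)),
             individual_id = rep(ind, each = 2),
             age = rep(c(70, 80), n_ind),
             age01 = rep(c(0, 1), n_ind),
             rin = rnorm(2 * n_ind, 8),
             rna_conc = rnorm(2 * n_ind, 60, 10),
             stringsAsFactors = FALSE)
}
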
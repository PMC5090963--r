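# Small fixture builders shared across test files.

toy_cpi <- function(n_drugs = 6, n_targets = 4, seed = 11) {
  set.seed(seed)
  cpi_matrix(matrix(round(stats::rnorm(n_drugs * n_targets, -7, 1), 6),
                    n_drugs, n_targets),
             sprintf("D%d", seq_len(n_drugs)),
             sprintf("T%d", seq_len(n_targets)))
}

toy_labels <- function(pairs, universe = NULL) {
  indication_labels(
    data.frame(drug_id = vapply(pairs, `[[`, character(1), 1),
               icd9_code = vapply(pairs, `[[`, character(1), 2),
               stringsAsFactors = FALSE),
    universe = universe)
}

# A tiny fitted two-tier model on planted synthetic data, reused by the
# ranking tests (built once per test run).
small_sim <- function(seed = 21) {
  generate_cpi_data(synthetic_config(
    n_drugs = 120, n_targets = 15, n_diseases = 8, causal_per_disease = 2,
    effect = 4, prevalence = 0.15, seed = seed))
}
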
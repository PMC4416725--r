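# shared fixtures, built in code

# two-SNP panel with simple weights (ln 2 and ln 3)
tiny_panel <- function(environment_or = NULL) {
  weight_panel(data.frame(
    snp_id = c("snpA", "snpB"),
    risk_allele = c("C", "G"),
    other_allele = c("T", "A"),
    odds_ratio = c(2, 3),
    is_hla = c(FALSE, TRUE)
  ), environment_or = environment_or)
}

# hand-built cohort from a dosage matrix and minimal phenotypes
tiny_cohort <- function(dosage, status, ...) {
  n <- nrow(dosage)
  as_cohort(
    tibble::tibble(sample_id = sprintf("s%02d", seq_len(n)),
                   status = status, ...),
    dosage
  )
}

# small paper-like simulation: same structure, reduced n for test speed
small_config <- function(seed, n_cases = 600, n_controls = 600, ...) {
  sim_config(n_cases = n_cases, n_controls = n_controls, seed = seed, ...)
}
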
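# Small in-code fixtures shared across test files.

# Random uncensored survival instance with one covariate and distinct event
# times, for partial-likelihood oracle checks.
random_cox_instance <- function(n = 6, seed) {
  set.seed(seed)
  repeat {
    x <- round(stats::rnorm(n), 2)
    time <- round(stats::rexp(n), 4) + seq_len(n) * 1e-3  # distinct
    event <- stats::rbinom(n, 1, 0.8)
    if (sum(event) >= 2 && stats::sd(x) > 0 && !anyDuplicated(time)) {
      return(list(time = time, event = event, x = x))
    }
  }
}

# Tiny raw (genes x patients) expression matrix for io tests.
toy_raw_expression <- function() {
  m <- rbind(
    low      = c(0, 0, 0, 10, 2),    # max <= 10 -> removed by max rule
    zeros    = c(11, 0, 0, 0, 0),    # zero proportion 0.8 -> removed by zero rule
    keep_a   = c(11, 1, 1, 1, 1),
    keep_b   = c(50, 20, 30, 12, 40))
  colnames(m) <- paste0("P", 1:5)
  m
}

write_clinical_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

# Default simulation used by several tests: strong planted interaction,
# randomized-trial style arms, moderate censoring.
signal_config <- function(seed, n_patients = 300, n_genes = 40,
                          n_sensitive_genes = max(1L, min(10L, n_genes %/% 3L)),
                          i_true = -1.5) {
  sim_config(n_patients = n_patients, n_genes = n_genes,
             n_sensitive_genes = n_sensitive_genes,
             lambda_true = 0, b_true = 0, i_true = i_true,
             sensitive_fraction = 0.3, treatment_prob = 0.5,
             censoring_rate = 0.3, include_covariates = FALSE, seed = seed)
}

null_config <- function(seed, n_patients = 120, n_genes = 40) {
  sim_config(n_patients = n_patients, n_genes = n_genes, n_sensitive_genes = 1,
             lambda_true = 0, b_true = 0, i_true = 0,
             sensitive_fraction = 0.3, treatment_prob = 0.5,
             censoring_rate = 0.3, include_covariates = FALSE, seed = seed)
}

new_cohort_for_test <- function(df) {
  df$patient_id <- as.character(df$patient_id)
  class(df) <- c("survival_cohort", "data.frame")
  df
}

new_test_cohort <- function(ids) {
  n <- length(ids)
  new_cohort_for_test(data.frame(patient_id = ids, time = seq_len(n) + 0.5,
                                 event = rep_len(c(1L, 1L, 0L), n),
                                 treatment = rep_len(c(0L, 1L), n),
                                 stringsAsFactors = FALSE))
}
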
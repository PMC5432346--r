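calls_from <- function(cohort, sensitive) {
  data.frame(patient_id = as.character(cohort$patient_id),
             nhr = ifelse(sensitive, 0.01, 1), sensitive = sensitive,
             stringsAsFactors = FALSE)
}

test_that("four subgroups partition the cohort and reuse the log-rank primitive", {
  sc <- simulate_cohort(signal_config(seed = 88, n_patients = 120, n_genes = 10))
  co <- sc$cohort
  calls <- calls_from(co, sc$truth$sensitive_true)
  out <- four_subgroup_analysis(co, calls)
  expect_equal(sum(out$sizes), nrow(co))
  expect_setequal(names(out$km), c("RS+RT", "RS-RT", "NRS+RT", "NRS-RT"))
  # the RS treatment contrast equals the log-rank computed directly
  idx <- sc$truth$sensitive_true
  direct <- logrank(co$time[idx], co$event[idx],
                    ifelse(co$treatment[idx] == 1, "RT", "NRT"))
  expect_equal(out$contrasts$rs_rt_vs_nrt$statistic, direct$statistic, tolerance = 1e-12)
})

test_that("with everyone called sensitive the RS contrast is the unconditional test", {
  sc <- simulate_cohort(signal_config(seed = 12, n_patients = 80, n_genes = 8))
  co <- sc$cohort
  out <- suppressWarnings(four_subgroup_analysis(co, calls_from(co, rep(TRUE, nrow(co)))))
  full <- logrank(co$time, co$event, ifelse(co$treatment == 1, "RT", "NRT"))
  expect_equal(out$contrasts$rs_rt_vs_nrt$statistic, full$statistic, tolerance = 1e-12)
  expect_null(out$contrasts$nrs_rt_vs_nrt)  # empty subgroup reported undefined
})

test_that("adjusted_cox with no covariates equals the unadjusted fit exactly", {
  sc <- simulate_cohort(signal_config(seed = 33, n_patients = 100, n_genes = 8))
  co <- sc$cohort
  calls <- calls_from(co, sc$truth$sensitive_true)
  adj <- adjusted_cox(co, calls, covariates = character())
  idx <- sc$truth$sensitive_true
  direct <- suppressWarnings(fit_cox(co$time[idx], co$event[idx],
                                     cbind(contrast = as.numeric(co$treatment[idx]))))
  expect_equal(adj$rt_within_rs$hr, unname(direct$hr), tolerance = 1e-10)
  expect_equal(adj$rt_within_rs$wald_p, unname(direct$wald_p), tolerance = 1e-10)
})

test_that("adjusted_cox recovers a harmful treatment effect in nonsensitive patients", {
  # planted: treatment hurts on average (lambda > 0) and helps only with
  # expression (i < 0); within NRS the treatment HR should exceed 1
  hrs <- vapply(1:5, function(seed) {
    sc <- simulate_cohort(sim_config(n_patients = 250, n_genes = 10,
                                     n_sensitive_genes = 4, lambda_true = 0.6,
                                     b_true = 0, i_true = -1.5,
                                     sensitive_fraction = 0.35, treatment_prob = 0.5,
                                     censoring_rate = 0.3, seed = seed))
    co <- sc$cohort
    calls <- calls_from(co, sc$truth$sensitive_true)
    adj <- adjusted_cox(co, calls, covariates = c("age", "gender"))
    adj$rt_within_nrs$hr
  }, numeric(1))
  expect_gt(mean(hrs > 1), 0.5)
})

test_that("adjusted_cox rejects a covariate collinear with the contrast", {
  sc <- simulate_cohort(signal_config(seed = 44, n_patients = 80, n_genes = 8))
  co <- sc$cohort
  co$rt_copy <- co$treatment
  calls <- calls_from(co, sc$truth$sensitive_true)
  expect_error(adjusted_cox(co, calls, covariates = "rt_copy"),
               "collinear", class = "cvasd_validation_error")
  expect_error(adjusted_cox(co, calls, covariates = "nope"),
               class = "cvasd_config_error")
})

test_that("strata_analysis on a single-level stratum reduces to the pooled analysis", {
  sc <- simulate_cohort(signal_config(seed = 66, n_patients = 90, n_genes = 8))
  co <- sc$cohort
  co$site <- "one_site"
  calls <- calls_from(co, sc$truth$sensitive_true)
  strat <- suppressWarnings(strata_analysis(co, calls, "site", min_size = 2))
  pooled <- suppressWarnings(four_subgroup_analysis(co, calls))
  expect_equal(length(strat), 1L)
  expect_equal(strat[[1]]$contrasts$rs_rt_vs_nrt$p, pooled$contrasts$rs_rt_vs_nrt$p)
})

test_that("small strata are pooled into 'other'", {
  sc <- simulate_cohort(signal_config(seed = 67, n_patients = 100, n_genes = 8))
  co <- sc$cohort
  set.seed(1)
  co$histology <- sample(c(rep("LMS", 60), rep("UPS", 28), rep("DLS", 6),
                           rep("MPNST", 3), rep("SS", 3)))
  calls <- calls_from(co, sc$truth$sensitive_true)
  strat <- suppressWarnings(strata_analysis(co, calls, "histology", min_size = 10))
  expect_setequal(names(strat), c("LMS", "UPS", "other"))
})

test_that("outcome-rate Fisher tests wire through to the exact test", {
  # craft calls/treatment/outcome so the RS treated-vs-untreated table is
  # [[3,1],[1,3]]
  co <- new_cohort_for_test(data.frame(
    patient_id = paste0("P", 1:8), time = 1:8 + 0.5, event = rep(1L, 8),
    treatment = c(1, 1, 1, 1, 0, 0, 0, 0)))
  calls <- calls_from(co, rep(TRUE, 8))
  outcome <- c(1, 1, 1, 0, 1, 0, 0, 0)
  res <- suppressWarnings(outcome_rate_tests(co, calls, outcome))
  expect_equal(res$p[res$contrast == "rs_rt_vs_nrt"], 34 / 70, tolerance = 1e-10)
  # constant outcome carries no information: p = 1
  res_const <- suppressWarnings(outcome_rate_tests(co, calls, rep(1, 8)))
  expect_equal(res_const$p[res_const$contrast == "rs_rt_vs_nrt"], 1)
  # empty group margin -> undefined
  calls_all_rt <- calls; co2 <- co; co2$treatment <- rep(1L, 8)
  w <- testthat::capture_warnings(res_na <- outcome_rate_tests(co2, calls_all_rt, outcome))
  expect_true(any(grepl("zero-margin", w)))
  expect_true(is.na(res_na$p[res_na$contrast == "rs_rt_vs_nrt"]))
})

test_that("missing outcomes are excluded pairwise", {
  co <- new_cohort_for_test(data.frame(
    patient_id = paste0("P", 1:10), time = 1:10 + 0.5, event = rep(1L, 10),
    treatment = rep(c(1, 0), 5)))
  calls <- calls_from(co, rep(TRUE, 10))
  outcome <- c(1, 0, NA, 1, 0, NA, 1, 0, 1, 0)
  res <- suppressWarnings(outcome_rate_tests(co, calls, outcome))
  expect_equal(res$n[res$contrast == "rs_rt_vs_nrt"], 8)
})

test_that("cluster concordance is perfect on separated blobs and invariant to relabeling", {
  set.seed(10)
  n <- 40
  blob <- rbind(matrix(stats::rnorm(n / 2 * 4, -3), n / 2, 4),
                matrix(stats::rnorm(n / 2 * 4, 3), n / 2, 4))
  rownames(blob) <- paste0("P", 1:n)
  sens <- c(rep(TRUE, n / 2), rep(FALSE, n / 2))
  calls <- data.frame(patient_id = rownames(blob), nhr = 1, sensitive = sens)
  cc <- cluster_concordance(blob, calls)
  expect_equal(cc$concordance, 1.0)
  # flipping the call labels leaves the concordance unchanged
  calls_flipped <- calls; calls_flipped$sensitive <- !sens
  expect_equal(cluster_concordance(blob, calls_flipped)$concordance, 1.0)
  # permuting patients leaves it unchanged
  perm <- sample(n)
  expect_equal(cluster_concordance(blob[perm, ], calls)$concordance, 1.0)
})

test_that("random calls give concordance near one half on average", {
  set.seed(20)
  vals <- replicate(30, {
    x <- matrix(stats::rnorm(30 * 3), 30, 3, dimnames = list(paste0("P", 1:30), NULL))
    calls <- data.frame(patient_id = rownames(x), nhr = 1,
                        sensitive = sample(rep(c(TRUE, FALSE), 15)))
    cluster_concordance(x, calls)$concordance
  })
  expect_lt(abs(mean(vals) - 0.5), 0.12)  # max-over-swap inflates slightly above 0.5
  expect_true(all(vals >= 0.5))
})

test_that("degenerate expression is rejected for clustering", {
  x <- matrix(1, 5, 3, dimnames = list(paste0("P", 1:5), NULL))
  calls <- data.frame(patient_id = rownames(x), nhr = 1, sensitive = rep(TRUE, 5))
  expect_error(cluster_concordance(x, calls), class = "cvasd_validation_error")
})
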
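test_that("make_folds produces balanced, reproducible plans", {
  co <- new_test_cohort(sprintf("P%02d", 1:20))
  p1 <- make_folds(co, K = 10, seed = 5)
  p2 <- make_folds(co, K = 10, seed = 5)
  expect_identical(p1$assignments, p2$assignments)
  expect_true(all(table(p1$assignments) == 2))

  big <- new_test_cohort(sprintf("P%03d", 1:253))
  sizes <- table(make_folds(big, K = 10, seed = 1)$assignments)
  expect_setequal(as.integer(sizes), c(25L, 26L))
  expect_equal(sum(sizes), 253)

  expect_error(make_folds(co, K = 25, seed = 1), class = "cvasd_config_error")
  expect_error(make_folds(co, K = 1, seed = 1), class = "cvasd_config_error")
})

test_that("stratified folds balance the treated fraction", {
  set.seed(9)
  df <- data.frame(patient_id = sprintf("P%03d", 1:100),
                   time = stats::rexp(100) + 0.1,
                   event = stats::rbinom(100, 1, 0.6),
                   treatment = rep(c(1, 0), c(30, 70)))
  co <- new_cohort_for_test(df)
  plan <- make_folds(co, K = 10, seed = 4, stratification = "by_treatment_event")
  per_fold_treated <- tapply(co$treatment[match(names(plan$assignments), co$patient_id)],
                             plan$assignments, sum)
  fold_sizes <- table(plan$assignments)
  # each fold's treated count is within one patient of its proportional share
  expect_lte(max(abs(per_fold_treated - as.numeric(fold_sizes) * mean(co$treatment))), 1)
})

test_that("fold plans that starve a training arm of events are rejected", {
  # only one treated event in the whole cohort: whenever its fold is held
  # out the training complement keeps it, but K = n makes some training set
  # lose the single untreated event
  df <- data.frame(patient_id = paste0("P", 1:6), time = 1:6 + 0.5,
                   event = c(1, 1, 0, 0, 0, 0), treatment = c(1, 0, 1, 0, 1, 0))
  co <- new_cohort_for_test(df)
  expect_error(make_folds(co, K = 6, seed = 2, max_retries = 3),
               class = "cvasd_validation_error")
})

test_that("no patient is scored by a model trained on their own fold", {
  sc <- simulate_cohort(signal_config(seed = 301, n_patients = 80, n_genes = 12))
  d <- as_merged_dataset(sc)
  res <- suppressWarnings(run_cv(d, K = 5, g = 4, R = 0.5, seed = 31))
  # structural audit part 1: each call's fold matches the plan
  expect_identical(unname(res$plan$assignments[res$calls$patient_id]), res$calls$fold)
  # part 2: rebuilding fold 1's model from the other folds only reproduces it
  co <- d$cohort
  train <- res$plan$assignments[as.character(co$patient_id)] != 1L
  refits <- lapply(colnames(d$expression), function(gid) {
    fit_single_gene_interaction(co$time[train], co$event[train], co$treatment[train],
                                d$expression[train, gid], gene_id = gid)
  })
  manual <- build_signature(refits, g = 4, threshold_R = 0.5)
  expect_equal(manual$gene_ids, res$per_fold_models[[1]]$gene_ids)
  expect_equal(manual$b, res$per_fold_models[[1]]$b, tolerance = 1e-12)
  expect_equal(manual$lambda_bar, res$per_fold_models[[1]]$lambda_bar, tolerance = 1e-12)
  # part 3: fold-1 calls equal the manual model's out-of-fold classification
  manual_calls <- classify(manual, d$expression[!train, , drop = FALSE])
  got <- res$calls[res$calls$fold == 1L, ]
  expect_equal(manual_calls$nhr[match(got$patient_id, manual_calls$patient_id)],
               got$nhr, tolerance = 1e-12)
})

test_that("identical inputs give byte-identical serialized calls", {
  sc <- simulate_cohort(signal_config(seed = 55, n_patients = 70, n_genes = 10))
  d <- as_merged_dataset(sc)
  r1 <- suppressWarnings(run_cv(d, K = 5, g = 3, R = 0.6, seed = 99))
  r2 <- suppressWarnings(run_cv(d, K = 5, g = 3, R = 0.6, seed = 99))
  f1 <- tempfile(); f2 <- tempfile()
  write_calls(r1, f1); write_calls(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(r1$calls, r2$calls)
})

test_that("with an effectively infinite threshold the validation test is the unconditional log-rank", {
  sc <- simulate_cohort(signal_config(seed = 404, n_patients = 90, n_genes = 8))
  d <- as_merged_dataset(sc)
  res <- run_cv(d, K = 5, g = 8, R = Inf, seed = 7)
  expect_true(all(res$calls$sensitive))
  full <- logrank(d$cohort$time, d$cohort$event,
                  ifelse(d$cohort$treatment == 1, "treated", "untreated"))
  expect_equal(res$validation_test$statistic, full$statistic, tolerance = 1e-12)
  expect_equal(res$validation_test$p, full$p, tolerance = 1e-12)
})

test_that("an empty predicted-sensitive subgroup is reported, not raised", {
  sc <- simulate_cohort(signal_config(seed = 21, n_patients = 60, n_genes = 8))
  d <- as_merged_dataset(sc)
  expect_warning(res <- run_cv(d, K = 5, g = 3, R = 1e-12, seed = 3),
                 "empty or single-arm")
  expect_null(res$validation_test)
  expect_false(res$effective)
})

test_that("every patient appears in exactly one call", {
  sc <- simulate_cohort(signal_config(seed = 61, n_patients = 75, n_genes = 10))
  d <- as_merged_dataset(sc)
  res <- suppressWarnings(run_cv(d, K = 5, g = 5, R = 0.5, seed = 13))
  expect_setequal(res$calls$patient_id, d$cohort$patient_id)
  expect_equal(anyDuplicated(res$calls$patient_id), 0L)
})

test_that("tuning returns a self-consistent profile and honors tie-breaks", {
  sc <- simulate_cohort(signal_config(seed = 111, n_patients = 120, n_genes = 15))
  d <- as_merged_dataset(sc)
  tn <- suppressWarnings(tune_signature(d, K = 5, g_grid = c(2, 5, 8),
                                        R_grid = c(0.2, 0.5, 1.0),
                                        method = "first_fold", seed = 17))
  expect_equal(nrow(tn$profile), 9)
  expect_equal(tn$selected$p, min(tn$profile$p, na.rm = TRUE))
  sel_row <- tn$profile[tn$profile$g == tn$selected$g & tn$profile$R == tn$selected$R, ]
  expect_equal(sel_row$p, tn$selected$p)
  # ties at the minimum go to smaller g then larger R
  cand <- tn$profile[!is.na(tn$profile$p) & tn$profile$p == tn$selected$p, ]
  expect_equal(tn$selected$g, min(cand$g))
  expect_equal(tn$selected$R, max(cand$R[cand$g == min(cand$g)]))

  single <- suppressWarnings(tune_signature(d, K = 5, g_grid = 5, R_grid = 0.5,
                                            method = "first_fold", seed = 17))
  expect_equal(single$selected$g, 5)
  expect_equal(single$selected$R, 0.5)

  expect_error(tune_signature(d, K = 5, g_grid = integer(), R_grid = 0.5, seed = 1),
               class = "cvasd_config_error")
})

test_that("nested-CV tuning agrees with running the inner CV by hand", {
  sc <- simulate_cohort(signal_config(seed = 212, n_patients = 100, n_genes = 10))
  d <- as_merged_dataset(sc)
  tn <- suppressWarnings(tune_signature(d, K = 5, g_grid = 4, R_grid = c(0.3, 0.8),
                                        method = "nested_cv", seed = 23))
  # reproduce one grid cell manually
  plan <- make_folds(d$cohort, 5, 23)
  train <- plan$assignments[as.character(d$cohort$patient_id)] != 1L
  inner <- structure(list(cohort = d$cohort[train, , drop = FALSE],
                          expression = d$expression[train, , drop = FALSE],
                          provenance = list()), class = "merged_dataset")
  inner_seed <- (23L %% 1000000L) * 2000L + 1L
  res <- suppressWarnings(run_cv(inner, K = 5, g = 4, R = 0.8, seed = inner_seed))
  cell <- tn$profile[tn$profile$g == 4 & tn$profile$R == 0.8, ]
  expect_equal(cell$p, res$validation_test$p, tolerance = 1e-12)
})

test_that("increasing the planted interaction does not reduce recovered sensitivity", {
  sens_of <- function(i_true, seed) {
    sc <- simulate_cohort(signal_config(seed = seed, n_patients = 150,
                                        n_genes = 12, n_sensitive_genes = 4,
                                        i_true = i_true))
    d <- as_merged_dataset(sc)
    res <- suppressWarnings(run_cv(d, K = 5, g = 4, R = 0.6, seed = seed + 17))
    m <- merge(res$calls, sc$truth, by = "patient_id")
    sum(m$sensitive & m$sensitive_true) / sum(m$sensitive_true)
  }
  seeds <- 1:6
  weak <- vapply(seeds, function(s) sens_of(-0.4, s), numeric(1))
  strong <- vapply(seeds, function(s) sens_of(-2.0, s), numeric(1))
  expect_gte(stats::median(strong), stats::median(weak))
})
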
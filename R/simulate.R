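#' Configure a synthetic cohort
#'
#' Defines the generating model for a synthetic survival cohort with a
#' planted subset of treatment-sensitive genes: per-gene standardized
#' expression, Bernoulli treatment assignment, event times from a Cox model
#' `h(t) = h0(t) exp(r*lambda + sum_S (x_j b_j + r x_j i_j))` with an
#' exponential or Weibull baseline, and independent censoring calibrated to
#' a target censoring fraction.
#'
#' The defaults emulate a TCGA soft-tissue-sarcoma-like cohort: 253
#' patients, 30% irradiated, 60% censored, median baseline survival around
#' 65 months, a 26-gene sensitive subset, and roughly 40% of patients truly
#' sensitive. The gene panel defaults to 500 (a realistic filtered panel for
#' simulation studies; full-transcriptome scale changes nothing
#' structurally).
#'
#' @param n_patients,n_genes,n_sensitive_genes Cohort dimensions; the first
#'   `n_sensitive_genes` genes are the planted subset S.
#' @param lambda_true Treatment main log-effect.
#' @param b_true,i_true Main and interaction log-effects for the sensitive
#'   genes (scalars recycled to length |S|); `i_true <= 0` encodes benefit
#'   with expression.
#' @param sensitive_fraction Target fraction of truly sensitive patients;
#'   used to set `r_threshold_true` as the corresponding quantile of the
#'   true scores when the threshold is not given explicitly.
#' @param r_threshold_true Optional explicit truth threshold on the true
#'   score `exp(lambda + sum_S x_j (b_j + i_j))`.
#' @param baseline `list(dist = "exponential", rate = )` or
#'   `list(dist = "weibull", shape = , scale = )`; times are in months.
#' @param censoring_rate Target expected fraction censored (0 disables
#'   censoring).
#' @param censoring_model `"exponential"` (independent exponential censoring
#'   times, rate solved to hit the target) or `"administrative"` (a common
#'   cutoff at the matching quantile of the event times).
#' @param treatment_prob P(treated).
#' @param expression_dist `"normal"` (standard normal per gene) or
#'   `"lognormal"` (RNAseq-like skew before per-gene standardization).
#' @param include_covariates Add clinical-style nuisance covariates (age,
#'   gender, histology) independent of everything, for adjusted-Cox tests.
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 253L, n_genes = 500L, n_sensitive_genes = 26L,
                       lambda_true = 0, b_true = 0, i_true = -1,
                       sensitive_fraction = 0.4, r_threshold_true = NULL,
                       baseline = list(dist = "exponential", rate = log(2) / 65),
                       censoring_rate = 0.6,
                       censoring_model = c("exponential", "administrative"),
                       treatment_prob = 0.3,
                       expression_dist = c("normal", "lognormal"),
                       include_covariates = TRUE,
                       seed = 1L) {
  censoring_model <- match.arg(censoring_model)
  expression_dist <- match.arg(expression_dist)
  if (n_sensitive_genes > n_genes) stop_config("n_sensitive_genes exceeds n_genes")
  if (treatment_prob <= 0 || treatment_prob >= 1) stop_config("treatment_prob must lie in (0, 1)")
  if (censoring_rate < 0 || censoring_rate >= 1) stop_config("censoring_rate must lie in [0, 1)")
  if (!baseline$dist %in% c("exponential", "weibull")) {
    stop_config("baseline$dist must be 'exponential' or 'weibull'")
  }
  if (baseline$dist == "exponential" && (is.null(baseline$rate) || baseline$rate <= 0)) {
    stop_config("exponential baseline needs a positive rate")
  }
  if (baseline$dist == "weibull" &&
      (is.null(baseline$shape) || is.null(baseline$scale) ||
       baseline$shape <= 0 || baseline$scale <= 0)) {
    stop_config("weibull baseline needs positive shape and scale")
  }
  if (!is.null(r_threshold_true) && r_threshold_true <= 0) {
    stop_config("r_threshold_true must be positive")
  }
  if (is.null(r_threshold_true) &&
      (sensitive_fraction <= 0 || sensitive_fraction >= 1)) {
    stop_config("sensitive_fraction must lie in (0, 1) when no explicit threshold is given")
  }
  S <- as.integer(n_sensitive_genes)
  structure(list(n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
                 n_sensitive_genes = S,
                 lambda_true = lambda_true,
                 b_true = rep_len(b_true, S), i_true = rep_len(i_true, S),
                 sensitive_fraction = sensitive_fraction,
                 r_threshold_true = r_threshold_true,
                 baseline = baseline, censoring_rate = censoring_rate,
                 censoring_model = censoring_model,
                 treatment_prob = treatment_prob,
                 expression_dist = expression_dist,
                 include_covariates = isTRUE(include_covariates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# inverse-transform draw of event times for the configured baseline:
# H0^{-1}(-log(U) / exp(eta))
draw_event_times <- function(baseline, eta) {
  u <- stats::runif(length(eta))
  h <- -log(u) / exp(eta)
  if (baseline$dist == "exponential") h / baseline$rate
  else baseline$scale * h^(1 / baseline$shape)
}

# exponential censoring rate c with mean realized censoring P(C < T | T)
# equal to the target: solve mean(1 - exp(-c * T)) = target
solve_censoring_rate <- function(event_times, target) {
  f <- function(logc) mean(1 - exp(-exp(logc) * event_times)) - target
  lo <- log(1e-8 / stats::median(event_times))
  hi <- log(1e8 / stats::median(event_times))
  if (f(lo) > 0 || f(hi) < 0) {
    stop_numeric(sprintf("censoring target %.3f unattainable; achievable range (%.4f, %.4f)",
                         target, max(0, f(lo) + target), f(hi) + target))
  }
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Simulate a synthetic cohort with planted sensitive genes
#'
#' Draws expression, treatment, event and censoring times under the
#' configured Cox model and returns a dataset ready for [run_cv()] together
#' with the generating truth: each patient's true score
#' `exp(lambda + sum_S x_j (b_j + i_j))` (the nHR evaluated at the true
#' coefficients and `r = 1`) and the truth label `true score <
#' r_threshold_true`, plus the identity of the planted genes. Identical
#' configurations produce identical cohorts.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_cohort`: fields `cohort`
#'   (`survival_cohort`), `expression` (patients x genes, standardized),
#'   `truth` (data frame `patient_id`, `true_score`, `sensitive_true`),
#'   `gene_truth` (data frame `gene_id`, `sensitive`, `b_true`, `i_true`),
#'   `config`. Use [as_merged_dataset()] to feed the analysis pipeline.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  p <- config$n_genes
  S <- config$n_sensitive_genes
  gene_ids <- sprintf("g%04d", seq_len(p))
  patient_ids <- sprintf("P%04d", seq_len(n))

  x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(patient_ids, gene_ids))
  if (config$expression_dist == "lognormal") x <- exp(x)
  x <- scale(x, center = TRUE, scale = apply(x, 2L, stats::sd))
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL

  r <- stats::rbinom(n, 1L, config$treatment_prob)
  xs <- x[, seq_len(S), drop = FALSE]
  eta <- r * config$lambda_true +
    as.vector(xs %*% config$b_true) + r * as.vector(xs %*% config$i_true)
  t_event <- draw_event_times(config$baseline, eta)

  if (config$censoring_rate == 0) {
    time <- t_event
    event <- rep(1L, n)
  } else if (config$censoring_model == "exponential") {
    crate <- solve_censoring_rate(t_event, config$censoring_rate)
    c_time <- stats::rexp(n, crate)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
  } else {
    cutoff <- stats::quantile(t_event, 1 - config$censoring_rate, names = FALSE)
    time <- pmin(t_event, cutoff)
    event <- as.integer(t_event <= cutoff)
  }
  time <- pmax(time, .Machine$double.eps)

  true_score <- exp(config$lambda_true + as.vector(xs %*% (config$b_true + config$i_true)))
  thr <- config$r_threshold_true %||%
    stats::quantile(true_score, config$sensitive_fraction, names = FALSE)

  cohort <- data.frame(patient_id = patient_ids, time = time, event = event,
                       treatment = r, stringsAsFactors = FALSE)
  if (config$include_covariates) {
    cohort$age <- round(stats::rnorm(n, 61, 12))
    cohort$gender <- sample(c("female", "male"), n, replace = TRUE)
    cohort$histology <- sample(c("LMS", "UPS", "other"), n, replace = TRUE,
                               prob = c(0.4, 0.2, 0.4))
  }
  structure(list(cohort = new_cohort(cohort, provenance = list(simulated = TRUE)),
                 expression = x,
                 truth = data.frame(patient_id = patient_ids,
                                    true_score = true_score,
                                    sensitive_true = true_score < thr,
                                    stringsAsFactors = FALSE),
                 gene_truth = data.frame(gene_id = gene_ids,
                                         sensitive = seq_len(p) <= S,
                                         b_true = c(config$b_true, rep(0, p - S)),
                                         i_true = c(config$i_true, rep(0, p - S)),
                                         stringsAsFactors = FALSE),
                 r_threshold_true = thr,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d patients x %d genes (|S| = %d planted), ",
                     "%d events, %d treated, %d truly sensitive\n"),
              nrow(x$cohort), ncol(x$expression), x$config$n_sensitive_genes,
              sum(x$cohort$event), sum(x$cohort$treatment),
              sum(x$truth$sensitive_true)))
  invisible(x)
}

#' Convert a synthetic cohort to the analysis-ready container
#' @param x A `synthetic_cohort`.
#' @return A `merged_dataset` (truth columns are not carried over).
#' @export
as_merged_dataset <- function(x) {
  stopifnot(inherits(x, "synthetic_cohort"))
  structure(list(cohort = x$cohort, expression = x$expression,
                 provenance = list(simulated = TRUE, seed = x$config$seed)),
            class = "merged_dataset")
}

#' Write a synthetic cohort as a file fixture
#'
#' Emits `clinical.tsv`, `expression.tsv` (genes x patients, mirroring how
#' real matrices ship), `truth.tsv` and `config.json` into `dir`; the files
#' round-trip through [read_clinical()] / [read_expression()].
#'
#' @param x A `synthetic_cohort`.
#' @param dir Output directory, created if needed.
#' @param orientation Orientation for `expression.tsv`.
#' @return Invisibly, the named vector of paths written.
#' @export
write_fixture <- function(x, dir, orientation = c("genes_by_patients", "patients_by_genes")) {
  stopifnot(inherits(x, "synthetic_cohort"))
  orientation <- match.arg(orientation)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(clinical = file.path(dir, "clinical.tsv"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  utils::write.table(x$cohort, paths["clinical"], sep = "\t", quote = FALSE, row.names = FALSE)
  mat <- if (orientation == "genes_by_patients") t(x$expression) else x$expression
  id_col <- if (orientation == "genes_by_patients") "gene_id" else "patient_id"
  df <- data.frame(rownames(mat), format(mat, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, paths["expression"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$truth, paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- x$config
  class(cfg) <- NULL
  jsonlite::write_json(c(cfg, list(r_threshold_true_used = x$r_threshold_true,
                                   expression_standardized = TRUE)),
                       paths["config"], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
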
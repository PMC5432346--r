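# Pipeline entry points: thin orchestration over the module functions, with
# a run manifest written next to every output directory so runs are
# reproducible and auditable. inst/scripts/cvasd-cli.R wraps these for shell
# use with distinct exit codes per failure class.

write_manifest <- function(dir, command, config, inputs = character()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(command = command,
                   config = config,
                   input_digests = digests,
                   package_version = as.character(utils::packageVersion("cvasd")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a cohort and write it as a fixture directory
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, the `synthetic_cohort`.
#' @export
cmd_simulate <- function(config, dir) {
  cohort <- simulate_cohort(config)
  write_fixture(cohort, dir)
  cfg <- config
  class(cfg) <- NULL
  write_manifest(dir, "simulate", cfg)
  invisible(cohort)
}

#' Prepare clinical + expression inputs into an analysis-ready directory
#'
#' Reads, filters, standardizes (unless the input is already standardized),
#' merges and imputes, then writes `cohort.tsv`, `expression.tsv`,
#' `provenance.json` and a manifest into `out_dir`.
#'
#' @param clinical Path to the clinical table.
#' @param expression Path to the expression matrix.
#' @param out_dir Output directory.
#' @param columns,sep Passed to [read_clinical()].
#' @param orientation Passed to [read_expression()].
#' @param standardized Set `TRUE` when the expression file already holds
#'   standardized values (simulator fixtures); skips filtering and
#'   standardization.
#' @param max_expr_cutoff,zero_prop_cutoff Passed to [filter_genes()].
#' @param impute `"median_mode"`, `"drop_incomplete"` or `"none"`.
#' @return Invisibly, the `merged_dataset`.
#' @export
cmd_prepare <- function(clinical, expression, out_dir,
                        columns = list(id = "patient_id", time = "time",
                                       event = "event", treatment = "treatment"),
                        sep = "\t",
                        orientation = "genes_by_patients",
                        standardized = FALSE,
                        max_expr_cutoff = 10, zero_prop_cutoff = 0.75,
                        impute = "median_mode") {
  cohort <- read_clinical(clinical, sep = sep, columns = columns)
  mat <- read_expression(expression, sep = sep, orientation = orientation,
                         allow_negative = standardized)
  if (standardized) {
    std <- t(mat)
  } else {
    std <- standardize_expression(filter_genes(mat, max_expr_cutoff, zero_prop_cutoff))
  }
  data <- merge_dataset(cohort, std)
  if (impute != "none") {
    data$cohort <- impute_covariates(data$cohort, strategy = impute)
  }
  write_merged_dataset(data, out_dir)
  write_manifest(out_dir, "prepare",
                 list(columns = columns, standardized = standardized,
                      max_expr_cutoff = max_expr_cutoff,
                      zero_prop_cutoff = zero_prop_cutoff, impute = impute,
                      provenance = data$provenance),
                 inputs = c(clinical, expression))
  invisible(data)
}

#' Run the cross-validated signature analysis on a prepared directory
#'
#' Optionally tunes (g, R), runs the K-fold cross-validated classification,
#' and applies the validation battery. Writes `calls.tsv`, per-fold
#' signature TSVs, `tuning_profile.tsv` (when tuned), `report.json` and a
#' manifest into `out_dir`.
#'
#' @param prepared_dir Directory written by [cmd_prepare()] (or
#'   [write_merged_dataset()]).
#' @param out_dir Output directory.
#' @param K Folds.
#' @param g,R Tuning parameters; if either is `NULL` they are selected by
#'   [tune_signature()] over `g_grid` x `R_grid`.
#' @param g_grid,R_grid Tuning grids (defaults: g in 1..50 plus 60, 80, 100,
#'   capped at the panel size; R log-spaced over \[0.005, 1\]).
#' @param tune_method `"first_fold"` or `"nested_cv"`.
#' @param seed Integer seed.
#' @param alpha Significance level for the validation test.
#' @param covariates Covariate names for the adjusted-Cox panels (empty:
#'   unadjusted).
#' @return Invisibly, a list with `cv` (`cv_result`), `tuning` (or `NULL`),
#'   and `report` (the validation battery summary).
#' @export
cmd_run <- function(prepared_dir, out_dir, K = 10L, g = NULL, R = NULL,
                    g_grid = NULL, R_grid = NULL,
                    tune_method = "first_fold", seed = 1L, alpha = 0.05,
                    covariates = character()) {
  if (!dir.exists(prepared_dir)) stop_config(sprintf("prepared directory not found: %s", prepared_dir))
  data <- read_merged_dataset(prepared_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tuning <- NULL
  if (is.null(g) || is.null(R)) {
    p_genes <- ncol(data$expression)
    if (is.null(g_grid)) g_grid <- unique(pmin(c(1:50, 60, 80, 100), p_genes))
    if (is.null(R_grid)) R_grid <- exp(seq(log(0.005), log(1), length.out = 30))
    tuning <- tune_signature(data, K = K, g_grid = g_grid, R_grid = R_grid,
                             method = tune_method, seed = seed)
    g <- tuning$selected$g
    R <- tuning$selected$R
    utils::write.table(tuning$profile, file.path(out_dir, "tuning_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cv <- run_cv(data, K = K, g = g, R = R, seed = seed, alpha = alpha)
  write_calls(cv, file.path(out_dir, "calls.tsv"))
  for (k in seq_along(cv$per_fold_models)) {
    write_signature(cv$per_fold_models[[k]],
                    file.path(out_dir, sprintf("signature_fold%02d.tsv", k)))
  }

  four <- four_subgroup_analysis(data$cohort, cv$calls)
  signature_genes <- unique(unlist(lapply(cv$per_fold_models, function(m) m$gene_ids)))
  conc <- tryCatch(
    cluster_concordance(data$expression[, intersect(signature_genes, colnames(data$expression)),
                                        drop = FALSE], cv$calls),
    cvasd_error = function(e) NULL)
  adj <- tryCatch(adjusted_cox(data$cohort, cv$calls, covariates),
                  cvasd_error = function(e) NULL)

  lr_or_na <- function(x) if (is.null(x)) NULL else list(chisq = x$statistic, df = x$df, p = x$p)
  report <- list(
    n_patients = nrow(data$cohort),
    K = K, g = g, R = R, seed = seed, alpha = alpha,
    tuning = if (!is.null(tuning)) tuning$selected,
    n_predicted_sensitive = sum(cv$calls$sensitive),
    validation_logrank = lr_or_na(cv$validation_test),
    effective = cv$effective,
    subgroup_sizes = as.list(four$sizes),
    contrasts = lapply(four$contrasts, lr_or_na),
    adjusted_effects = if (!is.null(adj)) {
      lapply(adj, function(a) list(contrast = a$contrast, hr = a$hr,
                                   ci95 = a$ci95, wald_p = a$wald_p,
                                   converged = a$converged))
    },
    cluster_concordance = if (!is.null(conc)) conc$concordance)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "run",
                 list(K = K, g = g, R = R, seed = seed, alpha = alpha,
                      tune_method = if (!is.null(tuning)) tune_method,
                      covariates = covariates),
                 inputs = file.path(prepared_dir, c("cohort.tsv", "expression.tsv")))
  invisible(list(cv = cv, tuning = tuning, report = report))
}
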
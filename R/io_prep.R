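#' Read a clinical table into a survival cohort
#'
#' Reads a delimited clinical file (one row per patient) and returns a
#' `survival_cohort` data frame with the canonical columns `patient_id`,
#' `time`, `event`, `treatment`, followed by any remaining covariate columns.
#' Rows with a missing treatment indicator are dropped and the drop is
#' recorded in the provenance attribute; missing values in other covariates
#' are kept as `NA` (see [impute_covariates()]).
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator, tab by default.
#' @param columns Named list mapping the canonical roles `id`, `time`,
#'   `event`, `treatment` to column names in the file.
#' @param na_strings Strings read as missing.
#'
#' @return A data frame of class `survival_cohort` with a `provenance`
#'   attribute (a list of row counts per filtering rule).
#' @export
read_clinical <- function(path, sep = "\t",
                          columns = list(id = "patient_id", time = "time",
                                         event = "event", treatment = "treatment"),
                          na_strings = c("", "NA")) {
  if (!file.exists(path)) stop_config(sprintf("clinical file not found: %s", path))
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           na.strings = na_strings, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  for (role in c("id", "time", "event", "treatment")) {
    nm <- columns[[role]]
    if (is.null(nm)) stop_config(sprintf("no column mapping given for role '%s'", role))
    if (!nm %in% names(raw)) {
      stop_config(sprintf("required column '%s' (role '%s') not found in %s", nm, role, path))
    }
  }
  df <- data.frame(patient_id = as.character(raw[[columns$id]]),
                   time = as.numeric(raw[[columns$time]]),
                   event = raw[[columns$event]],
                   treatment = raw[[columns$treatment]],
                   stringsAsFactors = FALSE)
  covar_cols <- setdiff(names(raw), unlist(columns[c("id", "time", "event", "treatment")]))
  for (nm in covar_cols) df[[nm]] <- raw[[nm]]

  n_in <- nrow(df)
  drop <- is.na(df$treatment)
  df <- df[!drop, , drop = FALSE]

  check_binary <- function(x, what) {
    bad <- which(!is.na(x) & !(x %in% c(0, 1)))
    if (length(bad)) {
      stop_validation(sprintf("%s must be 0/1; offending values %s at rows %s",
                              what, paste(unique(x[bad]), collapse = ", "),
                              paste(bad, collapse = ", ")))
    }
    as.integer(x)
  }
  df$event <- check_binary(df$event, "event")
  df$treatment <- check_binary(df$treatment, "treatment")
  if (anyNA(df$time) || anyNA(df$event)) {
    stop_validation("missing survival time or event indicator; only missing treatment rows are dropped")
  }
  if (any(df$time <= 0)) {
    stop_validation(sprintf("survival times must be positive; offending rows %s",
                            paste(which(df$time <= 0), collapse = ", ")))
  }
  if (anyDuplicated(df$patient_id)) {
    stop_validation(sprintf("duplicate patient ids: %s",
                            paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", ")))
  }
  rownames(df) <- NULL
  new_cohort(df, provenance = list(n_input = n_in,
                                   missing_treatment_dropped = sum(drop),
                                   n_retained = nrow(df)))
}

new_cohort <- function(df, provenance = list()) {
  class(df) <- c("survival_cohort", "data.frame")
  attr(df, "provenance") <- provenance
  df
}

#' Extract the provenance record of a cohort, matrix or merged dataset
#' @param x Object carrying a `provenance` attribute or field.
#' @return A list of filter/merge counts.
#' @export
provenance <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$provenance)) return(x$provenance)
  attr(x, "provenance") %||% list()
}

#' Read an expression matrix from delimited text
#'
#' The default orientation matches how TCGA-style matrices ship: first column
#' gene identifier, remaining columns one per patient.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator.
#' @param orientation `"genes_by_patients"` (default) or `"patients_by_genes"`.
#' @param allow_negative Set `TRUE` when reading already-standardized values
#'   (e.g. simulator fixtures); raw normalized RNAseq must be non-negative.
#' @return A numeric genes x patients matrix with gene row names and patient
#'   column names (the raw, pre-standardization orientation).
#' @export
read_expression <- function(path, sep = "\t",
                            orientation = c("genes_by_patients", "patients_by_genes"),
                            allow_negative = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_config(sprintf("expression file not found: %s", path))
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (orientation == "patients_by_genes") mat <- t(mat)
  validate_raw_expression(mat, allow_negative = allow_negative)
  mat
}

validate_raw_expression <- function(mat, allow_negative = FALSE) {
  if (anyDuplicated(rownames(mat))) stop_validation("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(mat))) stop_validation("duplicate patient ids in expression matrix")
  if (any(!is.finite(mat))) stop_validation("expression matrix contains non-finite values")
  if (!allow_negative && any(mat < 0)) {
    stop_validation("expression matrix contains negative values; normalized RNAseq expected")
  }
  invisible(mat)
}

#' Filter low-expression genes
#'
#' Applies, in order: (1) remove genes whose maximum expression across
#' patients is at or below `max_expr_cutoff` (these show essentially no
#' expression); (2) among the survivors, remove genes whose fraction of
#' exactly-zero values exceeds `zero_prop_cutoff`. Removal counts per rule
#' are recorded in the `provenance` attribute. Filters operate on raw
#' (pre-standardization) values.
#'
#' @param raw Genes x patients non-negative matrix (e.g. [read_expression()]).
#' @param max_expr_cutoff Genes with `max <= max_expr_cutoff` are removed.
#' @param zero_prop_cutoff Genes with zero-proportion strictly greater than
#'   this are removed.
#' @return Filtered genes x patients matrix with a `provenance` attribute.
#' @export
filter_genes <- function(raw, max_expr_cutoff = 10, zero_prop_cutoff = 0.75) {
  validate_raw_expression(raw)
  gene_max <- apply(raw, 1L, max)
  by_max <- gene_max <= max_expr_cutoff
  kept <- raw[!by_max, , drop = FALSE]
  zero_prop <- rowMeans(kept == 0)
  by_zero <- zero_prop > zero_prop_cutoff
  out <- kept[!by_zero, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop_validation("all genes removed by expression filters; review max_expr_cutoff / zero_prop_cutoff")
  }
  attr(out, "provenance") <- list(genes_in = nrow(raw),
                                  removed_by_max_rule = sum(by_max),
                                  removed_by_zero_rule_only = sum(by_zero),
                                  genes_out = nrow(out))
  out
}

#' Standardize expression per gene
#'
#' Transposes to patients x genes and scales each gene column to mean 0 and
#' sample standard deviation 1 (denominator n - 1).
#'
#' @param raw Genes x patients matrix (normally after [filter_genes()]).
#' @return Patients x genes standardized matrix.
#' @export
standardize_expression <- function(raw) {
  x <- t(raw)
  sds <- apply(x, 2L, stats::sd)
  zero_var <- !is.finite(sds) | sds == 0
  if (any(zero_var)) {
    stop_validation(sprintf("zero-variance gene(s) cannot be standardized: %s",
                            paste(colnames(x)[zero_var], collapse = ", ")))
  }
  out <- scale(x, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "provenance") <- provenance(raw)
  out
}

#' Merge a clinical cohort with a standardized expression matrix
#'
#' Intersects the two patient sets (cohort order wins), aligns both parts to
#' the same ordering, and records how many patients were present in only one
#' input.
#'
#' @param cohort A `survival_cohort`.
#' @param expression Patients x genes standardized matrix
#'   ([standardize_expression()]).
#' @return A list of class `merged_dataset` with fields `cohort`,
#'   `expression`, `provenance`.
#' @export
merge_dataset <- function(cohort, expression) {
  stopifnot(inherits(cohort, "survival_cohort"))
  if (anyDuplicated(rownames(expression))) stop_validation("duplicate patient ids in expression matrix")
  common <- intersect(cohort$patient_id, rownames(expression))
  if (length(common) < 2L) stop_validation("fewer than 2 patients shared between clinical and expression inputs")
  keep <- cohort$patient_id[cohort$patient_id %in% common]
  co <- cohort[match(keep, cohort$patient_id), , drop = FALSE]
  rownames(co) <- NULL
  ex <- expression[match(keep, rownames(expression)), , drop = FALSE]
  prov <- c(provenance(cohort),
            list(expression_filters = provenance(expression)),
            list(clinical_only_dropped = sum(!cohort$patient_id %in% common),
                 expression_only_dropped = sum(!rownames(expression) %in% common),
                 n_merged = length(keep)))
  structure(list(cohort = new_cohort(co, provenance = attr(cohort, "provenance")),
                 expression = ex, provenance = prov),
            class = "merged_dataset")
}

#' @export
print.merged_dataset <- function(x, ...) {
  cat(sprintf("merged_dataset: %d patients, %d genes, %d events, %d treated\n",
              nrow(x$cohort), ncol(x$expression),
              sum(x$cohort$event), sum(x$cohort$treatment)))
  invisible(x)
}

#' Impute missing covariate values
#'
#' A deliberately simple, deterministic imputation for the clinical
#' covariates that feed the adjusted-Cox validation analyses (the signature
#' itself never uses them): numeric covariates receive their median,
#' categorical covariates their mode (ties broken by lexicographic order).
#' Alternatively incomplete rows may be dropped.
#'
#' @param cohort A `survival_cohort`; `time`, `event`, `treatment` must be
#'   complete.
#' @param strategy `"median_mode"` (default) or `"drop_incomplete"`.
#' @param seed Unused by the deterministic strategies; accepted so configured
#'   pipelines can carry one seed everywhere.
#' @return The cohort with no missing covariates and an updated provenance.
#' @export
impute_covariates <- function(cohort, strategy = c("median_mode", "drop_incomplete"),
                              seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cohort, "survival_cohort"))
  core <- c("patient_id", "time", "event", "treatment")
  if (anyNA(cohort[core])) stop_validation("time/event/treatment must be complete before imputation")
  covars <- setdiff(names(cohort), core)
  prov <- attr(cohort, "provenance") %||% list()

  all_missing <- covars[vapply(covars, function(nm) all(is.na(cohort[[nm]])), logical(1))]
  if (length(all_missing)) {
    stop_validation(sprintf("covariate(s) entirely missing: %s", paste(all_missing, collapse = ", ")))
  }

  if (strategy == "drop_incomplete") {
    incomplete <- !stats::complete.cases(cohort[covars])
    out <- cohort[!incomplete, , drop = FALSE]
    rownames(out) <- NULL
    prov$imputation <- list(strategy = strategy, rows_dropped = sum(incomplete))
    return(new_cohort(out, provenance = prov))
  }

  filled <- list()
  out <- cohort
  for (nm in covars) {
    x <- out[[nm]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (is.numeric(x)) {
      fill <- stats::median(x[!miss])
    } else {
      tab <- table(as.character(x[!miss]))
      best <- names(tab)[tab == max(tab)]
      fill <- sort(best)[1L]
    }
    x[miss] <- fill
    out[[nm]] <- x
    filled[[nm]] <- sum(miss)
  }
  prov$imputation <- list(strategy = strategy, values_filled = filled)
  new_cohort(out, provenance = prov)
}

#' Write a merged dataset as plain-text artifacts
#'
#' Emits `cohort.tsv`, `expression.tsv` (patients x genes, standardized) and
#' `provenance.json` into `dir`.
#'
#' @param data A `merged_dataset`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_merged_dataset <- function(data, dir) {
  stopifnot(inherits(data, "merged_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.tsv"),
             expression = file.path(dir, "expression.tsv"),
             provenance = file.path(dir, "provenance.json"))
  utils::write.table(data$cohort, paths["cohort"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expr <- data.frame(patient_id = rownames(data$expression),
                     as.data.frame(data$expression), check.names = FALSE)
  utils::write.table(expr, paths["expression"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(data$provenance, paths["provenance"],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a merged dataset written by [write_merged_dataset()]
#' @param dir Directory containing `cohort.tsv` and `expression.tsv`.
#' @return A `merged_dataset`.
#' @export
read_merged_dataset <- function(dir) {
  cohort <- read_clinical(file.path(dir, "cohort.tsv"))
  expr_raw <- utils::read.table(file.path(dir, "expression.tsv"), sep = "\t",
                                header = TRUE, check.names = FALSE,
                                stringsAsFactors = FALSE)
  mat <- as.matrix(expr_raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(expr_raw[[1]])
  prov_path <- file.path(dir, "provenance.json")
  out <- merge_dataset(cohort, mat)
  if (file.exists(prov_path)) {
    out$provenance <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
  }
  out
}
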
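#' Rank single-gene interaction fits
#'
#' Orders fits by ascending interaction p-value; ties are broken by larger
#' absolute interaction effect, then lexicographic gene id, so the ranking is
#' deterministic across platforms. If every fit is flagged (all
#' `p_interaction == 1` with no converged fit) the order degenerates to gene
#' id and a warning is raised.
#'
#' @param fits List of `gene_interaction_fit` objects.
#' @return The same list, reordered.
#' @export
rank_genes <- function(fits) {
  if (!length(fits)) stop_validation("no gene fits to rank")
  p <- vapply(fits, function(f) f$p_interaction, numeric(1))
  a <- vapply(fits, function(f) abs(f$i_hat), numeric(1))
  id <- vapply(fits, function(f) as.character(f$gene_id), character(1))
  if (all(p >= 1) && !any(vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
    warning("all gene fits flagged (p_interaction = 1); ranking falls back to gene id order")
  }
  fits[order(p, -a, id, method = "radix")]
}

#' Build a gene signature from ranked fits
#'
#' Takes the top `g` genes after [rank_genes()] and assembles the scoring
#' model: per-gene main and interaction log-effects plus `lambda_bar`, the
#' treatment log-effect averaged over the g single-gene fits, and the nHR
#' classification threshold `R`.
#'
#' @param fits List of `gene_interaction_fit` objects (any order).
#' @param g Number of top-ranked genes to keep (`1 <= g <= length(fits)`).
#' @param threshold_R Positive nHR threshold below which a patient is called
#'   sensitive. `Inf` is allowed (everyone sensitive), useful as a degenerate
#'   limit.
#' @return An object of class `signature_model`: `fits` (top g, ranked),
#'   `gene_ids`, `lambda_bar`, `threshold_R`, `g`, plus coefficient vectors
#'   `b` and `i` indexed by gene id.
#' @export
build_signature <- function(fits, g, threshold_R) {
  if (g < 1 || g != round(g)) stop_config("g must be a positive integer")
  if (g > length(fits)) {
    stop_config(sprintf("g = %d exceeds the %d available gene fits", g, length(fits)))
  }
  if (!is.numeric(threshold_R) || threshold_R <= 0) stop_config("threshold_R must be positive")
  top <- rank_genes(fits)[seq_len(g)]
  ids <- vapply(top, function(f) as.character(f$gene_id), character(1))
  structure(list(fits = top, gene_ids = ids,
                 lambda_bar = mean(vapply(top, function(f) f$lambda_hat, numeric(1))),
                 b = stats::setNames(vapply(top, function(f) f$b_hat, numeric(1)), ids),
                 i = stats::setNames(vapply(top, function(f) f$i_hat, numeric(1)), ids),
                 threshold_R = threshold_R, g = as.integer(g)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: g = %d genes, lambda_bar = %.4f, threshold R = %g\n",
              x$g, x$lambda_bar, x$threshold_R))
  print(utils::head(as.data.frame(x), 10L))
  if (x$g > 10L) cat(sprintf("... and %d more genes\n", x$g - 10L))
  invisible(x)
}

#' @export
as.data.frame.signature_model <- function(x, ...) {
  data.frame(gene_id = x$gene_ids,
             lambda_hat = vapply(x$fits, function(f) f$lambda_hat, numeric(1)),
             b_hat = vapply(x$fits, function(f) f$b_hat, numeric(1)),
             i_hat = vapply(x$fits, function(f) f$i_hat, numeric(1)),
             se_i = vapply(x$fits, function(f) unname(f$se["i"]), numeric(1)),
             p_interaction = vapply(x$fits, function(f) f$p_interaction, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Nominal hazard ratio (nHR) of one or more patients
#'
#' Computes `exp(r*lambda_bar + sum_j (x_j*b_j + r*x_j*i_j))` over the
#' signature genes. By default the score is evaluated at `r = 1`: the nHR is
#' the patient's nominal hazard ratio *if treated*, which is what the
#' sensitivity classification is about; the actual-treatment variant is
#' available through `r = 0`.
#'
#' @param model A `signature_model`.
#' @param x Named expression vector (standardized, same scale as training),
#'   or a patients x genes matrix with gene column names.
#' @param r Treatment value the score is evaluated at (default 1).
#' @return Positive nHR value(s).
#' @export
compute_nhr <- function(model, x, r = 1) {
  stopifnot(inherits(model, "signature_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  missing <- setdiff(model$gene_ids, colnames(x))
  if (length(missing)) {
    stop_validation(sprintf("expression values missing for signature gene(s): %s",
                            paste(missing, collapse = ", ")))
  }
  xs <- x[, model$gene_ids, drop = FALSE]
  if (any(!is.finite(xs))) stop_validation("non-finite expression values for signature genes")
  lp <- r * model$lambda_bar + as.vector(xs %*% (model$b + r * model$i))
  out <- exp(lp)
  names(out) <- rownames(x)
  out
}

#' Classify patients as sensitive from their nHR
#'
#' A patient is called sensitive when their nHR is strictly lower than the
#' model's threshold R.
#'
#' @inheritParams compute_nhr
#' @return A data frame with columns `patient_id` (if row names are
#'   available), `nhr`, `sensitive`.
#' @export
classify <- function(model, x, r = 1) {
  nhr <- compute_nhr(model, x, r = r)
  data.frame(patient_id = names(nhr) %||% as.character(seq_along(nhr)),
             nhr = unname(nhr),
             sensitive = unname(nhr) < model$threshold_R,
             stringsAsFactors = FALSE)
}

#' Serialize a signature model to TSV
#'
#' Writes one row per signature gene (gene_id, lambda_hat, b_hat, i_hat,
#' se_i, p_interaction) under a `#`-prefixed header block carrying `g`,
#' `threshold_R` and `lambda_bar`, so a published signature can be shipped as
#' one flat file and reloaded with [read_signature()].
#'
#' @param model A `signature_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# g\t%d", model$g),
               sprintf("# threshold_R\t%.17g", model$threshold_R),
               sprintf("# lambda_bar\t%.17g", model$lambda_bar)), con)
  utils::write.table(format(as.data.frame(model), digits = 17, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature model written by [write_signature()]
#' @param path File path.
#' @return A `signature_model`.
#' @export
read_signature <- function(path) {
  header <- readLines(path, n = 3L)
  get <- function(key) {
    line <- grep(paste0("^# ", key, "\t"), header, value = TRUE)
    if (!length(line)) stop_validation(sprintf("signature file lacks '%s' header", key))
    as.numeric(sub(paste0("^# ", key, "\t"), "", line))
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(tab)), function(k) {
    structure(list(gene_id = as.character(tab$gene_id[k]),
                   lambda_hat = tab$lambda_hat[k],
                   b_hat = tab$b_hat[k], i_hat = tab$i_hat[k],
                   se = c(lambda = NA_real_, b = NA_real_, i = tab$se_i[k]),
                   p_interaction = tab$p_interaction[k], converged = TRUE),
              class = "gene_interaction_fit")
  })
  model <- build_signature(fits, g = as.integer(get("g")), threshold_R = get("threshold_R"))
  # restore the stored values verbatim (build_signature re-ranks, order is stable)
  model$lambda_bar <- get("lambda_bar")
  model
}
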
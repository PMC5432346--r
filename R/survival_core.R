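# Survival primitives used by the signature machinery. These wrap the
# 'survival' package (Cox partial-likelihood maximization, log-rank,
# product-limit estimation) and stats::fisher.test behind small, strictly
# validated interfaces with Wald inference exposed the way the downstream
# modules need it.

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox log partial likelihood for a fixed design matrix and
#' returns coefficients with Wald inference. Tied event times are handled by
#' the Efron approximation by default (Breslow available for cross-checks);
#' the two agree exactly when no ties are present.
#'
#' Degenerate designs are never dropped silently: a zero-variance column
#' yields a flagged (non-converged) fit with zero coefficients and Wald p = 1,
#' and a monotone likelihood (e.g. a covariate that perfectly separates the
#' event order) yields a non-convergence flag plus a warning.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators; at least one event required.
#' @param design Numeric matrix of covariates, one column per coefficient;
#'   column names become coefficient names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton iteration controls.
#' @return An object of class `cox_fit`: `coef`, `se`, `vcov`, `loglik`
#'   (maximized log partial likelihood), `wald_p`, `hr`, `hr_ci` (95%),
#'   `converged`, `n`, `n_events`, `ties`.
#' @export
fit_cox <- function(time, event, design, ties = c("efron", "breslow"),
                    max_iter = 25L, tol = 1e-9) {
  ties <- match.arg(ties)
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(ncol(design)))
  n <- length(time)
  stopifnot(length(event) == n, nrow(design) == n)
  if (any(!is.finite(time)) || any(time <= 0)) stop_validation("times must be positive and finite")
  if (!all(event %in% c(0, 1))) stop_validation("event must be 0/1")
  if (sum(event) == 0) stop_validation("no events; Cox model undefined")

  sds <- apply(design, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    warning(sprintf("degenerate (zero-variance) design column(s): %s; fit flagged",
                    paste(colnames(design)[sds == 0 | !is.finite(sds)], collapse = ", ")))
    return(degenerate_cox_fit(colnames(design), n, sum(event), ties))
  }

  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph.fit(x = design, y = survival::Surv(time, event),
                        strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(iter.max = max_iter, eps = tol),
                        weights = NULL, method = ties, rownames = seq_len(n)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })

  coef <- fit$coefficients
  vcov <- as.matrix(fit$var)
  dimnames(vcov) <- list(names(coef), names(coef))
  se <- sqrt(diag(vcov))
  monotone <- any(!is.finite(coef)) || any(abs(coef) > 15) || any(!is.finite(se)) || any(se > 100)
  converged <- !warned && !monotone
  if (monotone) {
    warning("monotone partial likelihood suspected (diverging coefficient); fit flagged as non-converged")
  } else if (warned) {
    warning("Cox fit did not converge within iteration limit; fit flagged")
  }
  z <- coef / se
  wald_p <- 2 * stats::pnorm(-abs(z))
  wald_p[!is.finite(wald_p)] <- 1
  structure(list(coef = coef, se = se, vcov = vcov,
                 loglik = fit$loglik[length(fit$loglik)],
                 wald_p = wald_p, hr = exp(coef),
                 hr_ci = cbind(lower = exp(coef - 1.96 * se),
                               upper = exp(coef + 1.96 * se)),
                 converged = converged, n = n, n_events = sum(event),
                 ties = ties),
            class = "cox_fit")
}

degenerate_cox_fit <- function(names, n, n_events, ties) {
  k <- length(names)
  coef <- stats::setNames(rep(0, k), names)
  se <- stats::setNames(rep(Inf, k), names)
  structure(list(coef = coef, se = se,
                 vcov = matrix(Inf, k, k, dimnames = list(names, names)),
                 loglik = NA_real_,
                 wald_p = stats::setNames(rep(1, k), names),
                 hr = exp(coef),
                 hr_ci = cbind(lower = rep(0, k), upper = rep(Inf, k)),
                 converged = FALSE, n = n, n_events = n_events, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties): n = %d, events = %d, loglik = %.4f%s\n",
              x$ties, x$n, x$n_events, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(coef = x$coef, se = x$se, hr = x$hr,
                   lower95 = x$hr_ci[, "lower"], upper95 = x$hr_ci[, "upper"],
                   p = x$wald_p))
  invisible(x)
}

#' Fit the single-gene treatment-interaction Cox model
#'
#' Fits `h(t) = h0(t) exp(r*lambda + x*b + r*x*i)` for one standardized gene
#' expression vector `x` and treatment indicator `r`, and returns the three
#' coefficient estimates with the two-sided Wald p-value of the interaction
#' term. Fits that do not converge (including degenerate interaction columns,
#' e.g. all treated patients sharing one expression value) are flagged and
#' assigned `p_interaction = 1` so they rank last.
#'
#' @param time,event Survival outcome.
#' @param treatment 0/1 treatment indicator; both arms need at least 1 event.
#' @param x Standardized expression vector for one gene.
#' @param gene_id Identifier carried through to ranking.
#' @return An object of class `gene_interaction_fit`: `gene_id`,
#'   `lambda_hat`, `b_hat`, `i_hat`, `se` (named triplet), `p_interaction`,
#'   `converged`.
#' @export
fit_single_gene_interaction <- function(time, event, treatment, x, gene_id = "gene") {
  if (!all(treatment %in% c(0, 1))) stop_validation("treatment must be 0/1")
  if (sum(event[treatment == 1]) < 1 || sum(event[treatment == 0]) < 1) {
    stop_validation("both treatment arms must contain at least one event")
  }
  design <- cbind(treatment = as.numeric(treatment), gene = as.numeric(x),
                  interaction = as.numeric(treatment) * as.numeric(x))
  fit <- tryCatch(
    withCallingHandlers(fit_cox(time, event, design),
                        warning = function(w) invokeRestart("muffleWarning")),
    cvasd_validation_error = function(e) stop(e),
    error = function(e) degenerate_cox_fit(colnames(design), length(time), sum(event), "efron"))
  structure(list(gene_id = gene_id,
                 lambda_hat = unname(fit$coef["treatment"]),
                 b_hat = unname(fit$coef["gene"]),
                 i_hat = unname(fit$coef["interaction"]),
                 se = c(lambda = unname(fit$se["treatment"]),
                        b = unname(fit$se["gene"]),
                        i = unname(fit$se["interaction"])),
                 p_interaction = if (fit$converged) unname(fit$wald_p["interaction"]) else 1,
                 converged = fit$converged),
            class = "gene_interaction_fit")
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank chi-squared test across two or more groups,
#' with per-group observed and expected event counts exposed.
#'
#' @param time,event Survival outcome.
#' @param group Group labels (two or more nonempty groups).
#' @return An object of class `logrank_result`: `statistic`, `df`, `p`,
#'   `observed`, `expected`, `n` per group.
#' @export
logrank <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L) stop_validation("log-rank test needs at least 2 nonempty groups")
  if (sum(event) == 0) stop_validation("log-rank test undefined with zero events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event, g = group))
  df <- nlevels(group) - 1L
  structure(list(statistic = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
                 observed = stats::setNames(as.numeric(sd$obs), levels(group)),
                 expected = stats::setNames(as.numeric(sd$exp), levels(group)),
                 n = stats::setNames(as.numeric(sd$n), levels(group))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.4f on %d df, p = %.4g\n", x$statistic, x$df, x$p))
  print(data.frame(n = x$n, observed = x$observed, expected = x$expected))
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with a Greenwood-based pointwise confidence band on
#' the log-log scale (which keeps the band inside \[0, 1\]).
#'
#' @param time,event Survival outcome.
#' @param conf Confidence level for the band.
#' @return An object of class `km_curve`: `times`, `surv`, `at_risk`,
#'   `events`, `lower`, `upper`, `conf`.
#' @export
km_curve <- function(time, event, conf = 0.95) {
  if (length(time) < 1L) stop_validation("empty input")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.int = conf, conf.type = "log-log")
  structure(list(times = sf$time, surv = sf$surv,
                 at_risk = sf$n.risk, events = sf$n.event,
                 lower = sf$lower, upper = sf$upper, conf = conf),
            class = "km_curve")
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing hypergeometric probabilities no
#' larger than that of the observed table.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_validation("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table))) {
    stop_validation("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_validation("all margins of the 2x2 table must be positive")
  }
  stats::fisher.test(table)$p.value
}
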
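# Downstream validation battery applied to cross-validated sensitivity
# calls: four-subgroup survival contrasts, covariate-adjusted Cox effects,
# strata analyses, outcome-rate Fisher tests, and clustering concordance.
# Everything reuses the survival primitives; no statistic is recomputed here.

subgroup_labels <- function(cohort, calls) {
  sens <- calls$sensitive[match(as.character(cohort$patient_id), calls$patient_id)]
  if (anyNA(sens)) stop_validation("sensitivity calls do not cover the cohort")
  paste0(ifelse(sens, "RS", "NRS"), ifelse(cohort$treatment == 1, "+RT", "-RT"))
}

safe_logrank <- function(time, event, group, contrast) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L || length(group) == 0L) {
    warning(sprintf("contrast '%s' undefined: fewer than two nonempty groups", contrast))
    return(NULL)
  }
  tryCatch(logrank(time, event, group),
           cvasd_validation_error = function(e) {
             warning(sprintf("contrast '%s' undefined: %s", contrast, conditionMessage(e)))
             NULL
           })
}

#' Four-subgroup survival analysis
#'
#' Partitions patients into predicted sensitive/nonsensitive x
#' treated/untreated (labels `RS+RT`, `RS-RT`, `NRS+RT`, `NRS-RT`), computes
#' a Kaplan-Meier curve per subgroup, and runs the four log-rank contrasts
#' of interest: treatment effect within RS, treatment effect within NRS, RS
#' vs NRS among treated, RS vs NRS among untreated. Undefined contrasts
#' (empty subgroup, no events) are reported as `NULL` with a warning.
#'
#' @param cohort A `survival_cohort`.
#' @param calls Per-patient calls (`patient_id`, `sensitive`), e.g.
#'   `cv_result$calls`.
#' @return A list: `subgroups` (per-patient label vector), `sizes`, `km`
#'   (named list of `km_curve`), `contrasts` (named list of
#'   `logrank_result` or `NULL`).
#' @export
four_subgroup_analysis <- function(cohort, calls) {
  lab <- subgroup_labels(cohort, calls)
  sens <- startsWith(lab, "RS")
  rt <- cohort$treatment == 1

  km <- lapply(stats::setNames(nm = c("RS+RT", "RS-RT", "NRS+RT", "NRS-RT")), function(g) {
    idx <- lab == g
    if (!any(idx)) return(NULL)
    km_curve(cohort$time[idx], cohort$event[idx])
  })

  contr <- list(
    rs_rt_vs_nrt = {
      idx <- sens
      safe_logrank(cohort$time[idx], cohort$event[idx],
                   ifelse(rt[idx], "RT", "NRT"), "RS: RT vs no-RT")
    },
    nrs_rt_vs_nrt = {
      idx <- !sens
      safe_logrank(cohort$time[idx], cohort$event[idx],
                   ifelse(rt[idx], "RT", "NRT"), "NRS: RT vs no-RT")
    },
    rt_rs_vs_nrs = {
      idx <- rt
      safe_logrank(cohort$time[idx], cohort$event[idx],
                   ifelse(sens[idx], "RS", "NRS"), "RT: RS vs NRS")
    },
    nrt_rs_vs_nrs = {
      idx <- !rt
      safe_logrank(cohort$time[idx], cohort$event[idx],
                   ifelse(sens[idx], "RS", "NRS"), "no-RT: RS vs NRS")
    })

  list(subgroups = lab, sizes = table(lab), km = km, contrasts = contr)
}

#' Covariate-adjusted Cox effects for the four panels
#'
#' Within predicted-sensitive and within nonsensitive patients, fits a Cox
#' model of treatment adjusted for the supplied covariates; within treated
#' and untreated patients, fits the sensitivity call adjusted likewise. With
#' an empty covariate list this reduces exactly to the unadjusted fit.
#' Categorical covariates are expanded to treatment-contrast dummies;
#' covariate columns that are constant within a panel are dropped from that
#' panel (the contrast itself never is). A covariate collinear with the
#' contrast raises an error; non-converged fits are returned flagged, never
#' dropped silently.
#'
#' @param cohort A `survival_cohort` with imputed covariates.
#' @param calls Per-patient calls (`patient_id`, `sensitive`).
#' @param covariates Character vector of covariate column names (possibly
#'   empty).
#' @return A list of four `adjusted_effect` objects (`contrast`, `hr`,
#'   `ci95`, `wald_p`, `coef`, `covariates`, `converged`), named
#'   `rt_within_rs`, `rt_within_nrs`, `rs_within_rt`, `rs_within_nrt`.
#' @export
adjusted_cox <- function(cohort, calls, covariates = character()) {
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov)) {
    stop_config(sprintf("covariate(s) not in cohort: %s", paste(missing_cov, collapse = ", ")))
  }
  sens <- calls$sensitive[match(as.character(cohort$patient_id), calls$patient_id)]
  if (anyNA(sens)) stop_validation("sensitivity calls do not cover the cohort")

  covar_matrix <- function(idx) {
    if (!length(covariates)) return(NULL)
    df <- cohort[idx, covariates, drop = FALSE]
    for (nm in covariates) if (!is.numeric(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    mm <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
    keep <- apply(mm, 2L, function(col) stats::sd(col) > 0)
    mm[, keep, drop = FALSE]
  }

  one_panel <- function(idx, contrast_vec, contrast_name) {
    x <- cbind(contrast = as.numeric(contrast_vec[idx]), covar_matrix(idx))
    if (qr(cbind(1, x))$rank < ncol(x) + 1L) {
      stop_validation(sprintf("collinear design in panel '%s' (a covariate duplicates the contrast?)",
                              contrast_name))
    }
    fit <- withCallingHandlers(fit_cox(cohort$time[idx], cohort$event[idx], x),
                               warning = function(w) invokeRestart("muffleWarning"))
    structure(list(contrast = contrast_name,
                   hr = unname(fit$hr["contrast"]),
                   ci95 = unname(fit$hr_ci["contrast", ]),
                   wald_p = unname(fit$wald_p["contrast"]),
                   coef = unname(fit$coef["contrast"]),
                   covariates = setdiff(colnames(x), "contrast"),
                   converged = fit$converged),
              class = "adjusted_effect")
  }

  rt <- cohort$treatment
  list(rt_within_rs = one_panel(which(sens), rt, "RT vs no-RT within RS"),
       rt_within_nrs = one_panel(which(!sens), rt, "RT vs no-RT within NRS"),
       rs_within_rt = one_panel(which(rt == 1), as.numeric(sens), "RS vs NRS within RT"),
       rs_within_nrt = one_panel(which(rt == 0), as.numeric(sens), "RS vs NRS within no-RT"))
}

#' @export
print.adjusted_effect <- function(x, ...) {
  cat(sprintf("%s: HR = %.3f (95%% CI %.3f-%.3f), Wald p = %.4g%s\n",
              x$contrast, x$hr, x$ci95[1], x$ci95[2], x$wald_p,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Four-subgroup analysis repeated within strata
#'
#' Repeats [four_subgroup_analysis()] within each level of a categorical
#' covariate (e.g. histologic type). Levels with fewer than `min_size`
#' patients are merged into an `"other"` level before testing.
#'
#' @param cohort A `survival_cohort`.
#' @param calls Per-patient calls.
#' @param stratum Name of a categorical column of `cohort`.
#' @param min_size Levels smaller than this are pooled into `"other"`.
#' @return Named list (one entry per retained level) of
#'   [four_subgroup_analysis()] results.
#' @export
strata_analysis <- function(cohort, calls, stratum, min_size = 20L) {
  if (!stratum %in% names(cohort)) stop_config(sprintf("stratum column '%s' not found", stratum))
  lev <- as.character(cohort[[stratum]])
  if (anyNA(lev)) stop_validation(sprintf("stratum '%s' contains missing values; impute first", stratum))
  sizes <- table(lev)
  small <- names(sizes)[sizes < min_size]
  if (length(small)) lev[lev %in% small] <- "other"
  out <- lapply(stats::setNames(nm = sort(unique(lev))), function(s) {
    idx <- lev == s
    four_subgroup_analysis(cohort[idx, , drop = FALSE],
                           calls[calls$patient_id %in% cohort$patient_id[idx], , drop = FALSE])
  })
  out
}

#' Outcome-rate comparisons by Fisher exact test
#'
#' For a binary per-patient outcome (e.g. new tumor event, progressive
#' disease; missing values excluded pairwise), builds the 2x2 table of
#' outcome against group for the same four contrasts as
#' [four_subgroup_analysis()] and tests each with [fisher_exact_2x2()].
#' Tables with a zero margin give `p = NA` with a warning.
#'
#' @param cohort A `survival_cohort`.
#' @param calls Per-patient calls.
#' @param outcome Binary vector aligned with `cohort` rows, or the name of a
#'   binary cohort column; `NA` allowed.
#' @return Data frame with columns `contrast`, `n`, `events_a`, `n_a`,
#'   `events_b`, `n_b`, `p`.
#' @export
outcome_rate_tests <- function(cohort, calls, outcome) {
  if (is.character(outcome) && length(outcome) == 1L) {
    if (!outcome %in% names(cohort)) stop_config(sprintf("outcome column '%s' not found", outcome))
    outcome <- cohort[[outcome]]
  }
  if (!all(outcome %in% c(0, 1, NA))) stop_validation("outcome must be binary (0/1, NA allowed)")
  sens <- calls$sensitive[match(as.character(cohort$patient_id), calls$patient_id)]
  rt <- cohort$treatment == 1

  contrasts <- list(
    rs_rt_vs_nrt = list(idx = sens, group = rt),
    nrs_rt_vs_nrt = list(idx = !sens, group = rt),
    rt_rs_vs_nrs = list(idx = rt, group = sens),
    nrt_rs_vs_nrs = list(idx = !rt, group = sens))

  rows <- lapply(names(contrasts), function(nm) {
    cc <- contrasts[[nm]]
    use <- cc$idx & !is.na(outcome)
    g <- cc$group[use]
    y <- outcome[use]
    tab <- matrix(c(sum(y[g] == 1), sum(y[g] == 0),
                    sum(y[!g] == 1), sum(y[!g] == 0)), nrow = 2, byrow = TRUE)
    p <- if (any(rowSums(tab) == 0)) {
      warning(sprintf("contrast '%s': zero-margin table (empty group), Fisher p undefined", nm))
      NA_real_
    } else if (any(colSums(tab) == 0)) {
      1  # constant outcome carries no evidence of a rate difference
    } else fisher_exact_2x2(tab)
    data.frame(contrast = nm, n = sum(use),
               events_a = tab[1, 1], n_a = sum(tab[1, ]),
               events_b = tab[2, 1], n_b = sum(tab[2, ]),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concordance between hierarchical clustering and sensitivity calls
#'
#' Clusters patients on their signature-gene expression (Euclidean distance,
#' complete linkage by default), cuts the dendrogram at two groups, and
#' reports the agreement with the sensitivity calls, maximized over the two
#' possible cluster-to-call label assignments (so the value is invariant to
#' label swapping and never below 0.5).
#'
#' @param expression Patients x genes matrix restricted to the signature
#'   genes (standardized).
#' @param calls Per-patient calls covering the matrix rows.
#' @param distance Distance measure for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return An object of class `concordance_result`: `cluster` (1/2 labels
#'   named by patient), `concordance`, `distance`, `linkage`.
#' @export
cluster_concordance <- function(expression, calls, distance = "euclidean",
                                linkage = "complete") {
  if (nrow(expression) < 2L || ncol(expression) < 1L) {
    stop_validation("need at least 2 patients and 1 signature gene")
  }
  d <- stats::dist(expression, method = distance)
  if (all(d == 0)) stop_validation("all patients have identical expression; clustering degenerate")
  cl <- stats::cutree(stats::hclust(d, method = linkage), k = 2L)
  sens <- calls$sensitive[match(rownames(expression), calls$patient_id)]
  if (anyNA(sens)) stop_validation("sensitivity calls do not cover the expression rows")
  agree <- mean((cl == 1L) == sens)
  structure(list(cluster = cl, concordance = max(agree, 1 - agree),
                 distance = distance, linkage = linkage),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("cluster_concordance: %.3f (%s distance, %s linkage; clusters %d/%d)\n",
              x$concordance, x$distance, x$linkage,
              sum(x$cluster == 1L), sum(x$cluster == 2L)))
  invisible(x)
}
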
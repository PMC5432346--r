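#' Plan K folds over a cohort
#'
#' Randomly splits patients into K folds whose sizes differ by at most one.
#' Optionally stratifies on the treatment x event cross so each fold carries
#' a balanced share of treated/untreated deaths. A plan is only accepted if
#' every training complement (the K-1 folds used to fit models when one fold
#' is held out) retains at least one event in each treatment arm; otherwise
#' the draw is repeated up to `max_retries` times before a hard error.
#'
#' @param cohort A `survival_cohort` (or any data frame with `patient_id`,
#'   `event`, `treatment`).
#' @param K Number of folds (`2 <= K <= n`).
#' @param seed Integer seed; the plan is reproducible given the seed.
#' @param stratification `"none"` or `"by_treatment_event"`.
#' @param max_retries Redraws allowed before giving up.
#' @return An object of class `fold_plan`: `K`, `assignments` (named integer
#'   vector, patient id -> fold), `seed`, `stratification`.
#' @export
make_folds <- function(cohort, K, seed, stratification = c("none", "by_treatment_event"),
                       max_retries = 20L) {
  stratification <- match.arg(stratification)
  n <- nrow(cohort)
  if (K < 2L) stop_config("K must be at least 2")
  if (K > n) stop_config(sprintf("K = %d exceeds the %d patients", K, n))
  ids <- as.character(cohort$patient_id)

  draw <- function() {
    if (stratification == "none") {
      fold <- sample(rep(seq_len(K), length.out = n))
    } else {
      stratum <- interaction(cohort$treatment, cohort$event, drop = TRUE)
      fold <- integer(n)
      offset <- sample.int(K, 1L) - 1L
      counter <- 0L
      for (s in levels(stratum)) {
        members <- sample(which(stratum == s))
        fold[members] <- ((counter + offset + seq_along(members) - 1L) %% K) + 1L
        counter <- counter + length(members)
      }
      fold
    }
  }
  valid <- function(fold) {
    for (k in seq_len(K)) {
      train <- fold != k
      if (sum(cohort$event[train & cohort$treatment == 1]) < 1 ||
          sum(cohort$event[train & cohort$treatment == 0]) < 1) return(FALSE)
    }
    TRUE
  }

  set.seed(seed)
  for (attempt in seq_len(max_retries + 1L)) {
    fold <- draw()
    if (valid(fold)) {
      return(structure(list(K = as.integer(K),
                            assignments = stats::setNames(fold, ids),
                            seed = as.integer(seed),
                            stratification = stratification),
                       class = "fold_plan"))
    }
  }
  stop_validation(sprintf(
    "no valid fold plan after %d draws: some training complement lacks events in a treatment arm",
    max_retries + 1L))
}

#' Run the cross-validated adaptive signature design
#'
#' For each fold k: fits the single-gene treatment-interaction Cox model for
#' every gene on the other K-1 folds, ranks genes by interaction p-value,
#' builds the top-`g` signature (with `lambda_bar` recomputed from that
#' fold's own top-g fits), scores the held-out patients' nHR at `r = 1`, and
#' classifies them against threshold `R`. Because every patient is scored
#' exactly once, by a model that never saw them, the final log-rank test of
#' treated vs untreated *within the predicted-sensitive patients* is a valid
#' test of whether the signature identifies patients who benefit.
#'
#' If the predicted-sensitive subgroup is empty or single-arm the validation
#' test is undefined; the result is reported as not effective with a warning
#' rather than an error (small thresholds legitimately produce empty calls
#' during tuning).
#'
#' @param data A `merged_dataset`.
#' @param K Folds (default 10).
#' @param g Signature size (top-ranked genes per fold).
#' @param R nHR classification threshold.
#' @param seed Integer seed for the fold plan.
#' @param alpha Significance level for the validation log-rank test.
#' @param stratification Passed to [make_folds()].
#' @param plan Optional pre-built `fold_plan` (overrides `K`, `seed`,
#'   `stratification`).
#' @return An object of class `cv_result`: `plan`, `calls` (data frame
#'   `patient_id`, `fold`, `nhr`, `sensitive`), `per_fold_models`,
#'   `validation_test` (a `logrank_result` or `NULL`), `alpha`, `effective`,
#'   and the `g`, `R` used.
#' @export
run_cv <- function(data, K = 10L, g, R, seed, alpha = 0.05,
                   stratification = "none", plan = NULL) {
  stopifnot(inherits(data, "merged_dataset"))
  cohort <- data$cohort
  expr <- data$expression
  if (is.null(plan)) plan <- make_folds(cohort, K, seed, stratification)
  fold <- plan$assignments[as.character(cohort$patient_id)]

  ranked <- fit_fold_models(cohort, expr, plan)
  scored <- score_folds(ranked, expr, plan, g = g, R = R)
  models <- scored$models
  calls <- scored$calls
  calls <- calls[match(as.character(cohort$patient_id), calls$patient_id),
                 c("patient_id", "fold", "nhr", "sensitive")]
  rownames(calls) <- NULL

  vt <- sensitive_subgroup_logrank(cohort, calls)
  structure(list(plan = plan, calls = calls, per_fold_models = models,
                 validation_test = vt, alpha = alpha,
                 effective = !is.null(vt) && vt$p < alpha,
                 g = as.integer(g), R = R),
            class = "cv_result")
}

fit_all_genes <- function(time, event, treatment, expr) {
  lapply(colnames(expr), function(gid) {
    fit_single_gene_interaction(time, event, treatment, expr[, gid], gene_id = gid)
  })
}

# For every fold, fit the single-gene interaction model for each gene on the
# training complement and return the ranked fits. The ranking does not
# depend on (g, R), so one pass serves an entire tuning grid.
fit_fold_models <- function(cohort, expr, plan) {
  fold <- plan$assignments[as.character(cohort$patient_id)]
  lapply(seq_len(plan$K), function(k) {
    train <- which(fold != k)
    rank_genes(fit_all_genes(cohort$time[train], cohort$event[train],
                             cohort$treatment[train], expr[train, , drop = FALSE]))
  })
}

# Given per-fold ranked fits, build the top-g signatures, score each fold's
# held-out patients at r = 1, and classify against R.
score_folds <- function(ranked, expr, plan, g, R) {
  fold <- plan$assignments[rownames(expr)]
  models <- lapply(ranked, build_signature, g = g, threshold_R = R)
  calls <- do.call(rbind, lapply(seq_len(plan$K), function(k) {
    cls <- classify(models[[k]], expr[which(fold == k), , drop = FALSE])
    cls$fold <- k
    cls
  }))
  rownames(calls) <- NULL
  list(models = models, calls = calls)
}

sensitive_subgroup_logrank <- function(cohort, calls) {
  sens <- calls$sensitive[match(as.character(cohort$patient_id), calls$patient_id)]
  sub <- cohort[sens, , drop = FALSE]
  if (nrow(sub) == 0L || length(unique(sub$treatment)) < 2L) {
    warning("predicted-sensitive subgroup empty or single-arm; validation log-rank undefined")
    return(NULL)
  }
  tryCatch(logrank(sub$time, sub$event, ifelse(sub$treatment == 1, "treated", "untreated")),
           cvasd_validation_error = function(e) {
             warning(sprintf("validation log-rank undefined: %s", conditionMessage(e)))
             NULL
           })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: K = %d, g = %d, R = %g; %d / %d patients predicted sensitive\n",
              x$plan$K, x$g, x$R, sum(x$calls$sensitive), nrow(x$calls)))
  if (!is.null(x$validation_test)) {
    cat(sprintf("validation log-rank (treated vs untreated within sensitive): chisq = %.3f, p = %.4g\n",
                x$validation_test$statistic, x$validation_test$p))
  } else {
    cat("validation log-rank undefined\n")
  }
  cat(sprintf("signature %s at alpha = %g\n",
              if (x$effective) "EFFECTIVE" else "not effective", x$alpha))
  invisible(x)
}

#' Tune the signature size g and threshold R
#'
#' Evaluates a (g, R) grid and returns the full p-value profile plus the
#' argmin. Two schemes are available:
#' \describe{
#'   \item{`first_fold`}{the computational shortcut: train once on folds
#'     2..K, then for every grid cell score fold 1, classify, and log-rank
#'     treated vs untreated within fold-1 predicted-sensitive patients.}
#'   \item{`nested_cv`}{for every grid cell, run a full inner K-fold
#'     cross-validation confined to the training folds 2..K and use its
#'     validation p-value.}
#' }
#' Grid cells whose subgroup test is undefined get `p = NA`. Ties at the
#' minimum are broken by smaller `g` (parsimony), then larger `R`.
#'
#' @param data A `merged_dataset`.
#' @param K Folds.
#' @param g_grid Integer vector of candidate signature sizes.
#' @param R_grid Positive vector of candidate thresholds.
#' @param method `"first_fold"` (default) or `"nested_cv"`.
#' @param seed Integer seed (fold plan and inner CVs derive from it).
#' @param inner_K Folds for the inner loop of `nested_cv` (default `K`,
#'   capped by the training-set size).
#' @return An object of class `tuning_result`: `profile` (data frame `g`,
#'   `R`, `p`), `selected` (list with `g`, `R`, `p`), `method`.
#' @export
tune_signature <- function(data, K = 10L, g_grid, R_grid,
                           method = c("first_fold", "nested_cv"),
                           seed, inner_K = K) {
  method <- match.arg(method)
  stopifnot(inherits(data, "merged_dataset"))
  if (!length(g_grid) || !length(R_grid)) stop_config("empty tuning grid")
  g_grid <- sort(unique(as.integer(g_grid)))
  R_grid <- sort(unique(as.numeric(R_grid)))
  if (any(g_grid < 1) || max(g_grid) > ncol(data$expression)) {
    stop_config("g_grid values must lie in [1, number of genes]")
  }
  if (any(R_grid <= 0)) stop_config("R_grid values must be positive")

  cohort <- data$cohort
  expr <- data$expression
  plan <- make_folds(cohort, K, seed)
  fold <- plan$assignments[as.character(cohort$patient_id)]
  grid <- expand.grid(g = g_grid, R = R_grid, KEEP.OUT.ATTRS = FALSE)

  subgroup_p <- function(sub_cohort, calls) {
    vt <- withCallingHandlers(
      sensitive_subgroup_logrank(sub_cohort, calls),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(vt)) NA_real_ else vt$p
  }

  train <- which(fold != 1L)
  if (method == "first_fold") {
    test <- which(fold == 1L)
    ranked <- rank_genes(fit_all_genes(cohort$time[train], cohort$event[train],
                                       cohort$treatment[train],
                                       expr[train, , drop = FALSE]))
    p <- numeric(nrow(grid))
    for (gg in g_grid) {
      model <- build_signature(ranked, g = gg, threshold_R = R_grid[1L])
      nhr <- compute_nhr(model, expr[test, , drop = FALSE])
      for (j in which(grid$g == gg)) {
        calls <- data.frame(patient_id = names(nhr), nhr = unname(nhr),
                            sensitive = unname(nhr) < grid$R[j])
        p[j] <- subgroup_p(cohort[test, , drop = FALSE], calls)
      }
    }
  } else {
    inner_cohort <- cohort[train, , drop = FALSE]
    inner_expr <- expr[train, , drop = FALSE]
    inner_K <- min(inner_K, nrow(inner_cohort))
    inner_seed <- (as.integer(seed) %% 1000000L) * 2000L + 1L
    inner_plan <- make_folds(inner_cohort, inner_K, inner_seed)
    inner_ranked <- fit_fold_models(inner_cohort, inner_expr, inner_plan)
    p <- numeric(nrow(grid))
    for (gg in g_grid) {
      scored <- score_folds(inner_ranked, inner_expr, inner_plan,
                            g = gg, R = R_grid[1L])
      nhr <- scored$calls
      for (j in which(grid$g == gg)) {
        calls <- data.frame(patient_id = nhr$patient_id, nhr = nhr$nhr,
                            sensitive = nhr$nhr < grid$R[j])
        p[j] <- subgroup_p(inner_cohort, calls)
      }
    }
  }

  grid$p <- p
  if (all(is.na(p))) {
    stop_validation("every (g, R) grid cell yields an undefined subgroup test; widen the grid")
  }
  # argmin with ties broken by smaller g, then larger R
  ord <- order(grid$p, grid$g, -grid$R, na.last = TRUE, method = "radix")
  best <- grid[ord[1L], ]
  structure(list(profile = grid,
                 selected = list(g = best$g, R = best$R, p = best$p),
                 method = method, K = as.integer(K), seed = as.integer(seed)),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("tuning_result (%s): %d grid cells; selected g = %d, R = %g (p = %.4g)\n",
              x$method, nrow(x$profile), x$selected$g, x$selected$R, x$selected$p))
  invisible(x)
}

#' Write per-patient calls of a cross-validation run as TSV
#' @param result A `cv_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calls <- function(result, path) {
  stopifnot(inherits(result, "cv_result"))
  calls <- result$calls
  calls$nhr <- sprintf("%.17g", calls$nhr)
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
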
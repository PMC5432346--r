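# cvasd — cross-validated adaptive signature design for survival outcomes

`cvasd` identifies treatment-sensitive patients (the motivating case:
radiosensitive sarcoma patients) from gene-expression-by-treatment
interactions under a Cox proportional-hazards model, and validates the
resulting classifier in the same cohort through K-fold cross-validation —
the adaptive signature design extended to censored survival endpoints.

## The method in brief

For standardized expression values $x_j$ and treatment indicator $r$, a
subset $S$ of sensitive genes is assumed to modify the treatment effect:

$$h(t \mid X) = h_0(t)\exp\Big(r\lambda + \sum_{j\in S} x_j b_j + r\sum_{j\in S} x_j i_j\Big).$$

Each gene is screened with the single-gene Cox model
$h_0(t)\exp(r\lambda + x_j b_j + r x_j i_j)$; genes are ranked by the Wald
p-value of the interaction $\hat i_j$, and the top $g$ form the signature.
A patient's **nominal hazard ratio** is

$$\mathrm{nHR} = \exp\Big(r\bar\lambda + \sum_{j=1}^{g}(x_j\hat b_j + r\,x_j\hat i_j)\Big),$$

evaluated at $r = 1$ (the hazard ratio *if treated*), with $\bar\lambda$
the mean of the $g$ treatment-effect estimates; patients with
$\mathrm{nHR} < R$ are called sensitive. In K-fold cross-validation every
patient is scored by models trained without their fold, and the validation
test is the log-rank comparison of treated vs untreated patients within
the pooled predicted-sensitive subgroup. The tuning pair $(g, R)$ is
selected by grid search (first-fold shortcut or nested inner CV). A
downstream battery — four-subgroup survival contrasts, covariate-adjusted
Cox effects, strata analyses, outcome-rate Fisher tests, and clustering
concordance — probes the calls from independent angles. A simulator
generates cohorts with planted sensitive genes and ground truth for all of
it.

See `vignettes/cvasd-methods.Rmd` for the model, conventions, tuning
schemes, and measured operating characteristics.

## Worked example

```r
library(cvasd)

cfg <- sim_config(n_patients = 300, n_genes = 40, n_sensitive_genes = 10,
                  lambda_true = 0, b_true = 0, i_true = -1.5,
                  sensitive_fraction = 0.3, treatment_prob = 0.5,
                  censoring_rate = 0.3, include_covariates = FALSE, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> synthetic_cohort: 300 patients x 40 genes (|S| = 10 planted), 207 events,
#>   144 treated, 90 truly sensitive

data <- as_merged_dataset(cohort)
tuned <- tune_signature(data, K = 10, g_grid = 10,
                        R_grid = exp(seq(log(0.005), log(1), length.out = 30)),
                        method = "nested_cv", seed = 7)
tuned
#> tuning_result (nested_cv): 30 grid cells; selected g = 10, R = 0.401117 (p = 2.629e-11)

result <- run_cv(data, K = 10, g = 10, R = tuned$selected$R, seed = 7)
result
#> cv_result: K = 10, g = 10, R = 0.401117; 85 / 300 patients predicted sensitive
#> validation log-rank (treated vs untreated within sensitive): chisq = 40.828, p = 1.662e-10
#> signature EFFECTIVE at alpha = 0.05

four <- four_subgroup_analysis(data$cohort, result$calls)
four$contrasts$rs_rt_vs_nrt
#> log-rank: chisq = 40.8285 on 1 df, p = 1.662e-10
#>      n observed expected
#> NRT 50       41 20.31721
#> RT  35        6 26.68279
```

Reading the output: 85 of 300 patients are called sensitive by
out-of-fold models; among them, treated patients die far less often than
expected under no treatment effect (6 observed vs 26.7 expected deaths),
so the signature is declared effective. Against the generator's truth
labels this run classifies with sensitivity 0.744 and specificity 0.914.

File-based pipelines use the same machinery: `cmd_simulate()` /
`cmd_prepare()` / `cmd_run()` read and write TSV/JSON artifacts with run
manifests (or `Rscript inst/scripts/cvasd-cli.R {simulate|prepare|run} ...`
from a shell). Preprocessing of real clinical + RNAseq inputs
(`read_clinical()`, `filter_genes()`, `standardize_expression()`,
`merge_dataset()`, `impute_covariates()`) records every filtering decision
in a provenance record.

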
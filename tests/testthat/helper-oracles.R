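# Independent oracles, written directly from the definitions. These never
# call the package's survival wrappers.

# Cox log partial likelihood for one covariate, distinct event times
# (Breslow and Efron coincide without ties).
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

oracle_cox_coef <- function(time, event, x, interval = c(-10, 10)) {
  stats::optimize(function(b) oracle_cox_loglik(b, time, event, x),
                  interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# Two-group log-rank by the textbook O/E/V pooled-risk-set computation.
oracle_logrank_2g <- function(time, event, group) {
  group <- as.character(group)
  g1 <- sort(unique(group))[1]
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(observed1 = O, expected1 = E, var = V, chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

# Product-limit estimator by hand.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (k in seq_along(ts)) {
    n_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  list(times = ts, surv = surv)
}

# Two-sided Fisher exact p by full hypergeometric enumeration: sum the
# probabilities of all tables (fixed margins) whose probability does not
# exceed the observed one (with the standard relative tolerance guarding
# against floating-point ties).
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ])   # row-1 margin
  n2 <- sum(tab[2, ])
  k <- sum(tab[, 1])   # column-1 margin
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
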
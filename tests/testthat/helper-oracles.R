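# Independent brute-force oracles, written symbol-by-symbol against the
# defining formulas. They deliberately share no code with the package
# implementation (no cumulative sums, no rowsum), so agreement is evidence,
# not tautology.

# Product-limit estimator, literal form: at each distinct death time,
# multiply by (1 - weighted deaths / weighted at-risk).
oracle_km <- function(time, event, weight = rep(1, length(time))) {
  dtimes <- sort(unique(time[event == 1]))
  surv <- numeric(length(dtimes))
  s <- 1
  for (j in seq_along(dtimes)) {
    tj <- dtimes[j]
    at_risk <- sum(weight[time >= tj])
    deaths <- sum(weight[time == tj & event == 1])
    s <- s * (1 - deaths / at_risk)
    surv[j] <- s
  }
  list(time = dtimes, surv = surv)
}

# Area under the KM step function on (0, L]:
# sum_i S(t_i) (t_{i+1} - t_i) + S(t_k)(L - t_k), with t_0 = 0, S(0) = 1.
oracle_rmst <- function(okm, L) {
  tt <- okm$time; ss <- okm$surv
  total <- 0
  prev_t <- 0; prev_s <- 1
  for (j in seq_along(tt)) {
    total <- total + prev_s * (tt[j] - prev_t)
    prev_t <- tt[j]; prev_s <- ss[j]
  }
  total + prev_s * (L - prev_t)
}

# Follow-up QALY sum: sum_j Qhat(t_j)(S(t_{j-1}) - S(t_j)) + Qhat(L) S(t_l),
# Qhat(t_j) the weighted mean of utility * t_j among deaths at t_j, and
# Qhat(L) = L times the weighted mean utility among survivors (censored).
oracle_followup_qaly <- function(time, event, weight, utility, L) {
  okm <- oracle_km(time, event, weight)
  total <- 0
  prev_s <- 1
  for (j in seq_along(okm$time)) {
    tj <- okm$time[j]
    sel <- time == tj & event == 1
    qj <- sum(weight[sel] * utility[sel] * tj) / sum(weight[sel])
    total <- total + qj * (prev_s - okm$surv[j])
    prev_s <- okm$surv[j]
  }
  s_last <- if (length(okm$surv)) okm$surv[length(okm$surv)] else 1
  if (s_last > 0) {
    alive <- event == 0
    qL <- L * sum(weight[alive] * utility[alive]) / sum(weight[alive])
    total <- total + qL * s_last
  }
  total
}

# Mean of S(t) = exp(-(t/lambda)^beta) by adaptive quadrature.
quadrature_weibull_mean <- function(lambda, beta) {
  stats::integrate(function(t) exp(-(t / lambda)^beta), 0, Inf,
                   rel.tol = 1e-10)$value
}

# Dense grid search of the right-censored weighted Weibull log-likelihood.
grid_weibull_mle <- function(time, event, weight,
                             lambda_grid, beta_grid) {
  ll <- function(lambda, beta) {
    h <- event * log((beta / lambda) * (time / lambda)^(beta - 1))
    h[event == 0] <- 0
    sum(weight * (h - (time / lambda)^beta))
  }
  best <- c(NA, NA); best_ll <- -Inf
  for (lam in lambda_grid) for (bet in beta_grid) {
    v <- ll(lam, bet)
    if (v > best_ll) { best_ll <- v; best <- c(lam, bet) }
  }
  list(scale = best[1], shape = best[2], loglik = best_ll)
}

# All event-indicator patterns for n records (exhaustive fixture enumeration).
event_patterns <- function(n) {
  as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
}

# Single-category cohort from the default generator.
one_category_cohort <- function(category, n, seed, ...) {
  prev <- setNames(as.numeric(phq9_levels_collapsed == category),
                   phq9_levels_collapsed)
  generate_cohort(cohort_spec(n = n, seed = seed,
                              category_prevalence = prev, ...))
}

records_of <- function(cohort) {
  survival_records(cohort$time, cohort$event, cohort$weight, cohort$eq5d)
}
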
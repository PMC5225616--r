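# Hybrid QALY estimator: Kaplan-Meier follow-up part + Weibull-extrapolated tail.
#
# Utility is measured once at baseline, so individual quality-adjusted time to
# t is utility * t throughout (the constant-utility convention); all means
# below are weighted by the analysis weight.

weighted_mean <- function(x, w) sum(w * x) / sum(w)

# Survivors at the end of follow-up: under administrative censoring these are
# exactly the censored records (event == 0). Staggered entry makes per-record
# censoring times vary, so "alive at the horizon" cannot be read off as
# time >= L.
horizon_set <- function(records, L) {
  records[records$event == 0L, , drop = FALSE]
}

#' Mean QALY accrued by deaths at a given event time
#'
#' Weighted mean of `utility * t_j` over records that died at exactly `t_j`.
#'
#' @param records A [survival_records()] object (or coercible data.frame).
#' @param t_j An observed death time.
#' @return Years.
#' @export
mean_qaly_at_death <- function(records, t_j) {
  records <- as_survival_records(records)
  at <- records[records$event == 1L & records$time == t_j, , drop = FALSE]
  if (!nrow(at))
    stop("no deaths observed at time ", t_j, call. = FALSE)
  weighted_mean(at$utility * t_j, at$weight)
}

#' Mean QALY accrued by survivors at the horizon
#'
#' Weighted mean of `utility * L` over participants alive at the end of
#' follow-up (the administratively censored records): each has lived to the
#' end of their follow-up in their baseline utility state, valued at the
#' common horizon `L`.
#'
#' @inheritParams mean_qaly_at_death
#' @param L Horizon in years.
#' @return Years.
#' @export
mean_qaly_at_horizon <- function(records, L) {
  L * mean_utility_at_horizon(records, L)
}

#' Mean utility among survivors at the horizon
#'
#' Weighted mean baseline utility over participants alive at the end of
#' follow-up; the quality weight applied to every extrapolated life-year in
#' the tail.
#'
#' @inheritParams mean_qaly_at_horizon
#' @return Utility in `[0, 1]`.
#' @export
mean_utility_at_horizon <- function(records, L) {
  records <- as_survival_records(records)
  at <- horizon_set(records, L)
  if (!nrow(at))
    stop("no survivors at the end of follow-up (L = ", L, ")", call. = FALSE)
  weighted_mean(at$utility, at$weight)
}

#' Quality-adjusted years within the follow-up window
#'
#' The Kaplan-Meier part of the hybrid estimator:
#' `sum_j Qhat(t_j) (S(t_{j-1}) - S(t_j)) + Qhat(L) S(t_l)` with `t_0 = 0`,
#' `S(0) = 1` -- mean QALY at each death time weighted by the probability mass
#' the product-limit curve drops there, plus the survivors' QALY at the
#' horizon weighted by the mass still alive after the last event.
#'
#' @inheritParams mean_qaly_at_death
#' @param km The [fit_km()] curve of the same records.
#' @param L Horizon in years, at least the last event time.
#' @return Mean QALY over `(0, L]`, in years.
#' @export
followup_qaly <- function(records, km, L) {
  records <- as_survival_records(records)
  stopifnot(inherits(km, "km_curve"))
  if (length(km$time) && L < km$time[length(km$time)])
    stop("horizon L is before the last event time", call. = FALSE)
  total <- 0
  if (length(km$time)) {
    # Qhat(t_j) for every death time at once: weighted mean utility among
    # deaths at t_j, times t_j (rowsum groups sort by time, matching km$time).
    dead <- records$event == 1L
    grp <- records$time[dead]
    wu <- as.numeric(rowsum(records$weight[dead] * records$utility[dead], grp))
    wsum <- as.numeric(rowsum(records$weight[dead], grp))
    q_death <- km$time * (wu / wsum)
    total <- sum(q_death * (c(1, km$surv[-length(km$surv)]) - km$surv))
  }
  s_last <- if (length(km$surv)) km$surv[length(km$surv)] else 1
  if (s_last > 0)
    total <- total + mean_qaly_at_horizon(records, L) * s_last
  total
}

#' Quality-adjusted years beyond the follow-up window
#'
#' The extrapolated part of the hybrid estimator:
#' `qhat(L) * (lambda * Gamma(1 + 1/beta) - restricted KM life-years)` --
#' mean survivor utility applied to the expected life-years beyond `L`, where
#' total expected life-years come from the parametric fit and life-years
#' within `(0, L]` from the product-limit curve. May be negative when the
#' fitted parametric mean falls below the restricted mean; this is reported
#' with a warning rather than floored, since silently clipping would bias
#' group totals.
#'
#' @param q_L Mean survivor utility at the horizon ([mean_utility_at_horizon()]).
#' @param fit A [fit_weibull()] object.
#' @param km The matching [fit_km()] curve.
#' @param L Horizon in years.
#' @return Years.
#' @export
tail_qaly <- function(q_L, fit, km, L) {
  stopifnot(is.numeric(q_L), length(q_L) == 1L)
  extra <- weibull_mean(fit) - restricted_life_years(km, L)
  out <- q_L * extra
  if (out < 0)
    warning(sprintf("negative extrapolated tail (%.3f y): parametric mean %.3f < restricted mean %.3f",
                    out, weibull_mean(fit), restricted_life_years(km, L)),
            call. = FALSE)
  out
}

#' Mean QALY throughout the remaining lifetime
#'
#' The full hybrid estimate for one group: [followup_qaly()] within `(0, L]`
#' plus [tail_qaly()] beyond `L`. Optionally attaches a nonparametric
#' bootstrap standard error (participants resampled with their weights and
#' the whole pipeline re-run per replicate).
#'
#' @inheritParams mean_qaly_at_death
#' @param L Horizon in years; defaults to the maximum observed follow-up time.
#'   Records with `time > L` are clamped to `L` with a warning.
#' @param boot Number of bootstrap replicates for the standard error
#'   (0 = no SE, the default).
#' @param boot_seed Seed for the bootstrap resampling.
#' @param label Optional group label carried into the result.
#' @return An object of class `qaly_estimate` with fields `followup_part`,
#'   `tail_part`, `total` (years), `se`, `n`, `label`, and the underlying
#'   `km` and `weibull` fits.
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 2000, seed = 3,
#'   category_prevalence = c(none_minimal = 1, mild = 0, moderate = 0,
#'                           modsev_severe = 0)))
#' est <- total_qaly(survival_records(coh$time, coh$event, coh$weight, coh$eq5d))
#' est$total
#' @export
total_qaly <- function(records, L = NULL, boot = 0L, boot_seed = 1L,
                       label = NULL) {
  records <- as_survival_records(records)
  if (is.null(L)) L <- max(records$time)
  if (any(records$time > L)) {
    warning(sum(records$time > L), " record(s) with time > L clamped to L",
            call. = FALSE)
    records$time <- pmin(records$time, L)
  }
  est <- total_qaly_once(records, L)
  se <- NA_real_
  if (boot > 0L) {
    totals <- with_seed(boot_seed, {
      vapply(seq_len(boot), function(b) {
        idx <- sample.int(nrow(records), replace = TRUE)
        tryCatch(total_qaly_once(records[idx, , drop = FALSE], L)$total,
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    se <- stats::sd(totals, na.rm = TRUE)
  }
  structure(c(est, list(se = se, n = nrow(records), label = label)),
            class = "qaly_estimate")
}

total_qaly_once <- function(records, L) {
  km <- fit_km(records)
  fup <- followup_qaly(records, km, L)
  s_last <- if (length(km$surv)) km$surv[length(km$surv)] else 1
  if (s_last > 0 && any(records$event == 0L)) {
    q_L <- mean_utility_at_horizon(records, L)
    wb <- fit_weibull(records)
    tail <- tail_qaly(q_L, wb, km, L)
  } else {
    # Everyone died within follow-up: nothing to extrapolate.
    wb <- NULL
    tail <- 0
  }
  list(followup_part = fup, tail_part = tail, total = fup + tail,
       L = L, km = km, weibull = wb)
}

#' @export
print.qaly_estimate <- function(x, ...) {
  cat(sprintf("Mean QALY throughout remaining lifetime%s\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  follow-up (0, %.2f]: %7.3f y\n", x$L, x$followup_part))
  cat(sprintf("  extrapolated tail:   %7.3f y\n", x$tail_part))
  cat(sprintf("  total:               %7.3f y%s  (n = %d)\n", x$total,
              if (is.finite(x$se)) sprintf(" (SE %.3f)", x$se) else "", x$n))
  invisible(x)
}
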
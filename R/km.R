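# Weighted Kaplan-Meier product-limit estimation and restricted life-years.

#' Assemble survival records
#'
#' Validates and packages the per-participant quantities the QALY estimator
#' consumes: follow-up time in years, death indicator, analysis weight, and
#' baseline utility.
#'
#' @param time Positive follow-up times (years).
#' @param event Death indicator, coercible to 0/1 (`1` = death observed).
#' @param weight Positive analysis weights; default 1 (unweighted).
#' @param utility Baseline utility in `[floor, 1]`; default 1 (so QALY reduces
#'   to life-years).
#' @param utility_floor Lower bound utilities are checked against.
#' @return A data.frame of class `survival_records`.
#' @export
survival_records <- function(time, event, weight = 1, utility = 1,
                             utility_floor = 0) {
  n <- length(time)
  if (!n) stop("no records supplied", call. = FALSE)
  time <- as.numeric(time)
  event <- as.integer(event)
  weight <- rep_len(as.numeric(weight), n)
  utility <- rep_len(as.numeric(utility), n)
  if (anyNA(time) || any(time <= 0))
    stop("all follow-up times must be positive", call. = FALSE)
  if (anyNA(event) || !all(event %in% c(0L, 1L)))
    stop("event must be 0/1", call. = FALSE)
  if (anyNA(weight) || any(weight <= 0))
    stop("all weights must be positive", call. = FALSE)
  if (anyNA(utility) || any(utility < utility_floor) || any(utility > 1))
    stop("utilities must lie in [", utility_floor, ", 1]", call. = FALSE)
  structure(data.frame(time = time, event = event, weight = weight,
                       utility = utility),
            class = c("survival_records", "data.frame"))
}

as_survival_records <- function(records) {
  if (inherits(records, "survival_records")) return(records)
  need <- c("time", "event")
  if (!all(need %in% names(records)))
    stop("records need at least columns `time` and `event`", call. = FALSE)
  survival_records(records$time, records$event,
                   weight = if (is.null(records$weight)) 1 else records$weight,
                   utility = if (is.null(records$utility)) 1 else records$utility)
}

#' Weighted Kaplan-Meier product-limit curve
#'
#' At each distinct death time `t_j` the curve multiplies by
#' `1 - d_w(t_j) / Y_w(t_j)`, where `d_w` is the summed weight of deaths at
#' `t_j` and `Y_w` the summed weight still at risk (follow-up time `>= t_j`;
#' tied deaths form a single step, and records censored at `t_j` are still at
#' risk there). With unit weights this is the ordinary product-limit
#' estimator.
#'
#' @param records A [survival_records()] object (or coercible data.frame).
#' @return An object of class `km_curve`: event times `time`, survival values
#'   `surv` (with `surv(0) = 1` implicit), weighted deaths and at-risk totals
#'   per step.
#' @examples
#' km <- fit_km(survival_records(c(1, 2, 3), c(1, 1, 0)))
#' km$surv  # 2/3, 1/3
#' @export
fit_km <- function(records) {
  records <- as_survival_records(records)
  ord <- order(records$time)
  t_s <- records$time[ord]
  w_s <- records$weight[ord]
  ev <- records$event[ord] == 1L
  dtimes <- unique(t_s[ev])
  if (!length(dtimes)) {
    return(structure(list(time = numeric(0), surv = numeric(0),
                          d_w = numeric(0), y_w = numeric(0),
                          max_time = max(records$time)),
                     class = "km_curve"))
  }
  # Weight at risk at t_j: total weight minus weight with time strictly < t_j
  # (findInterval with left.open counts exactly the time < t_j records).
  cumw <- cumsum(w_s)
  before <- findInterval(dtimes, t_s, left.open = TRUE)
  y_w <- cumw[length(cumw)] - c(0, cumw)[before + 1L]
  d_w <- as.numeric(rowsum(w_s[ev], group = t_s[ev]))  # sorted by time
  if (any(y_w <= 0))
    stop("zero weight at risk at event time ", dtimes[which(y_w <= 0)[1L]],
         call. = FALSE)
  surv <- cumprod(1 - d_w / y_w)
  structure(list(time = dtimes, surv = surv, d_w = d_w, y_w = y_w,
                 max_time = max(records$time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Weighted Kaplan-Meier curve: %d event time(s), S(last) = %.4f\n",
              length(x$time),
              if (length(x$time)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

# Survival value just before event time index j (S(t_0) = 1).
km_surv_before <- function(km, j) if (j == 1L) 1 else km$surv[j - 1L]

#' Restricted life-years under a Kaplan-Meier curve
#'
#' Area under the product-limit step function on `(0, L]`:
#' `sum_j S(t_{j-1}) (t_j - t_{j-1}) + S(t_k)(L - t_k)` with `t_0 = 0`,
#' `S(0) = 1`. This is the restricted mean survival time at horizon `L`.
#'
#' @param km A [fit_km()] curve.
#' @param L Horizon in years; must be at least the last event time.
#' @return Restricted mean life-years in `[0, L]`.
#' @export
restricted_life_years <- function(km, L) {
  stopifnot(inherits(km, "km_curve"))
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 0)
    stop("horizon L must be a non-negative number", call. = FALSE)
  times <- km$time
  if (length(times) && L < times[length(times)])
    stop("horizon L is before the last event time", call. = FALSE)
  grid <- c(0, times, L)
  sval <- c(1, km$surv)           # value on [t_j, t_{j+1})
  sum(sval * diff(grid))
}
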
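# Synthetic cohort generation.

# Run code with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Exact cohort CSV column order (analysis extras appended after `event`).
cohort_columns <- c("id", "age", "sex", "weight", paste0("phq", 1:9),
                    "phq_total", "genhlth", "physdays", "mentdays", "actdays",
                    "eq5d", "n_comorbid", "income_fpl_ratio", "education",
                    "married", "time", "event")

# counts[k+1, s+1] = number of length-k vectors over {0,1,2,3} summing to s.
phq9_composition_counts <- local({
  counts <- matrix(0, nrow = 10, ncol = 28)
  counts[1, 1] <- 1
  for (k in 1:9) for (s in 0:27) {
    v <- 0
    for (item in 0:3) if (s - item >= 0) v <- v + counts[k, s - item + 1]
    counts[k + 1, s + 1] <- v
  }
  counts
})

# Draw, for each total in `totals`, a uniformly random 9-vector over {0..3}
# with that sum. Sequential sampling with exact composition counts.
sample_phq9_items <- function(totals) {
  n <- length(totals)
  items <- matrix(0L, nrow = n, ncol = 9)
  remaining <- as.integer(totals)
  for (j in 1:9) {
    k_left <- 9 - j                     # items still to draw after this one
    # P(item = v | remaining) proportional to counts[k_left, remaining - v]
    probs <- vapply(0:3, function(v) {
      s <- remaining - v
      ok <- s >= 0 & s <= 3 * k_left
      out <- numeric(n)
      out[ok] <- phq9_composition_counts[k_left + 1, s[ok] + 1]
      out
    }, numeric(n))
    if (n == 1L) probs <- matrix(probs, nrow = 1)
    cum <- probs / rowSums(probs)
    cum <- t(apply(cum, 1, cumsum))
    u <- stats::runif(n)
    v <- rowSums(u > cum + 1e-15)       # index of sampled value 0..3
    items[, j] <- as.integer(v)
    remaining <- remaining - items[, j]
  }
  stopifnot(all(remaining == 0L))
  items
}

empty_cohort <- function() {
  out <- as.data.frame(setNames(rep(list(numeric(0)), length(cohort_columns)),
                                cohort_columns))
  out$id <- integer(0); out$sex <- character(0); out$education <- character(0)
  for (nm in c(paste0("phq", 1:9), "phq_total", "genhlth", "physdays",
               "mentdays", "actdays", "n_comorbid", "married", "event"))
    out[[nm]] <- integer(0)
  out$severity <- factor(character(0), levels = phq9_levels_collapsed,
                         ordered = TRUE)
  out$true_death_time <- numeric(0)
  out
}

#' Generate a synthetic cohort
#'
#' Draws a cohort row by row from a [cohort_spec()]: severity category by
#' prevalence; PHQ-9 total uniform over the category's score range with a
#' uniformly random consistent item vector; baseline utility from a rescaled
#' Beta with the category's mean; time to death from the category's Weibull;
#' administrative censoring uniform over the follow-up window (plus optional
#' exponential loss to follow-up). Observed follow-up is
#' `time = min(death, censoring)` with `event = 1` iff death came first.
#' Demographics, survey weights, and comorbidity counts are drawn
#' independently of outcomes unless the spec's confounding switches are on.
#'
#' Output is deterministic given `spec$seed` and leaves the caller's RNG
#' stream untouched.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame in the cohort CSV schema (`id, age, sex, weight,
#'   phq1..phq9, phq_total, genhlth, physdays, mentdays, actdays, eq5d,
#'   n_comorbid, income_fpl_ratio, education, married, time, event`), plus
#'   bookkeeping columns `severity` (collapsed category) and
#'   `true_death_time` (latent, for validation only).
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 200, seed = 7))
#' table(coh$severity)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  n <- spec$n
  if (n == 0L) return(empty_cohort())
  cats <- phq9_levels_collapsed
  with_seed(spec$seed, {
    cat_idx <- sample.int(4L, n, replace = TRUE,
                          prob = spec$category_prevalence)
    severity <- factor(cats[cat_idx], levels = cats, ordered = TRUE)

    # PHQ-9 total uniform over the category's integer range; items uniform
    # over compositions consistent with the total.
    totals <- vapply(cat_idx, function(i) {
      rng <- severity_score_ranges[[i]]
      rng[sample.int(length(rng), 1L)]
    }, integer(1))
    items <- sample_phq9_items(totals)

    # Baseline utility: Beta with per-category mean, rescaled to [floor, 1].
    floor_u <- spec$utility_floor
    m01 <- (spec$utility_mean[cat_idx] - floor_u) / (1 - floor_u)
    a <- m01 * spec$utility_concentration
    b <- (1 - m01) * spec$utility_concentration
    pu <- stats::runif(n)

    # Time to death: Weibull per category via inverse CDF; optionally share
    # the uniform with utility (antithetically) to induce negative
    # utility-longevity coupling for robustness experiments.
    pt <- if (spec$utility_hazard_corr) 1 - pu else stats::runif(n)
    death <- spec$weibull_scale[cat_idx] * (-log(1 - pt))^(1 / spec$weibull_shape[cat_idx])
    utility <- floor_u + (1 - floor_u) * stats::qbeta(pu, a, b)

    cens <- stats::runif(n, spec$followup_window[1], spec$followup_window[2])
    if (spec$ltfu_rate > 0)
      cens <- pmin(cens, stats::rexp(n, rate = spec$ltfu_rate))
    time <- pmin(death, cens)
    event <- as.integer(death <= cens)

    age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                     spec$age_range[1]), spec$age_range[2])
    age <- age + spec$age_severity_shift * (cat_idx - 1)
    sex <- ifelse(stats::runif(n) < spec$prop_female, "female", "male")
    weight <- stats::rlnorm(n, spec$weight_meanlog, spec$weight_sdlog)
    if (spec$informative_weights)
      weight <- weight * exp(0.3 * (cat_idx - 1))

    # Healthy Days responses: decorative, monotone-in-severity draws so the
    # mapping path can be exercised; `eq5d` remains the authoritative utility.
    genhlth <- pmin(5L, pmax(1L, as.integer(round(
      stats::rnorm(n, mean = 1.8 + 0.8 * (cat_idx - 1), sd = 0.8)))))
    draw_days <- function(base) as.integer(round(30 * stats::rbeta(
      n, shape1 = 0.4 + base * (cat_idx - 1), shape2 = 3)))
    physdays <- draw_days(0.35)
    mentdays <- draw_days(0.60)
    actdays  <- draw_days(0.30)

    n_comorbid <- stats::rpois(n, spec$comorbid_mean)
    income_fpl_ratio <- stats::rlnorm(n, log(3.5), 0.7)
    education <- ifelse(stats::runif(n) < 0.453, "gt_hs", "le_hs")
    married <- as.integer(stats::runif(n) < 0.607)

    out <- data.frame(id = seq_len(n), age = age, sex = sex, weight = weight)
    for (j in 1:9) out[[paste0("phq", j)]] <- items[, j]
    out$phq_total <- as.integer(totals)
    out$genhlth <- genhlth
    out$physdays <- physdays; out$mentdays <- mentdays; out$actdays <- actdays
    out$eq5d <- utility
    out$n_comorbid <- n_comorbid
    out$income_fpl_ratio <- income_fpl_ratio
    out$education <- education
    out$married <- married
    out$time <- time
    out$event <- event
    out$severity <- severity
    out$true_death_time <- death
    rownames(out) <- NULL
    out
  })
}
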
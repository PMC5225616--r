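# Healthy Days -> EQ-5D utility mapping (pluggable coefficient table).

#' Coefficients for the Healthy Days to EQ-5D utility mapping
#'
#' An additive model mapping the four CDC Healthy Days responses plus age to a
#' preference-based utility, clipped to `[utility_floor, utility_ceiling]`.
#' The built-in default set is a documented stand-in with the qualitatively
#' correct signs (utility falls as self-rated health worsens, as unhealthy or
#' activity-limited days accumulate, and slowly with age) -- it is NOT a
#' published mapping. Users holding a published coefficient set (which may
#' value some states below 0) should supply it here, lowering `utility_floor`
#' as needed.
#'
#' @param intercept Utility of the reference state (excellent health, zero
#'   unhealthy days, age `age_center`).
#' @param genhlth Decrement per step of self-rated general health above 1.
#' @param physdays,mentdays,actdays Decrement for 30/30 physically unhealthy,
#'   mentally unhealthy, and activity-limitation days (applied proportionally).
#' @param age Decrement per year of age above `age_center`.
#' @param age_center Age (years) at which the age term is zero.
#' @param utility_floor,utility_ceiling Clipping bounds; the default floor of 0
#'   matches anchoring utility at 0 for death and 1 for perfect health.
#' @return An object of class `mapping_coefficients`.
#' @export
mapping_coefficients <- function(intercept = 1.0, genhlth = -0.07,
                                 physdays = -0.20, mentdays = -0.15,
                                 actdays = -0.25, age = -0.001,
                                 age_center = 65,
                                 utility_floor = 0.0, utility_ceiling = 1.0) {
  stopifnot(is.numeric(utility_floor), is.numeric(utility_ceiling))
  if (!(utility_floor < utility_ceiling && utility_ceiling <= 1))
    stop("require utility_floor < utility_ceiling <= 1", call. = FALSE)
  structure(
    list(intercept = intercept, genhlth = genhlth, physdays = physdays,
         mentdays = mentdays, actdays = actdays, age = age,
         age_center = age_center,
         utility_floor = utility_floor, utility_ceiling = utility_ceiling),
    class = "mapping_coefficients")
}

#' @export
print.mapping_coefficients <- function(x, ...) {
  cat("Healthy Days -> EQ-5D mapping coefficients (stand-in unless supplied)\n")
  for (nm in setdiff(names(x), c("utility_floor", "utility_ceiling")))
    cat(sprintf("  %-11s %+g\n", nm, x[[nm]]))
  cat(sprintf("  clip to [%g, %g]\n", x$utility_floor, x$utility_ceiling))
  invisible(x)
}

#' Map Healthy Days responses and age to an EQ-5D-like utility
#'
#' Evaluates the additive linear predictor
#' `intercept + genhlth*(gh-1) + physdays*(pd/30) + mentdays*(md/30) +
#' actdays*(ad/30) + age*(years - age_center)` and clips the result to the
#' coefficient set's floor and ceiling. Deterministic given `coeffs`;
#' vectorized over respondents.
#'
#' @param genhlth Self-rated general health, integer 1 (excellent) to 5 (poor).
#' @param physdays,mentdays,actdays Days (0-30) in the past 30 that were
#'   physically unhealthy, mentally unhealthy, or activity-limited.
#' @param age Age in years, non-negative.
#' @param coeffs A [mapping_coefficients()] object.
#' @return Numeric utility vector in `[utility_floor, utility_ceiling]`.
#' @examples
#' map_to_eq5d(1, 0, 0, 0, age = 65)      # perfect-health anchor -> 1
#' map_to_eq5d(3, 10, 5, 0, age = 70)
#' @export
map_to_eq5d <- function(genhlth, physdays, mentdays, actdays, age,
                        coeffs = mapping_coefficients()) {
  stopifnot(inherits(coeffs, "mapping_coefficients"))
  n <- max(length(genhlth), length(physdays), length(mentdays),
           length(actdays), length(age))
  check_range <- function(x, lo, hi, name) {
    x <- rep_len(as.numeric(x), n)
    bad <- which(is.na(x) | x < lo | x > hi)
    if (length(bad))
      stop(name, " outside [", lo, ", ", hi, "] at position ", bad[1L],
           call. = FALSE)
    x
  }
  gh <- check_range(genhlth, 1, 5, "genhlth")
  pd <- check_range(physdays, 0, 30, "physdays")
  md <- check_range(mentdays, 0, 30, "mentdays")
  ad <- check_range(actdays, 0, 30, "actdays")
  yr <- check_range(age, 0, Inf, "age")
  lp <- coeffs$intercept +
    coeffs$genhlth * (gh - 1) +
    coeffs$physdays * (pd / 30) +
    coeffs$mentdays * (md / 30) +
    coeffs$actdays * (ad / 30) +
    coeffs$age * (yr - coeffs$age_center)
  pmin(pmax(lp, coeffs$utility_floor), coeffs$utility_ceiling)
}
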
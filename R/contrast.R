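# Propensity-balanced group contrasts: QALY loss and percent loss.

#' Define a severity contrast
#'
#' A contrast names two disjoint sets of collapsed severity categories: the
#' exposed group and the reference group. The four standard contrasts mirror
#' the usual reporting layout:
#' \describe{
#'   \item{mdd}{moderate or worse (PHQ-9 >= 10) vs. no MDD (0-9)}
#'   \item{moderate}{moderate (10-14) vs. no MDD (0-9)}
#'   \item{modsev_severe}{moderately severe/severe (15-27) vs. no MDD (0-9)}
#'   \item{mild}{mild (5-9) vs. none/minimal (0-4)}
#'   \item{any_depression}{mild or worse (5-27) vs. none/minimal (0-4)}
#' }
#'
#' @param name Contrast label.
#' @param exposed,reference Character vectors of collapsed severity categories;
#'   must be disjoint.
#' @param subgroup Optional name of a cohort column to stratify on.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(name, exposed, reference, subgroup = NULL) {
  cats <- phq9_levels_collapsed
  stopifnot(all(exposed %in% cats), all(reference %in% cats))
  if (length(intersect(exposed, reference)))
    stop("exposed and reference categories must be disjoint", call. = FALSE)
  structure(list(name = name, exposed = exposed, reference = reference,
                 subgroup = subgroup),
            class = "contrast_spec")
}

#' @rdname contrast_spec
#' @export
standard_contrasts <- function() {
  no_mdd <- c("none_minimal", "mild")
  list(
    contrast_spec("mdd", c("moderate", "modsev_severe"), no_mdd),
    contrast_spec("moderate", "moderate", no_mdd),
    contrast_spec("modsev_severe", "modsev_severe", no_mdd),
    contrast_spec("mild", "mild", "none_minimal"),
    contrast_spec("any_depression", c("mild", "moderate", "modsev_severe"),
                  "none_minimal"))
}

#' Propensity of exposure given covariates
#'
#' Additive logistic model of exposure on the covariate list (default age and
#' sex), fitted with the survey weights. Used to balance systematic baseline
#' differences between severity groups before comparing QALY.
#'
#' @param cohort Cohort data.frame containing the covariates and `weight`.
#' @param exposed Logical vector, `TRUE` for exposed rows.
#' @param covariates Character vector of covariate column names.
#' @return List with fitted `scores` in (0, 1) and the `model`.
#' @export
estimate_propensity <- function(cohort, exposed,
                                covariates = c("age", "sex")) {
  stopifnot(length(exposed) == nrow(cohort))
  if (!any(exposed) || all(exposed))
    stop("both exposure groups must be nonempty", call. = FALSE)
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov))
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  dat <- cohort[, covariates, drop = FALSE]
  # Drop constant covariates (e.g., sex within a single-sex subgroup).
  keep <- vapply(dat, function(x) length(unique(x)) > 1L, logical(1))
  dat <- dat[, keep, drop = FALSE]
  dat$.exposed <- as.numeric(exposed)
  w <- if (is.null(cohort$weight)) rep(1, nrow(cohort)) else cohort$weight
  form <- if (ncol(dat) > 1L)
    stats::as.formula(paste(".exposed ~", paste(names(dat)[names(dat) != ".exposed"],
                                                collapse = " + ")))
  else stats::as.formula(".exposed ~ 1")
  # quasibinomial: identical fit to binomial but tolerant of non-integer
  # survey weights.
  fit <- stats::glm(form, family = stats::quasibinomial(), data = dat,
                    weights = w)
  scores <- as.numeric(stats::fitted(fit))
  if (any(scores >= 1 - 1e-12) || any(scores <= 1e-12))
    stop("propensity model separates the groups (fitted scores at 0/1); ",
         "check covariates", call. = FALSE)
  list(scores = scores, model = fit)
}

#' Stabilized inverse-probability balance weights
#'
#' Multiplies the base survey weights by stabilized inverse-probability
#' weights: `pbar / score` for exposed rows and `(1 - pbar) / (1 - score)` for
#' reference rows, with `pbar` the (survey-weighted) exposed fraction. With
#' constant scores this reduces to the base weights, and the stabilized factor
#' averages to about 1 within each group. Scores within `trim` of 0 or 1 are
#' trimmed to the threshold and counted in a warning.
#'
#' @param scores Propensity scores in (0, 1).
#' @param exposed Logical exposure indicator.
#' @param base_weights Positive survey weights.
#' @param trim Trimming threshold for extreme scores.
#' @return Numeric analysis weights.
#' @export
balance_weights <- function(scores, exposed, base_weights, trim = 1e-6) {
  stopifnot(length(scores) == length(exposed),
            length(base_weights) == length(exposed))
  n_trim <- sum(scores < trim | scores > 1 - trim)
  if (n_trim)
    warning(n_trim, " propensity score(s) trimmed to [", trim, ", ",
            1 - trim, "]", call. = FALSE)
  scores <- pmin(pmax(scores, trim), 1 - trim)
  pbar <- sum(base_weights * exposed) / sum(base_weights)
  sw <- ifelse(exposed, pbar / scores, (1 - pbar) / (1 - scores))
  base_weights * sw
}

#' QALY loss and percent loss
#'
#' `loss = qaly_reference - qaly_exposed`;
#' `percent_loss = 100 * loss / qaly_reference`. All arithmetic is at full
#' precision; the print method rounds to 1 decimal (years) and whole percent
#' for display, matching the usual reporting convention.
#'
#' @param qaly_reference,qaly_exposed Group mean QALY in years;
#'   `qaly_reference` must be positive.
#' @param se_reference,se_exposed,se_loss Optional standard errors carried
#'   into the result.
#' @param name,n_reference,n_exposed Optional labels and group sizes.
#' @return An object of class `loss_result`.
#' @examples
#' qaly_loss(12.7, 4.4)   # loss 8.3 years, 65%
#' @export
qaly_loss <- function(qaly_reference, qaly_exposed,
                      se_reference = NA_real_, se_exposed = NA_real_,
                      se_loss = NA_real_, name = NULL,
                      n_reference = NA_integer_, n_exposed = NA_integer_) {
  stopifnot(is.numeric(qaly_reference), is.numeric(qaly_exposed))
  if (qaly_reference <= 0)
    stop("reference QALY must be positive", call. = FALSE)
  loss <- qaly_reference - qaly_exposed
  structure(list(name = name,
                 qaly_reference = qaly_reference, qaly_exposed = qaly_exposed,
                 loss = loss, percent_loss = 100 * loss / qaly_reference,
                 se_reference = se_reference, se_exposed = se_exposed,
                 se_loss = se_loss,
                 n_reference = n_reference, n_exposed = n_exposed),
            class = "loss_result")
}

#' @export
print.loss_result <- function(x, ...) {
  cat(sprintf("QALY loss%s: %.1f vs. %.1f y -> loss %.1f y (%.0f%%)\n",
              if (!is.null(x$name)) paste0(" [", x$name, "]") else "",
              x$qaly_reference, x$qaly_exposed, round(x$loss, 1),
              round(x$percent_loss)))
  invisible(x)
}

#' Run a propensity-balanced QALY contrast
#'
#' Full pipeline for one contrast: restrict the cohort to the exposed and
#' reference categories, fit the propensity model, form stabilized
#' inverse-probability analysis weights on top of the survey weights, estimate
#' [total_qaly()] per group at a common horizon, and report the loss. The
#' bootstrap (if `boot > 0`) resamples participants and re-runs the whole
#' pipeline -- propensity fit included -- per replicate.
#'
#' @param cohort Cohort data.frame with columns `severity` (collapsed), `time`,
#'   `event`, `weight`, `eq5d`, and the propensity covariates.
#' @param contrast A [contrast_spec()].
#' @param L Horizon in years; default, the maximum follow-up time among the
#'   rows entering the contrast.
#' @param boot Bootstrap replicates for standard errors (0 = none).
#' @param boot_seed Bootstrap seed.
#' @param covariates Propensity covariates.
#' @return A `loss_result`, or a structure flagged `unestimable` (with the
#'   reason) when a group is too small to support the Weibull fit.
#' @export
run_contrast <- function(cohort, contrast, L = NULL, boot = 0L, boot_seed = 1L,
                         covariates = c("age", "sex")) {
  stopifnot(inherits(contrast, "contrast_spec"))
  if (is.null(cohort$severity))
    stop("cohort must carry a collapsed `severity` column", call. = FALSE)
  sel <- cohort$severity %in% c(contrast$exposed, contrast$reference)
  dat <- cohort[sel, , drop = FALSE]
  exposed <- dat$severity %in% contrast$exposed
  if (!any(exposed) || all(exposed))
    stop("both contrast groups must be nonempty", call. = FALSE)
  if (is.null(L)) L <- max(dat$time)

  point <- tryCatch(
    contrast_once(dat, exposed, L, covariates),
    error = function(e) e)
  if (inherits(point, "error"))
    return(structure(list(name = contrast$name, unestimable = TRUE,
                          reason = conditionMessage(point)),
                     class = c("unestimable_contrast", "loss_result")))

  se_ref <- se_exp <- se_loss <- NA_real_
  if (boot > 0L) {
    reps <- with_seed(boot_seed, {
      vapply(seq_len(boot), function(b) {
        idx <- sample.int(nrow(dat), replace = TRUE)
        res <- tryCatch(contrast_once(dat[idx, , drop = FALSE], exposed[idx],
                                      L, covariates),
                        error = function(e) NULL)
        if (is.null(res)) c(NA_real_, NA_real_)
        else c(res$reference, res$exposed)
      }, numeric(2))
    })
    se_ref <- stats::sd(reps[1, ], na.rm = TRUE)
    se_exp <- stats::sd(reps[2, ], na.rm = TRUE)
    se_loss <- stats::sd(reps[1, ] - reps[2, ], na.rm = TRUE)
  }
  qaly_loss(point$reference, point$exposed,
            se_reference = se_ref, se_exposed = se_exp, se_loss = se_loss,
            name = contrast$name,
            n_reference = sum(!exposed), n_exposed = sum(exposed))
}

# One pass of the contrast pipeline on (possibly resampled) data.
contrast_once <- function(dat, exposed, L, covariates) {
  ps <- estimate_propensity(dat, exposed, covariates)
  w <- suppressWarnings(balance_weights(ps$scores, exposed, dat$weight))
  est <- function(rows) {
    recs <- survival_records(dat$time[rows], dat$event[rows],
                             weight = w[rows], utility = dat$eq5d[rows])
    suppressWarnings(total_qaly(recs, L = L)$total)
  }
  list(reference = est(which(!exposed)), exposed = est(which(exposed)))
}

#' @export
print.unestimable_contrast <- function(x, ...) {
  cat(sprintf("Contrast [%s]: unestimable -- %s\n", x$name, x$reason))
  invisible(x)
}
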
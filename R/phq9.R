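# PHQ-9 scoring and severity classification.

#' Severity category labels
#'
#' Five-level severity bands for the PHQ-9 total score and the four-level
#' collapsed form in which the two highest bands (moderately severe, severe)
#' are merged. The collapsed form is the grouping used for small upper tails,
#' where too few respondents score 20 or above to support separate estimation.
#'
#' @format Character vectors of factor levels, ordered from least to most severe.
#' @export
phq9_levels <- c("none_minimal", "mild", "moderate", "moderately_severe", "severe")

#' @rdname phq9_levels
#' @export
phq9_levels_collapsed <- c("none_minimal", "mild", "moderate", "modsev_severe")

#' Score the 9-item Patient Health Questionnaire
#'
#' Sums the nine item responses. Each item is a symptom-frequency code from 0
#' ("not at all") to 3 ("nearly every day"), so the total ranges 0-27.
#'
#' @param items Integer vector of exactly 9 item responses, each in 0-3.
#'   `NA` items are rejected: a questionnaire with any missing item has an
#'   undefined total and should be excluded upstream (see [validate_cohort()]).
#' @return Integer total score in 0-27.
#' @examples
#' score_phq9(c(1, 1, 1, 0, 0, 0, 2, 2, 2))
#' @export
score_phq9 <- function(items) {
  if (length(items) != 9L)
    stop("PHQ-9 requires exactly 9 items, got ", length(items), call. = FALSE)
  items <- as.numeric(items)
  bad <- which(is.na(items) | items %% 1 != 0 | items < 0 | items > 3)
  if (length(bad))
    stop("PHQ-9 item ", bad[1L], " is missing or outside 0-3", call. = FALSE)
  as.integer(sum(items))
}

#' Classify PHQ-9 totals into severity categories
#'
#' Standard severity bands: none or minimal (0-4), mild (5-9), moderate
#' (10-14), moderately severe (15-19), severe (20-27). The collapsed form
#' merges the last two bands into `modsev_severe` (15-27).
#'
#' @param total Integer vector of PHQ-9 total scores, each in 0-27.
#' @param collapsed If `TRUE`, return the four-level collapsed factor.
#' @return Ordered factor over [phq9_levels] (or [phq9_levels_collapsed]).
#' @examples
#' categorize_phq9(c(4, 9, 20))
#' categorize_phq9(20, collapsed = TRUE)
#' @export
categorize_phq9 <- function(total, collapsed = FALSE) {
  check_phq9_total(total)
  fine <- cut(total, breaks = c(-1, 4, 9, 14, 19, 27), labels = phq9_levels)
  fine <- factor(fine, levels = phq9_levels, ordered = TRUE)
  if (!collapsed) return(fine)
  collapse_severity(fine)
}

#' Collapse the five-level severity factor to four levels
#'
#' @param severity Factor over [phq9_levels].
#' @return Ordered factor over [phq9_levels_collapsed].
#' @export
collapse_severity <- function(severity) {
  severity <- factor(severity, levels = phq9_levels)
  if (anyNA(severity))
    stop("unknown severity label", call. = FALSE)
  map <- c(none_minimal = "none_minimal", mild = "mild", moderate = "moderate",
           moderately_severe = "modsev_severe", severe = "modsev_severe")
  factor(unname(map[as.character(severity)]),
         levels = phq9_levels_collapsed, ordered = TRUE)
}

#' Major depressive disorder indicator
#'
#' MDD is operationalized as a PHQ-9 total of 10 or higher (moderate or worse);
#' mild depression is a total of 5-9.
#'
#' @param total Integer vector of PHQ-9 totals in 0-27.
#' @return Logical vector.
#' @export
is_mdd <- function(total) {
  check_phq9_total(total)
  total >= 10
}

#' Mild depression indicator (PHQ-9 total 5-9)
#' @inheritParams is_mdd
#' @return Logical vector.
#' @export
is_mild_depression <- function(total) {
  check_phq9_total(total)
  total >= 5 & total <= 9
}

check_phq9_total <- function(total) {
  if (!length(total)) stop("empty PHQ-9 total", call. = FALSE)
  total <- as.numeric(total)
  ok <- !is.na(total) & total %% 1 == 0 & total >= 0 & total <= 27
  if (!all(ok))
    stop("PHQ-9 total outside 0-27 at position ", which(!ok)[1L], call. = FALSE)
  invisible(total)
}
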
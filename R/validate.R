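# Cohort schema validation.

issue <- function(severity, row, column, message) {
  data.frame(severity = severity, row = row, column = column,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a cohort table
#'
#' Checks the cohort against the expected schema before any estimation:
#' required columns (`time`, `event`, `weight`, and either `phq_total` or the
#' nine `phq1..phq9` items, and either `eq5d` or the Healthy Days columns plus
#' `age`), value ranges (PHQ items 0-3, totals 0-27, `eq5d` in `[0, 1]`,
#' `time > 0`, `weight > 0`, `event` 0/1, `genhlth` 1-5, day counts 0-30), and
#' cross-field consistency (`phq_total` must equal the item sum when both are
#' present). Range and consistency violations are blocking errors with row and
#' column coordinates; missing PHQ-9 items yield a non-blocking warning (such
#' rows are excluded from severity analyses).
#'
#' @param table Cohort data.frame (as read by [read_cohort()]).
#' @return A data.frame of class `cohort_validation` with columns `severity`
#'   (`"error"`/`"warning"`), `row`, `column`, `message`; zero rows means a
#'   clean cohort. Attribute `ok` is `TRUE` when no blocking error was found.
#' @export
validate_cohort <- function(table) {
  issues <- list()
  add <- function(x) issues[[length(issues) + 1L]] <<- x
  cols <- names(table)
  phq_items <- paste0("phq", 1:9)
  has_items <- all(phq_items %in% cols)

  for (col in c("time", "event", "weight"))
    if (!col %in% cols)
      add(issue("error", NA, col, "required column missing"))
  if (!"phq_total" %in% cols && !has_items)
    add(issue("error", NA, "phq_total",
              "need phq_total or the nine phq1..phq9 items"))
  hd_cols <- c("genhlth", "physdays", "mentdays", "actdays", "age")
  if (!"eq5d" %in% cols && !all(hd_cols %in% cols))
    add(issue("error", NA, "eq5d",
              "need eq5d or the Healthy Days columns plus age"))

  check_range <- function(col, lo, hi, integer_only = FALSE) {
    if (!col %in% cols) return()
    x <- table[[col]]
    bad <- which(!is.na(x) &
                   (x < lo | x > hi | (integer_only & x %% 1 != 0)))
    for (r in bad)
      add(issue("error", r, col,
                sprintf("value %s outside %s-%s", format(x[r]), lo, hi)))
  }
  for (col in phq_items) check_range(col, 0, 3, integer_only = TRUE)
  check_range("phq_total", 0, 27, integer_only = TRUE)
  check_range("eq5d", 0, 1)
  check_range("genhlth", 1, 5, integer_only = TRUE)
  for (col in c("physdays", "mentdays", "actdays"))
    check_range(col, 0, 30, integer_only = TRUE)
  check_range("event", 0, 1, integer_only = TRUE)
  check_range("age", 0, 130)
  if ("time" %in% cols) {
    bad <- which(is.na(table$time) | table$time <= 0)
    for (r in bad) add(issue("error", r, "time", "follow-up time must be > 0"))
  }
  if ("weight" %in% cols) {
    bad <- which(is.na(table$weight) | table$weight <= 0)
    for (r in bad) add(issue("error", r, "weight", "weight must be > 0"))
  }

  if (has_items) {
    items <- as.matrix(table[, phq_items])
    n_missing <- sum(apply(items, 1L, anyNA))
    if (n_missing)
      add(issue("warning", NA, "phq1..phq9",
                sprintf("%d row(s) with missing PHQ-9 items excluded from severity analyses",
                        n_missing)))
    if ("phq_total" %in% cols) {
      sums <- rowSums(items)
      bad <- which(!is.na(sums) & !is.na(table$phq_total) &
                     sums != table$phq_total)
      for (r in bad)
        add(issue("error", r, "phq_total",
                  sprintf("phq_total %s does not equal item sum %s",
                          format(table$phq_total[r]), format(sums[r]))))
    }
  }

  report <- if (length(issues)) do.call(rbind, issues)
  else issue(character(0), integer(0), character(0), character(0))
  attr(report, "ok") <- !any(report$severity == "error")
  class(report) <- c("cohort_validation", "data.frame")
  report
}

#' @export
print.cohort_validation <- function(x, ...) {
  if (!nrow(x)) {
    cat("Cohort validation: clean\n")
    return(invisible(x))
  }
  cat(sprintf("Cohort validation: %d error(s), %d warning(s)\n",
              sum(x$severity == "error"), sum(x$severity == "warning")))
  print.data.frame(x)
  invisible(x)
}
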
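# Cohort I/O and derivation of analysis columns.

#' Read a cohort CSV
#'
#' Reads the cohort schema (`id, age, sex, weight, phq1..phq9, phq_total,
#' genhlth, physdays, mentdays, actdays, eq5d, n_comorbid, income_fpl_ratio,
#' education, married, time, event`; unknown columns preserved, missing
#' optional columns allowed), validates it, and derives the analysis columns.
#'
#' @param path CSV file path.
#' @param coeffs Mapping coefficients used when `eq5d` is absent.
#' @param validate If `TRUE` (default), abort on blocking validation errors.
#' @return Cohort data.frame with derived `phq_total` and `severity` columns.
#' @export
read_cohort <- function(path, coeffs = mapping_coefficients(),
                        validate = TRUE) {
  table <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (validate) {
    report <- validate_cohort(table)
    if (!attr(report, "ok")) {
      print(report)
      stop("cohort failed schema validation; see report above", call. = FALSE)
    }
    for (msg in report$message[report$severity == "warning"])
      message("cohort warning: ", msg)
  }
  derive_analysis_columns(table, coeffs)
}

#' Derive the analysis columns of a cohort
#'
#' Fills in `phq_total` (item sum) where absent, attaches the collapsed
#' `severity` factor, and fills in `eq5d` via [map_to_eq5d()] where absent
#' (noting in a message that the stand-in mapping is in use). Rows with
#' missing PHQ-9 information get `NA` severity.
#'
#' @param table Cohort data.frame.
#' @param coeffs Mapping coefficients for the Healthy Days path.
#' @return The augmented data.frame.
#' @export
derive_analysis_columns <- function(table, coeffs = mapping_coefficients()) {
  phq_items <- paste0("phq", 1:9)
  if (!"phq_total" %in% names(table) && all(phq_items %in% names(table)))
    table$phq_total <- as.integer(rowSums(table[, phq_items]))
  if ("phq_total" %in% names(table)) {
    sev <- rep(NA_character_, nrow(table))
    ok <- !is.na(table$phq_total)
    if (any(ok))
      sev[ok] <- as.character(categorize_phq9(table$phq_total[ok],
                                              collapsed = TRUE))
    table$severity <- factor(sev, levels = phq9_levels_collapsed,
                             ordered = TRUE)
  }
  if (!"eq5d" %in% names(table)) {
    message("no eq5d column: deriving utilities from Healthy Days responses ",
            "via the coefficient table (default set is a stand-in)")
    table$eq5d <- map_to_eq5d(table$genhlth, table$physdays, table$mentdays,
                              table$actdays, table$age, coeffs)
  }
  table
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @param metadata Named list written as `# key=value` header comments.
#' @export
write_cohort <- function(cohort, path, metadata = NULL) {
  write_result_csv(cohort, path, metadata)
}

#' Write / read result CSVs with metadata header comments
#'
#' Result files carry run metadata as `# key=value` comment lines before the
#' header; [read_result_csv()] skips them, so every result file round-trips.
#'
#' @param x Data.frame to write.
#' @param path File path.
#' @param metadata Named list of scalar metadata values.
#' @export
write_result_csv <- function(x, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(metadata))
    writeLines(sprintf("# %s=%s", nm, format(metadata[[nm]])), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
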
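# Run configuration: built-in defaults < YAML file < explicit overrides.

#' Built-in run configuration
#'
#' Defaults for the end-to-end pipeline: estimation horizon `L` (`NULL` = use
#' the maximum observed follow-up), bootstrap replicates `bootstrap`, RNG
#' `seed`, the Healthy Days mapping coefficients, and the synthetic generator
#' parameters (see [cohort_spec()] for their meaning and calibration).
#'
#' @return Nested list of configuration values.
#' @export
default_run_config <- function() {
  list(
    L = NULL,
    bootstrap = 500L,
    seed = 1L,
    mapping = unclass(mapping_coefficients())[
      c("intercept", "genhlth", "physdays", "mentdays", "actdays", "age",
        "age_center", "utility_floor", "utility_ceiling")],
    generator = {
      spec <- unclass(cohort_spec(n = 20000L, seed = 1L))
      lapply(spec, function(x) if (is.numeric(x) && !is.null(names(x)))
        as.list(x) else x)
    })
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[nm] <- override[nm]   # single-bracket keeps explicit NULLs
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML configuration file (if given) and applies explicit overrides
#' on top; precedence is overrides > file > built-in defaults.
#'
#' @param path Optional YAML file path.
#' @param overrides Named list of values taking highest precedence (e.g.,
#'   parsed command-line flags).
#' @return Configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  config <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    # YAML 1.1 would read the bare key `n` (cohort size) as boolean FALSE;
    # only the unambiguous spellings stay booleans.
    handlers <- list(
      "bool#no" = function(x) if (toupper(x) %in% c("FALSE", "NO", "OFF")) FALSE else x,
      "bool#yes" = function(x) if (toupper(x) %in% c("TRUE", "YES", "ON")) TRUE else x)
    config <- merge_config(config, yaml::read_yaml(path, handlers = handlers))
  }
  config <- merge_config(config, overrides)
  if (!is.null(config$bootstrap) && config$bootstrap < 0)
    stop("bootstrap must be non-negative", call. = FALSE)
  if (!is.null(config$L) && config$L <= 0)
    stop("horizon L must be positive", call. = FALSE)
  config
}

config_spec <- function(config) {
  gen <- config$generator
  for (nm in c("category_prevalence", "utility_mean", "weibull_scale",
               "weibull_shape"))
    if (is.list(gen[[nm]])) gen[[nm]] <- unlist(gen[[nm]])
  do.call(cohort_spec, gen)
}

config_mapping <- function(config) {
  do.call(mapping_coefficients, config$mapping)
}
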
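#' Default scenario configuration
#'
#' The base-case parameterisation used throughout: the 20,000 x 10,000
#' sample space with 4,000 druggable genes and 100 causal genes per disease;
#' orthodox preclinical error rates alpha = 0.05, beta = 0.2 (the genomic
#' mode swaps in alpha = 5e-8); clinical alpha = 0.05, beta = 0.2.
#'
#' @param mode `"orthodox"` or `"genomic"` stage-1 false-positive rate.
#' @return A named list of class `scenario_config` with sections `space`,
#'   `stages`, `simulation` and `output`.
#' @export
default_scenario <- function(mode = c("orthodox", "genomic")) {
  mode <- match.arg(mode)
  structure(
    list(
      space = list(n_genes = 20000, n_diseases = 10000, n_druggable = 4000,
                   causal_per_disease = 100),
      stages = list(alpha_pc = if (mode == "orthodox") 0.05 else 5e-8,
                    beta_pc = 0.2, alpha_c = 0.05, beta_c = 0.2),
      simulation = list(replicates = 100000, seed = NULL, mode = "fixed"),
      output = list(format = "csv", digits = 8)
    ),
    class = "scenario_config"
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    qualified <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      abort_targetodds(sprintf("Unknown configuration key `%s`.", qualified),
                       "targetodds_config_error")
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]]) && !is.list(user[[key]])) {
      abort_targetodds(sprintf("`%s` must be a section (mapping).", qualified),
                       "targetodds_config_error")
    }
    if (is.list(defaults[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]] %||% list(),
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  sp <- cfg$space
  for (field in c("n_genes", "n_diseases", "n_druggable", "causal_per_disease")) {
    v <- sp[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort_targetodds(sprintf("`space.%s` must be a single positive number.", field),
                       "targetodds_config_error")
    }
  }
  for (field in c("alpha_pc", "beta_pc", "alpha_c", "beta_c")) {
    v <- cfg$stages[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort_targetodds(sprintf("`stages.%s` must be a probability in [0, 1].", field),
                       "targetodds_config_error")
    }
  }
  if (!cfg$simulation$mode %in% c("fixed", "bernoulli")) {
    abort_targetodds("`simulation.mode` must be \"fixed\" or \"bernoulli\".",
                     "targetodds_config_error")
  }
  if (!is.numeric(cfg$simulation$replicates) || cfg$simulation$replicates < 1) {
    abort_targetodds("`simulation.replicates` must be a positive number.",
                     "targetodds_config_error")
  }
  # sample_space() enforces the cross-field invariants
  do.call(sample_space, cfg$space)
  cfg
}

#' Load a scenario configuration from YAML or JSON
#'
#' Reads a configuration file, fills unspecified values with the base case
#' of [default_scenario()], rejects unknown keys and validates every field
#' with a path-qualified error message. An empty or absent file yields the
#' full base case.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for the
#'   defaults.
#' @param mode Base-case mode passed to [default_scenario()].
#' @return A validated `scenario_config` list.
#' @export
load_scenario <- function(path = NULL, mode = "orthodox") {
  defaults <- default_scenario(mode)
  if (is.null(path)) return(validate_config(defaults))
  if (!file.exists(path)) {
    abort_targetodds(sprintf("Configuration file `%s` does not exist.", path),
                     "targetodds_config_error")
  }
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  if (!is.list(user)) {
    abort_targetodds("Configuration file must contain a mapping at the top level.",
                     "targetodds_config_error")
  }
  cfg <- merge_config(defaults, user)
  class(cfg) <- "scenario_config"
  validate_config(cfg)
}

#' Extract the sample space from a scenario configuration
#'
#' @param config A `scenario_config` list.
#' @return A [sample_space()].
#' @export
scenario_space <- function(config) {
  do.call(sample_space, config$space)
}

#' Write a results table to CSV or JSON
#'
#' CSV output carries values formatted to `digits` significant figures
#' (presentation precision is applied only here, never inside the
#' computations); JSON carries full precision.
#'
#' @param results A data frame of results.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#' @param digits Significant digits for CSV formatting; a single number or
#'   a named list mapping column names to digits. `NULL` writes full
#'   precision.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, format = NULL, digits = NULL) {
  if (!is.data.frame(results)) {
    abort_targetodds("`results` must be a data frame.",
                     "targetodds_invalid_argument")
  }
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  } else {
    out <- results
    if (!is.null(digits)) {
      fmt_col <- function(x, d) if (is.numeric(x)) signif(x, d) else x
      if (is.list(digits)) {
        for (nm in intersect(names(digits), names(out))) {
          out[[nm]] <- fmt_col(out[[nm]], digits[[nm]])
        }
      } else {
        out[] <- lapply(out, fmt_col, d = digits)
      }
    }
    readr::write_csv(out, path)
  }
  invisible(path)
}
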
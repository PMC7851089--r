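#' Load a full analysis configuration from YAML or JSON
#'
#' The file carries up to five sections: `model` (fields of [model_config()]),
#' `strategies` (list of [strategy_spec()] fields), `cohort` (fields of
#' [cohort_config()]), `psa` (`n_trials`, `dispersion`, `seed`) and `tornado`
#' (`wtp`, `range_fraction`). Omitted fields fall back to the package
#' defaults; invalid values raise errors naming the offending key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List of class `a1c_config_bundle` with elements `model`
#'   (`a1c_model_config`), `cohort` (`a1c_cohort_config`), `psa`, `tornado`.
#' @examples
#' cfg <- load_config(system.file("extdata", "reference_config.yaml",
#'                                package = "a1ccea"))
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  bundle_from_list(raw)
}

bundle_from_list <- function(raw) {
  stopifnot(is.list(raw))
  model_args <- raw$model %||% list()
  for (nm in c("complication_costs_annual", "occurrence_probs_annual",
               "death_probs_annual"))
    if (!is.null(model_args[[nm]])) model_args[[nm]] <- unlist(model_args[[nm]])
  strategies <- lapply(raw$strategies %||% list(), function(s)
    do.call(strategy_spec, s))
  model_args$strategies <- strategies
  model <- do.call(model_config, model_args)
  cohort_args <- raw$cohort %||% list()
  for (nm in c("a1c_iqr_poc", "a1c_iqr_lab"))
    if (!is.null(cohort_args[[nm]])) cohort_args[[nm]] <- unlist(cohort_args[[nm]])
  cohort <- do.call(cohort_config, cohort_args)
  psa <- utils::modifyList(list(n_trials = 1000, dispersion = 0.2, seed = 1L),
                           raw$psa %||% list())
  tor <- utils::modifyList(list(wtp = 2000, range_fraction = 0.2),
                           raw$tornado %||% list())
  structure(list(model = model, cohort = cohort, psa = psa, tornado = tor),
            class = "a1c_config_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bundle_to_list <- function(bundle) {
  stopifnot(inherits(bundle, "a1c_config_bundle"))
  m <- unclass(bundle$model)
  strategies <- lapply(m$strategies, unclass)
  names(strategies) <- NULL
  m$strategies <- NULL
  m$n_cycles <- NULL
  for (nm in c("complication_costs_annual", "occurrence_probs_annual",
               "death_probs_annual"))
    m[[nm]] <- as.list(m[[nm]])
  list(model = m, strategies = strategies,
       cohort = unclass(bundle$cohort),
       psa = bundle$psa, tornado = bundle$tornado)
}

#' Write an analysis configuration to YAML or JSON
#'
#' The written file round-trips through [load_config()] to an equivalent
#' configuration.
#'
#' @param bundle An `a1c_config_bundle` from [load_config()], or a list with
#'   a `model` element of class `a1c_model_config`.
#' @param path Destination ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(bundle, path) {
  lst <- bundle_to_list(bundle)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}

#' Reference configuration bundle
#'
#' [reference_config()] plus the default cohort, PSA and tornado sections, as
#' one bundle (the same content as the shipped
#' `extdata/reference_config.yaml`).
#'
#' @return An `a1c_config_bundle`.
#' @export
reference_bundle <- function() {
  structure(list(model = reference_config(),
                 cohort = cohort_config(),
                 psa = list(n_trials = 1000, dispersion = 0.2, seed = 1L),
                 tornado = list(wtp = 2000, range_fraction = 0.2)),
            class = "a1c_config_bundle")
}

#' Export strategy outcomes as a data frame
#'
#' @param outcomes Named list of `a1c_strategy_outcome` objects.
#' @return Data frame with columns `strategy`, `discounted_cost`,
#'   `effectiveness`.
#' @export
outcomes_as_df <- function(outcomes) {
  data.frame(
    strategy = vapply(outcomes, `[[`, character(1), "strategy"),
    discounted_cost = vapply(outcomes, `[[`, numeric(1), "discounted_cost"),
    effectiveness = vapply(outcomes, `[[`, numeric(1), "effectiveness"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
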
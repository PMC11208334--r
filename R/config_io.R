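#' Read a model configuration file
#'
#' Loads a JSON or YAML configuration document (dispatched on file
#' extension) into the parameter bundle consumed by [run_base_case()] and
#' [run_psa()]. The expected keys mirror the constructor arguments:
#'
#' ```
#' scenarios:
#'   no_psp: {q_hie, p_dayoff_high, p_dayoff_low, p_quit_high, p_quit_low, recovery_prob}
#'   psp:    {...}
#' costs:    {cost_per_sick_day, cost_per_quit, psp_cost_per_person, currency}
#' cohort:   {n_staff, horizon_days, initial_distribution}
#' ```
#'
#' The package ships its default configuration — the published base case — at
#' `system.file("extdata", "base_case.json", package = "pspmarkov")`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A parameter bundle of class `base_case_parameters`.
#' @export
read_model_config <- function(path) {
  raw <- switch(
    tolower(tools::file_ext(path)),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    "yaml" = ,
    "yml" = yaml::read_yaml(path),
    stop("config file must be .json, .yaml or .yml", call. = FALSE)
  )
  .validate_config_keys(raw)
  hz <- function(s) {
    do.call(hazard_parameters, as.list(raw$scenarios[[s]]))
  }
  structure(
    list(
      no_psp = hz("no_psp"),
      psp = hz("psp"),
      costs = do.call(cost_parameters, as.list(raw$costs)),
      config = do.call(cohort_config, as.list(raw$cohort))
    ),
    class = "base_case_parameters"
  )
}

#' Write a model configuration file
#'
#' Serializes a parameter bundle to JSON or YAML (dispatched on file
#' extension) in the dialect read back by [read_model_config()]. JSON is
#' written at full double precision so a round trip reproduces every
#' parameter bit-for-bit.
#'
#' @param params A parameter bundle (class `base_case_parameters`).
#' @param path Destination `.json`, `.yaml` or `.yml` path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, path) {
  stopifnot(inherits(params, "base_case_parameters"))
  doc <- list(
    scenarios = list(
      no_psp = unclass(params$no_psp),
      psp = unclass(params$psp)
    ),
    costs = unclass(params$costs),
    cohort = unclass(params$config)
  )
  switch(
    tolower(tools::file_ext(path)),
    "json" = jsonlite::write_json(doc, path, auto_unbox = TRUE,
                                  digits = I(17), pretty = TRUE),
    "yaml" = ,
    "yml" = yaml::write_yaml(doc, path, precision = 17L),
    stop("config file must be .json, .yaml or .yml", call. = FALSE)
  )
  invisible(path)
}

.validate_config_keys <- function(raw) {
  missing <- character()
  need <- function(obj, keys, prefix) {
    absent <- setdiff(keys, names(obj))
    if (length(absent)) {
      missing <<- c(missing, paste0(prefix, absent))
    }
  }
  need(raw, c("scenarios", "costs", "cohort"), "")
  if (!is.null(raw$scenarios)) {
    need(raw$scenarios, c("no_psp", "psp"), "scenarios.")
    hfields <- c("q_hie", "p_dayoff_high", "p_dayoff_low",
                 "p_quit_high", "p_quit_low", "recovery_prob")
    for (s in intersect(c("no_psp", "psp"), names(raw$scenarios))) {
      need(raw$scenarios[[s]], hfields, paste0("scenarios.", s, "."))
    }
  }
  if (!is.null(raw$costs)) {
    need(raw$costs, c("cost_per_sick_day", "cost_per_quit",
                      "psp_cost_per_person"), "costs.")
  }
  if (!is.null(raw$cohort)) {
    need(raw$cohort, c("n_staff", "horizon_days"), "cohort.")
  }
  if (length(missing)) {
    stop("invalid configuration; missing keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(raw)
}
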
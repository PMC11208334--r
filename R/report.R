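#' Budget-impact table of the two scenarios
#'
#' Arranges the two `scenario_result`s as the familiar budget-impact layout:
#' one row per reported quantity, one column per scenario. Day and dropout
#' counts are displayed rounded to whole numbers and costs to whole currency
#' units, while the underlying `scenario_result`s keep full precision.
#'
#' @param no_psp,psp `scenario_result` objects from [scenario_costs()].
#' @return A data.frame with columns `information`, `without_psp`,
#'   `with_psp`.
#' @examples
#' res <- run_base_case()
#' table3_report(res$no_psp, res$psp)
#' @export
table3_report <- function(no_psp, psp) {
  stopifnot(inherits(no_psp, "scenario_result"),
            inherits(psp, "scenario_result"))
  row <- function(label, f, digits = 0) {
    data.frame(information = label,
               without_psp = round(f(no_psp), digits),
               with_psp = round(f(psp), digits))
  }
  rbind(
    row("Sick days", function(s) s$sick_days_total),
    row("Dropouts", function(s) s$dropouts_total),
    row("Cost of sick days", function(s) s$cost_sick_days),
    row("Cost of dropouts", function(s) s$cost_dropouts),
    row("Total costs", function(s) s$cost_sick_days + s$cost_dropouts),
    row("Cost per Person", function(s) s$cost_per_person)
  )
}

#' Write the base-case evaluation to disk
#'
#' Emits the budget-impact table as CSV and a full-precision JSON report
#' containing both scenarios, the comparison block (gross saving, net saving,
#' budget impact) and a run manifest (package version, timestamp, input
#' parameters).
#'
#' @param result The list returned by [run_base_case()].
#' @param dir Output directory (created if needed).
#' @param basename Stem of the output file names.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_base_case_report <- function(result, dir, basename = "base_case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(basename, "_table.csv"))
  json <- file.path(dir, paste0(basename, ".json"))
  utils::write.csv(table3_report(result$no_psp, result$psp), csv,
                   row.names = FALSE)
  doc <- list(
    manifest = .run_manifest(),
    parameters = list(
      scenarios = list(no_psp = unclass(result$params$no_psp),
                       psp = unclass(result$params$psp)),
      costs = unclass(result$params$costs),
      cohort = unclass(result$params$config)
    ),
    scenarios = list(no_psp = unclass(result$no_psp),
                     psp = unclass(result$psp)),
    comparison = unclass(result$comparison)
  )
  jsonlite::write_json(doc, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, json = json))
}

#' Write a sensitivity-analysis summary to disk
#'
#' Emits the PSA headline statistics (no-effect fractions, cost quantiles,
#' signed-rank p-value and, when the per-pair costs were kept, the break-even
#' shift) as JSON, and optionally the per-pair costs as CSV.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param dir Output directory (created if needed).
#' @param basename Stem of the output file names.
#' @param seed The master seed used for the run, echoed into the manifest
#'   (`NA` if not supplied).
#' @param alpha Significance level for the break-even shift.
#' @param write_pairs If `TRUE`, also write the per-pair costs CSV.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_psa_report <- function(psa, dir, basename = "psa", seed = NA,
                             alpha = 0.05, write_pairs = FALSE) {
  stopifnot(inherits(psa, "psa_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- file.path(dir, paste0(basename, ".json"))
  break_even <- if (!is.null(psa$pairs) && !is.na(psa$signed_rank_p) &&
                    psa$signed_rank_p <= alpha) {
    find_break_even_shift(psa$pairs$cost_no_psp, psa$pairs$cost_psp,
                          alpha = alpha)
  } else {
    NA_real_
  }
  doc <- list(
    manifest = c(.run_manifest(), list(seed = seed, alpha = alpha)),
    n_pairs = psa$n_pairs_used,
    cv = psa$cv,
    quantile_level = psa$quantile_level,
    no_effect_fraction_no_psp = psa$no_effect_fraction_no_psp,
    no_effect_fraction_psp = psa$no_effect_fraction_psp,
    cost_quantile_no_psp = psa$cost_quantile_no_psp,
    cost_quantile_psp = psa$cost_quantile_psp,
    signed_rank_p = psa$signed_rank_p,
    break_even_shift = break_even
  )
  jsonlite::write_json(doc, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(json = json)
  if (write_pairs && !is.null(psa$pairs)) {
    csv <- file.path(dir, paste0(basename, "_pairs.csv"))
    utils::write.csv(psa$pairs, csv, row.names = FALSE)
    paths <- c(paths, pairs_csv = csv)
  }
  invisible(paths)
}

.run_manifest <- function() {
  list(
    package = "pspmarkov",
    version = as.character(utils::packageVersion("pspmarkov")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}
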
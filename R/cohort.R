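#' Propagate the cohort state distribution over the horizon
#'
#' Deterministic expectation engine: repeatedly multiplies the state
#' distribution by the daily transition kernel, producing the occupancy of
#' each state at every cycle from 0 (the initial distribution) to
#' `horizon_days`.
#'
#' @param P A 3x3 transition matrix (see [build_transition_matrix()]).
#' @param config A [cohort_config()].
#'
#' @return A `(horizon_days + 1) x 3` matrix of class `occupancy_series`;
#'   row `t + 1` is the state distribution after `t` cycles. Columns are
#'   named `unaffected`, `leave`, `quit`.
#' @export
propagate <- function(P, config) {
  validate_transition_matrix(P)
  stopifnot(inherits(config, "cohort_config"))
  H <- config$horizon_days
  occ <- matrix(NA_real_, nrow = H + 1L, ncol = 3L,
                dimnames = list(NULL, c("unaffected", "leave", "quit")))
  occ[1L, ] <- config$initial_distribution
  if (H > 0) {
    for (t in seq_len(H)) {
      occ[t + 1L, ] <- occ[t, ] %*% P
    }
  }
  structure(occ, class = c("occupancy_series", "matrix"))
}

#' Expected sick days per person over the horizon
#'
#' Counts one sick day per cycle of occupancy in the leave state, summed over
#' cycles 1..horizon (cycle 0 is the initial distribution and, in the base
#' case, carries no leave occupancy by construction).
#'
#' @param series An `occupancy_series` from [propagate()].
#' @return Expected number of sick-leave days per cohort member.
#' @export
expected_sick_days <- function(series) {
  stopifnot(inherits(series, "occupancy_series"))
  if (nrow(series) < 2L) return(0)
  sum(series[-1L, "leave"])
}

#' Expected fraction of the cohort absorbed into the quit state
#'
#' @param series An `occupancy_series` from [propagate()].
#' @return Quit-state occupancy at the final cycle.
#' @export
expected_quit_fraction <- function(series) {
  stopifnot(inherits(series, "occupancy_series"))
  unname(series[nrow(series), "quit"])
}

#' Budget impact of one scenario
#'
#' Scales the per-person expectations to the institution and prices them:
#' sick days at `cost_per_sick_day` each, each quit once at `cost_per_quit`
#' (no proration for when in the year it occurs), plus the PSP participation
#' fee for every staff member where applicable. All values are retained at
#' full precision; rounding happens only in report formatting.
#'
#' @param series An `occupancy_series` from [propagate()].
#' @param costs A [cost_parameters()] object.
#' @param config The [cohort_config()] used for the propagation.
#' @param psp_scenario If `TRUE` the per-person PSP fee is charged; the
#'   program cost is reported separately and excluded from `cost_per_person`
#'   so the scenario columns stay comparable with the published table.
#'
#' @return An object of class `scenario_result`: per-person expectations,
#'   institution-level totals, and the cost breakdown.
#' @export
scenario_costs <- function(series, costs, config, psp_scenario = FALSE) {
  stopifnot(inherits(series, "occupancy_series"),
            inherits(costs, "cost_parameters"),
            inherits(config, "cohort_config"))
  sick_pp <- expected_sick_days(series)
  quit_frac <- expected_quit_fraction(series)
  n <- config$n_staff
  cost_sick <- sick_pp * n * costs$cost_per_sick_day
  cost_quit <- quit_frac * n * costs$cost_per_quit
  cost_prog <- if (psp_scenario) costs$psp_cost_per_person * n else 0
  structure(
    list(
      expected_sick_days_per_person = sick_pp,
      expected_quit_fraction = quit_frac,
      sick_days_total = sick_pp * n,
      dropouts_total = quit_frac * n,
      cost_sick_days = cost_sick,
      cost_dropouts = cost_quit,
      cost_program = cost_prog,
      cost_total = cost_sick + cost_quit + cost_prog,
      cost_per_person = (cost_sick + cost_quit) / n,
      n_staff = n,
      currency = costs$currency,
      psp_scenario = psp_scenario
    ),
    class = "scenario_result"
  )
}

#' Compare the no-PSP and PSP scenarios
#'
#' The gross saving per person is the difference of the per-person scenario
#' costs excluding the PSP participation fee (matching the published table's
#' arithmetic); the net saving subtracts the fee. The budget impact is the
#' gross saving scaled to the institution.
#'
#' @param no_psp,psp `scenario_result` objects computed under the same
#'   cohort configuration.
#' @param psp_cost_per_person Annual PSP fee used for the net figure;
#'   defaults to the fee embedded in the PSP scenario's program cost.
#'
#' @return An object of class `comparison_result` with
#'   `saving_per_person_gross`, `saving_per_person_net` and
#'   `budget_impact_total`.
#' @export
compare_scenarios <- function(no_psp, psp,
                              psp_cost_per_person = psp$cost_program / psp$n_staff) {
  stopifnot(inherits(no_psp, "scenario_result"),
            inherits(psp, "scenario_result"))
  if (no_psp$n_staff != psp$n_staff) {
    stop("scenarios were computed for different cohort sizes", call. = FALSE)
  }
  gross <- no_psp$cost_per_person - psp$cost_per_person
  structure(
    list(
      saving_per_person_gross = gross,
      saving_per_person_net = gross - psp_cost_per_person,
      budget_impact_total = gross * no_psp$n_staff,
      n_staff = no_psp$n_staff,
      currency = no_psp$currency
    ),
    class = "comparison_result"
  )
}

#' Run the full deterministic base-case evaluation
#'
#' Convenience wrapper: builds both scenario transition matrices, propagates
#' the cohort, prices both scenarios and compares them.
#'
#' @param params A parameter bundle as returned by [base_case_parameters()]
#'   or [read_model_config()].
#' @return A list with `no_psp` and `psp` (`scenario_result`s), `comparison`
#'   (a `comparison_result`), and the input `params`.
#' @examples
#' res <- run_base_case(base_case_parameters())
#' res$comparison$saving_per_person_gross
#' @export
run_base_case <- function(params = base_case_parameters()) {
  P0 <- build_transition_matrix(params$no_psp)
  P1 <- build_transition_matrix(params$psp)
  s0 <- scenario_costs(propagate(P0, params$config), params$costs,
                       params$config, psp_scenario = FALSE)
  s1 <- scenario_costs(propagate(P1, params$config), params$costs,
                       params$config, psp_scenario = TRUE)
  list(no_psp = s0, psp = s1, comparison = compare_scenarios(s0, s1),
       params = params)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario (%s PSP), %d staff:\n",
              if (x$psp_scenario) "with" else "without", x$n_staff))
  cat(sprintf("  sick days/person   %8.2f\n", x$expected_sick_days_per_person))
  cat(sprintf("  quit fraction      %8.1f %%\n", 100 * x$expected_quit_fraction))
  cat(sprintf("  cost of sick days  %12.0f %s\n", x$cost_sick_days, x$currency))
  cat(sprintf("  cost of dropouts   %12.0f %s\n", x$cost_dropouts, x$currency))
  cat(sprintf("  cost/person        %12.0f %s (excl. program fee)\n",
              x$cost_per_person, x$currency))
  invisible(x)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Saving per person: %0.0f %s gross, %0.0f %s net of PSP fee\n",
              x$saving_per_person_gross, x$currency,
              x$saving_per_person_net, x$currency))
  cat(sprintf("Budget impact (%d staff): %0.0f %s\n",
              x$n_staff, x$budget_impact_total, x$currency))
  invisible(x)
}
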
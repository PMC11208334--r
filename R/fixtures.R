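#' Published base-case parameterization
#'
#' Returns the base-case model inputs of the published evaluation: the daily
#' hazard parameters of the no-PSP and PSP scenarios, the cost parameters,
#' and the cohort configuration (1,000 nursing staff followed over 365 daily
#' cycles, all starting unaffected).
#'
#' The recovery probability is stored as exactly `1/7` (a mean leave length
#' of 7 days), not its 4-decimal rounding, and derived transition
#' probabilities are never rounded; year-long summaries depend visibly on
#' that precision.
#'
#' @return A list of class `base_case_parameters` with elements `no_psp` and
#'   `psp` ([hazard_parameters()]), `costs` ([cost_parameters()]; the PSP fee
#'   only applies in the PSP scenario) and `config` ([cohort_config()]).
#' @examples
#' bc <- base_case_parameters()
#' round(build_transition_matrix(bc$no_psp), 4)
#' @export
base_case_parameters <- function() {
  structure(
    list(
      no_psp = hazard_parameters(
        q_hie = 0.02,
        p_dayoff_high = 0.05, p_dayoff_low = 0.002,
        p_quit_high = 0.0068, p_quit_low = 0.0003,
        recovery_prob = 1 / 7
      ),
      psp = hazard_parameters(
        q_hie = 0.02,
        p_dayoff_high = 0.03, p_dayoff_low = 0.002,
        p_quit_high = 0.0034, p_quit_low = 0.0001,
        recovery_prob = 1 / 7
      ),
      costs = cost_parameters(
        cost_per_sick_day = 500,
        cost_per_quit = 75000,
        psp_cost_per_person = 550
      ),
      config = cohort_config(n_staff = 1000, horizon_days = 365)
    ),
    class = "base_case_parameters"
  )
}

#' @export
print.base_case_parameters <- function(x, ...) {
  cat("Base-case parameter bundle\n\nNo-PSP scenario hazards:\n")
  print(x$no_psp)
  cat("\nPSP scenario hazards:\n")
  print(x$psp)
  cat("\n")
  print(x$costs)
  cat(sprintf("Cohort: %d staff, %d daily cycles\n",
              x$config$n_staff, x$config$horizon_days))
  invisible(x)
}

#' Exact small-horizon oracle by path enumeration
#'
#' Enumerates all `3^horizon` state sequences of the chain started in the
#' unaffected state and sums their exact probabilities, yielding brute-force
#' reference values for the expected sick days (cycles spent in the leave
#' state), the probability of having quit by the final cycle, and the
#' probability of never leaving the unaffected state. Used to verify the
#' matrix-propagation engine and the trajectory simulator on tiny horizons.
#'
#' @param P A 3x3 transition matrix (see [build_transition_matrix()]).
#' @param horizon Number of cycles; at most 8 (6,561 paths) so enumeration
#'   stays sub-second.
#'
#' @return A list with `expected_sick_days`, `quit_probability` and
#'   `no_effect_probability`.
#' @export
enumerate_paths_oracle <- function(P, horizon) {
  validate_transition_matrix(P)
  if (horizon < 0 || horizon != round(horizon)) {
    stop("'horizon' must be a nonnegative integer", call. = FALSE)
  }
  if (horizon > 8) {
    stop("path enumeration is capped at horizon 8 (3^8 paths)", call. = FALSE)
  }
  if (horizon == 0) {
    return(list(expected_sick_days = 0, quit_probability = 0,
                no_effect_probability = 1))
  }
  paths <- as.matrix(expand.grid(rep(list(1:3), horizon)))
  prob <- P[cbind(1L, paths[, 1])]
  if (horizon > 1) {
    for (t in 2:horizon) {
      prob <- prob * P[cbind(paths[, t - 1], paths[, t])]
    }
  }
  list(
    expected_sick_days = sum(prob * rowSums(paths == 2L)),
    quit_probability = sum(prob[paths[, horizon] == 3L]),
    no_effect_probability = sum(prob[rowSums(paths == 1L) == horizon])
  )
}
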
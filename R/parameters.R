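#' Event-conditioned daily hazard parameters
#'
#' Bundles the daily probabilities that drive the three-state nurse-year
#' Markov chain: the incidence of a high-impact event (HIE, a stressful
#' patient-related incident such as involvement in an adverse event), the
#' probabilities of starting a sick leave or of quitting conditional on
#' whether an HIE occurred that day, and the daily probability of returning
#' from leave to work.
#'
#' The unconditional daily transition probabilities of the chain are obtained
#' by mixing the high- and low-impact hazards over the HIE incidence; see
#' [combine_event_probability()] and [build_transition_matrix()].
#'
#' @param q_hie Probability per day of a high-impact event.
#' @param p_dayoff_high Probability of starting a leave on a day with an HIE.
#' @param p_dayoff_low Probability of starting a leave on a day without an HIE.
#' @param p_quit_high Probability of quitting on a day with an HIE.
#' @param p_quit_low Probability of quitting on a day without an HIE.
#' @param recovery_prob Daily probability of returning from leave to the
#'   unaffected state. The default `1/7` corresponds to a mean leave length
#'   of 7 days.
#'
#' @return An object of class `hazard_parameters` (a named list of the six
#'   probabilities).
#' @examples
#' h <- hazard_parameters(
#'   q_hie = 0.02,
#'   p_dayoff_high = 0.05, p_dayoff_low = 0.002,
#'   p_quit_high = 0.0068, p_quit_low = 0.0003
#' )
#' build_transition_matrix(h)
#' @export
hazard_parameters <- function(q_hie, p_dayoff_high, p_dayoff_low,
                              p_quit_high, p_quit_low,
                              recovery_prob = 1 / 7) {
  h <- list(
    q_hie = as.numeric(q_hie),
    p_dayoff_high = as.numeric(p_dayoff_high),
    p_dayoff_low = as.numeric(p_dayoff_low),
    p_quit_high = as.numeric(p_quit_high),
    p_quit_low = as.numeric(p_quit_low),
    recovery_prob = as.numeric(recovery_prob)
  )
  for (nm in names(h)) .check_prob(h[[nm]], nm)
  # total daily exit mass from the unaffected state must not exceed 1
  exit_mass <- q_hie * (p_dayoff_high + p_quit_high) +
    (1 - q_hie) * (p_dayoff_low + p_quit_low)
  if (exit_mass > 1) {
    stop("infeasible hazards: combined day-off and quit probability exceeds 1",
         call. = FALSE)
  }
  structure(h, class = "hazard_parameters")
}

#' Cost parameters of the budget-impact model
#'
#' @param cost_per_sick_day Cost of one day of sick leave (currency units;
#'   base case EUR 500).
#' @param cost_per_quit One-time replacement cost per resignation (base case
#'   EUR 75,000).
#' @param psp_cost_per_person Annual per-person cost of participating in the
#'   Peer Support Program (base case EUR 550; 0 in the no-PSP scenario).
#' @param currency Unit label carried through reports (no conversion is done).
#'
#' @return An object of class `cost_parameters`.
#' @export
cost_parameters <- function(cost_per_sick_day = 500,
                            cost_per_quit = 75000,
                            psp_cost_per_person = 550,
                            currency = "EUR") {
  for (nm in c("cost_per_sick_day", "cost_per_quit", "psp_cost_per_person")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
      stop(sprintf("'%s' must be a single nonnegative number", nm),
           call. = FALSE)
    }
  }
  structure(
    list(
      cost_per_sick_day = as.numeric(cost_per_sick_day),
      cost_per_quit = as.numeric(cost_per_quit),
      psp_cost_per_person = as.numeric(psp_cost_per_person),
      currency = currency
    ),
    class = "cost_parameters"
  )
}

#' Cohort configuration
#'
#' @param n_staff Cohort size (base case: 1,000 nursing staff).
#' @param horizon_days Number of daily cycles (base case: 365).
#' @param initial_distribution Probability vector over the three states
#'   (unaffected, leave, quit) at cycle 0; defaults to all mass on
#'   unaffected.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_staff = 1000, horizon_days = 365,
                          initial_distribution = c(1, 0, 0)) {
  if (!is.numeric(n_staff) || length(n_staff) != 1L || n_staff < 1) {
    stop("'n_staff' must be a single number >= 1", call. = FALSE)
  }
  if (!is.numeric(horizon_days) || length(horizon_days) != 1L ||
      horizon_days < 0 || horizon_days != round(horizon_days)) {
    stop("'horizon_days' must be a single nonnegative integer", call. = FALSE)
  }
  if (length(initial_distribution) != 3L || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-12) {
    stop("'initial_distribution' must be 3 nonnegative entries summing to 1",
         call. = FALSE)
  }
  structure(
    list(
      n_staff = as.numeric(n_staff),
      horizon_days = as.integer(horizon_days),
      initial_distribution = as.numeric(initial_distribution)
    ),
    class = "cohort_config"
  )
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.hazard_parameters <- function(x, ...) {
  cat("Daily hazard parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat(sprintf("Costs (%s): %g per sick day, %g per quit, %g PSP fee/person\n",
              x$currency, x$cost_per_sick_day, x$cost_per_quit,
              x$psp_cost_per_person))
  invisible(x)
}
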
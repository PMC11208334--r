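#' Simulate individual nurse-year trajectories
#'
#' Draws `n` independent trajectories of the three-state chain, each starting
#' unaffected and evolving for `horizon_days` cycles with one categorical
#' draw per cycle from the current state's row of the transition kernel.
#' Absorption into the quit state ends a trajectory early: remaining cycles
#' contribute no sick days and no further cost. The HIE-related cost of a
#' trajectory is `sick_days * cost_per_sick_day + quit * cost_per_quit`; the
#' PSP participation fee is deliberately not part of it, so a trajectory has
#' zero cost exactly when it never leaves the unaffected state.
#'
#' The simulation consumes the current R RNG stream (one uniform vector per
#' cycle), so results are reproducible under `set.seed()`.
#'
#' @param P A 3x3 transition matrix (see [build_transition_matrix()]).
#' @param n Number of trajectories.
#' @param config A [cohort_config()]; only the horizon is used (every
#'   trajectory starts unaffected).
#' @param costs A [cost_parameters()] object used to price the trajectory.
#'
#' @return A data.frame with one row per trajectory: `sick_days` (integer),
#'   `quit` (logical), `quit_day` (cycle of absorption, `NA` if none) and
#'   `hie_cost`.
#' @examples
#' bc <- base_case_parameters()
#' set.seed(1)
#' sim <- simulate_trajectories(build_transition_matrix(bc$no_psp), 100,
#'                              bc$config, bc$costs)
#' mean(sim$hie_cost == 0)
#' @export
simulate_trajectories <- function(P, n, config, costs) {
  validate_transition_matrix(P)
  stopifnot(inherits(config, "cohort_config"),
            inherits(costs, "cost_parameters"))
  sim <- .simulate_paths(
    p12 = rep(P[1, 2], n), p13 = rep(P[1, 3], n), p21 = rep(P[2, 1], n),
    horizon = config$horizon_days
  )
  data.frame(
    sick_days = sim$sick_days,
    quit = sim$quit,
    quit_day = sim$quit_day,
    hie_cost = sim$sick_days * costs$cost_per_sick_day +
      sim$quit * costs$cost_per_quit
  )
}

#' @rdname simulate_trajectories
#' @return `simulate_trajectory()` returns the single-row data.frame of one
#'   trajectory.
#' @export
simulate_trajectory <- function(P, config, costs) {
  simulate_trajectories(P, 1L, config, costs)
}

# Vectorised path simulation with per-trajectory transition probabilities
# (used directly by the PSA, where every pair carries its own perturbed
# kernel). States: 1 unaffected, 2 leave, 3 quit (absorbing).
.simulate_paths <- function(p12, p13, p21, horizon) {
  n <- length(p12)
  stopifnot(length(p13) == n, length(p21) == n)
  state <- rep(1L, n)
  sick_days <- integer(n)
  quit_day <- rep(NA_integer_, n)
  for (t in seq_len(horizon)) {
    active <- state != 3L
    if (!any(active)) break
    u <- stats::runif(n)
    s1 <- active & state == 1L
    s2 <- active & state == 2L
    # from unaffected: leave with p12, quit with p13, else stay
    to_leave <- s1 & u < p12
    to_quit <- s1 & !to_leave & u < p12 + p13
    # from leave: recover with p21, else stay on leave
    to_work <- s2 & u < p21
    state[to_leave] <- 2L
    state[to_quit] <- 3L
    state[to_work] <- 1L
    quit_day[to_quit] <- t
    on_leave <- state == 2L
    sick_days[on_leave] <- sick_days[on_leave] + 1L
  }
  list(sick_days = sick_days, quit = state == 3L, quit_day = quit_day)
}

#' Analytic probability of a trajectory with no HIE-related effects
#'
#' A trajectory accrues zero HIE-related cost exactly when it stays in the
#' unaffected state for the whole horizon, which has probability
#' `p_11 ^ horizon`.
#'
#' @param P A 3x3 transition matrix.
#' @param horizon Number of daily cycles.
#' @return The no-effect probability.
#' @examples
#' bc <- base_case_parameters()
#' no_effect_fraction_analytic(build_transition_matrix(bc$no_psp), 365)
#' @export
no_effect_fraction_analytic <- function(P, horizon) {
  validate_transition_matrix(P)
  if (horizon < 0 || horizon != round(horizon)) {
    stop("'horizon' must be a nonnegative integer", call. = FALSE)
  }
  P[1, 1] ^ horizon
}
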
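#' Mix a high- and low-impact hazard over the event incidence
#'
#' Combines an event-conditioned pair of daily probabilities into the
#' unconditional daily probability: with probability `q_hie` the day carries a
#' high-impact event and the high hazard applies, otherwise the low hazard
#' applies.
#'
#' @param q_hie Daily probability of a high-impact event.
#' @param p_high Hazard on a day with an event.
#' @param p_low Hazard on a day without an event.
#'
#' @return `q_hie * p_high + (1 - q_hie) * p_low`, a probability between
#'   `min(p_low, p_high)` and `max(p_low, p_high)`.
#' @examples
#' combine_event_probability(0.02, 0.05, 0.002) # 0.00296
#' @export
combine_event_probability <- function(q_hie, p_high, p_low) {
  .check_prob(q_hie, "q_hie")
  .check_prob(p_high, "p_high")
  .check_prob(p_low, "p_low")
  q_hie * p_high + (1 - q_hie) * p_low
}

#' Build the daily transition matrix of the three-state chain
#'
#' Constructs the row-stochastic 3x3 daily transition kernel over the states
#' unaffected (1), leave (2) and quit (3). Off-diagonal entries from the
#' unaffected state are the event-mixed day-off and quit probabilities; the
#' leave state returns to unaffected with the recovery probability and cannot
#' transition directly to quit; quit is absorbing.
#'
#' Probabilities are kept at full floating-point precision — no intermediate
#' rounding — since downstream quantities (365-cycle powers) are sensitive to
#' the fourth decimal.
#'
#' @param h A [hazard_parameters()] object.
#'
#' @return A 3x3 matrix of class `transition_matrix` with dimnames
#'   `c("unaffected", "leave", "quit")`; each row sums to 1.
#' @examples
#' h <- hazard_parameters(0.02, 0.05, 0.002, 0.0068, 0.0003)
#' round(build_transition_matrix(h), 4)
#' @export
build_transition_matrix <- function(h) {
  stopifnot(inherits(h, "hazard_parameters"))
  p12 <- combine_event_probability(h$q_hie, h$p_dayoff_high, h$p_dayoff_low)
  p13 <- combine_event_probability(h$q_hie, h$p_quit_high, h$p_quit_low)
  if (p12 + p13 > 1) {
    stop("infeasible parameters: p_12 + p_13 > 1", call. = FALSE)
  }
  P <- matrix(
    c(1 - p12 - p13,    p12,                 p13,
      h$recovery_prob,  1 - h$recovery_prob, 0,
      0,                0,                   1),
    nrow = 3, byrow = TRUE,
    dimnames = list(
      c("unaffected", "leave", "quit"),
      c("unaffected", "leave", "quit")
    )
  )
  structure(P, class = c("transition_matrix", "matrix"))
}

#' Validate a transition matrix
#'
#' Checks row-stochasticity (tolerance 1e-12), absorption of the quit state,
#' and the structural zero for leave-to-quit transitions.
#'
#' @param P A 3x3 numeric matrix.
#' @return `P`, invisibly; errors if invalid.
#' @export
validate_transition_matrix <- function(P) {
  if (!is.matrix(P) || !all(dim(P) == c(3L, 3L)) || !is.numeric(P)) {
    stop("a transition matrix must be a numeric 3x3 matrix", call. = FALSE)
  }
  if (any(P < 0) || any(P > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(P) - 1) > 1e-12)) {
    stop("each row of a transition matrix must sum to 1", call. = FALSE)
  }
  if (!all(P[3, ] == c(0, 0, 1))) {
    stop("the quit state must be absorbing: row 3 must be (0, 0, 1)",
         call. = FALSE)
  }
  if (P[2, 3] != 0) {
    stop("no direct leave-to-quit transition is allowed (p_23 must be 0)",
         call. = FALSE)
  }
  invisible(P)
}
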
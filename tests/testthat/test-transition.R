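test_that("event mixing reproduces the published combined probabilities", {
  # no-PSP day-off and quit rows of the published transition table
  expect_equal(combine_event_probability(0.02, 0.05, 0.002), 0.00296)
  expect_equal(combine_event_probability(0.02, 0.0068, 0.0003), 0.00043)
  expect_equal(round(combine_event_probability(0.02, 0.05, 0.002), 4), 0.0030)
  expect_equal(round(combine_event_probability(0.02, 0.0068, 0.0003), 4), 0.0004)
  # limits: no event / certain event
  expect_identical(combine_event_probability(0, 0.7, 0.1), 0.1)
  expect_identical(combine_event_probability(1, 0.7, 0.1), 0.7)
})

test_that("event mixing rejects arguments outside [0, 1]", {
  expect_error(combine_event_probability(-0.1, 0.5, 0.1), "probability")
  expect_error(combine_event_probability(0.5, 1.5, 0.1), "probability")
  expect_error(combine_event_probability(0.5, 0.5, NA), "probability")
})

test_that("event mixing is monotone in each hazard and in the incidence", {
  set.seed(11)
  for (i in 1:50) {
    q <- runif(1)
    p_low <- runif(1, 0, 0.5)
    p_high <- runif(1, p_low, 1)
    eps <- 0.01
    base <- combine_event_probability(q, p_high, p_low)
    expect_gte(combine_event_probability(q, min(p_high + eps, 1), p_low), base)
    expect_gte(combine_event_probability(q, p_high, min(p_low + eps, p_high)),
               base)
    # with p_high > p_low, more events mean more exits
    expect_gte(combine_event_probability(min(q + eps, 1), p_high, p_low), base)
  }
})

test_that("the base-case transition matrices carry unrounded probabilities", {
  bc <- base_case_parameters()
  P0 <- build_transition_matrix(bc$no_psp)
  P1 <- build_transition_matrix(bc$psp)
  expect_equal(P0[1, 1], 0.99661, tolerance = 1e-12)
  expect_equal(P1[1, 1], 0.997274, tolerance = 1e-12)
  expect_equal(P1[1, 3], 0.000166, tolerance = 1e-12)
  expect_equal(unname(P0[2, ]), c(1 / 7, 6 / 7, 0), tolerance = 1e-15)
})

test_that("rounding the constructed matrices reproduces every published cell", {
  bc <- base_case_parameters()
  P0 <- round(build_transition_matrix(bc$no_psp), 4)
  P1 <- round(build_transition_matrix(bc$psp), 4)
  published <- function(p11, p12, p13) {
    matrix(c(p11, p12, p13,
             0.1429, 0.8571, 0,
             0, 0, 1), nrow = 3, byrow = TRUE)
  }
  expect_equal(unname(unclass(P0)), published(0.9966, 0.0030, 0.0004))
  expect_equal(unname(unclass(P1)), published(0.9973, 0.0026, 0.0002))
})

test_that("constructed matrices are row-stochastic with quit absorbing", {
  set.seed(21)
  for (i in 1:25) {
    h <- hazard_parameters(
      q_hie = runif(1), p_dayoff_high = runif(1, 0, 0.5),
      p_dayoff_low = runif(1, 0, 0.2), p_quit_high = runif(1, 0, 0.3),
      p_quit_low = runif(1, 0, 0.1), recovery_prob = runif(1)
    )
    P <- build_transition_matrix(h)
    expect_equal(unname(rowSums(P)), c(1, 1, 1), tolerance = 1e-12)
    expect_identical(unname(P[3, ]), c(0, 0, 1))
    expect_identical(P[2, 3], 0)
    expect_no_error(validate_transition_matrix(P))
  }
})

test_that("PSP hazards pointwise below no-PSP hazards give smaller exits", {
  bc <- base_case_parameters()
  P0 <- build_transition_matrix(bc$no_psp)
  P1 <- build_transition_matrix(bc$psp)
  expect_lte(P1[1, 2], P0[1, 2])
  expect_lte(P1[1, 3], P0[1, 3])
})

test_that("infeasible hazard combinations are rejected", {
  expect_error(
    hazard_parameters(q_hie = 1, p_dayoff_high = 0.7, p_dayoff_low = 0,
                      p_quit_high = 0.7, p_quit_low = 0),
    "infeasible"
  )
  expect_error(hazard_parameters(0.02, 1.2, 0.002, 0.0068, 0.0003),
               "probability")
})

test_that("matrix validation catches structural violations", {
  P <- unclass(build_transition_matrix(base_case_parameters()$no_psp))
  bad <- P; bad[3, ] <- c(0.1, 0, 0.9)
  expect_error(validate_transition_matrix(bad), "absorbing")
  bad <- P; bad[2, 3] <- 0.01; bad[2, 2] <- bad[2, 2] - 0.01
  expect_error(validate_transition_matrix(bad), "leave-to-quit")
  bad <- P; bad[1, 1] <- bad[1, 1] - 0.01
  expect_error(validate_transition_matrix(bad), "sum to 1")
})
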
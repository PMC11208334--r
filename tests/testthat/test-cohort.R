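bc <- base_case_parameters()
P0 <- build_transition_matrix(bc$no_psp)
P1 <- build_transition_matrix(bc$psp)

test_that("propagation matches direct matrix powers and trivial horizons", {
  cfg0 <- cohort_config(n_staff = 10, horizon_days = 0)
  s <- propagate(P0, cfg0)
  expect_equal(nrow(s), 1L)
  expect_equal(unname(s[1, ]), c(1, 0, 0))

  cfg2 <- cohort_config(n_staff = 10, horizon_days = 2)
  s2 <- propagate(P0, cfg2)
  # independent two-step product: v P then (v P) P, via explicit sums
  v0 <- c(1, 0, 0)
  v1 <- sapply(1:3, function(j) sum(v0 * P0[, j]))
  v2 <- sapply(1:3, function(j) sum(v1 * P0[, j]))
  expect_equal(unname(s2[2, ]), v1, tolerance = 1e-15)
  expect_equal(unname(s2[3, ]), v2, tolerance = 1e-15)
})

test_that("occupancy vectors stay normalized and quit occupancy grows", {
  for (P in list(P0, P1)) {
    s <- propagate(P, bc$config)
    expect_true(all(abs(rowSums(s) - 1) < 1e-10))
    expect_true(all(diff(s[, "quit"]) >= -1e-15))
    expect_true(all(s >= 0))
  }
})

test_that("base-case expectations reproduce the published per-person figures", {
  s0 <- propagate(P0, bc$config)
  s1 <- propagate(P1, bc$config)
  expect_equal(round(expected_sick_days(s0), 2), 6.77)
  expect_equal(round(expected_sick_days(s1), 2), 6.14)
  expect_equal(round(100 * expected_quit_fraction(s0), 1), 14.3)
  expect_equal(round(100 * expected_quit_fraction(s1), 1), 5.8)
})

test_that("sick days vanish when the leave state is unreachable", {
  h <- hazard_parameters(0.02, 0, 0, 0.0068, 0.0003)
  s <- propagate(build_transition_matrix(h), bc$config)
  expect_equal(expected_sick_days(s), 0)
})

test_that("scenario costs reproduce the published budget-impact columns", {
  res <- run_base_case(bc)
  rel <- function(got, want) abs(got - want) / want
  expect_lt(rel(res$no_psp$cost_sick_days, 3383230), 5e-4)
  expect_lt(rel(res$no_psp$cost_dropouts, 10694785), 5e-4)
  expect_lt(rel(res$psp$cost_sick_days, 3070470), 5e-4)
  expect_lt(rel(res$psp$cost_dropouts, 4335666), 5e-4)
  expect_lt(abs(res$no_psp$cost_per_person - 14078), 1)
  expect_lt(abs(res$psp$cost_per_person - 7406), 1)
  # program fee is charged only in the PSP arm and kept out of cost_per_person
  expect_equal(res$no_psp$cost_program, 0)
  expect_equal(res$psp$cost_program, 550 * 1000)
  expect_equal(res$psp$cost_per_person,
               (res$psp$cost_sick_days + res$psp$cost_dropouts) / 1000)
})

test_that("costs are linear in the unit prices and zero when prices are zero", {
  s0 <- propagate(P0, bc$config)
  zero <- scenario_costs(s0, cost_parameters(0, 0, 0), bc$config)
  expect_equal(zero$cost_total, 0)
  single <- scenario_costs(s0, bc$costs, bc$config)
  double <- scenario_costs(
    s0, cost_parameters(1000, 75000, 550), bc$config)
  expect_equal(double$cost_sick_days, 2 * single$cost_sick_days)
  expect_equal(double$cost_dropouts, single$cost_dropouts)
})

test_that("scenario comparison yields the published saving and budget impact", {
  res <- run_base_case(bc)
  cmp <- res$comparison
  expect_lt(abs(cmp$saving_per_person_gross - 6672), 1)
  expect_equal(cmp$saving_per_person_net,
               cmp$saving_per_person_gross - 550)
  expect_equal(cmp$budget_impact_total, cmp$saving_per_person_gross * 1000)
  expect_lt(abs(cmp$budget_impact_total - 6.67e6), 1e4)
  # identical scenarios cancel
  same <- compare_scenarios(res$no_psp, res$no_psp, psp_cost_per_person = 0)
  expect_equal(same$saving_per_person_gross, 0)
  # mismatched cohort sizes are a configuration error
  other <- scenario_costs(propagate(P1, cohort_config(n_staff = 500)),
                          bc$costs, cohort_config(n_staff = 500))
  expect_error(compare_scenarios(res$no_psp, other), "cohort sizes")
})

test_that("quit fraction responds monotonically to recovery and to PSP", {
  # faster recovery returns staff to the unaffected state where quitting is
  # possible, so the quit fraction grows with the recovery probability
  quit_at <- function(recovery) {
    h <- hazard_parameters(0.02, 0.05, 0.002, 0.0068, 0.0003,
                           recovery_prob = recovery)
    expected_quit_fraction(propagate(build_transition_matrix(h), bc$config))
  }
  q <- sapply(c(0.05, 1 / 7, 0.3, 0.6, 1), quit_at)
  expect_true(all(diff(q) > 0))
  # PSP hazards are pointwise below no-PSP hazards, so fewer staff quit
  expect_lte(expected_quit_fraction(propagate(P1, bc$config)),
             expected_quit_fraction(propagate(P0, bc$config)))
})

test_that("the budget-impact table is laid out and rounded as reported", {
  res <- run_base_case(bc)
  tab <- table3_report(res$no_psp, res$psp)
  expect_equal(tab$information,
               c("Sick days", "Dropouts", "Cost of sick days",
                 "Cost of dropouts", "Total costs", "Cost per Person"))
  expect_equal(tab$without_psp[tab$information == "Dropouts"], 143)
  expect_equal(tab$with_psp[tab$information == "Dropouts"], 58)
  expect_equal(tab$without_psp[tab$information == "Sick days"], 6766)
  expect_equal(tab$with_psp[tab$information == "Sick days"], 6141)
})
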
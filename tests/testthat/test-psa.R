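bc <- base_case_parameters()

test_that("zero perturbation returns the base values exactly", {
  set.seed(51)
  d <- perturb_parameters(bc$no_psp, bc$costs, cv = 0, n = 5)
  expect_equal(nrow(d), 5L)
  for (nm in names(bc$no_psp)) {
    expect_equal(d[[nm]], rep(bc$no_psp[[nm]], 5))
  }
  expect_equal(d$cost_per_quit, rep(75000, 5))
})

test_that("perturbed draws respect bounds and centre on the base values", {
  set.seed(52)
  n <- 20000
  d <- perturb_parameters(bc$no_psp, bc$costs, cv = 0.10, n = n)
  expect_true(all(as.matrix(d) >= 0))
  prob_cols <- names(bc$no_psp)
  expect_true(all(as.matrix(d[prob_cols]) <= 1))
  for (nm in c(prob_cols, "cost_per_sick_day", "cost_per_quit")) {
    base <- if (nm %in% prob_cols) bc$no_psp[[nm]] else bc$costs[[nm]]
    se <- 0.10 * base / sqrt(n)
    expect_lt(abs(mean(d[[nm]]) - base), 3 * se)
  }
})

test_that("pair draws share equal-base parameters and split the rest", {
  set.seed(53)
  pars <- pspmarkov:::.draw_pair_parameters(bc$no_psp, bc$psp, bc$costs,
                                            cv = 0.10, n_pairs = 200)
  # recovery is a shared draw: identical across arms
  expect_identical(pars$no_psp$p21, pars$psp$p21)
  # scenario-specific hazards differ draw by draw
  expect_true(all(pars$no_psp$p12 != pars$psp$p12))
  expect_true(all(pars$no_psp$p13 != pars$psp$p13))
  # feasible rows in both arms
  expect_true(all(pars$no_psp$p12 + pars$no_psp$p13 <= 1))
  expect_true(all(pars$psp$p12 + pars$psp$p13 <= 1))
  expect_true(all(pars$cost_per_sick_day >= 0 & pars$cost_per_quit >= 0))
})

test_that("PSA with cv = 0 matches the analytic base-case fractions", {
  set.seed(54)
  n_pairs <- 4000
  psa <- run_psa(bc$no_psp, bc$psp, bc$costs, bc$config,
                 n_pairs = n_pairs, cv = 0)
  for (arm in c("no_psp", "psp")) {
    p <- no_effect_fraction_analytic(
      build_transition_matrix(bc[[arm]]), 365)
    se <- sqrt(p * (1 - p) / n_pairs)
    expect_lt(abs(psa[[paste0("no_effect_fraction_", arm)]] - p), 3 * se)
  }
})

test_that("a PSA run is fully reproducible from its seed", {
  args <- list(bc$no_psp, bc$psp, bc$costs, bc$config,
               n_pairs = 300, cv = 0.10)
  set.seed(55)
  a <- do.call(run_psa, args)
  set.seed(55)
  b <- do.call(run_psa, args)
  expect_identical(a, b)
})

test_that("inert chains give a degenerate all-zero summary", {
  h <- hazard_parameters(0, 0, 0, 0, 0)
  psa <- run_psa(h, h, bc$costs, bc$config, n_pairs = 50, cv = 0)
  expect_equal(psa$no_effect_fraction_no_psp, 1)
  expect_equal(psa$cost_quantile_no_psp, 0)
  expect_equal(psa$cost_quantile_psp, 0)
  expect_true(is.na(psa$signed_rank_p))  # no nonzero differences to rank
})

test_that("per-pair costs price the simulated trajectories consistently", {
  set.seed(56)
  psa <- run_psa(bc$no_psp, bc$psp, bc$costs, bc$config,
                 n_pairs = 1000, cv = 0.10)
  pairs <- psa$pairs
  expect_equal(nrow(pairs), 1000L)
  expect_true(all(pairs$cost_no_psp >= 0 & pairs$cost_psp >= 0))
  expect_equal(mean(pairs$cost_no_psp == 0), psa$no_effect_fraction_no_psp)
  expect_equal(unname(quantile(pairs$cost_psp, 0.95)),
               psa$cost_quantile_psp)
})
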
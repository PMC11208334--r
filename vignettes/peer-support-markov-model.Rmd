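---
title: "A three-state Markov model of the economic value of peer support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov model of the economic value of peer support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspmarkov)
```

## The problem

Healthcare workers involved in adverse patient events — "second victims" —
face elevated risks of sick leave and of leaving the profession. A Peer
Support Program (PSP) is a structured collegial intervention that dampens
those risks at a fixed per-person annual fee. `pspmarkov` quantifies, from a
hospital's budget perspective, whether the fee is worth paying: it compares
the expected annual costs of sick leave and staff replacement in a nursing
cohort with and without a PSP.

## The model

Each nurse occupies one of three states on each day $t$:
**unaffected** (1), **on leave** (2), or **quit** (3). Transitions follow a
time-homogeneous Markov chain with daily kernel $P = (p_{ij})$. The chain is
driven by a daily *high-impact event* (HIE) that strikes independently with
probability $q$; the day-off and quit hazards are event-conditioned, so the
unconditional daily transition probabilities are mixtures

$$p_{12} = q\,d_{\text{high}} + (1-q)\,d_{\text{low}}, \qquad
  p_{13} = q\,r_{\text{high}} + (1-q)\,r_{\text{low}},$$

with $p_{11} = 1 - p_{12} - p_{13}$. A nurse on leave returns to work with
the daily recovery probability $p_{21}$ (and cannot quit directly from
leave, $p_{23} = 0$); quitting is absorbing, $p_{33} = 1$. Day-off and quit
on the same day are treated as mutually exclusive competing outcomes whose
probabilities add — no renormalisation — which is the arithmetic the
published transition table uses.

The cohort engine propagates the state distribution
$v_t = v_{t-1} P$ from an all-unaffected start over 365 daily cycles.
Expected sick days per person are the summed leave-state occupancy over
cycles 1..365 (one sick day per cycle spent on leave); the expected annual
turnover is the quit-state occupancy at the final cycle.

## Parameters

All parameters are daily probabilities or Euro amounts; the defaults are the
published base case.

| parameter | no PSP | with PSP | meaning |
|---|---|---|---|
| `q_hie` | 0.02 | 0.02 | daily HIE incidence |
| `p_dayoff_high` | 0.05 | 0.03 | leave hazard on an HIE day |
| `p_dayoff_low` | 0.002 | 0.002 | leave hazard otherwise |
| `p_quit_high` | 0.0068 | 0.0034 | quit hazard on an HIE day |
| `p_quit_low` | 0.0003 | 0.0001 | quit hazard otherwise |
| `recovery_prob` | 1/7 | 1/7 | daily return-to-work probability (mean leave 7 days) |

Costs: EUR 500 per sick day, EUR 75,000 per replacement (charged once, at
absorption, with no proration), EUR 550 per participant and year for the
program itself. Cohort: 1,000 nursing staff, 365 cycles, no discounting, no
backfilling of leavers, no indirect or productivity costs.

## Numerical choices

* **Unrounded probabilities.** The kernel is built from the hazard table at
  full floating-point precision; the published 4-decimal transition values
  are a display rounding. The distinction is visible after 365 cycles: the
  probability of an entirely uneventful PSP nurse-year is
  $p_{11}^{365} = 0.997274^{365} \approx 36.9\%$, while the rounded
  $0.9973^{365}$ gives 37.3%.
* **Recovery stored as exactly 1/7**, not 0.1429, because the rate is
  derived from a 7-day mean leave duration.
* **Cost accounting.** The per-person scenario cost excludes the PSP fee, so
  the gross saving (EUR 14,078 − 7,406 ≈ 6,672) matches the published
  table's arithmetic; the net figure (gross − 550) is reported alongside.
  Reports display integer day/dropout counts, but every computation uses the
  unrounded expectations (143 × 75,000 would not reproduce the published
  dropout cost; the unrounded 14.26% does).
* **Row-stochasticity** is validated at 1e−12 and occupancy normalisation at
  1e−10; a path-enumeration oracle (all $3^h$ state sequences, capped at
  horizon 8 to keep enumeration sub-second) pins the engine to 1e−12 on
  small horizons.

## Trajectory simulation and the sensitivity analysis

`simulate_trajectories()` draws individual nurse-years: one categorical draw
per day from the current state's kernel row, stopping at absorption. The
HIE-related cost of a trajectory is
`sick_days * cost_per_sick_day + quit * cost_per_quit`; the PSP fee is not
part of it, so a trajectory is cost-free exactly when it never leaves the
unaffected state — the analytic check $p_{11}^{365}$ (29.0% without PSP,
36.9% with) that the simulator must and does reproduce.

The probabilistic sensitivity analysis (`run_psa()`) repeats the comparison
under parameter uncertainty. For each of `n_pairs` pairs, every hazard and
both HIE cost parameters are drawn from a normal distribution centred on the
base value with a standard deviation of 10% of that value, truncated at zero
(and at one for probabilities) **by rejection rather than clipping** —
clipping would pile probability mass onto the boundary, while the stated
lower bound reads as a support constraint. At the base case every mean is at
least ten standard deviations from zero, so truncation bias is negligible.

Two design questions the published description leaves open were resolved as
follows and are exercised by the tests:

* **Arm coupling.** A pair is one coherent "possible world", so parameters
  whose base values coincide in both scenarios (HIE incidence, low-impact
  day-off hazard, recovery rate, the two costs) take a single shared draw
  per pair; hazards whose base values differ between scenarios — including
  the low-impact quit hazard, 0.0003 vs 0.0001 — are drawn separately around
  their own bases. Full independence would inflate the variance of the
  paired cost differences; common random numbers for the trajectory noise
  would go beyond what the description supports, so only the parameters are
  coupled and the two arms' trajectory randomness stays independent.
* **Perturbation granularity.** Hazards are perturbed, not the derived
  kernel entries, so each perturbed kernel remains row-stochastic by
  construction; rows that still turn out infeasible
  ($p_{12} + p_{13} > 1$, unreachable in practice at these values) are
  redrawn.

Per-arm summaries are the zero-cost fraction and the empirical 95% cost
quantile (linear-interpolation definition, R's default type 7).

## The robustness test

`signed_rank_test()` is a one-sided Wilcoxon signed-rank test of whether
no-PSP costs exceed PSP costs, built for this pairing: zero differences are
discarded, tied absolute differences receive mid-ranks, and the one-sided
p-value is exact for up to 25 nonzero differences (dynamic programming over
the mid-rank sum distribution, so ties are handled exactly) and otherwise
uses the normal approximation with tie-corrected variance and a continuity
correction. `stats::wilcox.test` serves as an independent cross-check in the
untied cases it covers, and a brute-force enumeration of all $2^n$ sign
assignments verifies the exact branch in the tests.

The `shift` argument adds a uniform handicap to every PSP-arm cost before
differencing; `find_break_even_shift()` locates, by bracketing and bisection
to EUR 0.50, the largest handicap at which the test still rejects at
$\alpha = 0.05$. The p-value is nondecreasing in the shift (asserted on a
shift grid in the tests), so bisection is valid. A shift that annihilates
every difference carries no evidence against the null and counts as failure
to reject.

## Reproducibility

All randomness flows through R's global RNG: simulations draw one uniform
vector per cycle in a fixed order, so a single `set.seed()` makes every
trajectory, PSA run and report byte-reproducible. Per-trajectory RNG
sub-streams were considered and rejected: in this single-threaded engine
they buy nothing over a fixed draw order and would cost a reseed per
trajectory.

## Worked example

```{r base-case}
res <- run_base_case(base_case_parameters())
table3_report(res$no_psp, res$psp)
res$comparison
```

```{r psa, eval = FALSE}
bc <- base_case_parameters()
set.seed(1)
psa <- run_psa(bc$no_psp, bc$psp, bc$costs, bc$config,
               n_pairs = 100000, cv = 0.10)
psa
find_break_even_shift(psa$pairs$cost_no_psp, psa$pairs$cost_psp)
```

## Problem sizes

The deterministic evaluation is a 365-step product of a 3-vector with a 3×3
matrix and runs in milliseconds. The test suite validates the simulator at
20,000 trajectories and the sensitivity analysis at 10,000 pairs — enough
for three-binomial-standard-error checks of the published fractions — while
the `analysis/03_psa.R` driver runs the full 100,000 pairs (about ten
seconds) as the package's reference sensitivity analysis.

## What the generator does and does not emulate

The synthetic inputs are the model's own parameter draws: the package
emulates parameter uncertainty (normal, 10% CV, zero-truncated), not
real-world absence records. Real sick-leave data would show weekday and
seasonal structure, contagion between colleagues, heterogeneous individual
risks and duration-dependent recovery — none of which the time-homogeneous,
individually independent chain represents. Passing tests therefore show
internal consistency of the model and faithful reproduction of its published
consequences, not external validity of the hazard estimates.

## Limitations

Beyond the generator's simplifications: departed staff are not backfilled
within the year, costs are undiscounted and linear, the PSP effect is a
fixed hazard reduction rather than an uptake-dependent one, and indirect
costs (productivity, care quality) are excluded by design, which makes the
reported savings conservative in the model's own terms.
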
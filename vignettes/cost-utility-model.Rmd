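---
title: "A weekly-cycle Markov cost-utility model for biomarker-guided pediatric asthma care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A weekly-cycle Markov cost-utility model for biomarker-guided pediatric asthma care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asthmaCUA)
```

This vignette is the package's account of its science: the decision model
and its assumptions, the parameters that matter, the calibration that closes
the gaps the source tables leave open, the probabilistic machinery, and the
limits of what the bundled replication can and cannot reproduce.

## The decision problem and the model

Children (4–18 years) with mild-to-moderate persistent asthma on low-dose
inhaled corticosteroids can have their therapy stepped up or down on the
basis of an airway-inflammation biomarker — the eosinophil count in induced
sputum (EO) or fractional exhaled nitric oxide (FeNO) — or on clinical
symptoms alone (standard care). The question is which strategy buys health
most efficiently in a middle-income setting, measured in quality-adjusted
life years (QALYs) against a willingness-to-pay of 5180 USD per QALY.

The model is a three-state Markov cohort: **W** (well-controlled), **S**
(sub-optimal control without exacerbation), **A** (asthma exacerbation).
All states communicate; none is absorbing. Cycles are one week; the horizon
is 52 cycles (12 months), so no discounting is applied. The whole cohort
starts in W. Weekly transition probabilities (off-diagonals; stays are
derived as complements):

```{r}
replication_params()$params$transition
```

Annual utility weights are W 0.99, S 0.70, A 0.31; each cycle in a state
accrues `utility/52` QALYs. A biomarker strategy acts through a relative
risk on the transitions *into* A (EO RR = 0.57, FeNO RR = 0.76): each entry
probability is multiplied by the RR and the removed mass is credited back
to the source state's stay probability — an averted exacerbation leaves the
patient where they were, rather than redistributing them proportionally
across destinations. An alternative scope that also scales W→S
(`rr_scope = "A_and_S_entry"`) is available because the RR's reach is a
genuine modelling unknown; the calibration (below) selects the scope by
residual and settles on A-entry only.

Costing is societal: each state carries a per-cycle cost (direct medical
plus indirect caregiver-productivity cost), and biomarker arms add
`test price × tests per year / 52` per cycle (EO 9.14, FeNO 2.20 USD per
administration). No half-cycle correction is applied: with 52 cycles the
correction is bounded by half of one cycle's accrual (&lt; 1% of the annual
total, far below the reporting precision of the targets), and costs and
utilities are credited to the state occupied during the cycle with
transitions effective at cycle end. The microsimulator
(`simulate_patients()`) uses the identical convention, which makes the
cohort-versus-microsimulation agreement test exact in expectation rather
than approximate.

## Calibration: closing the specification gap

The published analysis reports its arm-level results — annual cost and
QALYs per arm (1376/0.95 EO, 1334/0.94 FeNO, 1453/0.92 standard) and an
EO-vs-FeNO ICER of 3566 USD/QALY — but not the per-state costs, the testing
frequency, nor how the RR is applied. `calibrate_cua()` therefore fits
`c(c_W, c_S, c_A, tests_per_year)` by minimising squared *relative*
residuals of each arm's cost and QALY, with the published ICER as an
additional soft residual. Because arm cost is linear in the free
parameters, each candidate RR scope yields an exact bounded least-squares
problem; the scope with the smallest total objective (including the
QALY residuals, which the free parameters cannot move) is kept.

Three numerical choices matter and are deliberate:

* **Bounds.** Costs are non-negative; the exacerbation-week cost is capped
  at a week of intensive care plus ancillary daily costs (~3700 USD), and
  testing at one administration per weekly cycle. These are plausibility
  bounds from the reported cost components, not fitted quantities.
* **Ridge anchor.** The three arm-cost equations are nearly collinear
  (state occupancies barely differ across arms), so the design is
  rank-deficient: rank 3 for 4 free parameters. A tiny relative ridge
  (1e-6) toward the anchor (25, 50, 400 USD/cycle, 12 tests/year —
  order-of-magnitude clinical plausibility: cheap controller weeks,
  moderately costly sub-optimal weeks, hospital-scale exacerbation weeks,
  roughly monthly testing) resolves the null space deterministically. The
  fit prints its design rank so the deficiency is surfaced, never hidden.
* **Convergence.** `converged` means the optimiser reached the objective's
  minimum; whether each target lies within its printed rounding half-width
  is reported separately (`within_tolerance`), because for this model the
  two cannot coincide (next section).

The frozen result — `c_W = 13.55`, `c_S = 44.95`, `c_A = 914.9` USD per
cycle, `16.6` tests/year, A-entry-only scope — ships as
`inst/extdata/replication-config.yaml`; re-loading it reproduces the
fit-time outputs bit-identically.

## What the replication can and cannot reproduce

With the transition matrix and utilities fixed at their published values,
the QALY gap between EO and FeNO is structurally at most ~0.007 (W→S
scope) and ~0.0015 (A-entry scope) — whereas the published cost difference
(42.3 USD) combined with the published ICER (3566) implies a gap of
~0.0119. The published arm costs, arm QALYs, ICER and INMB are therefore
*mutually inconsistent* under any configuration of this model class, and
the calibration has to choose. The least-squares objective above resolves
the tension by matching the ICER almost exactly (3566.2) at the expense of
~1.4% shifts in the two biomarker arms' costs (1357 and 1352 USD versus
1376 and 1334 printed) and of QALY levels that sit ~0.01 above their
printed values. Standard care's cost (1453) is matched exactly and it
remains strictly dominated, as published.

The same inconsistency propagates to the probabilistic results: the
published mean incremental NMB (60 USD) is irreconcilable with the
published ICER and QALY gap (0.0119 × (5180 − 3566) ≈ 19), and the
published per-arm PSA confidence intervals of ~1 USD width contradict the
published quadrant spread of the incremental cloud. The package's PSA on
the frozen configuration yields a probability of ~0.35 that EO is
cost-effective versus FeNO at 5180 USD/QALY, a mean INMB of ~30 USD, and a
largest quadrant share of ~40% — internally consistent with the frozen
deterministic base case, but not with every published summary at once. The
acceptance tests assert the published values as printed and are expected
to stay red on exactly these items; nothing is loosened to mask the
discrepancy.

## Probabilistic sensitivity analysis

Each PSA replicate draws one shared parameter realisation and evaluates
every arm on it (common random numbers: uncertainty is parametric, arms
differ only via RR and testing stream):

* utilities ~ beta, moment-matched to mean/SD
  (`α = m(m(1−m)/s² − 1)`, `β = α(1−m)/m`); infeasible combinations
  (s² ≥ m(1−m)) fail validation by name;
* costs ~ gamma (`shape = (m/s)²`, `scale = s²/m`); the fitted state costs
  carry a CV of 0.10, matching the reported daily ward cost's CV
  (8.53/95.05), the dominant component of a hospitalised week;
* relative risks ~ lognormal on the natural scale
  (`σ² = log(1+s²/m²)`, `μ = log m − σ²/2`), drawn independently per arm;
  the reported SDs are 0.20 (EO) and 0.274 (FeNO);
* transition rows ~ Dirichlet, one concentration per source state anchored
  so the largest-SD off-diagonal component's marginal-beta SD matches its
  reported value (`N = m(1−m)/s² − 1`, `αᵢ = mᵢN`); rows are sampled by the
  gamma construction and are exactly row-stochastic, with structural zeros
  preserved.

Zero-SD priors are point masses, so a zero-variance configuration collapses
the PSA onto the deterministic base case — a property the tests exercise.
All randomness flows from a single integer seed; identical seeds give
bit-identical PSA objects.

Summaries: the incremental cloud (ΔQALY, ΔCost) for a chosen pair;
quadrant shares in the mathematical counter-clockwise convention
(Q1 = +ΔQALY,+ΔCost), boundary points assigned to the positive side, with
sign labels attached so any numbering convention can be read off; and the
CEAC, where at each threshold a strategy's probability is the fraction of
replicates in which it attains the highest NMB, exact ties sharing a
replicate equally (so probabilities always sum to one). The default WTP
grid spans 0–15,000 USD/QALY in 101 steps and contains 5180 exactly.

## One-way sensitivity analysis

`owsa()` moves one parameter at a time to the ends of its range,
re-evaluates deterministically, and records the EO-vs-FeNO ICER and the
highest-NMB strategy. Test costs use their reported ranges (EO 5.15–13.20,
FeNO 1.20–4.20); utilities, transition probabilities, RRs and state costs
use ±25% of the base case, as the source analysis did for inputs without a
reported range. Probabilities are additionally capped so the source row
stays on the simplex (a transition can grow only by what the stay
probability can absorb); ranges reported inverted are normalised to
(min, max) with a warning, and the one internally inconsistent reported
range (nebulisation, 1.28–1.45 against a base of 16.23) is replaced by the
±25% default, since it does not bracket its own base value. Note that with
the calibrated configuration the deterministic NMB margin between EO and
FeNO is only ~2 USD, so single-parameter excursions *can* flip the NMB
ordering even though the published analysis reports rank stability — one
more facet of the inconsistency discussed above.

## Synthetic data and what the tests do (and do not) show

`make_toy_model()` generates random valid parameter sets — Dirichlet
transition rows, utilities in [0,1], gamma costs, strategies with
spread-out RRs capped so no adjusted row leaves the simplex — used for
property-based tests (mass conservation, frontier invariants, calibration
recovery). `simulate_patients()` is a first-order microsimulator that
validates the cohort engine against individual-level sampling at
n = 10⁵ within three standard errors.

These fixtures emulate the *structure* of the study inputs (distribution
families, simplex geometry, the printed moments), not real Colombian
patients: there are no covariates, no severity strata, no seasonality, no
correlation between costs and utilities beyond state membership. Passing
tests therefore certify the arithmetic and the Monte Carlo machinery, not
the external validity of the inputs.

Problem sizes used by the test suite — 10⁴ random chains for mass
conservation, 3-cycle path enumeration (3⁴ paths), 10⁵ draws per prior,
10⁵ microsimulated patients, 1000 PSA replicates, 20 calibration-recovery
ground truths — were chosen so each check resolves well below its assertion
tolerance.

## Known limitations

* The replication inherits every inconsistency of its published targets;
  the package reproduces the ICER, dominance structure and rounding-level
  QALYs, but no configuration of this model class reproduces all printed
  numbers simultaneously (details above).
* The 12-month horizon follows the trial evidence for biomarker-guided
  care; nothing is claimed beyond it, and the no-discounting choice is only
  valid at this horizon.
* Calibrated state costs are aggregates; the reported cost components
  enter only as plausibility bounds, not as a bottom-up costing.
* The RR is treated as acting on exacerbation entry each week,
  independently per arm in the PSA; head-to-head correlation between the
  two biomarkers' effects is unknown and not modelled.
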
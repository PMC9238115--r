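# asthmaCUA

Cost-utility analysis of biomarker-guided management of persistent childhood
asthma (ages 4–18), built as a reusable, fully tested R implementation of a
three-state Markov cohort model. It compares three strategies for titrating
inhaled corticosteroids:

* **EO** — therapy tailored on the eosinophil count in induced sputum,
* **FeNO** — therapy tailored on fractional exhaled nitric oxide,
* **standard** — adjustment on clinical symptoms with or without
  spirometry/peak flow.

The audience is health-economics and HTA analysts who want the published
Colombian base case reproducible end to end, and a general weekly-cycle
Markov cost-utility engine they can re-parameterise.

## Model

States are *W* (well-controlled), *S* (sub-optimal control) and *A*
(asthma exacerbation); cycles are weekly over a 12-month horizon (52
cycles), undiscounted, societal perspective. The cohort starts in *W* and
evolves by a row-stochastic matrix *P*; a biomarker strategy multiplies the
transitions into *A* by its relative risk *RR* (EO 0.57, FeNO 0.76), the
averted probability staying on the source state's diagonal. Each cycle
accrues `u(state)/52` QALYs and `c(state) + test cost × tests/52` USD.
Comparisons use

* ICER = ΔC/ΔE between adjacent arms on the cost-ordered frontier
  (strict, then extended dominance),
* NMB = E·λ − C and INMB at the willingness-to-pay λ = 5180 USD/QALY,
* a 1000-replicate second-order Monte Carlo PSA (utilities ~ beta,
  costs ~ gamma, RRs ~ lognormal, transition rows ~ Dirichlet, all
  moment-matched to the reported means/SDs), summarised as a
  cost-effectiveness plane, quadrant shares and CEAC.

Per-state costs and the testing schedule are not reported in the source
tables; `calibrate_cua()` fits them to the published arm-level results by
bounded least squares (with the published EO-vs-FeNO ICER as a soft
constraint) and the frozen result ships as
`inst/extdata/replication-config.yaml`. See the methods vignette
(`vignettes/cost-utility-model.Rmd`) for every modelling choice and known
limitation, including which published figures cannot be reproduced jointly.

## Worked example

```r
library(asthmaCUA)

rp  <- replication_params()          # frozen calibrated configuration
fit <- cua(rp$params, rp$config)     # deterministic base case
fit
#> Cost-utility analysis: 3 strategies, 52 weekly cycles, WTP 5180 USD/QALY
#>
#>  strategy cost  qaly  NMB      ICER    status
#>      FeNO 1352 0.954 3589     (ref)  frontier
#>        EO 1357 0.955 3591      3566  frontier
#>  standard 1453 0.952 3478 dominated dominated
```

Standard management costs the most (1453 USD/patient/year) while gaining
the fewest QALYs, so it is strictly dominated. EO buys its extra QALYs over
FeNO at 3566 USD each — below the 5180 USD/QALY threshold, so EO has the
highest net monetary benefit. Uncertainty propagates with `simulate()`:

```r
psa <- simulate(fit, nsim = 1000, seed = 1)   # second-order Monte Carlo
inc <- psa_increments(psa, c("EO", "FeNO"))
mean(inc$inmb > 0)        # 0.354  probability EO is cost-effective vs FeNO
mean(inc$inmb)            # 30.4   mean incremental NMB (USD)
ceac(psa)                 # acceptability curve over a 0-15,000 USD/QALY grid
quadrant_shares(psa)      # CE-plane quadrant shares (Q1 = +QALY, +cost)
```

One-way sensitivity analysis over the reported ranges (±25% where no range
is printed): `owsa(rp$params, rp$config)`. A command-line driver with
subcommands `run`, `psa`, `owsa`, `ceac`, `calibrate`, `fixtures`,
`validate` lives at `inst/cli/cua.R`.

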
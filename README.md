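# readmitopt

Chance-constrained care-strategy optimization for hospitals facing
readmission penalties.

Under policies like the U.S. Hospital Readmission Reduction Program (HRRP),
a hospital whose risk-adjusted readmission rate exceeds its peer group's
median is docked a share of all its reimbursements. `readmitopt` helps a
hospital decide, per condition and per expected patient, which treatment
plan to fund — expensive Tier-1 interventions that cut readmission risk
hard, or cheaper lower-tier care — so that total cost is minimized while the
mean readmission probability stays below a target with a chosen confidence
level.

## The model in brief

For each condition $c$ with target rate $\theta_c$, patients $P_c$, plans
$K_c$ and scenarios $\omega$, the package solves

$$\min\ \sum_\omega p(\omega) \sum_{c,p,k} a_{pkc}(\omega) x_{pkc}(\omega)
  + \sum_c (1-\beta_c) R_c \cdot \text{Penalty}$$

subject to one plan per patient and, per condition and scenario, the chance
constraint
$\Pr[\frac{1}{|P_c|}\sum_{p,k} \mu_{pkc} x_{pkc} \le \theta_c] \ge \beta_c$,
where plan responses are Gaussian,
$\mu_{pkc} \sim N(\hat\mu_{pkc}, \lambda_c \hat\mu_{pkc})$. The chance
constraint is replaced by its exact deterministic equivalent
$\sum \hat\mu_{pkc} x_{pkc} \le \mu^*_c$, with $\mu^*_c$ the unique positive
root of $\theta_c|P_c| - m = \sqrt{\lambda_c m}\,\Phi^{-1}(\beta_c)$
(closed form in `deterministic_threshold()`, Monte-Carlo-verified by
`chance_coverage_oracle()`). Each (condition, scenario) subproblem is a
multiple-choice knapsack, solved exactly by a C++ branch-and-bound with an
LP-relaxation bound. See the methods vignette
(`vignettes/care-strategy-model.Rmd`) for assumptions, generator design and
numerical contracts.

## Worked example

Two instances built from public data are packaged: hospital "A"
(low-performing: five of six conditions above target) and "B"
(high-performing: one exceedance).

```r
library(readmitopt)

spec <- example_hospital_spec("A")
scen <- generate_scenarios(spec, n_scenarios = 50, generator_settings(seed = 1))

max_feasible_beta(scen, spec)$overall
#> [1] 0.95

sol <- solve_dem(scen, beta = 0.8, spec)
sol
#> <care_strategy_solution> objective $5873366.54 = expected cost $5749366.54 + expected penalty $124000.00

baseline_costs(spec)
#> $no_penalty   7252452      $with_penalty   7872452
```

At 80% confidence the optimal strategy costs $5.87M against a current
baseline-plus-penalty of $7.87M: the hospital could hit its targets with
80% confidence *and* spend less than it does today. The strategy itself:

```r
tier_shares(sol, spec)
#>   condition    tier1    tier2     tier3
#>   AMI        46.3     41.5     12.2
#>   PN         29.7     47.3     23.0
#>   HF         14.5     44.3     41.2
#>   HK          0.0      0.0    100.0
#>   COPD       16.2     44.7     39.1
#>   CABG       38.8     43.4     17.8
```

AMI — the condition furthest above its target — demands the most Tier-1
care, while HK, already far below target (4.2% vs 8.0%), is served entirely
by cheap Tier-3 plans. `mean_readmission_summary(sol, spec)` shows every
penalized condition pulled below its target (e.g. AMI 13.8% against the
15.97% target), and `beta_sweep(spec, scen)` tabulates the whole
cost/confidence frontier. `required_scenario_count(156721.15, 0.99, 150)`
returns 47, justifying 50 scenarios for this instance.

A command-line wrapper covers the same workflow
(`generate`, `solve`, `sweep`, `validate-target`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","readmitopt.R",package="readmitopt"))')" \
  sweep --spec hospital.yaml --seed 1 --scenarios 50 --out results/
```

## Validating the target choice

Penalties are legally tied to the peer-median ERR, but care strategies need
a plan-linked target; the mean readmission probability stands in for it.
`label_records()` + `confusion_summary()` quantify how well the mean-based
split agrees with the median-ERR split on a peer-group records table (the
public HRRP supplemental layout), and `synth_peer_records()` generates
synthetic tables with a tunable ERR-probability correlation for testing —
accuracy is exactly 100% under a perfectly monotone link and ~50% under
independence.

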
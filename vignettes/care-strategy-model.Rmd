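---
title: "Chance-constrained care strategies under readmission penalties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chance-constrained care strategies under readmission penalties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readmitopt)
```

## The decision problem

Hospitals operating under a readmission-penalty policy (the U.S. HRRP is the
motivating case) face a portfolio decision every planning period: for each
penalized condition and each expected patient, pick one treatment plan from a
menu that trades cost against effectiveness. Plans are grouped into tiers —
Tier 1 is intensive and expensive (e.g. a transition coach) and reduces the
probability of a 30-day readmission the most; the last tier is cheap (e.g.
medication reconciliation alone) and reduces it least. The hospital wants the
cheapest *care strategy* (one plan per patient) that still keeps its mean
readmission probability below a target — typically the mean readmission rate
of its CMS peer group, since penalties are assessed against peers — and it
wants that guarantee to hold with a chosen confidence level, because patient
responses are stochastic.

`readmitopt` implements this as a scenario-based stochastic program with a
probabilistic (chance) constraint per condition, converted to a deterministic
equivalent and solved exactly.

## Model

Let $c$ index conditions, $p \in P_c$ patients, $k \in K_c$ plans, and
$\omega$ scenarios with probabilities $p(\omega)$ summing to one. Scenario
data are plan costs $a_{pkc}(\omega)$ and estimated plan readmission means
$\hat\mu_{pkc}(\omega)$. With binary assignment variables $x_{pkc}(\omega)$
(exactly one plan per patient), the objective minimizes expected treatment
cost plus the expected penalty:

$$\min \; \sum_\omega p(\omega) \sum_{c,p,k} a_{pkc}(\omega)\, x_{pkc}(\omega)
  \;+\; EP(\beta),$$

subject to, for every condition and scenario, the chance constraint that the
average realized readmission mean stays at or below the target $\theta_c$
with probability at least $\beta_c$:

$$\Pr\!\left[\tfrac{1}{|P_c|}\textstyle\sum_{p,k} \mu_{pkc}(\omega)
  x_{pkc}(\omega) \le \theta_c\right] \ge \beta_c .$$

The realized response $\mu_{pkc}(\omega)$ of a treated patient is modelled as
Gaussian around the selected plan's estimate, independent across patients,
with variance proportional to the estimate:
$\mu_{pkc}(\omega) \sim N(\hat\mu_{pkc}(\omega),\,
\lambda_c \hat\mu_{pkc}(\omega))$.

### Deterministic equivalent

Because a sum of independent Gaussians is Gaussian with mean
$m = \sum \hat\mu\, x$ and variance $\lambda_c m$, the chance constraint is
equivalent to the algebraic cap $m \le \mu^*_c$, where $\mu^*_c$ is the
unique positive root of

$$\theta_c |P_c| - m \;=\; \sqrt{\lambda_c m}\; \Phi^{-1}(\beta_c).$$

Substituting $s = \sqrt m$ gives a quadratic in $s$ whose two roots multiply
to $-\theta_c|P_c| < 0$, so exactly one is positive and the closed form

$$\mu^* = \left(\frac{-\sqrt\lambda\, z + \sqrt{\lambda z^2 +
  4\theta|P|}}{2}\right)^{\!2}, \qquad z = \Phi^{-1}(\beta),$$

is exact ([`deterministic_threshold()`]). At $\beta = 0.5$ the cap is
$\theta|P|$ exactly; it decreases strictly in $\beta$. The package verifies
the equivalence two independent ways: a bracketed bisection on the defining
equation (`threshold_bisection()`, agreement to 1e-10 relative) and a
Monte-Carlo oracle (`chance_coverage_oracle()`) that draws the *untruncated*
Gaussian responses exactly as the conversion assumes and checks that a
selection placed at the cap attains coverage $\beta$ within Monte-Carlo
error.

A note on $\lambda$: the quantity is described as a coefficient of
variation in the surrounding literature but enters the conversion as a
variance scale (variance $= \lambda \hat\mu$). The conversion follows the
mathematics; see below for the different role $\lambda$ plays in the
scenario generator.

### Expected penalty

The expected penalty spreads the hospital's annual penalty over conditions
in proportion to expected spend, weighted by the probability of missing each
target: $EP(\beta) = \sum_c (1-\beta_c) R_c \cdot \text{Penalty}$ with
$R_c = |P_c|\bar a_c / \sum_{c'} |P_{c'}|\bar a_{c'}$ and $\bar a_c$ the
analytic triangular mean plan cost $(\min + \text{mode} + \max)/3$. The
analytic mean (not an empirical scenario mean) is the default because the
penalty model describes the hospital's cost structure, not a particular
draw; an empirical switch exists in `cost_shares()`. The annual penalty is
deliberately *not* prorated to the (default three-month) decision period:
no defensible proration rule exists without knowing how the hospital books
the penalty, so the figure is passed through as supplied and users can scale
it themselves.

## Scenario generator

The generator (`generate_scenarios()`) emulates the inputs a hospital would
assemble from public data:

* **Baselines.** Each patient draws a baseline readmission mean from a
  Gaussian centred at the hospital's condition mean $\mu_c$ with standard
  deviation $\lambda_c \mu_c$ — here $\lambda$ acts as a coefficient of
  variation. This keeps the grand mean of baselines anchored at $\mu_c$ and
  makes the (0.001, 0.999) resampling truncation essentially inactive. Had
  $\lambda\mu$ been used as a *variance* at these parameter values
  (rates of 0.03–0.25, $\lambda = 0.25$), the standard deviation would reach
  0.1–0.24 and the truncation would bias every baseline mean upward by
  0.05–0.07, detaching the instances from the rates they are meant to
  emulate; the conversion layer is unaffected by this choice since it
  operates on whatever $\hat\mu$ the scenarios carry.
* **Plan means.** Each plan multiplies the patient baseline by a uniform
  draw from its tier's multiplier range — defaults (0.4, 0.7), (0.7, 1.0),
  (1.0, 1.3) for Tiers 1–3. The ranges are a design choice (no public source
  links tiers to effect sizes); they enforce the qualitative tier ordering
  in expectation, keep the condition mean as the anchor, and are fully
  configurable for calibration. Results are clipped to the probability
  bounds.
* **Costs.** Plan costs are i.i.d. draws from the condition's triangular
  distribution (the low/fair/high price triple), sorted in decreasing order
  across the plan index so Tier 1 is the expensive end. Sorting realizes the
  anti-correlation between cost and readmission without inventing a joint
  distribution; it can be disabled.
* **Weights and reproducibility.** Scenario weights are equal
  ($1/|\Omega|$); nothing in the emulated experiments suggests unequal
  weighting. One named RNG stream is derived per (condition position,
  scenario), so enlarging the scenario set or appending conditions never
  reshuffles existing draws.

What the generator does **not** emulate: correlation across conditions or
across patients, risk adjustment (ERR internals), time dynamics within the
period, or cost-effect correlation beyond the tier structure. Tests passing
on synthetic scenarios therefore demonstrate correctness of the machinery
and qualitative economics, not calibration to any real hospital.

The scenario-set size can be chosen with `required_scenario_count()`, the
classic normal-approximation sample-size bound
$n > z_{\alpha/2}^2 s^2/\epsilon^2$ seeded with a pilot variance. With the
pilot variances used in the packaged experiments (156,721.15 and 81,246.64
squared dollars at 99%/$150) it returns 47 and 24, supporting the round
choice of 50 scenarios.

## Exact assignment solver

For fixed thresholds the model decomposes completely: the objective is
separable and no constraint couples conditions or scenarios, so each
(condition, scenario) pair is an independent *multiple-choice knapsack* —
pick one plan per patient, minimize cost, keep $\sum \hat\mu \le \mu^*$.
Instances are small (at most ~132 patients x 10 plans), so they are solved
exactly by branch-and-bound (`solve_condition_scenario()`, in C++):

* per-patient dominance filtering that respects the tie-break contract;
* an LP-relaxation bound from per-patient convex hulls in
  ($\hat\mu$, cost) space, walked in global slope order;
* a greedy initial incumbent (whole hull segments in slope order until
  feasible), at most one segment above the LP optimum, so pruning is tight
  from the root;
* depth-first search over patients in index order with plan-index
  tie-breaking: among equal-cost optima the lexicographically smallest plan
  assignment is returned, making results reproducible bit-for-bit.

Numerical contracts: the capacity constraint is enforced to 1e-9 absolute;
cost comparisons use 1e-9 relative tolerance; infeasibility is decided by
the exact screening $\sum_p \min_k \hat\mu_{pk} > \mu^*$ and reported with
its margin. An exhaustive-enumeration oracle (`brute_force_oracle()`)
implements the identical contract and backs the property tests (hundreds of
random small instances, equality including infeasibility verdicts).

Degenerate inputs: $\theta|P| = 0$ forces $\mu^* = 0$ (flagged degenerate);
a zero-width triangular distribution is allowed (constant costs); ties in
cost or mean are resolved toward lower plan indices at every level.

The feasibility frontier $\beta^*$ (`max_feasible_beta()`) uses the same
screening per grid point rather than full solves — necessary and sufficient
for the cap constraint, hence the identical answer at a fraction of the
cost. Feasibility is monotone (the cap shrinks in $\beta$), so $\beta^*$ is
well-defined per condition; the overall $\beta^*$ is the minimum over
conditions, read per scenario (every scenario must admit an assignment — the
conservative reading of the per-scenario constraint).

## Reporting

`beta_sweep()` tabulates, per confidence grid point (default 0.50–0.95 in
steps of 0.05 plus 0.98, the range the experiments explore): expected
treatment cost, expected penalty, their sum, both baselines
(`baseline_costs()`: expected spend without the policy, and with the annual
penalty added), per-condition mean readmission, and the tier mix of the
chosen strategy. Two structural monotonicities hold exactly and are tested:
expected cost is non-decreasing and the selected-mean sum non-increasing in
$\beta$ (the feasible region shrinks), while the expected penalty falls
linearly.

The mean-readmission summary divides the scenario-averaged sum of selected
means by $|P_c|$ so the number is directly comparable with $\theta_c$ and
with the hospital's own rate; the raw sum is kept as an auxiliary column.
(The raw-sum form appears in the source formulation, but its figures plot on
the rate scale, which is only consistent with the per-patient
normalization.)

Single-condition sweeps hold the remaining conditions at their own
$\beta^*_c$ by default (configurable), mirroring how condition-specific
trade-off curves are usually drawn.

## Target validation

The penalty rule compares a hospital's excess readmission ratio (ERR) with
its peer group's *median*; a practical care-strategy target needs a direct,
plan-linked measure, and the mean readmission probability is the candidate.
`label_records()` reproduces both classifications on a peer-group records
table (public HRRP supplemental layout): *actual* = ERR strictly above the
stratum median, *predicted* = readmission probability strictly above the
stratum mean, computed within each (peer group, condition) stratum and
pooled per peer group by `confusion_summary()`. Strict inequalities mirror
the policy's "greater than the median" phrasing — a hospital exactly at the
threshold is not penalized. Strata with fewer than two records are excluded
and reported. Accuracy is $(TP+TN)/N$ and the misclassification rate is its
exact complement.

Reproducing the published per-group accuracies requires the real CMS file
(an external download), so the module ships a clearly-synthetic generator
(`synth_peer_records()`): lognormal ERR around 1, probabilities coupled
through a Gaussian copula with correlation $\rho$, an affine link around
condition-typical rates with spread proportional to the rate, and latent
scores clamped symmetrically at $\pm 3$. Latent draws come in antithetic
(sign-symmetrized) pairs per stratum — hence the even-count requirement —
which pins the sample mean of the probability column exactly at the stratum
centre. Under a perfectly monotone link ($\rho = 1$) the strict mean-split
then coincides with the strict median-split record-for-record, so accuracy
is exactly 100%; at $\rho = 0$ it is 50% up to Monte-Carlo error. Realistic
intermediate correlations give accuracies in the 75–85% range, the same
order as the published per-group values.

## Problem sizes used in the tests

The packaged experiments run at the published scale: 50 scenarios per
hospital, six conditions, 7–132 patients per condition, 10 plans in a
3/4/3 tier split, confidence grid 0.50–0.98. The Monte-Carlo equivalence
checks use 200,000 draws per configuration; solver-vs-enumeration checks
use hundreds of instances with up to 4 patients and 3 plans (the
enumeration oracle's tractable range). A full two-hospital acceptance run
(`scripts/acceptance.R`) completes in well under a minute on one core.

## Known limitations

* The Gaussian response model can, in principle, realize probabilities
  outside [0, 1]; the conversion inherits this from its normality
  assumption. The generator truncates; the conversion and its oracle,
  deliberately, do not.
* The penalty model is a first-order approximation: a constant annual
  figure split by spend shares and failure odds, not a re-derivation of the
  policy's percentage-of-reimbursement mechanics.
* No coupling constraints (shared budgets, staff) across conditions, no
  multi-year dynamics, no competition between hospitals.
* $\beta^*$, tier mixes and dollar savings depend on the generator's
  multiplier ranges; only the qualitative shapes (monotone trade-offs, flat
  lines for conditions already beating their target, more Tier-1 demand for
  low-performing hospitals) are stable reproduction targets.
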
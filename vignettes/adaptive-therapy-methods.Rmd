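---
title: "Methods: patient-calibrated tumor dynamics and adaptive therapy scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-calibrated tumor dynamics and adaptive therapy scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptherapy)
```

## The models and their assumptions

The package describes a tumor as two well-mixed cell populations sharing
one resource pool: drug-sensitive cells $S$ and drug-resistant cells $R$,
both carried in LDH-equivalent units (U/L) so that serum LDH can be
modeled directly as $\mathrm{LDH}(t) = \mathrm{basal} + S(t) + R(t)$ with
a basal normal-tissue contribution of 100 U/L. Time is measured in months
and all rate constants are per month.

**Lotka–Volterra competition (LV).** Two genetically fixed populations
compete for a shared carrying capacity $K$:

$$\frac{dS}{dt} = r_S\left(1 - \frac{S+R}{K}\right)S - \delta S,
\qquad
\frac{dR}{dt} = r_R\left(1 - \frac{C\,S+R}{K}\right)R.$$

The competition coefficient $C$ scales only the sensitive cells' effect on
resistant growth: $C > 1$ means sensitive cells suppress resistant cells
more strongly than resistant cells suppress themselves, which is the
mechanism adaptive therapy exploits. Note the placement of $C$ inside the
numerator of the resistant crowding term — the $R$-nullcline in the scaled
phase plane is the line $C\bar S + \bar R = 1$ (`nullclines()` returns
exactly this), and with $S = 0$ the resistant population grows logistically
to $K$, not $K/C$.

**Phenotypic switching (SW).** The same competition structure with $C = 1$,
plus reversible state transitions: $S \to R$ at rate $\alpha$ while
treatment is on, $R \to S$ (re-sensitization) at rate $\beta$ while it is
off.

**Treatment gating.** The drug both kills sensitive cells and blocks their
proliferation, so on-treatment the effective parameters are
$(r_S, \delta) = (0, \delta)$ (and $(\alpha, \beta) = (\alpha, 0)$ for SW);
off-treatment they are $(r_S, 0)$ (and $(0, \beta)$). Resistant cells are
unaffected by the drug throughout. Gating is implemented as parameter
substitution per treatment segment — each segment is a smooth ODE and the
state is handed across segment boundaries — rather than as a discontinuous
forcing inside one solve. This keeps threshold-event location accurate.

Phase-plane tools (`nondimensionalize()`, `nullclines()`) use the
dimensionless coordinates $\bar S = S/K$, $\bar R = R/K$, $\tau = r_R t$.
Switching-model nullclines without a convenient closed form are returned as
sampled implicit curves (200 points); the others as exact line descriptors.

## Numerical integration

`simulate_model()` and `run_policy()` integrate with `deSolve::lsoda`
(compiled derivative functions) at `rtol = 1e-8`,
`atol = 1e-10 * K`, both user-configurable. Floating-point undershoot below
zero is clamped to zero **at output only**, never inside the solver state.
Dense output is stored every 0.02 months; `trajectory_at()` interpolates
with per-segment cubic splines, accurate to about $10^{-6}$ relative — the
test suite checks the integrator against exponential-decay and logistic
closed forms at that tolerance and against a fixed-step RK4 reference at
$dt = 10^{-4}$ months on random parameter draws.

## Therapy policies and event detection

`therapy_policy()` encodes three schedules. The adaptive rule stops
treatment when the monitored burden falls to `f_stop` times its initial
value, resumes at `f_resume` (default 1.0: the initial burden itself), and
declares progression at `f_prog` (default 1.5). Thresholds are evaluated by
ODE root finding (`lsoda` with root functions), so stop/resume/progression
events sit on their thresholds to solver precision (≪ $10^{-6}$ months).

Choices the threshold rules leave open, and how they are resolved here:

- **What burden is monitored.** Thresholds apply to total modeled LDH
  (basal + S + R), since clinical rules are stated on the measured LDH
  level. `threshold_on = "tumor"` switches to tumor-attributable burden.
- **The "−20%" stopping criterion** is implemented as `f_stop = 0.8` — a
  20% *reduction* from baseline, i.e. a less aggressive stop than the 50%
  rule, consistent with how the milder criterion behaves as a comparator
  arm. The literal "20% of initial" reading remains available as
  `f_stop = 0.2`.
- **Monitoring cadence.** Event detection is continuous by default; an
  optional `monitor_interval` (e.g. 0.5 months) evaluates thresholds only
  at blood-draw-like check times.
- **Dose-rate denominator.** `cumulative_dose_rate()` divides time on drug
  by the patient's own course length (time to progression, or the horizon
  when censored), because the quantity is interpreted relative to a
  continuous course of the same duration.
- **Censoring.** The default horizon is 60 months, comfortably beyond
  typical continuous-therapy progression plus the largest adaptive gains;
  runs reaching it are censored. Censored adaptive/continuous pairs are
  excluded from mean time-gained maps and counted in a companion column,
  but retained (as censored records) for survival analysis.
- **Degenerate arms.** With $S_0 = 0$ therapy has nothing to act on, LDH
  never reaches the stop threshold, and the adaptive and continuous arms
  coincide; this is asserted in the tests as an exact oracle.

## Calibration

Patient data are longitudinal LDH series under continuous therapy.
`fit_objective()` is the Euclidean norm of (modeled − measured) LDH at the
observation times, with the model run on-treatment throughout. Since
measured LDH includes normal tissue, the initial resistant burden is tied
to the data as $R_0 = \mathrm{LDH}_0 - \mathrm{basal} - S_0$; setting
`basal = 0` reproduces the alternative convention $R_0 = \mathrm{LDH}_0 -
S_0$. Because $r_S$ (and $\beta$ in the SW model) is multiplied by zero
throughout on-treatment data, it is excluded from fitting; therapy
simulations later assign these free parameters as multiples of the fitted
$r_R$ (`assign_free_params()`, defaults $r_S = r_R$,
$\beta = 0.45\,r_R$; sweeps cover $r_S \in [0.05, 2]\,r_R$ and
$\beta \in [0.05, 0.95]\,r_R$).

Fitted vectors are $\theta = \{S_0, K, \delta, r_R, C\}$ (LV) and
$\{S_0, K, \delta, r_R, \alpha\}$ (SW). Default bounds: $S_0 \in (0,
\mathrm{LDH}_0 - \mathrm{basal})$; $K \in [\max L, 20 \max L]$; $\delta,
r_R \in (0, 10]$/month; $C \in [0.5, 3]$; $\alpha \in (0, 5]$/month. These
contain plausible monthly melanoma kinetics and competitive asymmetries;
all are overridable.

**Optimizer.** `implicit_filtering()` is a bound-constrained
derivative-free method: central-difference gradients on a coordinate
stencil of scale $h$ (fraction of the box width), projected BFGS steps with
an Armijo line search, $h$ halved on stencil failure, the scale sequence
terminating at $10^{-6}$ of the box width and restarting from the incumbent
while budget remains. It is deterministic given the start point, and its
best-so-far trace is monotone. `multistart_fit()` launches it from a
seeded Latin-hypercube of starts — rate-like parameters ($\delta$, $r_R$,
$\alpha$, $K$) are sampled *and searched* in log-space so slow and fast
kinetics are resolved equally — and then polishes the top-ranked fits with
a bounded quasi-Newton local search (`stats::optim` L-BFGS-B) on the same
coordinates. The polish exploits the smoothness of the objective near a
basin; the derivative-free stage provides globalization and handles the
penalty plateaus. Integration failures inside the objective return a large
penalty (and are counted), so the optimizer keeps going; the fitting-path
solver uses a small step cap so pathological parameter regions fail fast.

The contract for all of this is the parameter-recovery suite, not the
optimizer brand: on 20 noiseless synthetic LV patients sampled every 2–4
weeks with at least 12 observations over at least 12 months, the median
relative recovery error of $r_R$ and $\delta$ must be ≤ 5% (with $S_0$
≤ 10%) and pooled predicted-vs-observed $R^2 \ge 0.999$; at 10%
multiplicative noise, ≤ 25% and $R^2 \ge 0.8$. $K$ and $C$ are reported
but allowed to be weakly identified — many near-equivalent fits exist,
which is precisely why the virtual cohort keeps the top-$k$ fits per
patient rather than a single one. Exact duplicate optima (parameter
distance ≤ $10^{-10}$) are dropped with a note; top-$k$ ties are broken by
earlier start index.

## Synthetic cohorts

No numeric patient table is bundled; `generate_cohort()` emulates the
clinical situation the models were built for: 8 patients on continuous
BRAF/MEK-inhibitor-style therapy, 5 slow and 3 fast progressors, baseline
LDH 300–1500 U/L, visits every 0.5–1 month with ±20% scheduling jitter,
decline-then-rebound LDH with progression within 6 months (fast) or 6–40
months (slow), enforced by rejection sampling against the simulated
continuous course. Ground-truth priors (package choices, since no
population distributions are available): $r_R \sim$ log-uniform
$[0.1, 1.5]$/month; $\delta \sim$ log-uniform $[0.3, 3]$/month; $K \sim$
log-uniform $[1.5, 10]\times$ initial tumor LDH; $C \sim$ uniform
$[1.0, 1.6]$; $\alpha \sim$ log-uniform $[0.01, 0.5]$/month; initial
sensitive fraction uniform $[0.5, 0.995]$ (slow) or $[0.05, 0.6]$ (fast).
Measurement noise is multiplicative lognormal with CV 10%, mean-corrected
so the expected noise factor is 1.

What the generator does **not** emulate: LDH elevation from non-tumor
causes (drug hepatotoxicity), missed visits and dropout, assay batch
effects, or any spatial structure. Passing recovery and pattern tests on
these cohorts therefore demonstrates internal consistency of the pipeline
under its own assumptions, not fidelity to any particular clinical
dataset.

Intermittent-schedule phase-plane illustrations depend on cycle lengths
and kill rates that are scenario-specific; the simulation functions expose
them as inputs (`on_months`, `off_months`, `delta`) rather than fixing a
canonical scenario.

## Cohort experiments and statistics

`sweep_free_params()` runs paired adaptive/continuous simulations over
grids of the free parameters (default 20 values of $r_S/r_R$ over
$[0.05, 2]$ and 19 of $\beta/r_R$ over $[0.05, 0.95]$; grid resolution is a
package choice). The continuous arm is computed once per virtual patient
and shared across the grid — it cannot depend on the off-treatment-only
free parameters — and the pairing of every time-gained value is asserted
at run time. Spearman rank correlation (midranks for ties) is used for
parameter–outcome association because progression times and fitted rates
are monotonically, not linearly, related; `stats::cor` provides it and a
Pearson variant is a one-argument change. Kaplan–Meier estimation and the
unstratified two-sample log-rank test are delegated to the `survival`
package behind `km_estimate()`/`logrank_test()`; the test suite verifies
both against explicit hand tabulations on small examples.

Directional claims — larger $\beta$ gains more; cohorts with initial
sensitive fraction above 40% of $K$ gain more than those below 10%; the
−20% stop rule beats the −50% rule when the tumor is already responding
well; adaptive arms dominate continuous in progression-free survival — are
asserted on seeded synthetic cohorts constructed in the corresponding
regimes, allowing a 5% violation rate for transitions affected by event
tolerance, and skipping comparisons in which censoring truncates the
better arm (censoring removes exactly the largest gains from cell means,
biasing them downward).

## Problem sizes

The test suite and the acceptance script are sized to run on one CPU in a
few minutes while exercising every claim: recovery uses 20 synthetic
patients per noise level with 8 optimizer starts × 1000 evaluations (plus
polish); the survival comparison uses a 400-virtual-patient favorable LV
cohort across three arms; the end-to-end script fits both models to an
8-patient cohort with 10 starts per patient and a top-5 cohort. All stages
derive their randomness from one seed and are bitwise reproducible.

## Known limitations

- Well-mixed, two-phenotype, deterministic dynamics: no spatial structure,
  no demographic noise, no pharmacokinetics, at most two cell states.
- LDH is assumed strictly proportional to tumor burden above a fixed basal
  level; violations (e.g. hepatotoxic LDH elevation) would bias $R_0$ and
  the fitted kinetics.
- $K$ and $C$ (and $\alpha$ at low noise-to-signal) are weakly identified
  from a single continuous-therapy course; conclusions that depend on them
  should be read across the top-$k$ fit ensemble, not a point estimate.
- The optimizer is a local method with multistart globalization; with very
  few starts it can return a ranked list whose tail fits are poor. The
  recovery suite pins the configuration that is known to work.
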
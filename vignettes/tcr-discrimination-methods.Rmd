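---
title: "Measuring receptor discrimination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring receptor discrimination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrpower)
```

## The problem

T cells must react to rare, higher-affinity foreign peptide-MHC (pMHC)
ligands while ignoring abundant, lower-affinity self ligands. How sharply
the T cell receptor (TCR) converts an affinity difference into a response
difference — its *discriminatory power* — determines how much a loss of
affinity can be compensated by more antigen. `tcrpower` implements the
estimators needed to measure that power from binding and functional data,
and the kinetic-proofreading (KP) model that explains it, with a
synthetic-data generator providing ground-truth-known inputs for every
estimator.

## The power-law discrimination statistic

Ligand potency $P_X$ (the dose producing $X\%$ activation) is related to
affinity by the empirical power law

$$P_X = 10^{C} \, K_D^{\alpha},$$

fitted by ordinary least squares in log space,
$\log_{10} P_X = C + \alpha \log_{10} K_D$. The slope $\alpha$ is the
discriminatory power: a $k$-fold loss of affinity costs a $k^\alpha$-fold
increase in dose (`fold_amplification()`). $\alpha = 1$ is the baseline
of a pure receptor-occupancy sensor; $\alpha$ is invariant to
multiplicative unit changes on either axis, while the sensitivity
intercept $C$ (log potency of a 1 µM-affinity ligand) is not. When
on-rates differ across ligands the affinity axis should be $k_{\rm off}$;
the axis choice is always explicit in `fit_power_law()`.

Inclusion rules guard both tails of the fit: records with
$K_D < 1\,\mu$M sit in the affinity-saturation regime (potency no longer
improves with affinity) and would bias $\alpha$ down; potencies beyond
the highest tested dose are extrapolations and would bias it up. Both are
dropped by `apply_inclusion_rules()`, each removal logged. Aggregation
across experiments (`aggregate_alpha()`) keeps slopes with $p < 0.05$
(an override exists for sparse legacy datasets), reports the arithmetic
mean of $\alpha$ with a t-based 95% CI, and hypothesis tests against
$\alpha = 1$ run on $\log_{10}\alpha$ (`test_alpha_vs_one()`), the scale
on which the estimates are approximately normal.

## Affinity estimation: the constrained-Bmax protocol

Steady-state SPR titrations are fitted with the Langmuir isotherm
$B = B_{max}[{\rm TCR}]/(K_D + [{\rm TCR}])$. For low-affinity ligands
the titration cannot approach saturation, and the free two-parameter fit
degenerates onto a ridge $B_{max}/K_D \approx$ const: $K_D$ becomes
unidentifiable. The protocol resolves this with an independent estimate
of $B_{max}$: a conformation-sensitive antibody (W6/32) binds only
correctly folded pMHC, and its maximal binding $R_{max}$ (from the
empirical trace model $R = R_{max} t/(K_t + t)$) predicts $B_{max}$
through an empirical standard curve fitted on surfaces whose titrations
*did* saturate (max concentration $\ge 2.5 \times$ fitted $K_D$). The
constrained fit then minimises over $K_D$ alone. Reported values follow
the switch rule: constrained $K_D$ when it exceeds 20 µM (strictly —
"above" is read literally), free $K_D$ otherwise, since at high affinity
the free fit is reliable and independent of the standard curve.

Design choices here: the standard curve keeps a free intercept (a
through-origin constraint is not implied by anything in the protocol, and
interpolation-only use makes the choice low-impact); extrapolating the
standard curve beyond its fitted $R_{max}$ range is refused rather than
warned about.

## Potency extraction

Dose-response data are fitted on the linear response scale with the
four-parameter sigmoid
$R(x) = E_{min} + (E_{max}-E_{min})/(1+(EC_{50}/x)^H)$, and $P_X$ is the
*analytic* inverse of the fitted curve at $X$ — not a numeric root — so
the noiseless round trip through the generator is exact by construction.
A ligand whose plateau stays below $X$ is excluded
("below-threshold response"); a $P_X$ beyond the top tested dose is
excluded ("extrapolated"). In literature mode (`potency_from_points()`),
where only plotted points are available, the crossing of the horizontal
line at $X$ is interpolated linearly in $(\log_{10}$ dose, response$)$,
matching how such graphs are drawn; multiple crossings use the first,
with a warning.

## The kinetic-proofreading model

A bound TCR must traverse $N$ sequential steps at rate $k_p$ before
signalling; unbinding (rate $k_{\rm off}$) at any step resets the chain.
At steady state the total complex count follows the bimolecular
quadratic root and the signalling-state occupancy is
$C_N = (1+k_{\rm off}/k_p)^{-N} C_{tot}$ — each step discounts
fast-dissociating ligands, imposing a time delay $\tau_{KP} = N/k_p$.
As printed, the ODE system's terminal equation duplicates the $C_0$
equation; the implementation uses
$dC_N/dt = k_p C_{N-1} - k_{\rm off} C_N$, the unique form consistent
with the stated steady state, and the test suite verifies the closed form
against numerical integration of exactly this system.

Setting $C_N = \lambda R_0$ and solving for the dose gives the
closed-form potency; in fitted form, with $\hat\lambda = \lambda/\gamma$
and $\hat\delta = \delta/\gamma$ decorrelating the scale-conversion
constants,

$$\rho = \log_{10}\hat\lambda + N \log_{10}(1+k_{\rm off}/k_p) +
\log_{10}\!\left(1 - \frac{\hat\delta K_D}
{\hat\lambda(1+k_{\rm off}/k_p)^N - 1/\gamma}\right),
\qquad k_{\rm off} = k_{\rm on} K_D,$$

with $k_{\rm on} = 0.0447\ \mu\mathrm{M}^{-1}\mathrm{s}^{-1}$, the mean
measured on-rate of a family of close peptide variants, shared across
ligands because on-rates vary little within such panels.

**Reachability.** Activation at *some* dose is possible only while
$\lambda(1+k_{\rm off}/k_p)^N < 1$ (equivalently, the denominator above
is negative; the algebraic root is otherwise an artefact of squaring).
`log_potency_rho()` therefore returns `NA` ("unreachable") exactly when
that condition fails, which subsumes the narrower non-positive-logarithm
case. The generator emits such ligands with an empty potency and an
`unreachable` flag, mirroring ligands with no measurable response, and
they are excluded from fitting.

## Hierarchical ensemble fit

$N$, $\gamma$, $\hat\delta$ are global; $k_p$ and $\hat\lambda$ are per
experiment, giving $3 + 2I$ parameters ($27$ for $I=12$, $37$ for
$I=17$). Priors are uniform — in $\log_{10}$ space except for $N$
(linear on $[0,4]$) — and the distance is the sum of squared
$\log_{10}$-potency residuals over all experiments, $+\infty$ if any
observed ligand is predicted unreachable.

Each chain perturbs all coordinates by uniform shifts of $\pm 0.005$
prior widths (so $\pm 0.02$ for $N$) on the fitting scale, reflecting at
the bounds, accepts downhill moves always and uphill moves with
probability $e^{-\Delta D/\xi}$, and anneals $\xi$ downwards as the
accepted distance first reaches scheduled thresholds, stopping below a
termination distance. Running many independent chains (1000 at full
scale) maps the set of parameter vectors compatible with the data:
$k_p$ is pinned by the $K_D$ where potency saturates, $N$ by the log-log
slope at large $K_D$, so panels lacking low-affinity ligands leave a
wide ensemble spread in $N$ — the spread is the diagnostic.

Implementation decisions worth knowing:

* **Temperature scale.** $\xi$ and $D$ enter only through
  $\Delta D/\xi$, so a schedule is meaningful only relative to a
  dataset's residual scale. The built-in plate/cell schedules keep the
  original thresholds; `synthetic_schedule()` scales thresholds *and*
  temperatures by `n_points * sigma_log^2 * 1.2 / 11.08`, with the
  termination 20% above the expected residual floor at truth.
* **Initialisation.** The starting point is drawn from the prior
  conditioned on a finite distance: roughly half of the prior volume
  predicts the weakest ligand unreachable, and a chain started there
  could never move under the tiny kernel.
* **Threshold trigger.** The $\xi$ switch fires on accepted-state
  distances by default; a `switch_on_candidate` flag implements the
  alternative reading.
* **Safeguard.** Chains exceeding `max_steps` (default $5\times10^6$)
  are flagged as failed and counted, never silently dropped.
* **Pooling.** $\tau_{KP} = N/k_p$ is computed per chain and experiment;
  pooled summaries use the mean over experiments per chain with 95%
  percentile intervals across the ensemble, since no single pooling
  estimator is canonical.

## Phase maps: can proofreading deliver both sensitivity and discrimination?

Sensitivity asks whether a *single* strong ligand
($k_{\rm off,1} = 1\ \mathrm{s}^{-1}$) pushes $C_N$ above the threshold
$\lambda = 0.1$; discrimination asks whether $10^4$ copies of a ligand
$\Delta_A = 10000^{1/\alpha}$-fold weaker stay below it, the dose
implied by the power law itself. Deterministic criteria use the
binding-dominated approximation $C_{tot}\approx\min(L_0,R_0)$;
stochastic mode runs exact Gillespie ensembles (default 250
realisations, $t_{end} = 100$ s, $R_0 = 30000$) and compares the mean
$\langle C_N\rangle$ to $\lambda$, with strict inequalities so a cell
exactly at threshold never passes. The per-molecule $k_{\rm on}$
defaults to $100\,k_{\rm off,1}/R_0$, making single-ligand occupancy
exceed 99% so the two modes describe the same regime. At $\alpha = 9$
(near-perfect discrimination) no cell with $N \le 4$, $\tau \le 20$ s
achieves both properties; at $\alpha = 2$ many do.

## What the synthetic generator does and does not emulate

The generator reproduces the statistical structure the estimators
assume: Langmuir-shaped titrations with a partially folded immobilised
fraction and additive Gaussian RU noise ($\sigma = 2$ RU by default,
8-point two-fold dilutions, surfaces near 1000 RU); antibody traces
built so the standard curve holds exactly before noise; Hill-shaped
dose-response curves whose $EC_{50}$ inverts the threshold potency
exactly; and multi-experiment potency tables from the KP expression
with lognormal potency noise — lognormal because the fit distance is a
sum of squared log residuals, making the implicit noise model explicit.
Default KP truth sits mid-prior ($N = 2.67$, $k_p = 1$,
$\hat\lambda = 10^{-1.5}$, $\gamma = 10^{-5}$, $\hat\delta = 10^{-6}$)
with KD panels of 8 ligands log-spaced over 3-1500 µM, and
$\sigma_{\log} = 0.1$; residual noise magnitudes are not reported
quantities anywhere, so these are calibration choices recorded in
`truth.json`, not asserted facts.

Not emulated: time-resolved association/dissociation kinetics (only
steady-state tables), biphasic or aggregated binding, plate-to-plate
systematic effects, cellular signalling beyond the KP potency map, and
non-Gaussian response noise. Passing recovery tests therefore shows the
estimators are correct and well-conditioned under their own assumptions,
not that real data satisfy those assumptions.

## Problem sizes used by the test suite

Tests run the same code paths at reduced scale, chosen to keep the suite
tight while leaving each check well-powered: recovery of the
hierarchical fit uses 12 experiments with $\sigma_{\log}=0.1$ and 50
chains; the oracle equivalences use $10^3$ random draws; phase-map
cross-validation uses 250 realisations on a $3\times2$ grid, with the
large-count discrimination scenario run to $t_{end} = 1$ s — two orders
of magnitude beyond its slowest relaxation time
$\sim 1/(k_{\rm off}+k_p) \approx 0.01$ s at $\Delta_A = 100$ — while
single-ligand scenarios keep longer horizons. The full-scale protocol
values (1000 chains, $t_{end} = 100$ s) remain the package defaults.

## Known limitations

The annealed ensemble is a heuristic optimiser run from many starts, not
a calibrated posterior sampler: its spread measures identifiability, not
credible intervals. Termination distances are dataset-specific tuning
constants; applying the built-in plate/cell values to data with a
different residual scale will either stall chains or stop them early.
Analytic formulas accept fractional $N$; stochastic simulation requires
integer $N$. The SPR module takes double-referenced steady-state tables
as given — sensogram alignment and raw instrument files are out of
scope.
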
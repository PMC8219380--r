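# tcrpower

Quantifying how sharply the T cell receptor (TCR) — or any surface
receptor — discriminates between ligands of different binding affinity.

T cells respond to rare, higher-affinity foreign peptide-MHC ligands while
tolerating abundant, lower-affinity self ligands. The package is for
quantitative immunologists and modellers who want to put a number on that
ability and test the mechanism behind it. It implements, as one tested
toolchain:

* **Affinity estimation** from steady-state SPR titrations, including the
  constrained-Bmax Langmuir protocol: an empirical standard curve built
  from conformation-sensitive antibody (W6/32) binding fixes `Bmax` on
  curves too weak to saturate, extending reliable `KD` measurement into
  the millimolar regime (`fit_langmuir_free`, `fit_w632_rmax`,
  `build_standard_curve`, `fit_langmuir_constrained`,
  `select_reported_kd`).
* **Potency extraction** from dose-response data: four-parameter sigmoid
  fits and analytic interpolation of the threshold potency `P_X`, with
  strict no-extrapolation rules (`fit_hill`, `interpolate_potency`,
  `potency_from_points`).
* **The discrimination power** `alpha`, the slope of the power law
  `P_X = 10^C * KD^alpha` fitted in log space; `alpha = 1` is the
  receptor-occupancy baseline, and a `k`-fold affinity loss costs a
  `k^alpha`-fold dose increase (`fit_power_law`, `apply_inclusion_rules`,
  `aggregate_alpha`, `test_alpha_vs_one`, `fold_amplification`).
* **The kinetic-proofreading (KP) model**: closed-form steady state and
  potency for a receptor that must traverse `N` sequential steps at rate
  `kp` before signalling (time delay `tau_KP = N/kp`), plus a
  hierarchical fit of multi-experiment potency data by an annealed
  Metropolis-Hastings ensemble with global (`N`, `gamma`, `delta_hat`)
  and per-experiment (`kp`, `lambda_hat`) parameters
  (`log_potency_rho`, `kp_distance`, `fit_kp_ensemble`).
* **Sensitivity/discrimination phase maps** over `(N, tau = 1/kp)`,
  deterministic and by exact Gillespie simulation (`phase_map`,
  `gillespie_kp`, `sensitivity_ok`, `discrimination_ok`).
* **A synthetic-data generator** with known ground truth for every stage
  (`generate_spr_dataset`, `generate_kp_potency_dataset`,
  `generate_dose_response_dataset`, `generate_powerlaw_potency`), so each
  estimator ships with parameter-recovery evidence.

`run_pipeline()` ties the stages together file-to-file over plain CSV
schemas (see `?read_table`), writing run metadata alongside every output.

## Worked example

Generate a 12-experiment potency table from a known KP truth
(`N = 2.67` steps, `kp = 1 /s`, lognormal potency noise of 0.1 log10
units), estimate the discrimination power of one experiment, then recover
the proofreading parameters with a 50-chain ensemble:

```r
library(tcrpower)

truth <- kp_ground_truth()                 # N = 2.67, kp = 1, mid-prior scales
dat <- generate_kp_potency_dataset(truth, n_experiments = 12, seed = 1)

kept <- apply_inclusion_rules(dat$potency_table)$records
fit <- fit_power_law(kept[kept$experiment_id == "E01", ])
print(fit)
#> Power law (axis: kd, n = 8): alpha = 1.84 [1.45, 2.22], C = -2.83
#>   R^2 = 0.958, p(alpha = 0) = 2.29e-05

sch <- synthetic_schedule(n_points = nrow(kept), sigma_log = 0.1)
ens <- fit_kp_ensemble(dat$potency_table, n_chains = 50,
                       schedule = sch, seed = 2)
print(ens)
#> KP ensemble fit: 50/50 chains converged (27 parameters, 12 experiments)
#>   N (steps): median 2.53, range [2.46, 2.81]
#>   kp pooled mean 0.778 s^-1 (95% interval 0.628-1.14)
#>   tau_KP = N/kp pooled mean 3.48 s (95% interval 2.46-3.98)

fold_amplification(5, 2)
#> [1] 25
```

Reading the output: the single-experiment power law gives `alpha ≈ 1.8`
— a 5-fold affinity loss costs roughly a 25-fold dose increase, far from
the ~2-million-fold an `alpha = 9` (near-perfect) discriminator would
demand (`fold_amplification(5, 9)`). The ensemble recovers the
generating step number (median 2.53 against a truth of 2.67, with the
ensemble range quantifying identifiability) and the proofreading rate
within its 95% interval; `tau_KP = N/kp` is the implied proofreading
time delay in seconds. The hierarchical structure is visible in the
parameter count: 3 global + 2 x 12 local = 27.

The methods vignette
(`vignettes/tcr-discrimination-methods.Rmd`) documents the models,
parameter meanings and defaults, numerical choices, and what the
synthetic generator does and does not emulate.

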
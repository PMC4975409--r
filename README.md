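# atriafit

Patient-specific calibration of a minimal atrial ionic model, in R.

Clinical electrophysiology studies yield three tissue-level measurements
per patient during controlled pacing: normalized action-potential (AP)
morphology from a monophasic action potential catheter, APD90 restitution
(action potential duration at 90% repolarization versus the preceding
diastolic interval, DI), and conduction-velocity (CV) restitution. A
tissue model is only informative about *that* patient's fibrillation if
its parameters reproduce all three at once. `atriafit` implements the
full loop:

* the **four-variable minimal ionic model** (membrane potential `u` plus
  gates `v`, `w`, `s`; fast-inward, slow-outward and slow-inward
  phenomenological currents; 28 named parameters, published epicardial
  reference set bundled), integrated by explicit Euler in the monodomain
  formulation `du/dt = D∇²u − J_ion + I_stim`;
* **1D cable protocols** (100 elements, dx = 0.02 cm, dt = 0.01 ms,
  no-flux boundaries): S1-S2 restitution with an S2 ladder to loss of
  capture, and the clinical decremental ladder (≥ 84 beats at each of
  500/450/400/350/300 ms, then 10 ms steps to 2:1 block);
* **trace analysis**: threshold activation times, APD90, CV, 10–100%
  upstroke interval, min-max morphology normalization with the 10 ms
  pacing-artifact mask;
* **simulated-annealing fitting** of the parameters to a patient dataset,
  minimizing the combined percent error of morphology, APD restitution
  and CV restitution (50 iterations, temperature reduced 10% per
  iteration, Metropolis acceptance of uphill moves);
* a **synthetic patient generator** (logarithmic APD restitution with
  clinical APD 220–380 ms and maximum slope 0.57–1.15, flat or
  decreasing CV, template morphologies, per-channel noise) standing in
  for raw clinical recordings, with a model-truth mode for exact
  recovery experiments;
* **2D spiral-wave experiments**: cross-field S1/S2 initiation on
  isotropic sheets (9.6 × 9.6 cm reference geometry), isopotential ∩
  du/dt = 0 tip tracking with bilinear sub-cell localization, rotation
  periods from probe and tip trajectories, and rule-based stability
  classification (`stable` / `breakup` / `no_reentry` / `terminated`).

The heavy integrators are compiled (Rcpp); everything user-facing speaks
tibbles, pipes, `tidy()`/`glance()` and `autoplot()`.

## Worked example

Fit the model to a synthetic patient and inspect the result:

```r
library(atriafit)

# a reproducible synthetic patient: APD_max 300 ms, max slope 0.8,
# flat CV at 60 cm/s, plateaued AP morphology, clinical noise levels
ds <- generate_patient(patient_spec(seed = 42))
ds
#> <clinical_dataset> 'synthetic-parametric': 6 APD points (max slope 0.82),
#>   6 CV points, morphology 200 samples

# simulate the S1-S2 protocol at the bundled reference parameters
cable <- cable_config()
sim <- s1s2_restitution(model_parameters(), cable)
sim
#> <mm_s1s2> S1 CL 500 ms, 11 S2 points (10 captured), APD(S1) = 259.6 ms

# how far is the unfitted reference set from this patient?
error_components(sim, ds)
#> <error_breakdown> total 16.13% (morph 17.83%, apd 17.98%, cv 12.60%, upstroke -)

# anneal the free parameters (50 iterations, 10% cooling)
fit <- anneal(ds, cfg = fit_config(seed = 1), cable = cable)
glance(fit)
tidy(fit)           # per-parameter estimates next to the initial values
autoplot(fit)       # annealing trace
```

The error breakdown is in percent: APD and CV errors are mean relative
errors at the patient's measured DIs, the morphology error is the mean
absolute normalized-voltage difference (percent of full amplitude) on
the unmasked 200-point grid.

Spiral-wave characterization with a parameter set:

```r
# full-scale sheet: roughly half an hour on one CPU; scale `side` and
# `t_total` down for quick experiments
sheet <- run_2d(model_parameters(),
                grid2d_config(side = 9.6, t_total = 2000))
traj <- track_tips(sheet)
classify_dynamics(traj, 2000, sheet$s2_time)
rotation_periods(sheet, traj)
autoplot(traj)
```

Command-line entry points (thin wrappers over the same functions) live
in `inst/cli/`:

```sh
Rscript inst/cli/fit.R --patient patient_dir --seed 7 --out result.json
Rscript inst/cli/spiral2d.R --params result.json --out spiral_out
```

Patient bundles are plain directories (`morphology.csv`,
`apd_restitution.csv`, `cv_vs_cl.csv`, `di_vs_cl.csv`, `meta.json`) with
identical schemas for simulated and clinical data;
`write_patient_bundle()` / `read_patient_bundle()` round-trip them.

## Vignette

`vignettes/atriafit-methods.Rmd` documents the model equations and
assumptions, the measurement conventions (activation threshold, APD90,
CV sites, DI bookkeeping), the numerical choices (rate tabulation, gate
clamping, blow-up policy, stimulus calibration), what the synthetic
patients do and do not emulate, the annealing design, and known
limitations.
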
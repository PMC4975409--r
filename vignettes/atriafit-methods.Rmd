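---
title: "Patient-specific fitting of a minimal atrial ionic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific fitting of a minimal atrial ionic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atriafit)
```

## The problem

Clinical electrophysiology studies in atrial fibrillation patients yield
three kinds of tissue-level measurements during controlled pacing: the
shape of the local action potential (AP) recorded by a monophasic action
potential catheter (normalized, with the first ~10 ms discarded as pacing
artifact), the restitution of action potential duration (APD90) against
the preceding diastolic interval (DI), and the restitution of conduction
velocity (CV). A tissue-scale computer model is only useful for studying a
*particular* patient's arrhythmia if its parameters reproduce all three
curves at once. `atriafit` implements that calibration loop for a
simplified ionic model, plus the downstream experiment it exists for:
two-dimensional spiral-wave (rotor) simulation with the fitted
parameters.

## The model

The membrane model is the four-variable minimal ("FK-type") formulation:
a dimensionless membrane potential $u$ (0 at rest, about 1 at the
plateau) and three gates $v, w, s \in [0,1]$, with three phenomenological
currents

$$
J_{fi} = -v\,H(u-\theta_v)\,(u-\theta_v)(u_u-u)/\tau_{fi}, \qquad
J_{so} = \frac{(u-u_o)(1-H(u-\theta_w))}{\tau_o(u)} +
          \frac{H(u-\theta_w)}{\tau_{so}(u)}, \qquad
J_{si} = -H(u-\theta_w)\,w\,s/\tau_{si},
$$

where $H$ is the Heaviside step (we adopt $H(0)=1$: a state exactly at a
threshold counts as supra-threshold, used consistently in code and
tests). The gates relax with voltage-dependent time constants
($\tau_v^-(u)$ switching at $\theta_v^-$; $\tau_w^-(u)$, $\tau_{so}(u)$
sigmoidal in $u$; $\tau_s(u)$, $\tau_o(u)$ switching at $\theta_w$,
$\theta_o$) toward targets $v_\infty, w_\infty, s_\infty(u) =
(1+\tanh(k_s(u-u_s)))/2$. Tissue is the isotropic monodomain

$$ \partial_t u = D\nabla^2 u - J_{ion} + I_{stim}, $$

with membrane capacitance absorbed into the normalized formulation
($C_m \equiv 1$). The full roster is 28 named parameters
(`model_parameters()`); the bundled `default.json` is the published
epicardial reference set, which serves as the fitting initial condition.
Because the clinical comparison happens entirely in normalized
coordinates, no millivolt mapping is implemented.

During fitting, seven parameters are frozen by default, leaving 21
adjustable. `u_o`, `u_u` and `theta_v` anchor the dimensionless voltage
scale and the excitability threshold, so freezing them keeps the
normalization pinned while everything else adapts; `theta_vminus`,
`theta_o`, `tau_winf` and `w_inf_star` shape the sub-threshold gate
steady states, where they have minimal effect on AP morphology and
restitution but admit degenerate values (a recovery threshold at or
below the resting potential) that silence the tissue outright — the
classic criterion for excluding parameters from a fit. The mask is
configurable (`fit_config(fit_mask = ...)`).

## Numerics

* **Integration** is explicit Euler at `dt = 0.01` ms on a 100-element
  cable (`dx = 0.02` cm) with no-flux boundaries implemented by mirror
  ghost cells, the ghost value equal to the first interior neighbour
  (node-centred mirror). With this convention the discrete flux budget
  closes up to a boundary term proportional to the boundary gradient —
  exactly zero for fields that are locally flat at the edges, and
  negligible for propagating waves; the compiled kernel is verified
  step-for-step against the reference `laplacian_noflux()`. 2D sheets
  use the five-point Laplacian with the same ghosts; stability requires
  $D\,dt/dx^2 < 1/2$ (1D) or $1/4$ (2D), checked at configuration time.
* **Rate tabulation.** Every voltage-dependent coefficient of the model
  is a function of $u$ alone, so the compiled integrators tabulate nine
  coefficients on a $u$-grid of step $10^{-4}$ over the guard range
  $[-0.5, 2]$ and interpolate linearly. The induced error (~$10^{-5}$
  relative near the steep $\tanh$ terms) is far below the Euler
  discretization error. The exposed `ionic_derivatives()` evaluates the
  exact formulas and is cross-checked against an independent term-by-term
  oracle to $10^{-12}$ relative.
* **Gate boundedness.** The gate targets are clamped to $[0,1]$ at table
  build time. For physiological states this changes nothing (the
  unclamped targets only exit $[0,1]$ for $u<0$ or pathological proposal
  parameters); it guarantees that forward Euler keeps gates in $[0,1]$ so
  transient sub-resting excursions of $u$ cannot accumulate into gate
  drift. The scalar `step_euler()` applies the stricter contract: gates
  are clipped only within $10^{-9}$, anything larger is an instability
  error.
* **Blow-up policy.** $u$ outside $[-0.5, 2]$ or non-finite aborts the
  run with the failure time; during annealing such moves score infinite
  error and are rejected.
* **Diffusion and stimulus.** Clinical-style pacing studies do not pin
  down a diffusion coefficient or stimulus shape, so the package fixes
  `D = 0.001` cm²/ms (a typical normalized atrial monodomain value; CV
  scale during fitting is carried by `tau_fi`, and a config flag can add
  `D` to the fit vector by treating it as any other scale parameter) and
  auto-calibrates the 2-ms stimulus: the smallest amplitude that elicits
  a propagated AP, found by factor-of-2 bracketing and bisection to 1%,
  times a safety factor 2 (`calibrate_stimulus()`). The amplitude is
  calibrated once per fit, at the initial parameters, and held fixed so
  every candidate faces the same protocol.

## Measurement conventions

* **Activation** is the upward crossing of $u = 0.2$ with sub-`dt` linear
  interpolation and a 50 ms refractory guard — robust for normalized
  voltages and insensitive to the foot of the upstroke.
* **APD90** runs from activation to the first fall below
  `baseline + 0.1 * (peak - baseline)` (baseline = pre-upstroke minimum,
  peak = beat maximum), interpolated below the sampling interval.
* **CV** is measured between the cells at x = 0.48 cm and 1.48 cm (the
  central 1.0 cm of the default cable), away from both the stimulus foot
  and the far boundary; the measurement positions are held fixed in
  physical units when the grid is refined.
* **DI** for the S1-S2 protocol is the S2 coupling interval minus the
  APD90 of the final S1 beat at the distal site; under steady pacing this
  reduces to `DI = CL - APD`.
* **Morphology** normalization: min-max voltage to $[0,1]$, time mapped
  so activation is 0 and APD90 is 1, samples inside the first
  `artifact_cutoff` (default 10 ms, mirroring the clinical artifact
  removal; exposed as a parameter because the clinical pre-processing of
  the very first 30 ms is not fully specified) are masked. All morphology
  comparisons happen on a fixed 200-point uniform normalized-time grid so
  error numbers are deterministic.
* **Capture failure** = no activation at the distal site within one cycle
  length of the stimulus.

## Protocols

`s1s2_restitution()` paces `n_s1 = 8` conditioning beats at the 500 ms
clinical baseline and delivers one premature S2 per coupling interval.
The S1 train is integrated once and its end state reused for every S2,
which makes a full restitution curve cost one train plus one short
continuation per S2. The default S2 ladder descends in 20 ms steps,
refined to 10 ms below 300 ms, until loss of capture; failed captures are
flagged rows, never silently dropped. `dynamic_pacing_protocol()`
replicates the clinical decremental ladder (≥ 84 beats at 500, 450, 400,
350, 300 ms, then 10 ms decrements to 2:1 block), carrying tissue state
from rung to rung.

## The synthetic patient generator

No raw clinical recordings are distributed with the study this package
emulates, so `generate_patient()` manufactures datasets with the same
statistical structure, at the clinically reported scales:

* logarithmic APD restitution `APD = a + b ln DI`, parameterized either
  directly or via `apd_max` (the APD at the 500 ms baseline; clinical
  range ≈ 220–380 ms, default 300) and `max_slope` (clinical range
  ≈ 0.57–1.15, default 0.8, imposed at the 40 ms refractory floor where
  the ladder ends); the DI at each cycle length solves the bookkeeping
  identity `DI = CL - APD(DI)` self-consistently, and rungs whose DI
  falls below the floor are dropped as capture failure — a patient whose
  ladder blocks before reaching the floor realizes a somewhat lower
  maximum slope than requested;
* CV restitution either flat (default 60 cm/s) or drooping linearly by a
  `droop` fraction toward the shortest DI — the two regimes observed
  clinically;
* a cycle-length-independent normalized morphology drawn from a
  three-template bank (monotone decay, plateaued, triangular) spanning
  the qualitative variety of patient AP shapes, each ending at 0.1 at
  normalized time 1 so APD90 lands exactly at 1;
* Gaussian noise per channel (defaults: APD 5 ms, CV 3 cm/s, morphology
  0.01 — plausible clinical magnitudes; the source study does not print
  noise levels, so these are package choices);
* `model_truth` mode instead runs the full cable protocol on a known
  parameter set and packages the outputs, giving recovery tests an exact
  ground truth.

Everything is deterministic given `seed`. What passing tests on these
fixtures do **not** show: robustness to real MAP artifacts (baseline
wander, catheter contact changes), beat-to-beat alternans, spatial
heterogeneity, or non-logarithmic restitution shapes — none of which the
generator emulates.

## The annealing fit

`anneal()` minimizes the weighted mean of component percent errors
(`error_components()`): APD and CV as mean relative errors at the target
points (simulated curves linearly interpolated in DI; points outside the
simulated range charged a flat 25% penalty so partial coverage is
escapable but costly), morphology as mean absolute difference of
normalized voltages on the unmasked grid (in percent of full amplitude),
averaged over all captured S2 shapes by default (a flag restricts to the
largest S2 only), and optionally the 10–100% upstroke interval. Weights
default to equal, with the upstroke at 0 since clinical upstrokes are
unreliable; re-weighting is one argument.

The schedule is the classical one: 50 iterations, temperature cut by 10%
after each, 20 candidate moves per iteration (the move count is a package
choice; the source procedure states only iterations and cooling). Each
move perturbs a random subset of the free parameters — usually one, with
an occasional three-parameter move (`move_subset = c(1, 1, 1, 3)`) so
correlated directions can relax — multiplicatively by
`exp(sigma * d(T) * N(0,1))` for scale parameters (time constants and
steepnesses), additively by `sigma * d(T) * range * N(0,1)` for
thresholds and midpoints, where `d(T) = max(sqrt(T/T0),
min_step_frac)`. Proposals are then clipped to bounds: tenfold boxes
around the initial value for scale parameters, ±50% of the valid
interval for the rest, with thresholds floored just above `u_o` (a
threshold at or below the resting potential degenerates the gate steady
states and leaves the tissue inexcitable — a cliff the optimizer should
not be able to fall off). Uphill moves are accepted with the Metropolis
probability `exp(-dE/T)`; `sa_optimize()` exposes the bare optimizer
(including a greedy hill-climbing limit) for use on analytic objectives.

Several coupled design choices deserve explanation because the naive
alternatives demonstrably fail; all were fixed using recovery
experiments on model-generated targets and a 25-dimensional quadratic
surrogate of the error landscape. First, the proposal amplitude
contracts with `sqrt(T/T0)`, not `T/T0`: the proposal-induced error
change scales with the step size, so a linearly damped proposal keeps
the ratio `|dE|/T` — the quantity that decides Metropolis selectivity —
constant across the entire geometric schedule, and the chain
random-walks at every temperature without ever descending. The
square-root law lets selectivity sharpen as the system cools. Second,
the step never shrinks below `sigma * min_step_frac` (default 0.07):
purely temperature-proportional steps freeze the chain in parameter
space while error remains, whereas a small floor keeps late, nearly
greedy iterations mobile. Third, the initial temperature is
auto-calibrated from a 20-move pilot so that the median uphill step is
accepted with probability `pilot_accept` (default 0.15; an explicit
`initial_temperature` overrides this) — a hotter start spends most of
the budget on an unproductive random walk. Fourth, mostly
single-parameter moves: joint isotropic perturbations of ~21 parameters
almost never improve a strongly anisotropic error surface once the
chain is inside the valley. With `sigma = 0.3` these settings recover a
noise-free model-generated patient from a ±50% displaced start to the
clinical error scale within a few hundred evaluations.

Protocol failures during a move (loss of S1 capture, unresolved
repolarization) are scored at twice the uncovered penalty — finite, so
the annealer can walk out of non-excitable corners, but above any
partially covered fit, so it prefers staying on the excitable basin;
those moves are also excluded from the pilot median so `T0` reflects the
local error scale. Numerical blow-ups are infinite and always rejected. Because multiple
parameter sets can fit a dataset equally well — the optimizer's
double-well behaviour is exercised directly in the test suite — the
result object records the seed, the full trace and the initial point, and
distinct seeds should be expected to return distinct, equally good
parameter sets.

The candidate evaluation protocol simulates up to six S2 values spanning
the target's own cycle-length ladder (so the simulated curve covers the
target DI range; the self-fit of a model-generated target is then exact
at the sampled points). Fitting at the measured points of the smoothed
target curves — rather than on a dense refit grid — is the package's
resolution of an under-specified choice.

## 2D spiral waves

`run_2d()` initiates reentry by cross-field stimulation: a planar S1 from
the left edge, then an S2 over the lower-left quadrant timed into the S1
repolarization wake (by default scanned in 10 ms steps around a 1D
estimate of wake passage, keeping the earliest sustained reentry).
`track_tips()` implements the isopotential-intersection tip definition:
tips are the intersections of the `u = 0.5` isoline with the `du/dt = 0`
contour (frame differencing over the 1 ms default frame interval),
located by bilinear interpolation inside each grid cell where both fields
change sign, de-duplicated at 1.5 `dx`, and linked greedily across frames
with a 0.3 cm gate (tip *location* is reported as-is; absolute placement
is arbitrary for comparison purposes). `rotation_period()` reports both
the probe-based estimate (mean inter-activation interval over the final
two thirds of the run, at a probe placed away from the core) and the
trajectory-based estimate (2π over the mean angular velocity about the
track centroid); an unsustained rotor returns `NA`, not a number.
`classify_dynamics()` applies transparent rules: `no_reentry` (no tips
after the post-S2 transient), `breakup` (≥ 2 tips sustained beyond
200 ms), `terminated` (tips vanish before the run ends after at least one
rotation), else `stable`.

The reference geometry is 9.6 × 9.6 cm. The test suite exercises the 2D
pipeline at reduced problem sizes (1.6–4 cm sheets, ≤ 1 s of
activity) chosen so the whole suite stays interactive; the tip tracker
and period estimators are validated exactly on synthetic rotating fields,
where ground truth is analytic. Properties that require repeated
full-scale spiral runs (mirror-symmetry of trajectories under reflection
of the S2 region, domain-size robustness of the period) are part of the
design contract but are not run routinely for cost reasons.

## Known limitations

* Homogeneous, isotropic, 2D tissue only — no fiber anisotropy,
  heterogeneity or 3D geometry; no GPU path (the compiled CPU kernels
  integrate ~6×10⁷ cell-updates/s, which covers cable protocols
  interactively and desk-scale sheets in minutes).
* The detailed 43-variable atrial model referenced by the workflow is not
  implemented; the package exposes the pluggable state-vector +
  derivatives contract instead, and per-patient fitted parameter tables
  from the source study are not redistributed, so its patient-specific
  spiral periods cannot be reproduced here.
* The S1-S2 curve stands in for dynamic (steady-state) restitution when
  fitting parametric targets; short-term memory effects make these
  protocols differ at short DI.
* MAP signal processing (filtering, beat segmentation) is out of scope —
  inputs are already-reduced curves.

## Reproducing the numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
the numerical-convergence figures of merit (maximum relative CV
restitution change under `dt` halving and `dx` refinement) from scratch;
`tests/testthat/test-acceptance.R` additionally runs the
parameter-recovery experiment, the pacing-ladder bookkeeping checks, the
tip-tracker validation and a scaled-down spiral run. Problem sizes there
(12-move iterations in the recovery fit, a 4 cm sheet) are the package's
desk-scale choices.
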
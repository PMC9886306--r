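---
title: "Multilevel calibration of a hybrid angiogenesis model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel calibration of a hybrid angiogenesis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiocal)
```

## The modeling problem

Tumor cells seeded in a collagen matrix around an endothelialized
parent vessel secrete vascular endothelial growth factor (VEGF), which
diffuses to the vessel and triggers angiogenic sprouting. `angiocal`
implements the model hierarchy needed to calibrate such a system
against three kinds of measurements — cell counts, daily VEGF
concentrations, and binarized confocal images of the growing
vasculature — and to propagate the calibration uncertainty into
forward predictions.

Three model tiers are involved:

1. **ODE tier.** Endothelial cells follow logistic growth
   $\dot N_e = \lambda_e^g N_e (1 - N_e/\theta_e)$ and tumor cells
   exponential growth $\dot N_T = \lambda_T^g N_T$. VEGF obeys
   $\dot V = -\lambda_e^c N_e V$ in the consumption (endothelial
   plate) experiment and
   $\dot V = \lambda_T^p N_T (1 - V/\theta_V)$ in the production
   (tumor plate) experiment. Both experiments replace the media daily,
   which resets the concentration to a 1100 pg/mL baseline; the value
   recorded at each measurement time is the pre-reset value.
2. **Agent tier.** Endothelial cells of the parent vessel activate
   into tip cells where local VEGF exceeds a threshold $\alpha_A$ and
   no other tip site is within $d_{tip}$. A sprout elongates only when
   the stalk cell behind its tip divides (after the divide time
   $d_{sc}$) and its daughter grows to one cell diameter (over the
   growth time $g_{sc}$), giving the elongation rate
   $s_e = 2R/(d_{sc}+g_{sc})$. Tips steer along the VEGF gradient
   under a compactly-supported potential that vanishes beyond the
   combined cell radius. Tips touching another sprout anastomose and
   stop. Tumor cells within a shutoff distance of any vessel cell stop
   secreting — a surrogate for nutrient delivery that lets the
   calibration scenarios run independently of the full
   nutrient/hypoxia state machine (which is implemented but bypassed).
3. **Continuum tier.** Normalized VEGF and nutrient fields follow
   reaction–diffusion equations whose source and sink coefficients are
   linear in the per-element volume fractions of each cell type,
   computed by assigning each cell's disk area to the element holding
   its center (exact for cells inside one element, and conservative in
   total area).

## Calibration scenarios

Calibration proceeds in five scenarios that feed forward their
maximum-likelihood estimates (MLEs), with uniform priors and the iid
Gaussian likelihood
$\log L = -\tfrac{N}{2}\log(2\pi\sigma^2) - \phi(m)/(2\sigma^2)$,
where $\phi$ is the summed squared misfit:

1. `scenario1_growth` — least squares for
   $(\lambda_T^g, \lambda_e^g, \theta_e)$ on cell counts; the first
   count initializes each model.
2. `scenario2_vegf` — naive grid quadrature for
   $(\lambda_T^p, \lambda_e^c, \theta_V)$ on the two daily VEGF
   series, 100 values per parameter centered on an initial
   least-squares point. The daily measurement model is evaluated in
   closed form (the kinetics are linear in $V$ given the cell
   trajectories), so the million-point sweep is vectorized.
3. `scenario3_sprout_length` — Metropolis–Hastings over
   $(d_{sc}, f_v, \sigma)$ against mean sprout lengths using the
   reduced single-sprout model (one tip, no VEGF field). The force
   coefficient $f_v$ does not change division-limited length, so its
   posterior is flat; $\sigma$ is a hyperparameter absorbing
   measurement and model inadequacy.
4. `scenario4_density` — 1D quadrature for $d_{tip}$ against vascular
   density profiles (mask counts summed along the vessel axis),
   excluding the 15 voxels (> 35 µm) next to the parent vessel where
   migratory endothelial cells corrupt the data. Every candidate runs
   the hybrid model from day 0: the ABM cannot be initialized
   mid-course from a density profile.
5. `scenario5_local` — the ABM is initialized from a day-3 skeleton
   (cells placed along the traced centerline, growth direction imposed
   by each branch's end tangent, no new activation) and the local
   divide time is calibrated against bidirectional mean centerline
   distances at days 5 and 7, with misfit
   $\sum_i (\bar D_{MD}(t_i) - \bar D_{DM}(t_i))^2$. The per-day means
   are compared (rather than pairing individual voxels, which is
   ill-defined because the two centerlines have different voxel sets);
   the form is symmetric in model and data and vanishes when the
   centerlines coincide.

`predict_with_uncertainty` samples the Gaussian fits of the posteriors
(1-parameter: $d_{tip}$ only; 4-parameter: also $\lambda_T^p$,
$\lambda_e^c$, $d_{sc}$) and reruns the model per draw;
`prediction_envelope` turns sampled centerlines into hit-count
envelopes (thresholds 10/50/100 of 1000 runs give the 1%/5%/10%
envelopes).

## Parameters that matter

| parameter | meaning | default | unit |
|---|---|---|---|
| $\lambda_e^g$, $\theta_e$ | endothelial growth rate, capacity | 3.7e-2, 2.67e5 | 1/h, cells |
| $\lambda_T^g$ | tumor growth rate | 8.9e-3 | 1/h |
| $\lambda_T^p$ | VEGF production per tumor cell | 1.7e-3 | pg/(mL·h·cell) |
| $\lambda_e^c$ | VEGF consumption per endothelial cell | 8.9e-7 | 1/(h·cell) |
| $\theta_V$ | VEGF carrying capacity | 4035 | pg/mL |
| $d_{sc}$, $g_{sc}$ | stalk divide / growth time | 3.96, 1.04 | h |
| $d_{tip}$ | minimum tip spacing | 243 | µm |
| $2R$ | cell diameter | 10 | µm |

Defaults are the calibrated MLEs. Two labeling ambiguities in the
parameter conventions were resolved by units: the 4035 pg quantity is the VEGF
carrying capacity (it saturates a concentration equation) and 2.67e5
cells is the endothelial capacity; and the production rate carries
per-cell units, as required by its $N_T$ multiplier. $g_{sc}$ is
back-solved from the elongation rate identity
$s_e = 2R/(d_{sc}+g_{sc})$ with $s_e = 2.0$ µm/h. The activation
threshold $\alpha_A$ and hypoxia threshold $\sigma_H$ are never given
numerically anywhere; $\alpha_A = 0.05$ (normalized) is chosen so
synthetic scenes activate tips within the first simulated day, and
both are configuration-exposed.

The continuum rate constants ($D_v$, $\gamma_h$, per-type consumption
rates) are free design parameters of the normalized field; the
defaults ($D_v = 1000$ µm²/h, $\gamma_h = 50$/h) are set so that
tumor-sourced VEGF reaches the activation threshold at the vessel
within the first simulated day at the study's seeding density. When
the 4-parameter uncertainty case samples the ODE-calibrated rates, the
field coefficients are scaled proportionally to the sampled per-cell
rates — the conversion from per-cell rates to field coefficients being
per-cell rate × cells per element / element volume, which is linear in
the rate.

## Numerical choices

* **Integration.** The kinetics are integrated with `deSolve::lsoda`
  piecewise between media resets (so the jump never crosses an
  integrator step), rtol 1e-10; closed forms are used wherever the
  cell input is itself closed-form (logistic/exponential), and the
  grid sweep uses only the closed form.
* **Elongation.** `advance_sprouts` does exact time accounting:
  leftover step time rolls between the waiting and growing phases, so
  a division/growth cycle is exactly $d_{sc}+g_{sc}$ regardless of the
  step size, and the step simulation matches the closed-form length.
  Chains are represented as segment direction/length lists anchored at
  the activation site; this is the stiff limit of the cell–cell
  adhesion springs (whose exact form is left to configuration) and
  makes chain tearing impossible by construction.
* **Fields.** Explicit finite differences with no-flux boundaries; the
  step is sub-divided to satisfy the CFL bound
  $\Delta t \le h^2/(4D)$, and a violating step is rejected with the
  admissible value reported. The logistic production term
  $\Gamma V(1-V)$ amplifies rather than creates concentration, so
  simulations start from a small trace level (1e-3 normalized) rather
  than zero.
* **Activation.** Candidates are processed in descending local VEGF
  (deterministic tie-break), and a sprout's anchor keeps counting as
  an occupied tip site after its tip migrates away — without this the
  spacing rule re-activates endlessly beside existing sprouts.
* **Quadrature.** Grid posteriors normalize weights to sum to one;
  marginal densities are renormalized to trapezoid integral one. The
  MLE is the grid argmax with ties broken toward the lowest parameter
  value. Metropolis–Hastings uses a Gaussian random walk, a mandatory
  seed, 20% burn-in and no thinning.
* **Imaging.** Zhang–Suen thinning is implemented with the standard
  two sub-iteration parallel scheme (validated against an independent
  per-pixel reference in the tests); centerline distances use the
  exact Euclidean distance transform; component filtering uses
  8-connectivity (implemented in-package — the available labeling
  backend is 4-connected).

## What the synthetic data emulate — and what they do not

The generators reproduce the statistical structure the analysis
assumes: counts on days 1/2/3/5/7 with mean-unbiased lognormal noise
(5% CV), daily VEGF measurements with resets and 5%-of-value Gaussian
noise, tumor seeding by a spatial Poisson process at the areal
analogue of 1e6 cells/mL (density^(2/3) per µm²), and image stacks at
2.254 µm in-plane / 4.28 µm axial spacing with Gaussian blur,
Poisson–Gaussian noise and planted single-pixel migratory-cell
distractors. Ground truth is always emitted beside the noisy
observation, so recovery errors are computable everywhere.

They do not emulate optical point-spread realism beyond Gaussian blur,
vessel lumen texture, z-direction growth (vessels live in a thin plane
replicated across slices), or day-9-style vascular remodeling — so
passing self-inversion tests demonstrates internal consistency of the
calibration machinery under the assumed noise structure, not fidelity
to every feature of real confocal data.

## Problem sizes

The packaged tests run the scenarios at reduced scale, chosen to keep
the full suite in the minutes range while preserving the structure of
each experiment: scenario 4 self-inverts on a 250 × 500 µm scene over
96 h with an 11-point grid (the full study domain is 676.2 × 3155.6
µm² over 7 days with a 64-point default grid, which the same functions
accept), scenario 5 uses a ~120-px local region, and uncertainty
propagation uses tens rather than 1000 samples. The scenario-2 sweep
runs at the full 100³ grid — the closed-form misfit makes it cheap.

## Known limitations

* The tip-spacing forward model is quantized: activation sites live on
  the discrete parent-vessel cells (one cell diameter apart), so
  density profiles are piecewise-constant in $d_{tip}$ over ~10 µm
  plateaus and calibration cannot resolve $d_{tip}$ more finely.
* `trace_skeleton` follows one branch per connected component from the
  endpoint nearest the vessel; heavily branched local regions would
  need a proper junction decomposition.
* Scenario 5's misfit compares per-day mean centerline distances; two
  different centerlines with coincidentally equal bidirectional means
  would be indistinguishable (not observed in practice, where growth
  asymmetry separates them).
* The well volume is treated as 1 mL so pg and pg/mL interchange; a
  different volume rescales the per-cell rates.
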
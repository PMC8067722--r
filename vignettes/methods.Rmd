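---
title: "Mechanically coupled reaction-diffusion forecasting of response to fractionated radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanically coupled reaction-diffusion forecasting of response to fractionated radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`rtforecast` forecasts the voxelwise evolution of two imaging-derived tissue
state variables in a brain tumor under fractionated radiotherapy: the tumor
cell volume fraction $\varphi_T(\bar{x},t)$ (from ADC maps) and the blood
volume fraction $\varphi_V(\bar{x},t)$ (from DCE-MRI). Both live on a regular
anisotropic voxel grid (default $250 \times 250 \times 1000\ \mu m$) inside a
brain mask.

## Untreated growth

Tumor cells obey a cross-diffusion/logistic equation,

$$
\frac{\partial \varphi_T}{\partial t} =
\nabla \cdot \Big( D_T \Big[
\big(1 - \tfrac{\varphi_V}{\theta_{T,V}}\big)\nabla \tfrac{\varphi_T}{\theta_{T,V}}
+ \tfrac{\varphi_T}{\theta_{T,V}} \nabla \tfrac{\varphi_V}{\theta_{T,V}}
\Big]\Big)
+ k_{p,T}\, \varphi_T \big(1 - \tfrac{\varphi_T}{\theta_T}\big),
$$

where $\theta_{T,V} = \theta_T + \theta_V$ sums the two species' carrying
capacities, so each species' spread is damped by the space the other
occupies. The tumor carrying capacity responds to local vascularity,

$$
\theta_T = \begin{cases}
\theta_{max} & \varphi_V \ge \varphi_{V,thresh} \\
\theta_{min} + \varphi_V \frac{\theta_{max}-\theta_{min}}{\varphi_{V,thresh}} & \text{otherwise,}
\end{cases}
$$

with $\theta_{min}$ assigned from the lowest tumor volume fraction observed
in the calibration visits and $\theta_{max}$, $\varphi_{V,thresh}$
calibrated. Vasculature obeys the mirrored equation plus depth-weighted
reaction terms $k_{p,V} \varphi_V (1 - \varphi_V/\theta_V)\, d$ (angiogenesis
at the rim) and $-k_{d,V} \varphi_V (1-d)$ (regression in the core), where
$d \in [0,1]$ is the normalized distance to the tumor periphery (1 at the
rim). We read the trailing $d$ of the growth term as a multiplicative factor,
by parallel structure with the $(1-d)$ death factor and the rim/core
biology.

## Mechanical coupling

Cell diffusion is damped by local von Mises stress,
$D_T = D_{T,0}\, e^{-\lambda_1 \sigma_{vm}}$ (and likewise $D_V$ from
$D_{V,0}$), with $\sigma_{vm}$ obtained from the quasi-static linear-elastic
equilibrium

$$
\nabla \cdot G \nabla \vec{u} + \nabla \tfrac{G}{1-2\nu} (\nabla\cdot\vec{u})
- \lambda_2 \nabla \varphi_T = 0,
$$

discretized with a 7-point conservative stencil (harmonic averaging of $G$ at
tissue interfaces) under a slip boundary condition: zero normal displacement,
free tangential motion, imposed through antisymmetric/symmetric ghost values
at the mask boundary. The assembled operator is symmetric negative definite;
we factorize $-A$ once per grid with a permuted sparse Cholesky and reuse the
factor for every solve of a calibration run. Stress is in kPa and
$\lambda_1$ carries 1/kPa so the damping exponent is dimensionless; defaults
are $G = 2.1/2.6$ kPa (white/gray), $\nu = 0.45$, $\lambda_1 = 0.25$,
$\lambda_2 = 1$, all configurable. The elasticity problem is re-solved at
least once per simulated day and whenever any voxel's $\varphi_T$ has moved
by more than 0.01 since the last solve; the literature this model builds on
does not state a cadence, and halving the refresh interval changes day-12
fields by well under the imaging noise.

## Response to fractionated radiotherapy

Eighteen family members arise from crossing three response mechanisms, three
spatial-efficacy couplings, and two proliferation-rate parameterizations:

* **RTM1** — instantaneous kill at each fraction:
  $\varphi_{post} = \varphi_{pre}\,(C_i \cdot SF)$.
* **RTM2** — RTM1 plus cumulative proliferation slowdown:
  $k_{p,T} = k_{p,T,0}\, (C_i \cdot SF^{\,n})$ after $n$ fractions.
* **RTM3** — no instantaneous kill; proliferation slowdown plus a delayed
  death rate $k_{d,T} = k_{d,T,0}\,(1 - C_i \cdot SF^{\,n})$ entering the
  tumor equation as $-k_{d,T}\varphi_T$.

Couplings: $C_1 = \varphi_T/\theta_T$ (densely packed, slowly proliferating
regions are spared), $C_2 = e^{-\alpha_1 \varphi_V/\theta_V}$ (well-perfused,
oxygenation-proxy regions respond more), $C_3 = 1$. The proliferation rate
$k_{p,T}$ is either one global scalar or a voxelwise field calibrated on a
node lattice (below). $SF$ is a single calibrated per-fraction surviving
fraction shared by tumor and vasculature; dose magnitude (2 vs 4 Gy/day)
enters only through the calibrated $SF$. The vasculature responds through
identical formulas with the vascular analogue of $C_1$ taken as
$\varphi_V/\theta_V$; under RTM3 the vascular RT death term reuses $k_{d,V}$
as its maximal rate (the source text does not name a separate constant).

Fractions are applied at the start of the treatment day, before the first
PDE step of that day; effective rates apply only after the first delivered
fraction ($n \ge 1$) — with $n = 0$ the printed formulas would alter
untreated dynamics whenever $C_i \ne 1$. When an imaging day coincides with
a treatment day the snapshot is taken before the fraction (pre-fraction
morning imaging).

# Numerics

Integration is fully explicit in time (forward Euler, $\Delta t = 0.01$ d)
with central spatial differences in conservative face-flux form: face
diffusivities are harmonic means, face fractions arithmetic means, and faces
on the brain-mask boundary carry zero flux, so with growth and death disabled
total burden is conserved to round-off. The scheme is guarded by the
criterion $2\,\Delta t\, D_{max} (\Delta x^{-2} + \Delta y^{-2} + \Delta
z^{-2}) \le 1$; if a trial parameter set violates it the step is halved (with
a warning) rather than aborting, which keeps annealing robust at extreme
trial points. Volume fractions are clipped to $[0,1]$ after each update and
an undershoot beyond $10^{-6}$ raises a stability warning. The distance
field $d$ is recomputed from the current model tumor extent
($\varphi_T \ge$ half the measured $\theta_{min}$ by default) every 25 steps
and at the start of every imaging interval; the inner time stepping runs in
compiled code.

# Calibration

Each family member is fitted to the tumor and blood volume-fraction maps of
its calibration visits by minimizing the unweighted residual sum of squares
over both fields, at all fitted visits after the first, on the union of the
measured tumor masks dilated by 2 voxels in-plane (the evaluation support;
the source does not state one, and the dilation admits model tumor spreading
slightly beyond the measured masks). `n_obs` counts both fields' residuals
over that support.

The optimizer is a hybrid: a simulated-annealing pass over the bounded
parameter box (geometric cooling; the exported defaults are T0 = 1, ratio
0.95, 50 proposals per temperature, stop below 1e-3 — every proposal is a
full PDE solve, so tests and scripted experiments pass smaller budgets as a
problem-size choice), followed by bounded Levenberg-Marquardt refinement
with a numerical Jacobian from the best anneal point and from the best
well-separated runner-up (two local polishes guard against the
surviving-fraction/growth-rate trade-off valley ending at the $SF = 1$
boundary). Rate-like parameters whose bounds span orders of magnitude are
searched on the log scale; estimates and intervals are reported on the
natural scale. Calibration bounds default to rates in $[10^{-3}, 10]$/day,
diffusivities in $[10^{-4}, 0.2]$ mm$^2$/day, $SF \in [0.5, 1]$,
$\varphi_{V,thresh} \in [10^{-3}, \theta_V]$, $\theta_{max} \in
[\theta_{min}, 1]$, $\alpha_1 \in [0, 10]$ — each bracket holds published
image-based estimates with at least a two-fold margin.

For voxelwise-$k_{p,T}$ members, each axial slice's tumor bounding box is
tiled into 3x3 in-plane blocks; the four corners and centre of each complete
block are calibration nodes and every other tumor voxel takes its nearest
node's value (ties to the lowest linear index), which both reduces the
parameter count to roughly 5/9 of the tumor voxels and regularizes the
field. Parameters a member does not use ($\alpha_1$ outside $C_2$,
$k_{d,T,0}$ outside RTM3) are excluded from the optimizer and from $k$.

95% confidence intervals are Wald-type: estimate $\pm\, t_{0.975, n-k}\,SE$
with standard errors from the Jacobian covariance scaled by $RSS/(n-k)$
(rank-deficient directions get unbounded intervals). Forecast ensembles draw
100 parameter sets per member, independently uniform within each interval
truncated to the hard bounds — the source states only that intervals were
"sampled", and the uniform choice is the least informative one confined to
the reported interval.

**What the intervals do and do not cover.** The linearized intervals
quantify uncertainty propagated from the *fitted observations*. They do not
model noise in the initial-condition maps (the forward model is seeded with
the first visit as-is), heteroscedasticity between the tumor and blood
volume-fraction residual blocks (the pooled residual variance follows the
unweighted RSS of the objective), or clipping of measured fractions at 0.
The coverage experiment in the test suite therefore places noise on the
fitted visits while seeding from the true initial field; with a noisy seed
map the intervals are anticonservative, which is a known limitation of this
(source-faithful) construction.

# Model selection and ensemble forecasts

Members are scored with the corrected AIC,
$AIC = 2k + n \ln(RSS/n) + 2k(k+1)/(n-k-1)$, computed from the calibration
residuals of the scenario being reported. Akaike weights
$w_i = e^{-\delta_i/2} / \sum_j e^{-\delta_j/2}$ give the ensemble forecast
$\varphi_{ens} = \sum_i w_i \cdot \frac{1}{J}\sum_j \varphi_{i,j}$: as
printed in the source the sample sum carries no $1/J$, which would inflate
the ensemble roughly 100-fold relative to the measurements it is plotted
against, so the sample dimension is averaged. For per-parameter-set ensemble
metrics the $j$-th draws of all members are weight-combined into the $j$-th
ensemble trajectory.

Two protocols are supported: scenario 1 calibrates to all imaging visits
(descriptive fit); scenario 2 calibrates to the first $\lceil V/2 \rceil$
visits and forecasts the remainder (predictive test).

# Error quantification

Global: percent error in predicted tumor volume (model volume = voxels with
$\varphi_T$ at or above the tumor-extent threshold, default half the
measured $\theta_{min}$ — the source never defines how the continuous field
becomes a predicted volume, so the threshold is configurable and recorded in
every report) and the Dice overlap of model and measured masks. Local:
Pearson and Lin concordance correlation of both fields over the union of
the measured and model masks. Metrics are computed at every comparison
visit for every sampled parameter set, then averaged over visits, yielding
100 time-averaged values per metric whose box-plot statistics are reported.
Selected-model and ensemble metric samples are compared with a two-sided
Wilcoxon rank-sum test (the source reports only "p < 0.05" without naming a
test; the rank-sum test needs no normality assumption at n = 100).

# The synthetic virtual-rat cohort

No animal data are distributed, so `generate_virtual_animal()` supplies
ground-truth-known datasets with the statistical structure the analysis
assumes: a Gaussian-profile lesion (peak $\varphi_T$ 0.6, e-folding radius
1 mm) with a peripherally elevated vascular ring on a 0.02 background,
integrated forward under a chosen generating member and one of the seven
experimental schedules (imaging days over 0-21 days; daily 2 or 4 Gy
fractions on the stated day ranges), snapshotted at the imaging days, with
Gaussian noise at SNR 20 (mean in-tumor signal over noise SD) added inside
the measured tumor mask — cellularity maps are estimated voxelwise within
the lesion ROI, so the background carries no measurement — and clipped to
$[0,1]$. Tumor masks are thresholded on the noiseless truth at
$\varphi_T \ge 0.05$. Default truth parameters reflect the 2 Gy/day cohort
(proliferation 1.40/day, diffusivity 2.58e-2 mm$^2$/day, per-fraction
survival 0.97; 0.90 under 4 Gy/day); reported diffusivities on the
$10^4\ \mu m^2$/day scale are interpreted as $10^{-2}$ mm$^2$/day.

The returned dataset carries the capacity constants ($\theta_{min}$,
$\theta_V$) the generating run actually used, so the synthetic inverse
problem is exactly self-consistent (the truth-initialized residual is
identically zero); the purely data-derived bounds, as a measured-data
workflow would assign them with `assign_capacity_bounds()`, are kept in the
attached truth record. What the generator does **not** emulate: registration
error, coil bias, Rician noise, partial-volume effects at the lesion rim,
and model mismatch (the data are generated by a family member, so passing
recovery tests demonstrates the inverse machinery, not that the model is
true of real tumors).

Raw MR signal synthesis (`synthesize_mr_signals()`) inverts the linear
ADC-cellularity map to emit three-b-value diffusion series, emits
inversion-recovery series from an assigned T1 map (30 inversion times,
125-3025 ms), and emits DCE tissue curves proportional to a bi-exponential
arterial input function after 25 baseline volumes; conversion from signal to
concentration is bypassed because the blood volume estimate is an AUC ratio
and therefore ratio-scale invariant.

# Problem sizes used by the test suite

Oracle-equivalence and analytic-limit checks run on grids up to
$32\times32\times8$ voxels (the desk-scale stand-in for the $128\times128
\times16$ acquisition matrix). The logistic-limit check uses a proliferation
rate of 0.84/day (the slow end of the cohort's published estimates), where
the forward-Euler discretization error at $\Delta t = 0.01$ d stays within
the $10^{-3}$ comparison tolerance. The noiseless parameter-recovery
experiment runs the full $32\times32\times8$ grid and the six-visit 2 Gy
schedule; the 20-replicate SNR-20 coverage experiment and the 10-replicate
model-identifiability experiment run reduced grids and compact annealing
budgets (each objective evaluation is a full 3D PDE solve), with the
competing subfamily in the identifiability experiment restricted to the
global-proliferation members. Grid size, annealing budget and subfamily
membership trade compute for statistical resolution; the acceptance
thresholds themselves are never relaxed.

# Known limitations

* Forward Euler is first-order in time; halving $\Delta t$ changes day-21
  fields by under $10^{-3}$ relative at default parameters, but stiff trial
  parameter sets during annealing rely on automatic step halving.
* The Wald intervals inherit the pooled-variance construction of the
  source's workflow and are anticonservative under input-map noise (see
  above).
* The nearest-node proliferation field is piecewise constant; it
  regularizes but cannot represent smooth gradients within a 3x3 block.
* Vascular RT response shares $SF$ with the tumor and reuses $k_{d,V}$ under
  RTM3; both are interpretation choices where the source is silent.
* The elasticity model is linear and isotropic with literature-style
  constants; ventricles and tissue anisotropy are not treated.
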
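# rtforecast

Image-informed forecasting of tumor and vasculature response to fractionated
radiotherapy.

`rtforecast` is for computational-oncology researchers who calibrate
mechanistic tumor-growth models to longitudinal quantitative MRI and want
subject-specific forecasts of response to fractionated radiotherapy (RT). It
implements a family of 18 mechanically coupled reaction-diffusion models of
two voxelwise observables — the tumor cell volume fraction
$\varphi_T(\bar{x},t)$ (from ADC maps) and the blood volume fraction
$\varphi_V(\bar{x},t)$ (from DCE-MRI) — together with the calibration,
model-selection, ensemble-forecasting and error-quantification machinery
around them, and a synthetic virtual-animal generator with known ground
truth.

## The model in brief

Untreated growth couples the two species through cross-diffusion and a
vascularity-driven carrying capacity:

$$
\partial_t \varphi_T = \nabla\!\cdot\!\Big(D_T\Big[(1-\tfrac{\varphi_V}{\theta_{T,V}})\nabla\tfrac{\varphi_T}{\theta_{T,V}} + \tfrac{\varphi_T}{\theta_{T,V}}\nabla\tfrac{\varphi_V}{\theta_{T,V}}\Big]\Big) + k_{p,T}\varphi_T\big(1-\tfrac{\varphi_T}{\theta_T}\big),
$$

with $D_T = D_{T,0} e^{-\lambda_1 \sigma_{vm}}$ damped by von Mises stress
from a quasi-static linear-elastic solve forced by $\nabla\varphi_T$, and an
analogous vasculature equation whose growth is weighted toward the tumor rim
and death toward the core. RT enters through a per-fraction surviving
fraction $SF$ in one of three mechanisms (instantaneous kill; kill plus
cumulative proliferation slowdown $k_{p,T} = k_{p,T,0} C_i SF^n$; a delayed
death rate $k_{d,T} = k_{d,T,0}(1 - C_i SF^n)$), crossed with three spatial
efficacy couplings ($C_1 = \varphi_T/\theta_T$,
$C_2 = e^{-\alpha_1 \varphi_V/\theta_V}$, $C_3 = 1$) and global or voxelwise
proliferation — 18 members. Members are calibrated by a hybrid simulated
annealing + Levenberg-Marquardt fit, scored with the corrected AIC, and
combined into an Akaike-weighted ensemble forecast. Agreement is quantified
globally (percent tumor-volume error, Dice) and locally (Pearson and Lin
concordance correlation), per sampled parameter set, time-averaged.

See the methods vignette (`vignettes/methods.Rmd`) for the full model,
numerics, and design rationale.

## Worked example

Generate a virtual animal on the six-visit, 2 Gy/day schedule, calibrate two
family members to the first half of its visits, and forecast the rest:

```r
library(rtforecast)

ds <- generate_virtual_animal(
  synthetic_truth(seed = 7, noise_snr = 20, schedule = "animal3"),
  default_grid(20, 20, 6))

pipe <- run_pipeline(
  ds,
  specs    = list(model_spec("RTM1", "C3", "global"),
                  model_spec("RTM3", "C3", "global")),
  scenario = 2, seed = 7, n_samples = 25,
  sa = sa_control(T0 = 0.5, cooling = 0.7, iters_per_temp = 10, T_min = 0.02),
  fixed = list(D_V0 = 0.031, phi_V_thresh = 0.03, theta_max = 0.94,
               kp_V = 0.82, kd_V = 0.29))
pipe
```

```
pipeline_result: scenario 2, 2 members, selected global-C3-RTM3
           spec k      RSS       AIC       weight
 global-C3-RTM3 4 2.682653 -32697.70 1.000000e+00
 global-C3-RTM1 3 2.833675 -32457.84 8.255758e-53
```

The data were generated by the RTM3 (death-rate) member, and the corrected
AIC selects it: its residual sum of squares over the calibration visits is
enough smaller than the instantaneous-kill member's to overwhelm the
one-parameter penalty, so it carries essentially all the Akaike weight.
Forecast quality at the three held-out visits, per sampled parameter set and
averaged over visits:

```r
print(pipe$metrics_selected$summary, row.names = FALSE)
```

```
        metric       q25    median       q75
 pct_vol_error 0.0000000 0.0000000 0.0000000
          dice 1.0000000 1.0000000 1.0000000
         pcc_T 0.9100297 0.9172943 0.9195980
         ccc_T 0.8916555 0.9000789 0.9095863
         pcc_V 0.9888648 0.9892564 0.9893749
         ccc_V 0.9783064 0.9853889 0.9874216
```

At this coarse demonstration grid the thresholded forecast reproduces the
measured tumor masks exactly (volume error 0%, Dice 1 — the lesion edge is
steep relative to the voxel size, so the model and measured masks coincide
voxel for voxel), while the voxelwise fields agree with correlation 0.92
(tumor) and 0.99 (vasculature) and slightly lower concordance, reflecting
the imaging noise in the held-out maps.

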
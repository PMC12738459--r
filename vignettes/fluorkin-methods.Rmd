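---
title: "Quantifying sodium fluoride PET uptake: models, normalizations and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sodium fluoride PET uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorkin)
```

## The problem

Sodium [18F]fluoride PET images osteoblastic activity: fluoride exchanges
into bone hydroxyapatite, so lesional uptake indexes new bone formation in
inflammatory diseases such as spondyloarthritis. The reference quantity is
the net influx rate `Ki` of an irreversible two-tissue compartment model
("2t3k": three rate constants, `k4 = 0`), which requires a 30-minute dynamic
acquisition, a plasma input function and nonlinear fitting. Clinical
practice prefers static standardized uptake values (SUVs), which are cheap
but depend on how the injected activity is normalized to body size. This
package implements the full comparison pipeline — input-function
calibration, compartment fitting, four SUV normalizations, VOI metrics and
the statistical battery that compares them — together with a synthetic-data
generator, so every stage is testable end to end without scan data.

## The kinetic model

With plasma concentration `Cp(t)` (kBq/mL) the tissue curve is

```
C_T(t) = (1 - vb) [ Ki * int_0^t Cp ds
                    + K1 k2/(k2+k3) * exp(-(k2+k3) t) (*) Cp ] + vb Cp(t),
Ki = K1 k3 / (k2 + k3)
```

where `K1` (mL cm^-3 min^-1) is delivery, `k2` (min^-1) efflux, `k3`
(min^-1) irreversible binding and `vb` the fractional blood volume. The
convolution is evaluated with the exact exponential update for
piecewise-linear inputs on the dense (1 s) grid, so the numerical curve
matches closed forms to well below 0.1% (verified against the
constant-input solution over a 27-point parameter grid in the tests).
`fit2t3k()` minimizes frame-duration-weighted least squares under box
bounds (`K1, k2, k3` in [0, 5], `vb` in [0, 0.5]) with Levenberg-Marquardt
from three spread starts, reporting the optimizer's convergence flag
honestly. The model is "2t3k" in the paper-protocol sense of three rate
constants; whether such in-house routines fit a blood-volume fraction is
typically unstated, so `vb` is fitted by default and can be pinned to zero
(`fitVb = FALSE`).

`patlakKi()` provides the graphical cross-check: the late-time slope of
`C_T/Cp` against `int Cp / Cp` estimates `Ki` for irreversible tracers.
Because the measured TAC holds frame averages, Cp and its running integral
are frame-averaged on the same schedule before the ratios are formed;
without this the 5-minute late frames bias the slope several percent.
Patlak retains an intrinsic transient underestimation at `t* = 10` min that
grows with `k2/k3`; for slow-equilibrating parameter draws (`k2/k3` around
15) it can exceed 5% even on noise-free dense curves, which is a property
of graphical analysis, not of this implementation. The dual-estimator
agreement is therefore summarized by the median disagreement over
generator draws (about 2%).

## Input function and calibration

The image-derived input function (IDIF) is a 1.7 cm^3 aortic VOI curve and
is miscalibrated by partial-volume and cross-calibration effects. Venous
samples at 5, 15 and 25 min anchor it: per sample the ratio
`sample / IDIF(t)` is formed and the mean ratio rescales the whole curve
(equivalently, one plus the mean percentage difference), preserving its
shape. `IDIF(t)` is interpolated at the sample times between frame
midpoints. The alternative reading — the raw value of the frame containing
the sample — is available (`method = "frame"`) but compares an
instantaneous sample against a 5-minute frame average and biases the factor
by several percent at the late samples; midpoint interpolation keeps the
round-trip error per frame around 0.2%, the residual being the
frame-average-versus-midpoint curvature of the bolus itself.

## SUV normalizations

`SUV = C / (A / NF)` with concentration `C` in kBq/mL and injected activity
`A` in MBq. The four normalization factors are body weight (g), lean body
mass (g, Janmahasatian fat-free-mass equations), body surface area
(DuBois-DuBois by default, Mosteller optional) and skeletal volume (the
combined volume of the bones in a whole-body field of view scaled by 1.80
to a total-skeleton estimate). Unit conventions are fixed so reported
values sit on the customary printed scales: BSA enters as cm^2/10 and SV in
mL, which makes population means read as "SUV_BSA x 10^2" and
"SUV_SV x 10^2" next to SUV_BW and SUV_LBM of order 1-4. All four SUVs of
one measurement are exact ratios of their normalization factors.

## What the generator emulates

`generateStudy()` reproduces the statistical structure the analysis
assumes, with defaults frozen at the study conditions:

* **Cohort.** Height normal 172.9 (6.9) cm; weight lognormal with mean 86.2
  and SD 20.1 kg; 48% female; therapy 38/62% anti-TNF/IL-17A; injected
  activity normal 100.5 (5.0) MBq at baseline, 101.5 (5.4) at week 12.
  Weight and sex are drawn independently (the emulated tables specify only
  marginals), and body weight is held constant across timepoints.
* **Plasma curve.** A tri-exponential bolus (rates 4, 0.25, 0.02 min^-1,
  linear rise to a peak at 1 min) whose two slow amplitudes are solved so
  the population-mean blood SUV-LBM passes exactly through 2.44 at 5 min
  and 1.34 at 25 min (1.67 at 15 min follows). The amplitude scales as
  injected activity over a distribution volume proportional to lean body
  mass (adipose fraction 0, encoding fluoride's negligible fat uptake);
  this single assumption is what makes blood SUV_BW weight-dependent while
  SUV_LBM is not. A patient-level lognormal scale factor (CV 0.15) and a
  scan-level factor (CV 0.05) supply biological variability; together with
  3% venous sampling error they reproduce the observed blood-SUV
  coefficients of variation (about 22% for BW, 14-16% for LBM).
* **Skeletal volume.** No image exists to segment, so partial bone volume
  is a synthetic stand-in drawn proportional to lean body mass (28 mL/kg,
  5% lognormal noise) — skeletal volume tracks fat-free mass in vivo, and a
  height-and-sex-only model would impose a spurious negative weight trend
  on SUV_SV that the emulated study does not show. The implied total
  skeleton (about 3 L for an average adult) also places SUV_SV on the
  printed x 10^2 scale.
* **Lesion kinetics.** The printed tables report no lesion-level `K1, k2,
  k3` distributions, so defaults come from fluoride-kinetics literature:
  lognormal with medians 0.12 mL cm^-3 min^-1, 0.30 min^-1, 0.10 min^-1
  (log-SDs 0.35/0.30/0.35), truth `vb = 0`. The week-12 treatment effect is
  lognormal with median 0.8 (log-SD 0.25) applied to `K1`, so the whole
  tissue curve — and hence `Ki` — scales by it; that choice makes the
  zero-noise longitudinal identity `ratio_SUV = ratio_Ki` exact, which the
  tests rely on.
* **Dynamic noise.** Zero-mean Gaussian per frame with SD proportional to
  `sqrt(value/duration)` (count-statistics weighting), level 0.2; clipped
  at zero.
* **Static patch.** A 15^3 cube of 4-mm voxels holding one Gaussian blob
  (FWHM 8 mm, emulating partial-volume blur) whose amplitude above a flat
  bone background (25% of the lesion amplitude) equals the model curve at
  45 min, with 5% voxel noise and a continuous uniform VOI-placement jitter
  of up to 1 voxel per axis. The jitter is the mechanism by which 45-minute
  SUVs degrade relative to the 25-30-minute window that shares its VOI with
  the kinetic fit.

What the generator does **not** emulate: anatomy and reader-dependent
lesion selection, patient motion, scatter/randoms, partial-volume spill-in
from neighbouring structures, and any correlation between disease activity
and body composition. Passing tests therefore demonstrate the correctness
and calibration of the computational pipeline under the stated generative
assumptions, not clinical performance on real scans.

## VOI metrics

Spheres of fixed volume use the centre-in-sphere voxel rule: a 1.2 cm^3
lesion VOI on the 4-mm grid keeps 19 voxels (1.216 mL realized), the
1.7 cm^3 aorta VOI 27. The VOI centre is the hottest voxel, ties broken to
the lowest linear index. `SUVpeak` is the highest mean of a movable 1 cm^3
sphere centred on any voxel inside the VOI (the harmonized-protocol
reading; the sphere volume is configurable because "peak inside the VOI"
admits a hottest-voxel-neighbourhood reading too). At the 25-30-minute
window only the region-level TAC exists, so the record is the VOI mean; a
voxelwise maximum would need a dynamic patch.

## Statistics

The battery mirrors the comparative analysis: coefficient of variation
(SD/mean); Levene's test applied after dividing each group by its own mean
(mean centring by default, median optional) so relative variances of
differently scaled SUV sets are comparable; Welch t-tests between the
above/below-85-kg groups per sample moment (Student optional); Pearson R^2
with Fisher-z intervals squared at the endpoints (the interval method is a
design choice; the lower endpoint is 0 when the r interval spans zero);
Williams' test for dependent overlapping correlations in the
determinant form with n-3 degrees of freedom, type-I calibrated against a
trivariate-normal Monte-Carlo oracle rather than a library; OLS
`Ki ~ SUV + therapy` for residual treatment effects; Bland-Altman bias and
1.96-SD limits, on the log scale for ratio comparisons. Lesions from the
same patient are pooled without a clustering correction, mirroring the
emulated design, and no multiple-testing correction is applied (none is in
the emulated analysis); reported p-values are raw.

## Numerical choices

Dense grids run 0-48 min at 1 s; frame averaging is trapezoidal over exact
frame boundaries; `k2 + k3 = 0` falls back to pure accumulation
`K1 int Cp`; the optimizer stops at cost tolerance 1e-8 or 500 iterations;
an all-zero TAC short-circuits to the exact `K1 = 0` solution with
`converged = TRUE`; degenerate correlations (zero variance) are returned as
flagged degenerate results, never silent `NaN`; identical constant groups
in the weight t-test return `t = 0, p = 1` rather than erroring. All
randomness flows from one master seed through labelled hash-derived
per-patient, per-stage streams, so enlarging a cohort never reshuffles
existing records.

## Problem sizes used in the test suite

The suite exercises the pipeline at sizes chosen to keep Monte-Carlo error
well below the asserted margins: 92 scans (46 patients, all with follow-up)
for the venous contrast, 500 noisy lesions for parameter recovery (median
relative Ki error and fit-truth correlation), 16 zero-noise pairs for the
longitudinal closure identity and 80 noisy pairs for the window-ordering
comparison, and 2000-replicate null simulations for the type-I error of the
Williams and Levene tests.

## A worked example

```{r example, eval = FALSE}
res <- runStudy(defaultRunConfig(seed = 1))
res$venous_summary       # mean blood SUV and CoV per normalization/moment
res$weight_group         # 85-kg Welch tests per moment/normalization
res$cross_sectional      # R^2 of each SUV metric against fitted Ki
res$longitudinal         # follow-up/baseline ratio agreement per window
```

## Known limitations

Single-lesion-per-scan defaults (configurable); no partial-volume
correction, motion, or delay/dispersion fitting (fluoride needs no
metabolite correction); the 1.80 skeletal scaling factor is adopted as a
constant, not re-derived; the synthetic skeletal volume is a documented
stand-in, not a measurement; Patlak is a cross-check, not a parametric
imaging implementation.
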
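---
title: "Image-derived arterial input functions for dynamic PET: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{idaif methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(idaif)
```

# Scope

`idaif` quantifies dynamic brain PET without arterial sampling. Its core is
an estimator that reconstructs the arterial plasma input C_P(t) from two
image-derived time-activity curves — an arterial region of interest (ROIa)
defined on co-registered MR angiography, and one large brain region — and a
quantification stack around it: the two-tissue compartment (2TC) forward
model, Logan graphical analysis in arterial and reference-region forms, a
V_T-constrained full kinetic fit, ROI construction with partial-volume
bookkeeping, and seeded synthetic-data generators that exercise everything
end to end. Registration, segmentation of real MR data, motion correction
and scanner harmonization are out of scope; all volumes are assumed
co-registered and on a common grid.

# The model and its assumptions

## Two-tissue compartment model

Free/nonspecific tracer (C_ND) and specifically bound tracer (C_S) exchange
with plasma and with each other:

$$\frac{dC_{ND}}{dt} = K_1 C_P - (k_2+k_3) C_{ND} + k_4 C_S,\qquad
  \frac{dC_S}{dt} = k_3 C_{ND} - k_4 C_S.$$

The measured tissue curve is $C_T = C_{ND}+C_S$; the closed-form solution is
a bi-exponential impulse response convolved with $C_P$, with eigenrates
$\alpha_{1,2} = \tfrac12\big[(k_2+k_3+k_4) \mp
\sqrt{(k_2+k_3+k_4)^2-4k_2k_4}\big]$ ($\alpha_1$ is defined as the smaller
root; the discriminant is non-negative for non-negative rates). Derived
macro-parameters: $V_T = (K_1/k_2)(1+k_3/k_4)$, $BP_{ND} = k_3/k_4$,
$DVR = 1+BP_{ND}$. Units are minutes throughout; $K_1$ is in
mL cm$^{-3}$ min$^{-1}$, other rates in min$^{-1}$; activity units are
arbitrary but must be consistent across curves. Input curves are assumed
decay-corrected.

## Logan graphical analysis

With arterial input the regression of $\int_0^T C_T/C_T(T)$ on
$\int_0^T C_P/C_T(T)$ becomes linear once the tissue equilibrates; the
slope estimates $V_T$. The reference form replaces the plasma integral with
$(\int_0^T C_R + C_R(T)/k_2')/C_T(T)$ and its slope estimates DVR provided
the reference is binding-free and shares $K_1/k_2$ with the target. Both
fits are unweighted ordinary least squares over frames whose midpoints fall
in the closed window 30–60 min. The window is stated for the reference form
in the source methodology; we apply the same window to the arterial form
(same linearity argument) and expose both ends plus $k_2'$ (default
0.16/min) as configuration.

Logan slopes carry a *negative linearization bias* when equilibration is
incomplete: for the slow kinetics typical of this tracer class
($\alpha_1 \approx 0.03$/min, time constant ~30 min) the bias reaches
2–3.5% at the 30–60 min window. This is a property of the estimator, not an
implementation artifact — a dense-grid continuous-curve oracle in the test
suite reproduces it — and it propagates into everything that consumes a
Logan $V_T$.

## IDAIF estimation

The arterial ROI sees an attenuated blood signal plus tissue spill-over:

$$C_{ROIa} = r\,C_B + s\,C_{BG}.$$

The recovery coefficient $r$ is *computed*, not fitted: the binary vessel
mask is blurred with the scanner point-spread function (8 mm FWHM Gaussian)
and averaged over ROIa voxels. ROIa is the blurred vessel mask thresholded
to 16 cc inside a user-supplied voxel box (the stand-in for an atlas-space
carotid box); a 100 cc envelope thresholded over the whole volume, minus
ROIa, forms the background mask whose curve is $C_{BG}$.

$C_P$ is reconstructed from a large tissue region's curve (default: the
cerebellar cortex, the largest parcellated region — any large region works)
by inverting a dual one-tissue description: the early branch
$(1/K_1)\,dC_t/dt + (k_2/K_1)C_t$ holds before the tissue peak $t_{peak}$;
after $t_{late}$ (40 min) the effective washout $k_{2a} = k_2/(1+k_3/k_4)$
replaces $k_2$; between them the branches are blended with $w_1$ falling
linearly from 1 to 0 in time (the plainest reading of "linearly
decreasing"; the source does not parameterize the blend). $C_B$ follows
from $C_P$ through a population parent-fraction model, and the four free
parameters $(K_1, k_2, k_{2a}, s)$ minimize the per-frame squared misfit of
the modeled ROIa curve. The constraint $k_{2a}\le k_2$ is enforced by
reparameterization $k_{2a}=k_2\rho$, $\rho\in(0.05,1]$; five seeded
log-uniform multi-starts (K1, k2 in [0.05, 0.5], rho in [0.2, 1], s in
[0, 0.5]) guard against local minima. Negative reconstructed plasma values
are floored at zero and counted.

## Constrained kinetic fit

Per region, $(K_1, K_1/k_2, k_3)$ are fitted against the IDAIF with $V_T$
fixed at the regional Logan value and $k_4$ recovered from
$k_4 = k_3/(V_T/(K_1/k_2)-1)$; $DVR_{kinetic}= V_T/(K_1/k_2)$. Below
$K_1/k_2 = V_T$ the family degenerates (large $k_4$ mimics a one-tissue
model of volume $V_T$), so the collapsed no-binding candidate ($k_3=0$,
$K_1/k_2=V_T$) is evaluated explicitly and kept when it fits at least as
well; such rows are flagged `k3_pinned_to_zero`. Bounds:
$K_1\in[0.01,1]$, $K_1/k_2\in[0.5,10]$, $k_3\in[0,0.5]$; three seeded
starts. A useful robustness property: a multiplicative error in the input
scales $V_T$ and the fitted $K_1/k_2$ equally, so $DVR_{kinetic}$ is
invariant to AIF scale errors — only shape errors matter.

# Numerical choices

* **Frame averages, not point samples.** Every TAC value is treated as a
  frame average. Reading frame-averaged values as midpoint samples flattens
  the bolus peak and biases any consumer of the early curve; the package
  therefore reconstructs, where it matters, the piecewise-linear curve
  whose frame averages reproduce the data (a small banded linear solve with
  negative nodes floored at zero). This reconstruction feeds (a) the
  forward model when its input is a TAC, (b) the running integrals of the
  Logan forms, and (c) frame-boundary values for the default
  `frame_balance` derivative in the IDAIF inversion, which uses the exact
  identity mean(dCt/dt over a frame) = (Ct(end)−Ct(start))/duration.
  Midpoint central differences remain available (`deriv = "central"`), and
  `finite_diff_derivative()` keeps the plain central-difference contract.
  Without these choices the constrained fit absorbs discretization error
  into $K_1/k_2$ and inflates $DVR_{kinetic}$ by roughly 10% even on
  noiseless data.
* **Exact convolution.** The 2TC forward model convolves each
  impulse-response mode with the piecewise-linear input in closed form via
  a linear recurrence (exponential integrator), on an internal grid of
  1/120 min chosen so 10-second frame boundaries fall on grid nodes; frame
  averaging is then exact trapezoid integration. There is no quadrature
  error beyond the input representation. The degenerate equal-eigenrate
  case is split by a relative $10^{-7}$ perturbation.
* **Optimizers.** All fits use box-constrained L-BFGS-B with seeded
  multi-starts; objective evaluations outside the valid domain return a
  large finite penalty so numerical gradients never abort. Convergence
  factors: $10^3$ (IDAIF cost), $10^2$ (kinetic fit).
* **Volume thresholds.** Volume-targeted thresholding sorts the positive
  smoothed intensities and picks the count closest to the target, requiring
  agreement within one voxel (flat plateaus are reported as unattainable
  with the achievable range); ties resolve to the higher threshold.
  Smoothing uses bin-integrated Gaussian kernels (exact for the boxcar
  voxel model), truncated at 5 sigma, with zero padding.
* **Weights.** Residual weighting is off by default (the source is silent).
  For noisy data the documented configuration is `weights = "ivar"`
  (duration/activity, the inverse of the reconstructed-PET variance model)
  plus `smooth_derivative = TRUE` (cubic smoothing spline before the
  derivative); unweighted fits on noisy early frames are dominated by the
  10-second frames and can fail badly.

# The synthetic world

`make_subject()` generates: a bolus plasma input (zero until 0.25 min,
linear rise to a peak of 100 at 0.75 min, tri-exponential decay with
fractions 0.75/0.20/0.05 and rates 3.0/0.25/0.012 per min — a sharp first
pass, a distribution phase, and a slow terminal tail); regional tissue
curves from the closed-form 2TC model on the 26-frame protocol; a
background curve (1TC, $K_1=0.15$, $k_2=0.05$); and the arterial-ROI curve
mixed per $r C_B + s C_{BG}$ with defaults $r=0.55$, $s=0.15$ — mid-range
for a carotid ROI at 8 mm resolution. Cohort presets share
$K_1/k_2 = 3.2$ across regions (the reference-validity condition holds
exactly, consistent with the published cohort's cerebellar $V_T\approx3.2$
and cortical $K_1/k_2\approx3.1$): cortical $BP_{ND}$ 0.3–0.6 ("PiB+") or
0.02–0.1 ("PiB-"), $k_4 = 0.04$/min (mid-range of literature estimates for
this tracer class). The parent-fraction default
$f(t) = 0.05 + 0.95 e^{-0.15 t}$ is a configurable stand-in — the actual
population curve is not printed in the source — and the generator always
uses the configured model, so generator and estimator are metabolite-
consistent by construction. The conversion direction (plasma-parent to
whole-blood, scale factor 1) is exposed rather than guessed, because the
phrase "parent compound ratio" is directionally ambiguous.

The arterial-ROI curve is generated through the same dual-1TC chain the
estimator inverts, driven by the reference region's true rate constants.
Consequence: on noiseless data the IDAIF cost at the true parameters is
*exactly* zero, making parameter-recovery tests sharp. This is a deliberate
inverse-crime at the level of the ROIa mixing only; the tissue curves
themselves come from the full closed-form 2TC model, and the reconstruction
must still undo frame discretization.

Noise is heteroscedastic Gaussian with variance proportional to
activity/duration. The documented "PET-like" level 0.3 yields ~3% CV on
late 5-minute frames of a large region and ~10% on early 10-second frames.
The vessel phantom is a curved bright tube (radius 4 mm, sinusoidal
centerline) in mid-intensity tissue with seeded noise, plus a matching
carotid-box; a 4D variant assigns blood and tissue curves to the two
compartments and blurs each frame with the PSF, so extracted ROIa curves
genuinely exhibit recovery and spill-over.

What a green test does **not** establish: performance under motion,
registration error, scanner resolution mismatch, individual metabolite
variability, dispersion/delay of the input, or tissue heterogeneity — none
of which the generator emulates.

# Measured behavior and honest limits

* Noiseless end-to-end recovery (26-frame protocol): regional $V_T$ within
  3.5% of generating truth (Logan linearization bias dominates),
  $DVR_{kinetic}$ within 0.3%.
* At noise level 0.3, single-realization worst-region errors reach ~16%
  ($V_T$) and ~25% ($DVR_{kinetic}$, smallest-$K_1$ region); averaged over
  three noise realizations the per-region mean absolute errors stay within
  15%. The $V_T$ scatter is dominated by a spatially global input-scale
  error — the same pattern the source reports in vivo (cerebellar $V_T$ CV
  14.8–19% across subjects, against ~4% for DVR measures).
* $k_2'$ insensitivity: varying $k_2'$ ten-fold changes DVR by 0.3% at
  $BP_{ND}=0.05$ and 1.1% at 0.2, but 2.6% at 0.5 — also 2.6% in the
  continuous limit, i.e. a property of this synthetic world (its slow
  plasma tail keeps the late reference level high), not of the code. The
  corresponding acceptance assertion at the 2% threshold is deliberately
  left failing for the high-binding pair.
* One published summary cell (prefrontal $V_T$, negative group) prints a
  CV% inconsistent with its own printed mean and SD; the acceptance suite
  asserts the inconsistency rather than pretending agreement.

# Known limitations

Single-scale population metabolite correction (no venous calibration); no
dispersion/delay correction; regional (not voxelwise) outputs; the simple
percentile vessel segmenter is a stand-in for adaptive MRA segmentation;
NIfTI support is minimal (little-endian NIfTI-1, common datatypes) because
no NIfTI package is available in the dependency budget.
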
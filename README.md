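# idaif

Quantification of dynamic brain PET without arterial blood sampling, built
around an **image-derived arterial input function (IDAIF)**.

## The problem

Amyloid PET tracers such as [11C]PiB are normally quantified with a
reference-region method: the cerebellar cortex is assumed amyloid-free and
to share the target regions' delivery ratio K1/k2. In prion disease,
familial Alzheimer disease, stroke, or any condition that alters cerebellar
kinetics, that assumption fails. The alternative — full kinetic modeling
against the arterial plasma input C_P(t) — classically requires invasive
arterial catheterization. This package implements an image-based route: the
plasma input is *estimated* from two image-derived time-activity curves (an
arterial ROI built from co-registered MR angiography, and a large brain
region), after which every standard quantification follows.

## The model

Tissue kinetics follow the two-tissue compartment model,

    dC_ND/dt = K1 C_P - (k2 + k3) C_ND + k4 C_S
    dC_S/dt  = k3 C_ND - k4 C_S,          C_T = C_ND + C_S

whose closed-form solution is a bi-exponential impulse response (eigenrates
alpha_1,2 = ((k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4))/2) convolved with
C_P. Macro-parameters: total distribution volume V_T = (K1/k2)(1 + k3/k4),
binding potential BP_ND = k3/k4, and DVR = 1 + BP_ND.

**Logan graphical analysis.** Late-time linearization: regressing
int_0^T C_T / C_T(T) on int_0^T C_P / C_T(T) over 30–60 min gives V_T as
the slope; the reference-region form, with
x = (int_0^T C_R + C_R(T)/k2') / C_T(T) and k2' = 0.16/min, gives DVR.

**IDAIF estimation.** The arterial-ROI curve is modeled as
C_ROIa = r C_B + s C_BG, where r is the recovery coefficient (computed by
blurring the vessel mask with the 8 mm FWHM point-spread function and
averaging over the ROI), s is spill-over from a background shell, and C_B
is whole blood derived from C_P by a population parent-fraction model.
C_P itself is reconstructed from a large tissue region's curve via a dual
one-tissue model:

    C_P = (1/K1) dCt/dt + (k2 /K1) Ct     before the tissue peak
    C_P = (1/K1) dCt/dt + (k2a/K1) Ct     after 40 min   (k2a = k2/(1+k3/k4))

with a linear blend in between. The four free parameters (K1, k2, k2a, s)
are fitted by bounded multi-start nonlinear least squares on the measured
arterial-ROI curve; the fitted C_P then drives Logan analysis (V_T per
region) and a constrained 2TC fit (K1, K1/k2, k3 free; V_T fixed at the
Logan value) that yields DVR_kinetic = V_T / (K1/k2) without any reference
region.

## Worked example

```r
library(idaif)
sub <- make_subject(seed = 1, cohort = "PiB+", noise = 0)   # synthetic subject
fit <- fit_idaif(sub$tacs$cerebellum, sub$croia, sub$cbg,
                 r = sub$r, pf = sub$pf, seed = 1)
cat(sprintf("fitted spill-over s = %.3f (true %.3f), cost Q = %.2e\n",
            fit$params$s, sub$s, fit$diagnostics$Q))
tab <- quantify_subject(sub$tacs, fit$cp, ref_region = "cerebellum", seed = 1)
print(tab[, c("region", "V_T", "DVR_REF", "DVR_kinetic")], digits = 3)
```

prints

```
fitted spill-over s = 0.150 (true 0.150), cost Q = 4.72e-06
      region  V_T DVR_REF DVR_kinetic
1 cerebellum 3.20    1.00        1.00
2  precuneus 4.95    1.51        1.60
3 prefrontal 4.64    1.42        1.50
4   temporal 4.20    1.30        1.35
5    caudate 4.04    1.25        1.30
6         MC 4.46    1.37        1.44
```

The subject was generated with cerebellar V_T = 3.2 and cortical
BP_ND = 0.3–0.6 (true DVR 1.30–1.60). The fitted input recovers the
spill-over coefficient exactly on noiseless data; regional V_T carries the
expected 2–3% Logan linearization bias, DVR_kinetic matches the generating
DVR to ~0.2%, and DVR_REF shows the slightly larger negative bias intrinsic
to the reference-Logan linearization. `MC` is the mean cortical summary row.

## Documentation

The methods vignette (`vignettes/idaif-methods.Rmd`) describes the model
and its assumptions, every tunable parameter with units and defaults, what
the synthetic generator does and does not emulate, the numerical choices,
and known limitations.
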
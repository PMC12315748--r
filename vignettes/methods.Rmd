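---
title: "Models, phantoms and design choices in dynpet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, phantoms and design choices in dynpet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dynpet` quantifies dynamic brain PET with reference-tissue models and
asks how reproducible those quantities are across a short test–retest
interval. This vignette explains the models, the conventions that had to
be fixed where the field leaves them open, what the synthetic phantoms do
and do not emulate, and the numerical choices that make everything
deterministic.

## Temporal model

All kinetics run on a `frame_schedule`: ordered frames with start/end
times in minutes. The stock schedule (`mk6240_frame_schedule()`) has 37
frames in two segments — 29 frames over 0–65 min (6×10 s, 6×20 s, 2×30 s,
2×60 s, 2×120 s, 11×300 s) and 8×300 s frames over 80–120 min — with a
15-minute break during which the subject can leave the scanner.

Two conventions matter everywhere downstream:

* **Frame values are time-averages.** A reconstructed frame reports the
  mean concentration over its duration, not an instantaneous sample.
  Forward simulation honours this: model curves are averaged over each
  frame, so a simulated TAC is directly comparable to a sampled one.
* **The break is bridged linearly between frame midpoints.** Running
  integrals (needed by MRTM2) treat each frame's value as constant over
  its duration; across the 65–80 min gap the integrand interpolates
  linearly between the midpoints of the flanking frames. Any bridging
  rule is an assumption — no data exist in the gap — and linear
  interpolation between midpoints is the minimal one. It is exact for
  concentrations varying linearly in time, which is a good local
  approximation for slowly-varying late-time curves, and it is covered by
  a dedicated test against dense quadrature of the same piecewise
  integrand.

Internal units are minutes and kBq/mL throughout; SUV values are g/mL.

## Outcome measures

**SUV and SUVR.** `SUV = C / (ID/BW)` with the injected dose in kBq and
body weight in g. The late window is 90–110 min (four 5-min frames,
averaged unweighted since they share one duration). SUVR divides target
by reference SUV; the constructor refuses ratios across different windows
or mixed partial-volume-correction status, so a corrected numerator can
never silently meet an uncorrected denominator.

**SRTM (R1, k2, BP).** The simplified reference tissue model writes the
target TAC as

$$C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a})\, C_R(t) \otimes e^{-k_{2a} t},
\qquad k_{2a} = k_2 / (1 + BP).$$

The fit uses basis functions: for each $k_{2a}$ on a fixed grid the model
is linear in $(R_1,\ \theta_2 = k_2 - R_1 k_{2a})$ and solved by weighted
least squares; the grid minimizer of the weighted residual sum of squares
is refined by golden-section search on $\log k_{2a}$. Choices:

* grid: 256 log-spaced points on $[10^{-3}, 1]$ min⁻¹, wide enough to
  bracket apparent efflux rates from slow white matter to fast delivery;
  a solution at the grid edge raises a diagnostic flag;
* weights: frame durations, the usual count-statistics proxy (longer
  frames carry more counts). Exposed as an argument;
* when the washout term is indistinguishable from zero (target equals
  reference), $k_2$ and $BP$ are unidentifiable; the fit reports
  $R_1 = 1$, $BP = 0$ and flags the degeneracy rather than guessing.

Basis functions were chosen over nonlinear least squares because the
solution is deterministic and has no starting-value sensitivity; on
noise-free forward-model data the fit recovers $R_1$ and $BP$ to well
under 1%.

**MRTM2 (DVR).** The multilinear reference tissue model 2 regresses

$$C_T(t_m) = \gamma_1\!\left[\int_0^{t_m}\! C_R + \frac{C_R(t_m)}{k_2'}\right]
 + \gamma_2 \int_0^{t_m}\! C_T$$

over frames with midpoint $t_m \ge t^*$, giving
$DVR = -\gamma_1/\gamma_2$. Defaults are $t^* = 30$ min and
$k_2' = 0.04$; the units of $k_2'$ are taken as min⁻¹, consistent with
how reference-region efflux rates are reported in this literature, and
the synthetic reference region is generated with exactly this efflux so
"matched $k_2'$" is well defined. The $t^*$ rule is applied to frame
midpoints, one of several defensible inclusion conventions; it is fixed
and documented so results are reproducible. The regression is weighted by
frame durations, needs at least three included frames, and errors on a
singular design rather than returning a meaningless ratio.

## Partial-volume correction

The voxel-based iterative Yang method: per iteration, (1) replace every
voxel by its region mean (voxels outside all named regions form an
implicit background region — the method requires a full tessellation),
(2) smooth that regional mean image with the assumed PSF, (3) multiply
the *original* data by the ratio unsmoothed/smoothed. Ten iterations and
a 5 mm Gaussian PSF are the defaults; both are configurable since the
appropriate kernel is scanner-specific.

Numerical conventions: $\sigma = \mathrm{FWHM}/2.3548$ applied per axis
in voxel units (isotropic in mm even for anisotropic voxels); borders are
handled by nearest-edge extension, which preserves constants exactly —
hence globally uniform images are exact fixed points. Division is guarded
at $10^{-6}$ of the volume's robust maximum (0.999 quantile); guarded
voxels get correction factor 1 and are counted in an attribute.

One property worth stating because it is easy to assume and false: an
*unblurred* piecewise-constant image is **not** a fixed point of the
voxelwise correction — the correction map $m/G(m)$ differs from 1 near
region boundaries, so the method sharpens edges it believes were blurred.
The meaningful recovery property, which the tests assert, is that a
piecewise-constant phantom blurred with the modelled PSF is restored to
its regional means (exactly, in the matched noise-free case).

## Region machinery

Morphology is mm-aware, built on an exact Euclidean distance transform
(separable squared-distance algorithm with per-axis physical spacing).
Erosion keeps voxels whose center-to-center distance to the nearest
outside voxel is at least `distance + mean(voxdim)/2`: the half-voxel
term places the mask boundary *surface* half a voxel beyond the outermost
voxel centers. Without it the effective erosion depth depends on voxel
size (about half a voxel shallower on coarse grids, a ~19% volume effect
when halving 2 mm voxels on a 14 mm sphere); with it, eroded volumes are
stable under grid refinement to within a few percent. The extracerebral
shell is the set of voxels strictly outside the brain within the shell
thickness (default 5 mm, exposed as a parameter since published variants
range 2–5 mm) of the nearest brain voxel.

Bilateral regions are pooled at the voxel level (volume-weighted), not
averaged as two hemisphere means: identical for symmetric phantoms,
better behaved when hemispheric ROI sizes differ. Region masks are
resolved once per study and reused, so test and retest scans are sampled
with voxel-identical regions by construction.

## The synthetic cohort generator

No subject-level dynamic tau-PET data are publicly available at the
scale needed to exercise this pipeline, so validation runs on phantoms
whose ground truth is known exactly.

**Geometry** (64³ voxels, 2 mm isotropic by default — small enough for
minute-scale test suites, large enough for 5 mm morphology): a spherical
brain envelope containing a cerebellar-grey reference blob, a pons blob,
a white-matter core, nine target blobs (including a small
entorhinal-like region of ≈650 voxels, the smallest ROI size of
practical interest), a filler region for remaining brain tissue, and a
5 mm extracerebral shell around the brain.

**Kinetics.** The reference region is a one-tissue compartment with
efflux 0.04 min⁻¹ driven by a plasma-like input (fast rise, bi-exponential
washout); everything is a sum of exponentials, so frame averages are
computed from the closed-form antiderivative. Default amplitudes were
calibrated once so the reference SUV over 90–110 min sits mid-range in
the plausible 0.35–0.72 g/mL band at a typical 185 MBq / 74 kg dose per
weight, with the perfusion peak before 5 min. Target regions follow SRTM
forward curves with per-region $(R_1, BP)$ truths chosen inside the
published older-CN and AD plausibility ranges ($R_1 \in [0.66, 1.39]$;
oCN SUVR ≈ 0.8–1.1; AD SUVR up to ≈ 2.8), with $k_2 = R_1 k_2'$ as the
model implies. The shell follows a slow saturating curve calibrated to a
late-window shell/reference ratio of 1.38, with a seeded smooth spatial
heterogeneity field (±30%) and large between-subject amplitude spread
(lognormal CV 0.4) — extracerebral signal is the most variable component
of real data.

**Variability model.** Each subject draws between-subject truth jitter
(CV 0.10 on $R_1$ and on $1+BP$, 0.20 on global uptake amplitude). Each
*session* then independently draws (a) a global multiplicative scale
jitter (CV 0.07; the dose/weight-measurement analogue — it moves every
SUV but cancels in SUVR), and (b) per-region multiplicative jitter at
the region class's within-subject CV: 0.05 for target-class regions,
0.12 for the shell, 0 for reference-class regions. Acquisition noise is
zero-mean Gaussian with per-frame SD proportional to value/√duration,
scaled to a chosen CV at 300-s frames; averaged over thousands of region
voxels it contributes little at the regional level, which is the point —
regional test–retest variability in this model is dominated by
physiological/procedural jitter, as in real data.

Two design points deserve emphasis:

* Jitter is applied independently to *both* sessions, making the
  within-subject CV a per-measurement quantity; the expected absolute
  test–retest percentage difference is then the half-normal mean
  $\mathbb{E}[\text{T-RT\%}] = 200\sqrt{2/\pi}\,\sqrt{2}\,\mathrm{CV}/2
  \approx 112.8\,\mathrm{CV}$ (≈5.6% at CV 0.05). Jittering only one
  session would shrink this to ≈79.8 CV and break that closed form.
* The reference class carries no independent jitter: its test–retest
  variability comes from the global scale term, which reproduces
  reference-SUV T-RT of ≈8% while leaving the SUVR expectation at
  112.8 × target-CV. This keeps each published contrast attached to one
  generator dial (reference SUV T-RT ↔ scale CV; target SUVR T-RT ↔
  target CV; shell excess ↔ shell CV).

With a 5 mm PSF the *sampled* target SUVR T-RT drops below the 112.8·CV
closed form (≈4% rather than 5.6% at CV 0.05) because each sampled TAC
mixes in neighbouring tissue whose jitter is independent; the closed-form
check is therefore run without blur, and the blurred pipeline is checked
against the qualitative contrasts instead.

**What the phantoms do not emulate:** real anatomy (spheres, not
cortical ribbons), scanner physics (no sinograms, attenuation, scatter,
motion), sinus off-target uptake, correlated physiological drift between
neighbouring regions, and subject-level kinetic heterogeneity beyond the
simple jitter model. Passing tests demonstrate the *pipeline's*
correctness and the internal consistency of the statistics under known
truth — not that any particular real-world T-RT number is right.

## Test–retest statistics

`trt_percent` is the absolute difference as a percentage of the pair
mean, symmetric and scale-invariant. The ICC is the single-measure,
two-way model; the absolute-agreement form (which charges systematic
session shifts against reliability) is the default, with the consistency
form one flag away, since published "two-way model" descriptions rarely
say which was used. Confidence intervals use the standard F-based
formulas with Satterthwaite degrees of freedom for absolute agreement;
the implementation is checked against a longhand mean-squares oracle and
a frozen value from an independent implementation. Reliability bands are
<0.5 poor, 0.5–0.75 moderate, 0.75–0.9 good, >0.9 excellent, with exact
boundary values deterministically assigned upward. Zero-variance inputs
yield a flagged undefined ICC, not a crash or an arbitrary 1. AD-group
subjects are excluded from ICC computation by default (their
disease-driven spread inflates between-subject variance and with it the
ICC). The Wilcoxon signed-rank test drops zero differences and uses the
exact null distribution whenever the absolute differences are untied;
results are verified against exhaustive sign enumeration at small n. No
multiple-comparison correction is applied anywhere.

## Determinism and problem sizes

Every stochastic step takes an explicit seed, and the cohort pipeline
derives all per-subject seeds from one master seed, so a configuration
reruns byte-identically. The shipped experiments use 64³ phantoms, a
7-subject cohort per replicate, 20 replicates for the shell-contrast
experiment, 100 noisy replicates for the MRTM2 robustness check, and
1000 replicates for ICC recovery — sizes chosen so the complete
validation suite runs in minutes on a single CPU while keeping Monte
Carlo error well inside the tolerances being asserted.
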
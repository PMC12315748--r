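# dynpet

Reference-tissue quantification of dynamic brain PET, and the statistics
needed to ask whether those quantities are *reliable*: if the same subject
is scanned twice a few weeks apart with no biological change, how much do
the outcome measures move?

That question matters most for low-signal populations — e.g. older
cognitively normal subjects in tau-PET studies, where target uptake barely
exceeds the reference region and off-target extracerebral (meningeal)
signal is large and erratic. `dynpet` implements the full quantification
chain for a two-segment dynamic acquisition (0–65 min and 80–120 min with
a 15-minute break), plus a synthetic phantom generator so the whole chain
can be validated end to end against known ground truth.

## What it computes

**Outcome measures**, per region, from a 4D dynamic volume and a label map:

- `SUV_90–110` — standardized uptake value on the late window,
  `SUV = C / (ID / BW)` (g/mL), averaging the four 5-min frames in
  90–110 min.
- `SUVR` — `SUV_target / SUV_reference`, guarded so windows and
  partial-volume-correction status always match.
- `DVR` — distribution volume ratio from the multilinear reference tissue
  model 2 (MRTM2), regressing
  `C_T(t) = γ₁ [∫₀ᵗ C_R + C_R(t)/k₂′] + γ₂ ∫₀ᵗ C_T`
  over frames with midpoint ≥ t\* (defaults t\* = 30 min,
  k₂′ = 0.04 min⁻¹), with `DVR = −γ₁/γ₂`.
- `R1` — relative delivery `K1_target / K1_reference` from the simplified
  reference tissue model (SRTM),
  `C_T = R1·C_R + (k₂ − R1·k₂ₐ)·C_R ⊗ e^(−k₂ₐ t)`,
  fitted by basis functions over a log-spaced k₂ₐ grid with golden-section
  refinement (deterministic, no optimizer seed sensitivity).

**Partial-volume correction**: voxel-based iterative Yang — per iteration,
build a regional mean image, divide it by its PSF-smoothed version
(5 mm Gaussian by default), multiply the original data by the correction
map; 10 iterations by default.

**Region machinery**: mm-aware erosion and dilation on exact Euclidean
distance transforms (cerebellar grey eroded 3 mm, white matter eroded
4 mm, a 5 mm extracerebral shell outside the brain), composite regions
(meta-temporal), bilateral pooling.

**Test–retest statistics**:
`T-RT% = 200·|test − retest| / (test + retest)`; two-way ICC (absolute
agreement, single measure) with F-based 95% CIs and the conventional
reliability bands (<0.5 poor, 0.5–0.75 moderate, 0.75–0.9 good, >0.9
excellent); Bland–Altman bias and limits of agreement; exact Wilcoxon
signed-rank; Spearman and Kruskal–Wallis rank statistics. No
multiple-comparison correction is applied.

## Worked example

```r
library(dynpet)
sch <- mk6240_frame_schedule()           # 37 frames, 0-65 & 80-120 min
ref <- reference_tac_model(sch)          # synthetic cerebellar reference TAC
tgt <- srtm_forward(ref, srtm_params(R1 = 0.83, k2 = 0.0332, BP = 0.05))

srtm_fit(tgt, ref)
#> SRTM basis-function fit
#>   R1 = 0.8300   k2 = 0.0332 /min   BP = 0.0500   (k2a = 0.0316 /min)

mrtm2_fit(tgt, ref, t_star = 30, k2_prime = 0.04)
#> MRTM2 fit (t* = 30 min, k2' = 0.04 /min, 15 frames)
#>   DVR = 1.0496   (gamma1 = 0.03323, gamma2 = -0.03166, ...)
```

The fits recover the generating parameters: R1 = 0.83 exactly, and
DVR = 1.0496 against the model-implied 1 + BP = 1.05 (0.04% off). The
late-window ratio is slightly above DVR, as expected at 90–110 min:

```r
meta <- scan_meta(injected_dose = 185, body_weight = 74)  # MBq, kg
suvr(suv_window(tgt, meta), suv_window(ref, meta))
#> [1] 1.09
```

A full synthetic test–retest experiment — 7 subjects, paired scans,
5 mm PSF, within-subject CV 5% for targets and 12% for the extracerebral
shell:

```r
cfg <- pipeline_config(profile = "oCN", n_subjects = 7, seed = 1,
                       outcomes = c("SUV", "SUVR"))
res <- run_pipeline(cfg)
res
#> Test-retest pipeline result: 7 subjects (oCN), outcomes SUV/SUVR
#>   462 outcome rows, 17 regions; 0 failed fits
#>         region outcome mean_test trt_mean   icc icc_band
#>          cergm     SUV     0.553     9.76 0.590 moderate
#>     entorhinal     SUV     0.618     8.43 0.826     good
#>  extracerebral     SUV     0.578    12.93 0.839     good
#>  ...
```

`res$report` holds, for every region × outcome (× PVC status when
enabled): the group mean ± SD, mean ± SD T-RT%, ICC with CI and band,
Bland–Altman bias and limits of agreement, and the Wilcoxon p-value. The
extracerebral shell shows roughly twice the SUVR test–retest variability
of the target regions, the qualitative signature this package's cohort
generator is built to reproduce.

A thin CLI over the same functions lives in `inst/cli/dynpet.R`
(`simulate`, `pvc`, `trt-report`, `compare-refs`).

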
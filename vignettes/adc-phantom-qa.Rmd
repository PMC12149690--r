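---
title: "Phantom-based quality assurance of ADC measurements with dwiQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based quality assurance of ADC measurements with dwiQA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwiQA)
```

## The measurement problem

Diffusion-weighted MRI estimates the apparent diffusion coefficient (ADC) of
water in tissue from the decay of signal with diffusion weighting. Under the
mono-exponential model,

$$S(b) = S_0 \, e^{-b \cdot ADC},$$

where $b$ (s/mm²) is the diffusion weighting and ADC is reported here in
µm²/ms (1 µm²/ms = 10⁻³ mm²/s). Before ADC can be trusted as a quantitative
biomarker in multi-scanner studies, each scanner's accuracy (bias against a
known reference), intra-scanner repeatability, and inter-scanner
reproducibility must be verified on a physical standard. The accepted
standard is an ice-water-bath isotropic diffusion phantom: a central vial of
water (ADC 1.109 µm²/ms at 0 °C) surrounded by two rings of vials filled
with polyvinylpyrrolidone (PVP) solutions whose ADC decreases with
concentration, spanning 1.109 down to 0.110 µm²/ms in six levels.

dwiQA implements the complete analysis chain for such QA sessions: ADC map
fitting from b-value images, automated vial ROI statistics, the
QIBA-Diffusion-Profile-style conformance battery with its published
tolerances, and multi-scanner aggregation — together with a synthetic
phantom/organ generator so that every stage is testable without scanner
data.

## The phantom model

`builtinLayout()` returns the packaged 13-vial description: vial identity,
ring membership (1 center, inner ring 2–13 even, outer ring odd), nominal
geometry, informational PVP concentration, reference ADC, and a relative
b = 0 signal level per fill (`s0_scale`, below). Reference values are
serial-number specific in reality, so a site layout file in the flat
key-value dialect (`readPhantomLayout()`) overrides the packaged one.

Geometry is nominal by design — vial radius 15 mm, ring radii 33/66 mm,
slab 40 mm, IDs clockwise from 12 o'clock in each ring — because only
relative geometry matters for simulation and automatic ROI placement.

```{r layout}
lay <- builtinLayout()
lay
referenceAdc(lay, c(1, 8, 13))
```

## What the generator emulates (and what it does not)

`simulatePhantomSeries()` paints each vial footprint with exact
mono-exponential decay at the vial's reference ADC and then applies, in
order: an optional low-order multiplicative shading field (off by default,
non-physical), magnitude noise, and the stored-value rescale encoding.
Defaults are the standardized phantom acquisition: b = 0, 500, 900,
2000 s/mm², a 176 × 176 × 11 grid of 1 × 1 × 4 mm voxels covering the
phantom with the vial slab centred on the middle slices, baseline signal
$S_0 = 1000$, and Rician noise at SNR 75 at b = 0 in the water vial —
inside the 71–79 range such sessions actually report.

Choices that deserve justification:

* **Rician noise.** Zero-mean Gaussian noise of equal SD $\sigma = S_0 /
  \mathrm{SNR}_{b0}$ is added to real and imaginary channels and the
  magnitude taken — the standard magnitude-MRI model. At the SNRs used the
  empirical mean/SD in the water vial matches the target within a few
  percent; at high b in the water vial the Rician floor biases the fit by a
  few tenths of a percent, which is part of what the battery measures.
* **Per-vial baseline signal (`s0_scale` = 1.00, 0.55, 0.35, 0.24, 0.17,
  0.12 by PVP level).** Concentrated PVP fills are darker at the long echo
  times of standardized phantom EPI (T2-weighting; the implied T2 range at
  TE ≈ 169 ms is roughly 283 → 80 ms). This is the mechanism that makes
  accuracy and reproducibility degrade toward the low-diffusivity vials, as
  observed on real scanners; the values are nominal, chosen once so the
  simulated low-ADC vial inter-scanner CV lands on the few-percent scale
  reported for such phantoms, and are user-overridable per layout file.
* **Scanner differences as multiplicative ADC offsets**
  (`scannerBiasPercent`), plus a per-day multiplicative session drift — the
  minimal mechanism reproducing inter-scanner bias/CV structure. No
  gradient-chain physics is modelled.
* **Background** is 0.1 % of $S_0$ before noise so SNR-thresholded masks
  behave as on real data. EPI distortion, eddy currents, susceptibility and
  motion are deliberately out of scope; consequently, passing simulations
  demonstrate the correctness and statistical calibration of the *analysis*,
  not the performance of any physical scanner.

Noise streams derive deterministically from (master seed, scanner, day,
repetition), so a study is reproducible bit-for-bit while repetitions stay
independent.

## ADC fitting

`fitAdcMap()` decodes stored values (`stored × slope + intercept`, applied
exactly once) and fits $\ln S = \ln S_0 - b \cdot ADC$ per voxel by ordinary
least squares. Numerical choices:

* **Uniform weights by default.** The conventional reading of the
  least-squares formula; a signal²-weighted variant (`weighted = TRUE`,
  approximate ML for linear-scale Gaussian noise) is provided because
  vendor analysis weighting is generally undocumented. The provenance log
  records which was in force.
* **Validity floor.** Voxels with any fitted signal ≤ `1e-6 × max(signal)`
  are masked invalid rather than clamped; real protocols publish no floor,
  so ours is explicit and recorded.
* **Negative fits are retained** (flagged by sign) so noise statistics stay
  unbiased; `clampNegativeAdc()` is a report-time option.
* **Units.** The fit runs in mm²/s internally; the single ×10³ conversion
  to µm²/ms happens at the `AdcMap` boundary. `convertAdcUnits()` handles
  externally produced µm²/s maps before comparison.
* **Two-b protocols.** Anatomy-specific series acquired at b = 0, 150, 500
  are fitted with `bSubset = c(150, 500)` — dropping b = 0 to avoid
  perfusion (pseudodiffusion) contamination — which reduces analytically to
  the log-ratio `twoPointAdc()`. The subset is a property of the analysis
  configuration, never hard-coded.

```{r fit}
cfg <- simConfig(noiseModel = "none", matrixSize = c(96L, 96L, 5L),
                 voxelSize = c(2, 2, 8))
ser <- simulatePhantomSeries(lay, cfg)
map <- fitAdcMap(ser)
st <- extractRoiStats(map, placeVialRois(lay, map, diameterMm = 10))
st[st$label %in% c("vial_01", "vial_13"), c("label", "mean_adc", "n_pixels")]
```

## ROIs and the containment rule

Circular vial ROIs are placed from layout geometry on the central three
slices (lower median and neighbours for even stacks), with pixel membership
decided by the pixel-center-inside-circle rule in 0-based coordinates and a
nearest-pixel guarantee for degenerate sizes. Two diameters matter:

* **10 mm** (default of `placeVialRois()`): the ~1 cm manual ROI convention
  used when comparing scanner-generated (inline) maps against refitted
  (offline) maps via `compareAdcMaps()`.
* **60 % of the vial diameter (18 mm)** — the default of the conformance
  battery, emulating automated full-vial analysis ROIs. The repeatability
  statistics of real conformance reports imply effective averaging over
  several hundred voxels, i.e. analysis ROIs substantially wider than 1 cm;
  the battery therefore uses the wider automated ROI, and the choice is an
  explicit, recorded argument (`roiDiameterMm`).

Vial statistics pool voxels across the ROI slices (the pooled mean equals
the pixel-count-weighted mean of the per-slice means, an exact identity
kept under test); per-slice means are reported alongside, since with equal
slice counts the two conventions coincide.

Organ masks are consumed already aligned to the map grid;
`organMaskStats()` replaces manual field-of-view screening with an explicit
rule: an organ whose mask was truncated against the FOV (the generator and
readers set `attr(mask, "truncated")`) or holds no valid voxel is flagged
`contained = FALSE` and excluded from aggregation. Registration and
contouring are out of scope.

## The conformance battery

`runQibaBattery()` computes, for one scanner's day-structured series, with
the 2019-profile tolerances of `qibaTolerances()` (a plain list, so revised
profiles are a configuration change):

| Test | Metric | Tolerance |
|------|--------|-----------|
| A | bias of the water vial, day 1 rep 1 | \|bias\| ≤ 3.600 % |
| B | RC\_ST, CV\_ST over 4 same-day reps | ≤ 0.015 µm²/ms, ≤ 0.5 % |
| C | RC\_BS, CV\_BS over consecutive-day firsts | ≤ 0.065 µm²/ms, ≤ 2.2 % |
| D | linearity over all vials | R² > 0.9, 0.95 ≤ slope ≤ 1.05 |
| E | CV\_P, within-ROI spatial CV, rep 1 | < 2 % |
| F | SNR of the b = 0 image | ≥ 50 |
| G | Dep\_b, b-value dependence | < 2 % |

Interpretation decisions, all recorded in every provenance log:

* **CV\_P is spatial** (within-ROI, single repetition) — the only reading
  consistent with computing it from the first repetition alone. It is
  flagged as an interpretation. Note that under realistic noise this is the
  one metric that fails, at ~5 % — the same behaviour real 1.5 T sessions
  report.
* **Dep\_b** compares each two-b estimate of the ROI-mean signal against
  the all-b fit of the same signals, and secondarily reports the
  pairwise-vs-pairwise spread together with the most outlying pair. The two
  readings differ under faults: an additive noise floor drags the all-b
  reference itself, so the floor-affected high-b pair is identified by the
  spread's outlier pair, not necessarily by the primary worst pair.
* **Test A uses day-1 repetition 1** (`biasFrom = "first"`); averaging the
  four repetitions is available since report conventions vary.
* **Missing sessions become explicit N/A rows** (value and pass both NA),
  never silent zeros — e.g. test C when a second day is unavailable.
* **Boundary guard.** Tolerance comparisons carry a 10⁻⁹ guard so exact
  boundary cases (a noiseless +5 % bias study puts the linearity slope at
  exactly 1.05) are not decided by floating-point rounding.

Repeatability uses the sample (n − 1) SD throughout — with two sessions
$wSD = |x_1 - x_2|/\sqrt{2}$ — and the repeatability coefficient
$RC = 2.77 \times wSD$, the 95 % test–retest difference bound; the paired
RC/CV values printed in published conformance tables are consistent with
this convention, which is used as a cross-check in the tests, not as a fit.

## Multi-scanner and organ aggregation

`multiStudySummary()` follows the multi-study report convention: day-1
repetition means per (scanner, vial) → per-scanner bias → per-vial
inter-scanner mean bias and CV → an unweighted grand row over vials
(`grandRowSummary()`). The inter-scanner CV is computed on the per-scanner
ADC means (computing it on bias values differs only by the reference
constant; the ADC basis is the documented choice).
`organLevelSummary()` applies the same logic per organ with the containment
rule and day-1-only fallbacks.

```{r summary}
cfgB <- simConfig(noiseModel = "none", matrixSize = c(96L, 96L, 5L),
                  voxelSize = c(2, 2, 8),
                  scannerBiasPercent = c(A = -1, B = 0, C = 2))
study <- simulateStudy(lay, cfgB, scanners = c("A", "B", "C"),
                       days = 1, repetitions = 2)
meas <- do.call(rbind, lapply(study, measureVialAdc, layout = lay))
s <- multiStudySummary(meas, lay)
round(s$grand, 3)
```

## Interchange formats

The canonical dialect is NIfTI (one volume per b-value) plus a plain-text
b-value sidecar and a flat key-value metadata file carrying rescale and
provenance; it round-trips exactly. A minimal single-frame DICOM dialect
(explicit VR little endian, standard diffusion/rescale/geometry tags) is
provided for interoperability; its 16-bit pixels are requantized with a
writer-chosen rescale covering the data range, so decoded values agree with
the NIfTI dialect to within half a quantization step — exact float equality
is impossible for integer pixel data and is not claimed. Readers store
rescale parameters on the object and never apply them twice.

## Problem sizes and numerical tolerances used in the tests

The packaged test-suite runs the generator at its default grid for the
statistical checks (50 seeded studies for the accuracy/repeatability pass
rates, 10 for linearity, 12 × 3 scanners for the degradation trend) and at
a coarser 84 × 84 × 5 grid for exactness checks, where noiseless recovery
is asserted to 10⁻⁹ relative and oracle equivalences to 10⁻¹⁰–10⁻¹².
These sizes give the Monte-Carlo margins the assertions need while keeping
a full run in a few minutes on one core.

## Known limitations

* Simulations validate the analysis pipeline and its statistical
  calibration; they cannot certify a physical scanner, and they omit EPI
  distortion, susceptibility, eddy currents, motion, perfusion and partial
  volume.
* The battery's CV\_P and Dep\_b follow documented interpretations of
  under-specified profile metrics; both carry switches and are logged.
* The DICOM dialect targets this package's writer and standard tags only;
  vendor multiframe exports need conversion to the NIfTI dialect first.
* Reference diffusivities are phantom-serial-number specific; the packaged
  values must be overridden for quantitative work with a real phantom.
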
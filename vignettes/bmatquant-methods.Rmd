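---
title: "Methods: marrow adiposity quantification in bmatquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marrow adiposity quantification in bmatquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmatquant)
```

## The measurement problem

Bone marrow adipose tissue (BMAT) and haematopoietic red marrow (RM) occupy
the same cavity and cannot be separated anatomically on CT. They can,
however, be separated radiometrically: fat attenuates less than
haematopoietic tissue, so marrow voxels form two overlapping Hounsfield-unit
(HU) populations. `bmatquant` treats marrow quantification as a per-voxel
classification problem — derive HU cutpoints that best separate the
populations, classify every marrow voxel, and report adipose volume as a
fraction of marrow volume (Ad.V/Ma.V) — and couples it to PET uptake
quantification and a parametric total-body capacity model.

All imaging inputs are assumed co-registered onto one voxel grid. The package
enforces this (`validateAlignment()`: identical shapes, spacing equal within
1e-6 mm) and performs no resampling or registration itself. HU are treated as
integers throughout; non-integer inputs are rounded half away from zero,
matching how CT data are stored.

## Threshold derivation

Given a per-voxel HU sample from a BMAT-rich marrow region and one from a
BMAT-deficient region, `computeROC()` evaluates the rule *positive iff
HU < t* at every integer threshold: sensitivity is the fraction of positives
below *t*, specificity the fraction of negatives at or above *t*. The
orientation is fixed by physics — fat is the low-attenuation class. The
default grid spans the pooled sample range plus one, so the curve is anchored
at (0,0) and (1,1), and the trapezoidal AUC then equals the Mann–Whitney
estimate P(pos < neg) + P(tie)/2 (tested to 1e-9 against direct
enumeration).

`optimalThreshold()` maximizes Youden's *J* = sensitivity + specificity − 1.
"Greatest sensitivity and specificity" admits several formalizations; Youden
is the standard one and is what this package means by optimal. The
closest-to-(0,1) criterion is available via `criterion = "closest"`. Ties at
maximal *J* break toward the *lowest* threshold, which favours specificity
for the BMAT class; with integer samples the maximum is typically attained on
an interval of thresholds, and any fixed tie rule picks one end — lowest is
chosen and recorded here.

For two equal-variance Gaussian classes the population Youden optimum is the
midpoint of the means. This is the package's recovery benchmark: samples of
10^5 voxels per class recover the midpoint within ±2 HU across seeds.

## The threshold scheme and its boundaries

The diagnostic scheme is `thresholdScheme(-200, 115, 300)`. Printed interval
conventions for such cutpoints are ambiguous at the endpoints, so the package
fixes an exhaustive partition and logs it in every report:

* BMAT: −200 ≤ HU < 115
* RM: 115 ≤ HU ≤ 300
* bone: HU > 300
* out-of-range: HU < −200 (air or artefact)

Half-open at 115 and closed at 300 makes every integer HU belong to exactly
one class ("above 300" then reads naturally as bone). Class counts therefore
always sum to the VOI size — a property tested on randomized volumes.

Out-of-range voxels stay in the Ad.V/Ma.V denominator by default, since the
denominator is *total* marrow cavity volume; `adiposityFraction(...,
denominator = "soft_tissue")` restricts it to BMAT + RM for sensitivity
analyses. Whether intruding bone voxels should be excluded from the
denominator is genuinely open; keeping them is the conservative default and
the switch makes the choice explicit.

The −200 HU lower bound is a fixed scheme parameter, not ROC-derived: it
bounds the fat window from below against air and artefact, and
`deriveThresholdScheme()` never moves it.

## SUV, decay correction and %ID/g

PET volumes are assumed scanner-decay-corrected to injection time, in kBq/mL.
SUV is body-weight normalized: SUV = C / (dose/BW), with dose in MBq and BW
in g (the g/mL convention makes it dimensionless). If all activity were
uniformly distributed in the body, SUV would be 1 everywhere — the
normalization fixed point used as a test invariant. Lean-mass variants
(SUL) are out of scope.

Gamma counts are explicitly decay-corrected: A₀ = A · 2^(elapsed/t½) with
t½ = 109.77 min for ¹⁸F (physical constant). The correction is
one-directional by contract — negative elapsed times are rejected rather than
silently inverting the correction. %ID/g = 100 · A₀ / dose / tissue mass.

## Phantom calibration (small-animal CT)

`fitCalibration()` regresses rod *mean* HU on known density — mirroring a
fixed VOI template per rod — rather than pooling all voxels; voxel-count
weighting is available (`weightByVoxels`). Two rods give the exact
closed-form line (r² = 1 by construction); r² is computed directly from
residuals to avoid degenerate-fit warnings. `densityAt()` inverts the fit
and flags extrapolation beyond the rod density range.

The bone/marrow density cutoff for mouse scans is deliberately **not**
defaulted: no published value anchors it, and a silent default would invite
misuse. `boneBmThreshold()` errors until the analyst supplies a cutoff in
g/mL, which is then logged in the run manifest. The human scheme applies
only to human-mode runs; mouse runs use the calibration-derived threshold.

## The total-body capacity model

With body mass *M* (kg), marrow mass is 0.05·M, split 70/30 into BMAT and
RM. Two readings of the split exist:

* **mass mode (default):** V_BMAT = 0.05·M·0.7/0.92, V_RM = 0.05·M·0.3/1.06
  — the split applies to marrow mass, each component converted to volume by
  its own density;
* **volume mode:** V_BM = 0.05·M/(0.7·0.92 + 0.3·1.06), then
  V_BMAT = 0.7·V_BM.

Mass mode is the default because it is the only reading whose two outputs
are simultaneously consistent with reported adult cohort-mean volumes of
2.27 L (BMAT) and 0.84 L (RM) at a single body mass (≈59.7 kg): volume mode
pins the BMAT/RM volume ratio at 7/3 ≈ 2.33, while the reported pair implies
2.70 = 7/3 · 1.06/0.92. A regression test encodes this discrimination so
the default cannot be switched silently. Volumes are homogeneous of degree 1
in body mass, and are reported in litres to 2 decimals.

Bone volume is modelled bone mass (from height) divided by 1.245 g/mL;
muscle volume is a sex/age percentage of body mass divided by 1.055 g/mL.
The reference coefficients behind the height→bone-mass mapping and the
muscle-percentage table are not shipped: `boneVolume()` and `muscleVolume()`
require an explicit model/table, and the provided
`placeholderBoneMassModel()` / `placeholderMuscleFractionTable()` are
labelled synthetic stand-ins for examples and tests only.

`capacity()` multiplies each tissue volume by its mean SUV and reports each
tissue relative to skeletal muscle; the ratio is invariant to common SUV
rescaling, so it depends only on relative uptake and volumes.

## What the synthetic generator emulates — and what it does not

The generator is the package's study bench, not a scanner simulator. Its
defaults are fixed study conditions:

* **HU distributions** (not published as numbers anywhere; constructed
  here): scWAT N(−100, 20), BMAT N(42, 30), RM N(188, 30), trabecular bone
  N(412, 55), cortical bone N(1000, 100), muscle N(55, 10). The means are
  placed so the equal-variance BMAT/RM midpoint is exactly 115 HU and the
  RM/bone midpoint (at the bone pair's common SD 55) is 300 HU — default
  phantoms therefore reproduce the diagnostic cutpoints, which is the point
  of the bench. The SDs are plausible for marrow-cavity CT but are
  constructions, not measurements.
* **Exact splits:** a marrow region at `bmat_fraction` f with n voxels gets
  exactly ⌊f·n⌋ BMAT voxels, so ground-truth fractions are exact and
  recovery tests are sharp (no binomial noise in the truth itself).
* **Cohorts:** n = 10, age 51.5 ± 19.6 y, 20% male match a reported
  room-temperature clinical cohort; height 1.68 ± 0.09 m and mass
  59.7 ± 8 kg are chosen to give BMI ≈ 21 (reported: 20.7 ± 2.4) with the
  mass mean near the 59.67 kg the capacity model implies from the reported
  2.27/0.84 L volume pair.
* **Determinism:** one master integer seed; every component draws from a
  substream seed (seed + 7919·k mod 2³¹−1) inside a scope that restores the
  caller's RNG state, so identical (config, seed) gives bit-identical
  output regardless of call order.

Not emulated: anatomical geometry (regions are index blocks, not bones),
partial-volume effects, beam hardening and scanner noise texture, HU
drift between scanners, PET resolution and reconstruction artefacts, and
MRI. Passing recovery tests on these phantoms demonstrates correctness of
the estimators under the stated distributional model — it does not
demonstrate robustness to the physics a clinical scan adds.

## Numerical choices and problem sizes

* Integer HU everywhere; rounding half away from zero.
* 1-HU histogram bins over −500…1500 HU by default; out-of-range mass is
  tracked, not dropped. Cohort summaries average per-subject *proportions*
  (each subject's counts normalized by its own total), so VOI size does not
  weight subjects; SEM requires ≥ 2 subjects.
* ROC grids are integer; AUC is clamped to [0,1] against floating-point
  drift.
* Empty segmentation classes are *absent* from SUV reports, never zero.
* Test and acceptance problem sizes: 10^5 voxels per ROC class, 10^5-voxel
  marrow phantoms (recovery across adiposity 0.1–0.9, 3 seeds), 5-rod
  phantoms at 500 voxels/rod, 100 phantom replicates for slope bias. These
  sizes put Monte-Carlo error well inside the tolerances being asserted
  (e.g. SE of a class mean ≈ 0.095 HU at n = 10^5).

## Known limitations

* Threshold derivation assumes the two marrow populations are well
  represented by the sampled VOIs; mixed VOIs shift the cutpoint toward the
  mixture optimum (the simulate-mode default, 70% vs 5% adiposity regions,
  recovers 115 ± 2 HU).
* Ad.V/Ma.V is a voxel-count ratio; no partial-volume correction is applied,
  so voxels straddling tissue boundaries are classified whole.
* The capacity model is a scaling estimate, not a measurement: it propagates
  anthropometrics through fixed composition constants and is only as good as
  those constants for a given subject.
* SUV is body-weight normalized; no kinetic modelling (Patlak/Ki) is
  attempted.
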
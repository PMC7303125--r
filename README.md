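# bmatquant

Bone marrow adipose tissue (BMAT) makes up more than a tenth of total adipose
mass in adult humans, yet it is invisible to conventional body-composition
analysis: it sits inside the bone marrow cavity, interleaved with
haematopoietic (red) marrow. `bmatquant` is an R package for identifying and
quantifying BMAT from co-registered CT/PET volumes. It is aimed at imaging
scientists who have registered CT (and optionally PET) volumes with
volume-of-interest (VOI) masks and want reproducible marrow adiposity and
glucose-uptake quantification, and at methods developers who need a fully
synthetic test bench for such pipelines.

## What it computes

**Diagnostic HU thresholds by ROC.** Fat attenuates X-rays less than
haematopoietic tissue, so BMAT-rich marrow has lower Hounsfield units (HU)
than red marrow (RM). Given per-voxel HU samples from a BMAT-rich region
(e.g. sternum) and a BMAT-deficient region (e.g. vertebrae), the package
scans every integer threshold *t* under the rule *positive (BMAT) iff
HU < t* and picks the cutpoint maximizing Youden's
*J* = sensitivity + specificity − 1. On clinical data this procedure yields
the scheme used throughout:

| compartment | HU window |
|---|---|
| BMAT (yellow marrow) | −200 ≤ HU < 115 |
| red marrow | 115 ≤ HU ≤ 300 |
| bone | HU > 300 |

**Marrow segmentation and adiposity.** Each marrow-VOI voxel is classified
by the scheme; marrow adiposity is reported as Ad.V/Ma.V — BMAT volume as a
percentage of total marrow cavity volume.

**SUV quantification.** PET activity concentration *C* (kBq/mL) is converted
to body-weight standardized uptake value SUV = *C* / (dose / body mass) and
averaged per compartment.

**Phantom density calibration.** For small-animal CT, a tissue-equivalent
phantom with hydroxyapatite rods of known density (1.08–1.57 g/mL) is used to
fit HU = slope · density + intercept by ordinary least squares; an explicit
density cutoff is then mapped to an HU threshold separating bone from marrow.

**Gamma-count normalization.** Ex vivo counts per minute are converted to
activity, decay-corrected back to injection time
(A₀ = A · 2^(elapsed / t½), t½ = 109.77 min for ¹⁸F) and expressed as
percent injected dose per gram (%ID/g).

**Histomorphometry.** Adipocyte density (N.Ad/Ma.Ar, mm⁻²), adipocyte area
fraction (Ad.Ar/Ma.Ar, %) and multilocular counts (≥ 3 small lipid droplets)
from 2-D annotations.

**Total-body capacity model.** From anthropometrics: marrow is ~5% of body
mass, split 70/30 into BMAT and RM, converted to litres with densities 0.92
and 1.06 g/mL; bone and skeletal-muscle volumes come from a height→bone-mass
model (density 1.245) and sex/age muscle percentages (density 1.055). Each
tissue's uptake-capacity index is volume × mean SUV, reported relative to
skeletal muscle.

**Synthetic phantoms.** Every input above can be generated with known ground
truth: paired CT/PET phantoms with per-compartment Gaussian HU and uptake,
rod calibration phantoms, anthropometric cohorts, and adipocyte annotation
sets — so the whole pipeline is testable without clinical data.

## Worked example

```r
library(bmatquant)

ph <- generateHumanPhantom(phantomConfig(seed = 7))

## derive the diagnostic cutpoint from BMAT-rich vs BMAT-deficient marrow
der <- deriveThresholdScheme(extractVoiHU(ph$ct, ph$masks, "sternum_BM"),
                             extractVoiHU(ph$ct, ph$masks, "vertebrae_BM"))
der$scheme
#> ThresholdScheme: BMAT [-200, 115) HU | RM [115, 300] HU | bone > 300 HU | ...

seg <- segmentBM(ph$ct, ph$masks, "sternum_BM", der$scheme)
adv <- adiposityFraction(seg)
adv$ad_v_over_ma_v
#> 69.7        # percent of the marrow VOI classified BMAT (generated at 70%)

round(compartmentSUV(ph$pet, ph$masks, "sternum_BM", seg,
                     suvParams(injectedDose = 185, bodyMass = 60000)), 2)
#> BMAT   RM
#> 1.30 0.82   # mean SUV per compartment

round(bmVolumes(59.67), 2)
#> BMAT   RM
#> 2.27 0.84   # total-body marrow-compartment volumes (L) at 59.67 kg

capacity(c(BMAT = 2.27, muscle = 17.93), c(BMAT = 2.0, muscle = 0.85))
#>   tissue volume_L  suv uptake_index percent_of_muscle
#> 1   BMAT     2.27 2.00         4.54              29.8
#> 2 muscle    17.93 0.85        15.24             100.0
```

The derived threshold sits at the 115 HU cutpoint, the segmentation recovers
the 70% generated adiposity to within misclassified tail mass (~0.3
percentage points), and with a BMAT SUV of 2.0 against muscle at 0.85 the
BMAT glucose-uptake capacity index is ~30% of skeletal muscle's.

A thin command-line wrapper with `simulate`, `analyze-human`,
`analyze-mouse` and `calibrate` subcommands is installed at
`inst/cli/bmatquant` (YAML config via `--config`, plus `--seed` and
`--out`).

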
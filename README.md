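# dectpeel

Volumetric dual-energy CT (DECT) iodine quantification of peritumoral and
intratumoral layers, for predicting microvascular invasion (MVI) of
hepatocellular carcinoma — implemented as a reusable, fully testable R
pipeline driven by synthetic phantoms, for imaging scientists who want to
reproduce, stress-test, or extend this class of analysis without access to
clinical data.

MVI is a microscopic finding that predicts early recurrence after liver
resection. Its imaging correlate is subtle: arterial-phase hyperperfusion
in a thin shell of parenchyma just outside the tumor. DECT makes that
shell quantifiable — a paired 80/Sn150 kV acquisition supports voxelwise
two-material decomposition

    HU_low  = v + s_low  · c
    HU_high = v + s_high · c

into a virtual non-contrast value `v` (HU) and an iodine concentration `c`
(mg/mL). The pipeline then:

1. blends the mixed-energy reading image (0.6/0.4) and inverts the system
   above for the iodine map (`decompose_iodine`);
2. segments the tumor volumetrically from a reader-drawn maximal-diameter
   line by statistical region growing (`segment_tumor`), or accepts masks;
3. peels distance bands off the tumor boundary — outer layers 1, 2
   (0–2, 2–4 mm outside) and inner layers 1, 2 (0–2, 2–4 mm inside) plus
   five cumulative VOIs — using an anti-aliased Euclidean distance
   transform that reproduces analytic shell volumes to ~1% (`peel_layers`);
4. computes per-region statistics: mean HU, total and vital iodine
   concentration, and the normalized iodine concentration
   NIC = vital IC / aortic IC (`region_stats`, `run_case`);
5. runs the cohort statistics: Mann-Whitney and chi-square group
   comparisons, ROC with DeLong CIs and Youden cutoffs, odds ratios with
   Woolf intervals, univariate screening plus multivariate logistic
   regression, ICC and Cohen's kappa (`cohort_report`, `run_cohort`).

A synthetic-data module generates both voxel-level DECT phantoms (liver
ellipsoid, enhancing tumor, aortic cylinder, optional MVI-like peritumoral
rim, with exact ground-truth masks and iodine maps) and cohort-level
feature tables drawn from published group means and SDs
(`generate_phantom`, `generate_cohort`).

## Worked example

A phantom with a 2-mm peritumoral rim (+0.5 mg/mL iodine) walked through
the full per-case path:

```r
library(dectpeel)

ph   <- generate_phantom(phantom_spec(seed = 2, rim_present = TRUE,
                                      noise_sd = 8))
line <- diameter_line(c(17, 32, 32), c(35, 32, 32))   # across the tumor
case <- run_case(ph$study, ph$masks$aorta, line = line,
                 config = pipeline_config(), patient_id = "demo", mvi = 1)

round(case$features[, c("nic_tumor_2mm", "nic_outer1_2mm",
                        "nic_outer2_2mm", "nic_inner1_2mm")], 3)
#>   nic_tumor_2mm nic_outer1_2mm nic_outer2_2mm nic_inner1_2mm
#> 1          0.25          0.123          0.087           0.25
```

The tumor NIC of 0.25 is the constructed tumor-to-aorta iodine ratio
(2.5 / 10 mg/mL); outer layer 1 reads 0.123 because the rim raises the
0–2 mm shell above the parenchymal baseline (≈ 0.07 without a rim, the
scale reported for MVI-negative tumors), while outer layer 2 falls back
toward baseline — exactly the spatial signature the analysis targets.
The same script without the rim gives `nic_outer1_2mm ≈ 0.09`, and across
20 rim-positive vs 20 rim-negative phantoms the outer-layer-1 NIC
separates the groups with AUC 1.0 (`analysis/03_phantom_cohort.R`).

On the statistics side, the arithmetic fully determined by published
counts is recomputed exactly:

```r
roc_auc(c(rep(1, 8), rep(0, 14), rep(1, 9), rep(0, 5)),
        c(rep(0, 22), rep(1, 14)))$auc      # reader enhancement score
#> 0.6396104
odds_ratio(two_by_two(9, 5, 8, 14))          # exposed cases/controls ...
#> $or 3.15   $ci_low 0.78   $ci_high 12.73
```

## Analysis workflow

Numbered drivers under `analysis/` narrate the study end to end and write
their tables under `results/` (volumes go to `scratch/`):

| script | what it does |
| --- | --- |
| `01_phantom.R` | builds MVI-negative/positive phantoms, verifies exact decomposition round-trip |
| `02_single_case.R` | one case: segment, peel, quantify; prints the per-region NIC profile |
| `03_phantom_cohort.R` | 40 phantoms end to end; outer-layer-1 NIC ROC |
| `04_cohort_stats.R` | simulated 22/14 cohort; group/ROC/logistic tables plus count-determined statistics |

Run them from the repository root, e.g. `Rscript analysis/02_single_case.R`.

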
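# rehomvpa

Multivariate pattern analysis of resting-state fMRI regional homogeneity,
for researchers who want a fully testable, no-download implementation of
the classic case-control ReHo + SVM workflow.

Resting-state studies of disorders such as functional dyspepsia ask whether
the *spatial pattern* of spontaneous local synchrony distinguishes patients
from healthy controls, which regions drive that distinction, and whether
those regions track symptom severity.  `rehomvpa` implements that analysis
end-to-end:

1. **Temporal preprocessing** — motion QC (strict 1.5 mm / 1.5° gate),
   discard of the first 10 volumes, nuisance regression (6 motion
   parameters, linear trend, mean white-matter and ventricle signals,
   intercept), ideal 0.01–0.08 Hz band-pass.
2. **ReHo mapping** — voxelwise Kendall's coefficient of concordance
   W = 12S / (K²(n³−n) − KΣT) between each gray-matter voxel and its 26
   nearest neighbours (K = 27), normalised by the gray-matter mean W.
3. **Classification** — PCA to all N−1 informative components (a lossless
   rotation), linear soft-margin SVM (C = 1), leave-one-out
   cross-validation with fold-internal PCA; GR/SS/SC metrics.
4. **Discriminative map** — back-projection w_voxel = U·w; voxel- and
   cluster-level inference by label permutation (default 5000 permutations,
   voxel p < 0.02, cluster extent ≥ 10 voxels, cluster level 0.001,
   26-connectivity), with unit-norm weight maps so inference is on the
   pattern direction.
5. **ROI–symptom correlation** — 6 mm spheres at cluster peaks, mean
   normalised ReHo per patient, Pearson correlation with symptom severity
   and illness duration, Bonferroni-corrected at 0.01; Zung SDS/SAS scoring
   (raw × 1.25, cutoffs 53/50).

A synthetic-cohort generator (`simulateCohort()`) produces aligned 4D
BOLD-like volumes with *planted* local synchrony (per-subject mixing level
λᵢ), motion tables, tissue masks, and behavioural scores linearly coupled
to the planted effect — so every stage is validated against known ground
truth, with no scanner data required.

## Worked example

```r
library(rehomvpa)

cfg <- pipelineConfig(
  sim = simConfig(nPerGroup = 8, gridShape = c(16, 16, 16),
                  synchronyLambda = 0.8, seed = 11),
  nPerm = 300, clusterAlpha = 0.05, seed = 11)
report <- runPipeline(cfg)

round(report$metrics, 2)
#>     GR     SS     SC
#>  93.75  87.50 100.00
report$clusterTable[, c("size", "peak_x_mm", "peak_y_mm", "peak_z_mm",
                        "voxel_p", "cluster_p", "significant")]
#>   size peak_x_mm peak_y_mm peak_z_mm     voxel_p   cluster_p significant
#> 1   16      -1.5      -1.5      -1.5 0.003322259 0.006644518        TRUE
report$correlations
#>   roi        variable n         r     p_raw p_adjusted significant
#> 1   1             ndi 8 0.6040142 0.1127803  0.2255606       FALSE
#> 2   1 duration_months 8 0.5479883 0.1596865  0.3193730       FALSE
```

The 16 subjects (8 per group) carry a planted synchrony effect (λ = 0.8) in
a radius-2 sphere at the grid centre.  LOOCV classifies 15 of 16 correctly
(GR 93.75%: one patient missed, SS 87.5%; all controls correct, SC 100%).
Permutation inference finds one significant 16-voxel cluster whose peak
(world coordinates −1.5, −1.5, −1.5 mm) sits in the planted ROI.  The
patient NDI score was generated with positive coupling to λᵢ, and the ROI
correlation recovers r ≈ 0.60 — not significant after Bonferroni at n = 8,
as expected at that sample size.  (Cluster significance is assessed at 0.05
here because 300 permutations cannot resolve the 0.001 default; the
package warns about exactly this.)

A thin CLI over the same functions lives at `inst/cli/rehomvpa.R`
(`simulate` and `run` subcommands).

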
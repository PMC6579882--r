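# somatoseg

Does higher spatial resolution buy better separation of motor somatotopy
maps, or does the accompanying loss of BOLD sensitivity take it back?
`somatoseg` is an R package for studying that trade-off end to end. It
targets researchers comparing fMRI acquisition protocols — here 1.5 mm
and 2 mm 3D-EPI and 3 mm 2D-EPI presets with matched 90 mm head-foot
coverage — on their ability to segregate foot, hand and face
representations in cortical (M1, SMA) and subcortical (putamen,
pallidum, motor thalamus) regions of interest.

The package simulates block-design motor sessions with known ground
truth, and implements the full analysis chain:

* **Pattern component model.** Per ROI, condition-by-voxel coefficients
  follow `Y = Z U + E` with voxelwise pattern components
  `U ~ N(0, G)` and iid noise `σ²`; marginally each voxel profile is
  `N(0, ZGZᵀ + σ²I)`. `G` and `σ²` are estimated by
  expectation-maximization (`fit_pcm_em()`), cross-checked by direct
  numerical maximum likelihood (`fit_pcm_direct()`).
* **Index of Similarity.** `IoS = |atanh(r)|` for pattern correlations
  `r_ij = G_ij / √(G_ii G_jj)`; low IoS = high segregation. Z-tests on
  the signed Fisher-z scale with per-family Benjamini–Hochberg FDR
  (`similarity_report()`).
* **Subject-level GLM** with the canonical double-gamma HRF, pooled
  preparation covariate, motion covariates and six differential movement
  contrasts.
* **BOLD sensitivity**: residual tSNR maps and ROI summaries, the
  weighted variants tSNR/√TR, tSNR/√N and
  `tSNR_s = tSNR·√(N(1−φ)/(1+φ))`, top-5% t-scores, head-motion and
  scaled-variance quality metrics.
* **Somatotopy geometry**: thresholded activation maps, centers of mass
  and maxima in world mm, ROI-adjusted activation volumes, betweenness
  and gradient-direction checks, SVD projection onto ROI-specific
  principal axes.
* **Group statistics**: IoS–tSNR correlations, Type-II ANCOVA with
  nested model comparison and simple slopes, MANOVA with Pillai's trace,
  and 1-/2-way ANOVAs with Holm post hocs.

## Worked example

```r
library(somatoseg)

res <- run_pipeline(run_config(scenario = "subcortical_protocol_dependent",
                               n_subjects = 3, seed = 1))
res$summary$mean_ios_by_class_protocol
#>         class protocol        ios
#> 1    cortical    1.5mm 0.07719284
#> 2 subcortical    1.5mm 0.06870451
#> 3    cortical      2mm 0.09833498
#> 4 subcortical      2mm 0.24975560
#> 5    cortical      3mm 0.09641934
#> 6 subcortical      3mm 0.06597301
res$summary$betweenness_rate
#> [1] 1
```

Under the protocol-dependent scenario the subcortical mean IoS at 2 mm
(0.250) is several times the 1.5 mm and 3 mm values (≈ 0.07): the
intermediate resolution is the least segregated, while cortical ROIs
stay flat across protocols — the qualitative pattern the pipeline is
built to detect. A betweenness rate of 1 means the hand center of mass
lay between foot and face on at least one axis in every ROI at every
resolution, as programmed into the synthetic somatotopy. `res$ios_table`
holds the per-(ROI, resolution) IoS and tSNR values behind the group
statistics in `res$group` (correlation, ANCOVA, MANOVA, ANOVAs), and
`res$similarity` the per-ROI pair tables with Z, p and q values.

The methods vignette (`vignettes/somatotopy-segregation.Rmd`) documents
the model, the estimators, every fixed convention and the generator's
scope.

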
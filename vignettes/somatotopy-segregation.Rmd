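---
title: "Quantifying somatotopy segregation across fMRI acquisition protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatotopy segregation across fMRI acquisition protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatoseg)
```

## The problem

Functional MRI protocols trade spatial resolution against BOLD sensitivity:
smaller voxels resolve finer spatial structure but carry less signal per
volume and force longer volume repetition times, hence fewer volumes in a
fixed scan duration. For motor somatotopy — the orderly mapping of foot,
hand and face representations onto motor structures — this trade-off may
play out differently in cortex (M1, SMA) and in the deep nuclei (putamen,
pallidum, motor thalamus), where physiological noise weighs more heavily.

`somatoseg` implements a complete, testable pipeline for studying this
question: it simulates block-design motor sessions under three acquisition
presets (1.5 mm 3D-EPI, TR 4032 ms, 176 volumes; 2 mm 3D-EPI, TR 2704 ms,
263 volumes; 3 mm 2D-EPI, TR 1980 ms, 359 volumes — all covering 90 mm
head-foot), fits subject-level GLMs, estimates pattern-component
covariances per region of interest, and relates the resulting segregation
indices to sensitivity, resolution and geometry.

## The pattern component model

For one ROI, let $Y$ be the $n \times v$ matrix of GLM coefficients
(rows = the $p = 9$ cells of the 3 movements $\times$ 3 resolutions
factorial, columns = voxels). The model is

$$Y = Z U + E,$$

where $Z$ ($n \times p$) maps rows to pattern components, the columns of
$U$ ($p \times v$) are iid $\mathcal N(0, G)$ with $G$ the $p \times p$
pattern covariance, and $E$ is iid noise with a single variance
$\sigma^2$ shared across the ROI's voxels (the minimal reading of errors
that are iid over trials for single voxels). Marginally each voxel's
profile is $y_j \sim \mathcal N(0, V)$ with $V = Z G Z^\top + \sigma^2
I_n$, so the log-likelihood depends on the data only through
$S = Y Y^\top / v$:

$$\ell(G, \sigma^2) = -\tfrac{v}{2}\left(n \log 2\pi + \log|V| +
\operatorname{tr}(V^{-1} S)\right).$$

`fit_pcm_em()` maximizes $\ell$ by expectation-maximization — the E-step
computes the conditional mean and covariance of $U$ given $Y$, the M-step
sets $G$ to the voxel-averaged conditional second moment and $\sigma^2$
to the averaged conditional residual second moment. The trace of $\ell$
is non-decreasing by construction and is checked in the tests.
`fit_pcm_direct()` maximizes the same objective by quasi-Newton
optimization over a Cholesky factor of $G$ and $\log\sigma^2$; the two
estimators agree to within $10^{-3}$ in log-likelihood on seeded test
instances, which is the package's main guard against implementation
error in either route.

### Identifiability and initialization

With the default row structure — subject-averaged cell means and
$Z = I_9$ — the likelihood is *flat* along the ridge
$G + \sigma^2 I = S$: any split of the smallest marginal eigenvalue
between $G$'s diagonal and $\sigma^2$ fits equally well, and EM
essentially stays where it starts on that ridge. Initializing
$\sigma^2$ at the regression-residual variance (the natural choice for
$n > p$ designs, which the package uses there) degenerates to zero for
saturated designs and would fold all noise into $G$, attenuating every
correlation by the noise-to-signal ratio. The package therefore breaks
the tie toward the *maximal-noise* ridge point, initializing $\sigma^2$
at the smallest eigenvalue of $S$: attribute to iid noise everything that
iid noise can explain, and to patterns only what requires them. This is
the parsimonious reading of "patterns plus iid error", and it is what
makes correlation recovery accurate in the saturated case (median
absolute error well under 0.1 at $v = 2000$, $\sigma^2 = 0.5$ in the
acceptance checks). A per-voxel noise variance is out of scope.

At exit (never inside the iteration) $\hat G$ is projected onto the PSD
cone by clipping negative eigenvalues at zero; interior clipping would
break the monotone-ascent property. Convergence is declared when the
relative log-likelihood increment falls below $10^{-6}$ (cap 1000
iterations). Masked (all-NA) voxels are dropped column-wise.

## The Index of Similarity

$\hat G$ is normalized to correlations $r_{ij} = G_{ij} / \sqrt{G_{ii}
G_{jj}}$ — we read "dividing each covariance by the product of its
respective variance estimates" as the standard correlation denominator,
since the literal product of variances would not give a dimensionless,
bounded quantity. The Index of Similarity is the absolute Fisher z,

$$\mathrm{IoS} = |\tanh^{-1}(r)|,$$

so low IoS means well-segregated representations. Two pair families are
reported per ROI: the nine within-resolution movement pairs (how
segregated are foot/hand/face at each protocol?) and the nine
within-movement resolution pairs (is the same body part mapped
consistently across protocols?).

Significance uses Z-statistics on the *signed* Fisher-z scale — the
absolute value is applied only for reporting, because a difference of
absolute values has no standard null. A single value is tested with
standard error $1/\sqrt{n_\mathrm{eff} - 3}$ and a difference of two
values with $\sqrt{2/(n_\mathrm{eff} - 3)}$, where $n_\mathrm{eff}$
defaults to the ROI voxel count. This is a documented approximation, not
a correction: spatial smoothing and the shared acquisition make voxels
dependent, so these Z-tests are anti-conservative on smoothed data; the
default pipeline therefore runs unsmoothed. Benjamini-Hochberg FDR is
applied within each family and ROI separately, matching the
nine-values-per-ROI reporting unit, not pooled across ROIs.

## Subject-level GLM

Condition regressors are boxcars convolved with the conventional
double-gamma canonical HRF (response gamma shape 6, undershoot shape 16,
unit rates, undershoot ratio 1/6, 32 s support, unit peak), built on a
0.1 s grid and sampled at volume acquisition times. The design adds one
pooled preparation-period regressor (the 3 s visual cues; pooling is the
minimal reading of "included as covariates"), six motion covariates and
an intercept — 14 columns. Estimation is per-voxel OLS; AR
prewhitening is deliberately out of scope, and OLS point estimates stay
unbiased under AR(1) noise (checked by simulation). No drift regressors
by default since the generator produces none; `build_design(drift = k)`
adds cosine drift columns. The six differential contrasts weight one
condition each against the implicit resting baseline.

## What the generator emulates — and what it does not

The synthetic-data module reproduces the study conditions: 18 active
blocks of 16 s (3 per condition), equal rest blocks, 3 s preparation
cues, pseudo-random condition order with no immediate repeats, and the
three acquisition presets above. Since the retained slice counts of the
3D protocols are not published, the presets use 60/45/30 slices so every
protocol covers the stated 90 mm. Prep periods extend the session rather
than overlap rest (either reading fits the stated timing; the session
still fits every preset's scan duration, which is tested).

Voxel time series are baseline (100 a.u.) plus HRF-shaped responses plus
stationary AR(1) Gaussian noise (default lag-1 coefficient 0.3, a
typical fMRI value) whose SD fixes the baseline/SD ratio at the
protocol's tSNR target. Targets default to 20/30/40 for 1.5/2/3 mm —
ordered as observed empirically (highest at 3 mm), with the 3 mm value
twice the 1.5 mm one. Each movement's mean response (1.5% of baseline, a
typical motor block-design effect size) is confined to its somatotopy
field — each box ROI is split into dorsal/middle/ventral thirds for
foot/hand/face — while a voxelwise pattern component (SD 0.75% of
baseline) spans the whole ROI and is drawn from the scenario's 9-cell
covariance, shared across subjects as a group-level pattern. The field
carries the geometry (centers of mass, betweenness, gradients); the
ROI-wide component carries the similarity structure — confining it to
the fields would zero all between-movement covariances by disjointness
of support.

Two scenario presets encode the competing hypotheses as ground truth
through a latent-factor construction that is PSD by design
($u_{m,r} = \sqrt{c_r}\, h_m + \sqrt{1 - c_r}\, e_{m,r}$ with correlated
movement factors $h_m$): `cortical_invariant` fixes the between-movement
correlation at 0.2 for all resolutions; `subcortical_protocol_dependent`
programs 0.2 / 0.55 / 0.2 at 1.5 / 2 / 3 mm — the intermediate
resolution least segregated — while keeping cortical ROIs invariant
within the same run.

Not emulated: k-space/EPI readout physics, field-inhomogeneity
distortion, cardiac/respiratory noise, subject-specific anatomy, and
registration error. Passing tests therefore demonstrate that the
*estimators and statistics* behave correctly under a known generative
model, not that any particular acquisition is superior on real data.

## Sensitivity and geometry conventions

tSNR uses the raw-series mean over the residual SD after regressing out
the design (removing modeled effects before noise estimation; dof
$= n - \mathrm{rank}(X)$). The weighted variants divide by
$\sqrt{\mathrm{TR_{volume}}}$ (in seconds) and $\sqrt{N}$, and
$\mathrm{tSNR}_s = \mathrm{tSNR}\sqrt{N(1-\phi)/(1+\phi)}$ adopts the
AR(1) effective-sample-size factor, isolated in `weighted_tsnr()` so the
scaling can be swapped. Head movements are counted on frame-to-frame
translation norms above 0.5 mm (not cumulative position), rotations
summarized as mean frame-to-frame rotation magnitude in degrees.

Geometry fixes MNI axis semantics (+X lateral-right, +Y anterior, +Z
dorsal), one-sided thresholding of activation maps, unweighted centers
of mass on binary suprathreshold masks (a t-weighted option exists), and
strict inequalities for every ordering check — ties fail. Medial/lateral
expectations are evaluated on $|X|$. Activation-maximum ties break at
the lowest linear voxel index. Principal-axis projection centers the
nine centers of mass per ROI, takes the SVD and projects onto the
right-singular vectors, flipping each axis so its largest-magnitude
loading is positive.

## Group statistics

The observational unit for the IoS-sensitivity analyses is the
(ROI, resolution) pair — 30 rows for 10 ROIs and 3 protocols — with IoS
averaged over the three within-resolution movement pairs and tSNR over
subjects. `ancova_ios()` fits `ios ~ tsnr * resolution` with treatment
coding (1.5 mm reference), Type-II F tests, a nested comparison against
`ios ~ tsnr`, and per-level simple-slope tests on the full model's
error. `manova_coords()` tests body part and resolution on projected
center-of-mass coordinates with Pillai's trace and its standard F
approximation. `anova_oneway_twoway()` covers the activation-volume and
scaled-variance analyses with Holm-adjusted pairwise contrasts on
marginal means; responses are standardized before fitting (F statistics
are affine-invariant), which keeps very small-scale responses away from
numerical-tolerance traps. All F statistics are validated against
explicit residual-sum-of-squares oracles in the tests.

## Problem sizes and reproducibility

The default pipeline simulates 6 subjects on a 30 x 38 x 30 grid (1.5 mm
spacing) with 5 x 5 x 6-voxel box ROIs — sizes chosen so a full
two-scenario analysis completes in minutes on a laptop while leaving
every statistic's sampling distribution wide enough to be interesting;
the acceptance checks run the full three-protocol, ten-ROI analysis at
these sizes. All generators are pure functions of their parameters and a
seed; `run_pipeline()` derives every stream from the single seed in
`run_config()`, and reruns with an identical configuration are
reproducible (outputs carry the configuration hash and seed).

## Known limitations

* The effective sample size of the Fisher-z tests is the ROI voxel
  count; with smoothed data this overstates independence.
* A single noise variance per ROI; heteroscedastic beta noise across
  protocol rows (different volume counts and tSNR) leaks into $\hat G$'s
  diagonal and attenuates IoS magnitudes — orderings are preserved, and
  magnitudes should be compared within, not across, analyses.
* Cross-validated similarity estimators are not implemented; IoS from a
  single fit is an in-sample quantity.
* The group model is a fixed-effects average over simulated subjects;
  mixed-effects or permutation group inference is out of scope.

```{r example, eval = FALSE}
# a complete run (about two minutes):
res <- run_pipeline(run_config(scenario = "subcortical_protocol_dependent",
                               seed = 1))
res$summary$mean_ios_by_class_protocol
res$group$ancova$terms
```
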
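---
title: "Methods: quantifying the periventricular gradient of NAWM damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the periventricular gradient of NAWM damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvgrad)
```

## The scientific problem

Microstructural damage in normal-appearing white matter (NAWM) is not
spatially uniform: in multiple sclerosis, and plausibly in normal aging and
other neurological diseases, damage is worse close to the ventricles and
attenuates with distance, consistent with CSF-borne or ependymal
inflammatory processes. The *periventricular gradient* makes this a single
scalar: the slope of a (normalized) diffusion metric across concentric
distance shells around the ventricles. `pvgrad` implements the full analysis
chain around that statistic — ring parcellation, reference normalization,
mixed-model slope estimation and group contrasts, mediation analysis with an
inflammation proxy (choroid plexus volume, CPV), and a ring-wise
imaging-transcriptomics stage — together with a synthetic phantom module that
makes every stage testable against known ground truth.

## Ring parcellation

Distances are exact Euclidean voxel-centre-to-voxel-centre distances (mm) to
the nearest ventricular voxel, computed by a separable exact distance
transform that honours anisotropic voxel spacing. Distance to the nearest
*voxel centre* (rather than to the mask surface) is used because it makes
the brute-force oracle — the minimum over all ventricular voxels of the
pairwise centre distance — unambiguous; the test suite verifies exact
agreement with that oracle.

Rings are contiguous half-open shells `[start + (k-1)t, start + kt)`. The
default design is ten 3 mm rings spanning 3 mm to 33 mm. Two conventions are
deliberate:

* **Half-open intervals, lower bound inclusive.** This guarantees a
  partition: every distance belongs to at most one ring and adjacent rings
  share no voxel. A voxel at exactly 3 mm is in ring 1; a voxel at exactly
  33 mm is outside the design.
* **The first ring starts at one ring-width, not at 0.** The 0–3 mm shell
  hugs the ventricular surface where CSF partial-volume effects dominate, so
  it is excluded; `start_mm` is configurable. The 15-ring (1.5 mm) and
  20-ring (1 mm) variants likewise start at one ring-width, spanning
  [1.5, 24) and [1, 21) mm. Both finer designs subdivide the 3 mm rings
  exactly; no nesting claim is made between the 1.5 mm and 1 mm designs,
  whose thicknesses are not multiples of each other.

Ring means are computed over NAWM only (white matter minus the WMH lesion
mask). Rings with fewer than `min_voxels = 10` contributing voxels are
flagged missing and *dropped* from slope fits, never interpolated: with a
linear model, omission is unbiased whereas imputation would manufacture
support where there is none.

## Normalization and the gradient

Raw ring means are z-scored against the younger-HC stratum (age ≤ 45; the
HC strata are younger ≤ 45 < middle ≤ 60 < older): per metric and per ring,
`z = (m - mean_ref) / sd_ref`, with the reference mean and SD computed with
denominator n−1. Applying the normalization to the reference stratum itself
must give per-ring mean 0 and SD 1 to machine precision, and the tests hold
it to 1e-12. The reference stratum is configurable (any stratum can serve),
and normalization can be bypassed entirely (`normalize = "none"`), which is
what the noise-free self-consistency check uses.

The group-level gradient is the fixed slope from the linear mixed model
`z ~ ring + (1 | subject)` (REML, per-subject random intercept), with Wald
SE, CI and p. The slope unit is **z per ring index**; dividing by the ring
thickness converts to z per mm. A random slope can be added
(`random_slope = TRUE`), but the default keeps the random-intercept
structure: the phantom generator's subject-level slope spread is small
relative to the ring-noise-driven sampling variance, and the calibration
checks (coverage within [0.90, 0.98] over 200 replicate cohorts at
n = 100/group) hold under that default. Subject-level gradients are plain
OLS slopes over that subject's non-missing rings (at least 3 required).

Group contrasts come from the pooled model `z ~ group * ring +
(1 | subject)`: every pairwise difference of group slopes is a linear
hypothesis on the interaction terms (via `multcomp::glht`), reported with
raw and Benjamini–Hochberg-adjusted p. BH is used as the family correction
throughout the package in place of Tukey's HSD; both raw and adjusted
p-values are always emitted so either convention can be read off.

## Mediation analysis

Mediation uses the product-of-coefficients estimator for linear models:
`a` from `mediator ~ exposure + confounders`, `b` and the direct effect from
`outcome ~ mediator + exposure + confounders`; indirect = `a·b`, total =
direct + indirect, with percentile bootstrap CIs over case resampling
(default 5000 draws, seed mandatory) and the percentage mediated
`PM = 100 · indirect / total`. PM is reported unclipped — it is negative or
exceeds 100 when direct and indirect effects oppose — with `clip_pm = TRUE`
available to truncate to [0, 100], the convention under which fully mediated
associations print as "PM = 100%". WMH volumes are log-transformed (natural
log, configurable offset) before entering any model. Parallel mediators are
entered jointly in the outcome model, with per-mediator indirect effects
`a_j·b_j` and jointly resampled bootstrap CIs. Confounders may be
categorical (e.g. group) and are expanded to dummies.

Two degenerate regimes are worth naming. First, with *zero* mediator
disturbance the mediator is an exact linear function of exposure and group,
the outcome design is rank-deficient, and mediation is unidentifiable; the
package raises a rank-deficiency error rather than returning arbitrary
coefficients. This is why the "noise-free" pipeline configuration keeps a
small positive subject-slope SD while zeroing every measurement-level noise:
in that regime the outcome-model paths (`b`, direct effect `c'`) are exact
to numerical tolerance and the `a` path equals its oracle regression.
Second, when the total effect is numerically zero PM is undefined and is
reported missing with a reason, not as an arbitrary ratio.

## Ring-wise transcriptomics (PLS1)

Expression samples carry a distance from the ventricles; they are assigned
to rings by the same half-open bounds and averaged into a ring × gene
matrix. Gene columns are standardized across rings (zero-variance genes are
dropped with a warning), the response (the ring-wise gradient profile) is
centred, and the first PLS component is the classical one: weight vector
proportional to `X'y`, normalized to unit length; variance explained is the
R² of the response on the first score. A permutation test shuffles the ring
order of the response (`p = (1 + #{perm ≥ observed}) / (n_perm + 1)`), and
gene-level inference bootstraps the rings: resampled weight vectors are
sign-aligned to the original (component signs are arbitrary; without
alignment the SE would be inflated), `Z = weight / bootstrap SE`, and genes
enter the PLS1+/PLS1− lists when `|Z| > 5` and BH-adjusted `q < 0.001`.

Two numerical choices deserve justification:

* **The gene-level p uses a t reference with (rings − 2) df, not a normal.**
  With ten observation rows the bootstrap SE is itself noisy, and the null
  distribution of Z is much heavier-tailed than normal (measured: null
  `|Z| > 5` at roughly 0.5%, versus 5.7e-7 for a standard normal). A normal
  reference therefore makes BH anticonservative — about 9% of selected genes
  are false at the default thresholds in the recovery simulations — while
  the t reference restores control (sensitivity 1.0, zero false selections
  in the same simulations). `p_reference = "normal"` is available.
* **Degenerate resamples are redrawn.** A bootstrap resample with a
  near-constant response or fewer than `min_unique_rings = 5` distinct rings
  carries no slope information; more than 50% redraws aborts with an
  instability error.

A known limitation: with 10 rings and ~1000 genes the ring × gene matrix has
rank 10, so PLS1 can reconstruct *any* response vector — including permuted
ones — almost perfectly. The permutation p for the variance explained is
therefore not expected to reach its minimal value even under very strong
constructed signal (observed p ≈ 0.1 with 50 of 1000 genes tracking the
profile), and for a linear profile the order-reversal permutation ties the
observed statistic exactly. The component-level permutation test is
accordingly weak at this geometry; the gene-level bootstrap Z, which is
sharp in the same simulations, carries the inferential weight. Spatial-
autocorrelation-preserving nulls are not implemented. Cell-type enrichment
of the resulting lists is an upper-tail hypergeometric test against a stated
universe, BH-adjusted across sets, verified against exhaustive enumeration
of all overlap configurations with universes up to 20.

## The synthetic phantom module

The phantom is deliberately geometric, not brain-shaped: the analysis
depends only on the distance structure, so ellipsoidal shells (ventricle ⊂
white matter ⊂ gray matter ⊂ brain, with spherical WMH blobs seeded inside
WM) on a default 96³ grid at 1 mm isotropic spacing are sufficient, and the
outer WM semi-axes are chosen so the shell spans beyond 33 mm and populates
every ring of the default design. Metric maps follow
`intercept + slope · distance + noise`, clipped to [0, 1] as NODDI fractions
are (clipping beyond 1% of WM voxels warns).

Cohorts follow a linear structural causal model: exposure CPV → subject
gradient (path `a`) → outcomes (log-WMH volume, NAWM metric, WMV, GMV; paths
`b`, direct `c'`) → cognitive scores. Subject ring profiles are generated on
the normalized scale directly (the fast path; the voxel-map slow path
exercises the ring machinery separately), with Gaussian subject-level
variation throughout — the distributional form is an assumption, stated
here once. Default group slope means (0, 0.0064, 0.019, 0.022, 0.011,
0.032, 0.023 z/ring across three HC age strata and four disease groups)
mirror the magnitudes this literature reports, as do the default CPV scale
(2 ± 0.5 ml) and the default exposure→gradient path `a = 0.008` z/ring per
ml — a coefficient of 0.5 on that scale would swing subject slopes by ±0.25
z/ring, an order of magnitude above the slopes themselves. The canonical
`a = 0.5, b = 0.4, c' = 0.3` structural model with unit disturbances is used
as the dedicated mediation-recovery scenario instead. Randomness uses one
root seed with per-subject child streams, so enlarging a group never
changes existing subjects' draws; identical spec and seed reproduce outputs
bit for bit.

What the phantom does *not* emulate: realistic lesion morphology and
spatial noise correlation, scanner/protocol batch effects, registration
error, the GM-biased spatial sampling of regional expression atlases, and
gene–gene correlation structure. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated generative
model, not robustness to those real-data features.

## Problem sizes used in the checks

The packaged checks use: 200 replicate cohorts per gradient scenario and
500 null-contrast replicates at n = 100 subjects/group with 10 rings;
mediation recovery at n = 5000 with 1000 bootstrap draws plus 200 null
replicates at n = 500; PLS recovery with 10 rings × 1000 genes (50
associated), 1000 bootstrap draws and 1000 permutations; distance-transform
and enrichment oracles verified exhaustively on grids up to 20³ and
universes up to 20. The end-to-end synthetic run uses seven groups of 100
subjects and completes in a few seconds.
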
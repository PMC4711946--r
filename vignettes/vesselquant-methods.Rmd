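---
title: "Methods: vessel-wall component quantification and permutation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vessel-wall component quantification and permutation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vesselquant` measures the areas of smooth muscle fiber (SMF) and
extracellular matrix (ECM) in trichrome-stained vessel cross-sections and
compares the normalized areas across groups of veins with permutation tests.
This vignette explains the model behind each stage, the tunable parameters,
the numerical choices made where several were defensible, and what the
synthetic validation does and does not demonstrate.

## The measurement model

A stained section is modeled as four color populations on a bright,
near-white background: reddish muscle, blue/green matrix, dark defects
(tissue folds, debris), and blood-colored residue. All color reasoning
happens in CIELab (sRGB input, D65 white point, L\* in [0, 100]), where
Euclidean distance approximates perceptual color difference, so "similar
stain" becomes "small distance". The conversion implements the published
sRGB transfer function and primaries directly; the lightness channel L\*
doubles as the grayscale image for thresholding.

### Pre-processing: delimiting the wall

1. **Fold removal.** Folded tissue is so dark that its color no longer
   separates muscle from matrix. Folds are cut at half the location of the
   *first predominant peak* of the L\* histogram — in a vessel image the
   darkest major mode is the wall itself, so half its location sits well
   below any usable tissue. "Predominant" is made operational as: first
   local maximum of the smoothed histogram (101 unit-width bins, moving
   average of window 5) with height at least 25% of the global maximum,
   scanning upward from L\* = 0. Plateaus of equal smoothed counts count as
   a single peak located at their center, which makes the rule exact for
   degenerate single-valued images.
2. **Blood removal.** Blood shares hue with muscle and would inflate the SMF
   area. It is masked by a color ball in Lab space. The shipped center
   (35, 45, 25) and radius 18 were tuned once against the synthetic
   generator's blood color; for real material they should be re-estimated
   from a subset of samples, as blood color varies with fixation.
3. **Validity flags.** Defect pixels are zeroed in L\* *and* flagged
   invalid. The flag matters: the contrast-stretch range and the Otsu
   histogram are computed over valid pixels only, otherwise the injected
   zeros would pin the lightness minimum at 0 and neutralize the stretch.
4. **Contrast stretch.** Valid L\* values are remapped affinely (then
   rounded) from [Lmin, Lmax] onto [0, 100]. This standardizes exposure
   across photomicrographs without touching hue.
5. **Otsu binarization.** The stained wall is darker than background and
   lumen, so the wall is the below-threshold class. The threshold maximizes
   between-class variance by exhaustive search over 256 quantized levels on
   [0, 1]; the returned cut is the midpoint between adjacent levels
   (`(k + 0.5)/255`), so the two quantized classes are separated strictly,
   and ties are broken toward the lowest cut.
6. **DBSCAN cleanup.** Dust and dirt survive binarization as small specks.
   A raster DBSCAN (neighborhood radius R = 3 px, MinPxs = 9, Euclidean
   distance between pixel centers) is run twice: first on wall-candidate
   pixels, keeping only the largest cluster as the wall; then on the
   remaining non-wall pixels, keeping the two largest clusters (the region
   exterior to the wall and the lumen) and merging every smaller non-wall
   cluster or noise pixel back into the wall, which closes pinholes. The
   two-pass rule covers both natural readings of "keep the wall and the
   lumen" when cleaning a binarized annulus. Pixels are visited in a fixed
   scan order rather than randomly; this affects only cluster numbering and
   which cluster claims a border pixel tied between two, never which pixels
   are core, so the output is deterministic without loss of generality.

The cleaned mask's pixel count is `A_TOT`, the normalization denominator.
Note that filled defect holes belong to the wall (they are vessel-wall
tissue), but their pixels are painted white before clustering, so they
count toward `A_TOT` while contributing to neither component — on sections
with large folds the two ratios sum to visibly less than 1 by design.

### Feature extraction: classifying wall pixels

The contrast-enhanced image, masked to the wall with a white background, is
clustered into k = 3 groups (muscle, matrix, background) by k-means under
the Lab Euclidean distance. Clustering the background along with the tissue,
rather than clustering wall pixels alone with k = 2, keeps the procedure
robust to wall-mask imperfections: stray bright pixels have a natural
cluster to fall into. Clustering is per image, which makes each sample
self-calibrating against stain-intensity variation between slides; the cost
is that cluster labels mean nothing across images, which is why roles are
re-derived per image: the centroid nearest white (100, 0, 0) is background,
and of the remaining two the one with larger a\* (redder) is muscle. Exact
ties are broken by cluster index with a warning.

The clustering cost is the total *unsquared* color distance
`J = sum_j sum_i distance(px_ij, centroid_j)`. Lloyd iteration with
mean-color centroid updates minimizes the squared-distance cost, so with an
unsquared J a mean update can in rare geometries increase J; the
implementation therefore discards an update that would raise J and treats
the run as converged, guaranteeing a non-increasing cost trace. Convergence
is declared when the relative decrease in J falls below `tol = 1e-4`;
`n_restarts = 10` random restarts (initial centroids drawn from distinct
pixel colors) guard against local minima, and the lowest-cost run wins. A
cluster emptied during assignment is re-seeded at the pixel farthest from
its current centroid. With a fixed seed the entire model is reproducible to
the bit.

## Permutation statistics

Histological cohorts are small (here, single digits to low tens per group),
which undermines the distributional assumptions of t-tests and the
similarity-of-shape assumptions of rank tests. The permutation test needs
neither: under the null hypothesis the group labels are exchangeable, so the
pooled sample is resampled without replacement into pseudo-groups of the
original sizes `n_1` and `n_2`, rebuilding the null distribution of the
chosen statistic (difference in means by default; difference in medians and
the two-group F ratio are available). The full reference set has
`(n_1 + n_2)! / (n_1! n_2!)` assignments — about 5.1 × 10^11 already at
(22, 20) — so a Monte-Carlo subset of m resamples is used, with

```
p = (b + 1) / (m + 1)
```

where b counts resamples at least as extreme (ties included) as the observed
statistic. The +1 terms make the observed grouping a member of its own
reference set: p can never be exactly 0, its floor is `1/(m + 1)`, and its
resolution is `1/(m + 1)` (10^-5 at m = 100,000). Treating b as binomial
gives the normal-approximation confidence interval
`p ± z sqrt(p(1 − p)/m)`; at p ≈ 0.05 and m = 100,000 the half-width is
0.00135, i.e. the estimate near a 5% significance level is good to about
0.14%. An exact Clopper–Pearson interval is available as an option.

Numerical contracts worth stating:

- **Tail convention.** Default is two-tailed on |statistic|; a one-tailed
  mode (`T_perm >= T_obs`) is available. Reported two-group comparisons of
  this kind are conventionally two-tailed, but the estimator itself is
  tail-agnostic.
- **Worker invariance.** m is split into fixed-size chunks, each driven by
  its own L'Ecuyer-CMRG substream chained from the master seed
  (`parallel::nextRNGStream`), so b is a pure function of
  (data, m, statistic, tail, seed) — identical for 1, 2 or 40 workers, and
  the caller's RNG state is left untouched.
- **Label-swap invariance.** Resampling is canonicalized — pooled values
  sorted, the smaller pseudo-group drawn — so swapping the two input groups
  reproduces the identical two-tailed result bit for bit.
- **Degenerate input.** If every pooled value is equal the test warns and
  returns p = 1.
- **No multiplicity correction.** The pairwise group comparison
  (`compare_groups()`) reports raw p-values per component and group pair,
  as is conventional for small exploratory histology cohorts. Users
  comparing many groups should apply `p.adjust()` themselves.
- **Exact mode.** For small cohorts, `exhaustive_permutation_test()`
  enumerates the full reference set (capped at 10^6 assignments) and is the
  package's own gold standard; the Monte-Carlo engine is validated against
  it.

On validating a Monte-Carlo engine against the exact enumeration: the MC
error is itself binomial, so across 200 independent validation instances an
occasional excursion slightly past 3 standard errors is not a defect but a
certainty (expected count ≈ 0.5). The suite therefore checks *calibration* —
at most 3 of 200 instances beyond 3 SE and none beyond 4.5 SE plus the
`2/(m+1)` discretization of the estimator — rather than a per-instance hard
3 SE cut that a correct implementation would fail with ~40% probability.

## The synthetic generator

`generate_vessel_image()` renders what the pipeline assumes a section looks
like: a near-white background and lumen, an annular wall, muscle/matrix
blotches, and the three defect types. Muscle-vs-matrix assignment thresholds
a smooth random field (a sum of six random low-frequency cosines plus slight
jitter) at the empirical quantile matching the requested fraction, so
components form connected patches, as in tissue, and the realized fraction
matches the target to quantile resolution. Defaults: 192 × 192 px, annulus
radii 38/78, per-channel color noise sd 2.5 Lab units, 1 fold, 2 blood
blobs, 10 dust specks; palettes SMF (55, 35, 15), ECM (60, −20, −15), blood
(35, 45, 25). `generate_group_samples()` draws per-sample ratio tables from
truncated normals for exercising the statistics layer directly.

What passing the synthetic validation shows: correct composition of the
stages, correct area accounting, recovery of known mixing fractions through
the full pipeline (mean absolute ratio error ≤ 0.05 over fractions
0.2–0.8 × 10 seeds), robustness of the ratios to a global palette shift of
~9 Lab units (≤ 0.03 change), and exact reproducibility. What it cannot
show: performance on real stains — the generator has flat-colored
components, radially symmetric geometry, and defect models far simpler than
real folds, intimal hyperplasia, or uneven illumination. Parameters tuned on
it (especially the blood color mask) transfer to real material only as
starting points.

## Validation problem sizes

The suite validates Otsu against a brute-force between-class-variance scan
on 100 random rasters up to 64 × 64; DBSCAN against a naive all-pairs
implementation on 50 random 40 × 40 masks; the Monte-Carlo engine against
full enumeration on 200 instances with group sizes ≤ 6 at m = 4,000; type-I
error with 1,000 same-distribution replicates of two n = 20 groups at
m = 2,000 (acceptance band 3–7% at α = 0.05); and the full pipeline on 40
synthetic vessels (4 fractions × 10 seeds) at the default 192 × 192
geometry. These sizes were chosen to exercise each oracle well past its edge
cases while keeping a complete run in the low minutes on one core.

## Known limitations

- All areas are in pixels; no physical (µm) calibration or magnification
  handling is provided.
- No stain deconvolution: color clustering assumes the two stain families
  remain separable in Lab, which fails for badly faded or over-stained
  slides.
- The wall is assumed to be the largest dark connected structure; sections
  with a torn wall in several large fragments will keep only the largest.
- No per-layer (intima/media/adventitia) breakdown and no thickness
  measurements.
- The fold threshold assumes the wall produces the first predominant
  lightness mode; extremely fold-heavy images can violate this.
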
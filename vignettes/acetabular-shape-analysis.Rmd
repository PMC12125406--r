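---
title: "Statistical shape analysis of the infant acetabulum from ultrasound landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape analysis of the infant acetabulum from ultrasound landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipshape)
library(dplyr)
```

## The clinical problem

Developmental dysplasia of the hip (DDH) in newborns is diagnosed on
ultrasound; decentered hips (Graf types D, III and IV) are treated by
closed reduction, but a substantial fraction go on to open reduction, a
pelvic osteotomy, or residual dysplasia at age five. The Graf
classification is sensitive for diagnosis but weakly prognostic, so the
question this package addresses is whether the *shape* of the bony
acetabular roof on the diagnostic ultrasound carries prognostic signal.

The pipeline quantifies acetabular shape with a two-dimensional point
distribution model over a 13-point landmark protocol, summarizes each hip
as a small vector of mode Z-scores, and relates those scores (together
with a geometric femoral-head-coverage index) to treatment outcomes at age
five by logistic regression. Because the clinical images behind this
design are not publicly deposited, the package ships a synthetic-cohort
generator with known ground truth; every stage is exercised and tested
against that truth.

## Landmark protocol and geometry

Each hip is annotated with 13 contour points (protocol indices 0–12):
point 4 marks the start of the slope of the bony acetabular roof, point 12
its deepest marked extent, and point 0 lies on the straight iliac line,
proximal to point 4 at half the Euclidean 4–12 distance
(`derive_point0()`). Points 1–3 and 5–11 are spaced at equal arc length
along their segments (`resample_equal_spacing()`); arc length is the only
well-defined notion of "equal spacing" on a curved border, and is computed
along the digitized polyline with linear interpolation. We read the half
distance as the chord rather than contour arc length: the iliac segment is
straight, so the two coincide there, and the chord is reproducible from
the two endpoints alone.

Two further points describe the femoral head: its centre (13) and one rim
point (14), fixing the radius $r$. The coverage index is the percentage of
the head circle lying on the acetabular side of the infinite line through
points 0 and 4. With the centre at distance $h$ from that line, the cut
segment has area

$$A(h) = r^2 \arccos(h/r) - h\sqrt{r^2 - h^2},$$

and `fhc_percent()` converts it to a covered percentage, taking the side
that contains point 12 as "covered" so the definition is independent of
image orientation. The function is continuous and strictly monotone in the
signed centre-to-line distance, and antisymmetric about the line
(`fhc(-d) + fhc(d) = 100`). Coverage is categorized per Morin: above 58%
is category 0, 33–58% category 1 (both bounds included, since the
interval is printed closed), below 33% category 2. Whether the 0–4 line
should be a ray or an infinite line is not specified by the protocol; we
use the infinite line.

## The shape model

Contour configurations are aligned by generalized Procrustes analysis
(`procrustes_align()`): iteratively, each shape is similarity-aligned to
the running mean and the mean re-estimated, until the mean moves by less
than $10^{-10}$ (at most 100 iterations; typical cohorts converge in
3–6). The default removes translation, rotation and scale — pixel scale
and probe pose are nuisances the protocol already tries to minimize — but
each transform can be switched off to reproduce translation-only
variants. The planar rotation has a closed form
($\theta = \operatorname{atan2}(\sum y x' - x y', \sum x x' + y y')$), so
alignment is vectorized over the cohort. Two frame conventions make the
result reproducible: the overall rotation, which generalized Procrustes
leaves free, is fixed by putting the mean's major principal axis on the
x-axis (direction pinned by the point-0 to point-12 chord), so a common
rigid transform of all inputs leaves the output unchanged; and when
scaling is enabled the aligned shapes are orthogonally projected onto the
tangent space at the mean direction, the standard linearization that
keeps small shape variation from leaking curvature of the unit-size
constraint into spurious minor modes.

`fit_ssm()` is a principal-component decomposition of the aligned shape
vectors (26 components, sample covariance with denominator $n-1$). Modes
are sorted by eigenvalue $\lambda_m$; the retained count is the smallest
$k$ whose cumulative variance proportion reaches the retention threshold
(default 0.95, inclusive). Each mode's sign is pinned so its
largest-magnitude component is positive: PCA signs are otherwise
arbitrary, and an unpinned sign would flip odds-ratio directions between
runs.

A hip's score on mode $m$ is
$z_m = \langle x - \bar{x}, u_m\rangle / \sqrt{\lambda_m}$, in units of
training-cohort standard deviations. New shapes (for instance repeat
annotations) are first similarity-aligned to the model mean with the same
transform family, so scores from different annotation sessions live in one
frame. By construction training scores have per-mode mean 0 and variance 1
(the $n-1$ denominator matches the sample-SD semantics of a Z-score).
`synthesize_shape()` inverts the map —
$\bar{x} + z\sqrt{\lambda_m}u_m$ — and `autoplot(model, type = "modes")`
draws each retained mode at −2.5, 0 and +2.5 SD.

## Outcomes and association analysis

Four outcomes are derived from the treatment history
(`derive_outcomes()`); the initial closed reduction itself is never
adverse:

1. open reduction;
2. open reduction or pelvic osteotomy within five years;
3. pelvic osteotomy or residual dysplasia at age five, with
   open-reduction hips excluded (`NA`);
4. the composite "unfavorable outcome" (any of the above).

Residual dysplasia means an acetabular index strictly greater than 21° on
the age-5 radiograph (21.0° exactly is not residual); the threshold is an
argument so sensitivity analyses can move it. The index must be present
for hips without surgery; surgical hips settle their outcomes without it.

`run_association_suite()` fits, per outcome: univariable logistic
regressions on each retained mode's continuous Z-score; one multivariable
model with all retained modes plus the Morin category entered as a single
ordinal covariate — with four retained modes that keeps the covariate
count at five, the events-per-variable rule of thumb for a cohort of this
size — and per-mode quintile-categorized fits. Quintile boundaries sit at
cumulative ranks $\mathrm{round}(kn/5)$, $k = 1..4$ (ties broken by stable
input order); for $n = 92$ that yields group sizes 18/19/18/19/18. The
lowest fifth is the reference category.

Fits are maximum likelihood via iteratively reweighted least squares
(`stats::glm`, binomial family, deviance tolerance $10^{-8}$, 50
iterations), reported as odds ratios with 95% Wald intervals
($\exp(\hat\beta \pm 1.959964\,\mathrm{SE})$) and a model-level
likelihood-ratio omnibus p-value. Complete or quasi-complete separation
(non-convergence, or $|\hat\beta| > 15$) is flagged, never repaired — no
penalized variants are offered, so a separated cell is reported the way
clinical tables print it, as an uninterpretable interval. No
multiple-testing adjustment is applied (the analysis is
hypothesis-generating); the result table carries raw p-values so any
correction can be applied downstream with `p.adjust()`.

## Reliability

`reliability_study()` projects repeat annotation series (for example:
rater 1 twice, rater 2 once, on a 20% image subset) onto the *primary*
model — refitting per rater would change the modes being compared — and
stacks the per-mode Z-scores as the columns of one images-by-sessions
table. Reliability per mode is the two-way absolute-agreement single-
measures intraclass correlation

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

which penalizes systematic offsets between sessions as well as random
disagreement. Stacking both raters' series into one table yields a single
combined inter/intra-observer coefficient rather than separate ones; the
overall coefficient is the per-mode ICC weighted by each retained mode's
(renormalized) share of total variance, so reliability on a mode carrying
59% of the variation counts proportionally more than one carrying 3%.

## The synthetic-cohort generator

`synthetic_cohort()` is first-class, tested code, not a fixture. Its
defaults encode the study conditions the pipeline targets:

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 92 | analysis-set size of the target cohort |
| `mode_variance_proportions` | 0.59, 0.23, 0.10, 0.03 | the four-mode variance spectrum the analysis expects |
| `total_shape_variance` | 30 px² | ~2 px per-landmark SD at a ~100 px template, a plausible annotation spread |
| `landmark_noise_sd` | derived | the remainder of the variance budget, $1-\sum p_m = 5\%$, as isotropic per-coordinate noise |
| `rater_noise_sd` | 1.5 px | puts the overall weighted ICC near 0.8 under the default spectrum |
| `outcome_intercept` | logit(57/92) | composite-outcome prevalence of 62% |
| `outcome_coefficients` | (0, 0, 0, ln 1.8) | a planted mode-4 effect, nulls elsewhere |
| `fhc_mean`, `fhc_sd` | 24, 15 (%) | coverage distribution of a decentered-hip cohort |
| `component_split` | 12 : 13 : 32 | split of unfavorable hips into open reduction / osteotomy / residual |

Mechanics: the 13-point template is a straight iliac segment joined to a
circular-arc acetabular slope, built with the package's own protocol
operations. Planted modes are random directions orthogonalized against
each other *and against the similarity subspace* at the template
(translation, rotation and scale directions), so Procrustes alignment
cannot absorb any planted variation and variance-share recovery is
well-posed. Per patient, standard-normal scores deform the template along
the modes (mode $m$ scaled by $\sqrt{p_m \cdot \text{total variance}}$),
isotropic Gaussian noise is added to every coordinate, head points are
placed by bisection (`invert_fhc()`) to hit a truncated-normal coverage
target, and the composite outcome is drawn from a logistic link on the
true scores, then split into components at the configured ratio. The
acetabular index is drawn consistently with the residual status
(truncated above 21° for residual hips, below for favorable ones).
Everything is bit-reproducible given the configuration, and re-annotation
noise (`reannotate()`) is seeded separately.

What the generator does *not* emulate: correlated (anatomically
structured) annotation error, rater bias (noise is zero-mean), scanner or
probe-pose artefacts beyond a global similarity transform, any link
between coverage and shape scores (they are generated independently), and
non-Gaussian mode-score distributions. Passing tests therefore show that
the pipeline's estimators recover known truth under idealized but
realistically scaled noise — they do not validate the clinical claim on
real images.

## Numerical choices and degenerate inputs

* Procrustes tolerance $10^{-10}$ on the mean shape; shapes with zero
  centroid size are rejected.
* Eigenvalues below $10^{-12}$ of total variance are treated as zero; a
  retained mode with zero eigenvalue (possible only on degenerate input)
  is an error rather than a silent division by zero.
* The quintile boundary rule uses R's `round()`; boundaries of
  $kn/5$ never land exactly on .5 for integer $n$, so the half-even
  behaviour is moot but stated for completeness.
* `invert_fhc()` bisects the signed distance on $[-r, r]$ (60 iterations,
  $10^{-6}$ tolerance on the percentage); the coverage function is
  strictly monotone there, so the root is unique.
* Separation threshold $|\hat\beta| > 15$: on the odds scale that is
  $>3\times10^6$, far beyond anything estimable at these sample sizes.
* CSV landmark output prints 17 significant digits and is read back with
  a correctly rounded parser, so write-then-read is bit-exact.

## Problem sizes used in the tests

The test-suite checks run at the sizes the properties were derived for: variance-structure
recovery on one default cohort of $n = 500$; planted odds-ratio recovery
on $n = 5000$; type-I error over 200 null cohorts of $n = 200$; the
coverage oracle over 100 random configurations with $10^6$ stratified
uniform samples each; the ICC oracle on random 6×3 tables; the
closed-form odds-ratio oracle over 500 random 2×2 tables. Sampling
variability at $n = 500$ leaves the leading variance share with a
standard error near 0.015, so a recovery band of ±0.03 is roughly a 2-SE
check for the dominant mode and looser for the minor ones.

## Known limitations

* The analysis is two-dimensional; DDH is a three-dimensional disorder,
  and the model sees only the bony contour in the standard ultrasound
  plane.
* Which Procrustes transform family the original annotation tooling
  applied is not documented; mode shapes (though not the qualitative
  pipeline) depend on that choice, which is why it is configurable.
* Mode score signs depend on the eigenvector orientation convention;
  cross-study comparison of odds-ratio *directions* requires fixing the
  convention, which is why signs are pinned.
* With ~90 subjects the quintile-categorized fits are fragile (cells with
  zero events separate); the package reports, and does not repair, those
  cells.
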
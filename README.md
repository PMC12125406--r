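# hipshape

Statistical shape analysis of the infant acetabulum from 2-D ultrasound
landmarks.

In developmental dysplasia of the hip (DDH), decentered hips (Graf types
D, III, IV) are reduced early, but many still need an open reduction or a
pelvic osteotomy, or show residual dysplasia at age five — and the
standard ultrasound classification predicts little of that course.
`hipshape` asks whether the *shape* of the bony ilium–acetabulum contour
on the diagnostic ultrasound does, for researchers in pediatric
orthopedics and medical image analysis who work with landmark
annotations rather than raw images.

## What it computes

Given 13 contour landmarks per hip (plus two femoral-head points), the
package:

* aligns the cohort by **generalized Procrustes analysis**
  (translation/rotation/scale, configurable) with tangent-space
  projection, and fits a **point distribution model**: eigendecomposition
  of the sample covariance of aligned shape vectors, retaining the modes
  whose cumulative eigenvalue share reaches 95%,

  $$x \approx \bar{x} + \sum_m z_m \sqrt{\lambda_m}\, u_m,$$

  so each hip is summarized by mode Z-scores $z_m$ (SD units);
* measures **femoral head coverage** as the percentage of the head circle
  on the acetabular side of the iliac line through points 0 and 4, from
  the circular-segment area
  $A(h) = r^2\arccos(h/r) - h\sqrt{r^2-h^2}$, with Morin categories
  (>58% / 33–58% / <33%);
* derives four **treatment outcomes** (open reduction; any surgery;
  osteotomy or residual dysplasia, open reductions excluded; the
  composite "unfavorable outcome"), residual dysplasia meaning an
  acetabular index > 21° at age five;
* fits **logistic regressions** (univariable per mode, one multivariable
  model with the four modes + coverage category, and quintile-categorized
  variants), reporting odds ratios, 95% Wald CIs and likelihood-ratio
  omnibus p-values, with separation flagged rather than repaired;
* quantifies annotation **reliability** as a two-way absolute-agreement
  single-measures ICC per mode, combined into one overall coefficient
  weighted by each mode's variance share.

Because the clinical images are not publicly deposited, a
synthetic-cohort generator (`synthetic_cohort()`) with planted orthogonal
modes, noise levels and logistic outcome links provides ground truth for
every stage; the methods vignette
(`vignettes/acetabular-shape-analysis.Rmd`) documents the model,
defaults and limitations.

## Worked example

```r
library(hipshape)
library(dplyr)

cohort <- synthetic_cohort(synthetic_config(n_patients = 92, seed = 7))
shapes <- landmarks_to_shapes(cohort$landmarks)
model  <- fit_ssm(procrustes_align(shapes))
model
#> Acetabular statistical shape model
#>   92 training shapes, 13 landmarks
#>   4 mode(s) retained at the 95% variance rule
#>   retained variance shares: 65.2%, 21.6%, 7.0%, 3.3% (cumulative 97.0%)
```

Four modes pass the 95% rule; at n = 92 the leading sample share (65.2%)
sits a few points above the generator's planted 59% — ordinary eigenvalue
sampling spread at this cohort size. Scores, coverage and outcomes feed
the association suite:

```r
zs    <- shape_zscores(model, shapes)
suite <- run_association_suite(zs, cohort_fhc(cohort$landmarks),
                               derive_outcomes(cohort$records))
filter(suite, outcome_id == 4, model_form == "multivariable", mode == 4) |>
  select(term, odds_ratio, conf.low, conf.high, p.value)
#> # A tibble: 1 × 5
#>   term  odds_ratio conf.low conf.high p.value
#>   <chr>      <dbl>    <dbl>     <dbl>   <dbl>
#> 1 m4         0.369    0.210     0.650 0.000590
```

The generator planted a mode-4 log-odds ratio of ln(1.8) on the
unfavorable outcome. A PCA mode's sign is arbitrary, and here the fitted
mode 4 came out anti-parallel to the planted one, so the effect appears
as the reciprocal; orienting it by the fitted-vs-true score correlation
recovers the planted direction:

```r
z4 <- filter(zs, mode == 4)
s  <- sign(cor(z4$z, cohort$truth$z[match(z4$hip_id,
                                          cohort$records$hip_id), 4]))
0.369^s
#> [1] 2.71   # planted 1.8, n = 92: wide but right-signed
```

The whole analysis — inclusion flow, coverage, alignment, model,
associations, reliability, CSV bundle and manifest — is one call:

```r
run <- run_pipeline(seed = 7, out_dir = "results")
run
#> hipshape pipeline run
#>   included hips: 92
#>   retained modes: 4 (65%/22%/7%/3%)
#>   overall weighted ICC: 0.851
#>   association cells with p < 0.05: 17
```

The overall weighted ICC of 0.85 is the variance-weighted reliability of
mode scores under the default 1.5 px re-annotation noise on an 18-image
(20%) subset. `autoplot(model)` draws the scree, and
`autoplot(model, type = "modes")` the synthesized contours at −2.5/0/+2.5
SD per mode. A thin command-line wrapper is installed at
`inst/scripts/hipshape-run.R`.

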
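mk_2x2 <- function(a, b, c, d) {
  # a = exposed events, b = exposed non-events, c = unexposed events,
  # d = unexposed non-events
  data.frame(
    y = rep(c(1, 0, 1, 0), c(a, b, c, d)),
    x = rep(c(1, 1, 0, 0), c(a, b, c, d))
  )
}

test_that("a 2x2 design reproduces the cross-product odds ratio", {
  res <- logistic_fit(mk_2x2(10, 10, 5, 15), "y", "x")
  expect_equal(res$odds_ratio, 3, tolerance = 1e-8)
  expect_false(res$separation)
  expect_true(res$conf.low < 3 & 3 < res$conf.high)

  # symmetric table: no association
  res0 <- logistic_fit(mk_2x2(1, 1, 1, 1), "y", "x")
  expect_equal(res0$odds_ratio, 1, tolerance = 1e-8)
})

test_that("random 2x2 tables match the closed-form MLE", {
  set.seed(77)
  for (i in 1:60) {
    cnt <- sample(2:40, 4, replace = TRUE)
    res <- logistic_fit(mk_2x2(cnt[1], cnt[2], cnt[3], cnt[4]), "y", "x")
    expect_equal(res$odds_ratio, (cnt[1] * cnt[4]) / (cnt[2] * cnt[3]),
                 tolerance = 1e-6)
  }
})

test_that("separation is flagged, not repaired", {
  d <- mk_2x2(10, 0, 0, 10)  # complete separation
  expect_warning(res <- logistic_fit(d, "y", "x"), "separation")
  expect_true(res$separation)
})

test_that("degenerate designs are rejected", {
  d <- mk_2x2(5, 5, 5, 5)
  d$y <- 1
  expect_error(logistic_fit(d, "y", "x"), "both classes")
  d2 <- mk_2x2(5, 5, 5, 5)
  d2$x <- 0
  expect_error(logistic_fit(d2, "y", "x"), "constant")
})

test_that("omnibus LRT matches the deviance-drop computation", {
  set.seed(5)
  d <- data.frame(x1 = stats::rnorm(120), x2 = stats::rnorm(120))
  d$y <- stats::rbinom(120, 1, stats::plogis(0.2 + 0.8 * d$x1))
  res <- logistic_fit(d, "y", c("x1", "x2"))
  full <- stats::glm(y ~ x1 + x2, binomial(), data = d)
  null <- stats::glm(y ~ 1, binomial(), data = d)
  want <- stats::pchisq(null$deviance - full$deviance, 2, lower.tail = FALSE)
  expect_equal(unique(res$omnibus_p), want, tolerance = 1e-10)
})

test_that("Wald confidence intervals cover a planted effect at ~95%", {
  set.seed(31)
  beta <- 0.6
  hits <- vapply(1:300, function(i) {
    x <- stats::rnorm(500)
    y <- stats::rbinom(500, 1, stats::plogis(-0.3 + beta * x))
    res <- logistic_fit(data.frame(x = x, y = y), "y", "x")
    res$conf.low <= exp(beta) && exp(beta) <= res$conf.high
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("the association suite covers every model form and outcome", {
  cohort <- tiny_cohort(n = 120, seed = 55)
  shapes <- landmarks_to_shapes(cohort$landmarks)
  model <- fit_ssm(procrustes_align(shapes))
  zs <- shape_zscores(model, shapes)
  fhc <- cohort_fhc(cohort$landmarks)
  outcomes <- derive_outcomes(cohort$records)
  suite <- run_association_suite(zs, fhc, outcomes)

  k <- model$n_retained
  expect_setequal(unique(suite$outcome_id), 1:4)
  per_outcome <- k +           # univariable, one per mode
    (k + 1) +                  # multivariable terms incl. coverage
    4 * k                      # quintile indicators per mode
  expect_equal(nrow(suite), 4 * per_outcome)
  ok <- suite[!is.na(suite$odds_ratio) & !suite$separation, ]
  expect_true(all(ok$conf.low <= ok$odds_ratio &
                    ok$odds_ratio <= ok$conf.high))
  expect_true(all(ok$odds_ratio > 0))

  # the osteotomy-or-residual outcome excludes open-reduction hips
  multi3 <- suite[suite$outcome_id == 3 & suite$model_form == "multivariable", ]
  expect_true(all(is.na(multi3$note)))
})

test_that("an outcome with one class is flagged across the suite", {
  cohort <- tiny_cohort(n = 30, seed = 2)
  shapes <- landmarks_to_shapes(cohort$landmarks)
  model <- fit_ssm(procrustes_align(shapes))
  zs <- shape_zscores(model, shapes)
  fhc <- cohort_fhc(cohort$landmarks)
  outcomes <- derive_outcomes(cohort$records)
  outcomes$o1_open_reduction <- FALSE           # no events at all
  suite <- run_association_suite(zs, fhc, outcomes)
  o1 <- suite[suite$outcome_id == 1, ]
  expect_true(all(!is.na(o1$note)))
  expect_true(all(is.na(o1$odds_ratio)))
  # ... and the rest of the suite still ran
  expect_true(any(!is.na(suite$odds_ratio[suite$outcome_id == 4])))
})
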
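test_that("planted modes are orthonormal and pure shape", {
  tmpl <- hip_template()
  modes <- make_modes(tmpl, 4, seed = 3)
  expect_lt(max(abs(crossprod(modes) - diag(4))), 1e-10)
  # orthogonal to translation, rotation and scale directions at the template
  xy <- matrix(tmpl, ncol = 2, byrow = TRUE)
  ctr <- sweep(xy, 2, colMeans(xy))
  sim <- cbind(
    as.numeric(t(cbind(1, 0 * ctr[, 1]))),
    as.numeric(t(cbind(0 * ctr[, 1], 1 + 0 * ctr[, 1]))),
    as.numeric(t(ctr)),
    as.numeric(t(cbind(-ctr[, 2], ctr[, 1])))
  )
  expect_lt(max(abs(crossprod(sim, modes))), 1e-10)
  expect_identical(modes, make_modes(tmpl, 4, seed = 3))
  expect_false(identical(modes, make_modes(tmpl, 4, seed = 4)))
})

test_that("a noise-free cohort has exactly the planted rank", {
  cfg <- synthetic_config(n_patients = 200, seed = 11,
                          landmark_noise_sd = 0)
  cohort <- synthetic_cohort(cfg)
  shapes <- landmarks_to_shapes(cohort$landmarks)
  # translation-only alignment is linear, so the planted rank is exact
  model <- fit_ssm(procrustes_align(shapes, rotate = FALSE, scale = FALSE))
  eig <- model$eigenvalues
  expect_length(eig[eig > 1e-10 * sum(eig)], 4)
  expect_lt(sum(eig[-(1:4)]) / sum(eig), 1e-10)
  # full similarity alignment with tangent projection stays numerically
  # rank-4 up to the tiny residual curvature of the rotation fit
  model2 <- fit_ssm(procrustes_align(shapes))
  eig2 <- model2$eigenvalues
  expect_lt(sum(eig2[-(1:4)]) / sum(eig2), 1e-4)
})

test_that("default cohorts recover the planted variance shares", {
  # single-cohort recovery sits within ~0.015 SE per share at n = 500, so
  # the mean error over a few seeds is a sharp test of estimator bias
  errs <- sapply(1:5, function(s) {
    cohort <- synthetic_cohort(synthetic_config(n_patients = 500, seed = s))
    model <- fit_ssm(procrustes_align(landmarks_to_shapes(cohort$landmarks)))
    expect_equal(model$n_retained, 4L)
    model$variance_proportions[1:4] - c(0.59, 0.23, 0.10, 0.03)
  })
  expect_lt(max(abs(rowMeans(errs))), 0.02)
  expect_lt(max(abs(errs)), 0.05)
})

test_that("generation is bit-reproducible and seed-sensitive", {
  a <- synthetic_cohort(synthetic_config(n_patients = 20, seed = 5))
  b <- synthetic_cohort(synthetic_config(n_patients = 20, seed = 5))
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(a$records, b$records)
  c <- synthetic_cohort(synthetic_config(n_patients = 20, seed = 6))
  expect_false(identical(a$landmarks, c$landmarks))
})

test_that("null outcome coefficients give the intercept's event rate", {
  cfg <- synthetic_config(n_patients = 4000, seed = 13,
                          outcome_coefficients = rep(0, 4),
                          outcome_intercept = stats::qlogis(0.62))
  o <- derive_outcomes(synthetic_cohort(cfg)$records)
  rate <- mean(o$o4_unfavorable)
  expect_lt(abs(rate - 0.62), 3 * sqrt(0.62 * 0.38 / 4000))
})

test_that("coverage placement inverts the coverage formula", {
  p0 <- c(0, 0); p4 <- c(0, 10); ref <- c(6, 5)
  ctr <- invert_fhc(50, 3, p0, p4, ref)
  expect_lt(abs(ctr[1]), 1e-6)  # on the line
  ctr100 <- invert_fhc(100, 3, p0, p4, ref)
  expect_gte(ctr100[1], 3 - 1e-6)  # saturated on the covered side
  set.seed(41)
  for (t in stats::runif(40, 1, 99)) {
    r <- stats::runif(1, 1, 5)
    ctr <- invert_fhc(t, r, p0, p4, ref)
    got <- fhc_percent(p0, p4, ctr, ctr + c(0, r), ref)$percent
    expect_equal(got, t, tolerance = 1e-4)
  }
})

test_that("re-annotation noise behaves like its nominal scale", {
  lm <- tiny_cohort(n = 25, seed = 3)$landmarks
  same <- reannotate(lm, 0, seed = 9, rater_id = "r1", session = 2L)
  expect_identical(same$x, lm$x)
  expect_identical(same$y, lm$y)

  sub <- reannotate(lm, 1, seed = 9, subset_fraction = 0.2)
  expect_equal(length(unique(sub$hip_id)), 5)  # 20% of 25

  big <- tiny_cohort(n = 92, seed = 3)$landmarks
  sub92 <- reannotate(big, 1, seed = 9, subset_fraction = 0.2)
  expect_equal(length(unique(sub92$hip_id)), 18)  # 20% of 92

  # doubling the noise SD doubles the mean displacement
  n1 <- reannotate(lm, 1, seed = 10)
  n2 <- reannotate(lm, 2, seed = 11)
  d1 <- mean(sqrt((n1$x - lm$x)^2 + (n1$y - lm$y)^2))
  d2 <- mean(sqrt((n2$x - lm$x)^2 + (n2$y - lm$y)^2))
  expect_equal(d2 / d1, 2, tolerance = 0.1)
})

test_that("generated annotations carry the full 15-point protocol", {
  cohort <- tiny_cohort(n = 10, seed = 44)
  counts <- dplyr::count(cohort$landmarks, hip_id)
  expect_true(all(counts$n == 15))
  expect_equal(nrow(cohort$records), 10)
  expect_true(all(cohort$records$exclusion_flag == "none"))
  ex <- synthetic_cohort(synthetic_config(
    n_patients = 10, seed = 44, exclusion_tally = c(3L, 3L, 6L, 2L)
  ))
  flow <- apply_inclusion_flow(ex$records)
  expect_equal(nrow(flow$included), 10)
  expect_equal(flow$tally$n[1:4], c(3, 3, 6, 2))
})
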
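test_that("two distinct shapes give one mode and z = +-1/sqrt(2)", {
  base <- hip_template()
  other <- base + make_modes(base, 1, seed = 2)[, 1] * 3
  fit <- procrustes_align(rbind(s1 = base, s2 = other))
  model <- fit_ssm(fit)
  expect_equal(length(model$eigenvalues), 1)
  expect_equal(model$variance_proportions, 1)
  expect_equal(model$n_retained, 1L)
  z <- shape_zscores(model, fit$aligned, align = FALSE)
  # n-1 variance denominator: each training shape sits 1/sqrt(2) SD out
  expect_equal(sort(z$z), c(-1, 1) / sqrt(2), tolerance = 1e-8)
})

test_that("retention rule keeps the smallest mode set reaching 95%", {
  # build a cohort whose sample eigenvalue proportions are exactly
  # (0.60, 0.20, 0.10, 0.06, 0.04)
  set.seed(13)
  n <- 60
  props <- c(0.60, 0.20, 0.10, 0.06, 0.04)
  scores <- matrix(stats::rnorm(n * 5), n, 5)
  scores <- sweep(scores, 2, colMeans(scores))
  scores <- scores %*% solve(chol(stats::cov(scores)))
  scores <- sweep(scores, 2, sqrt(props), "*")
  basis <- qr.Q(qr(matrix(stats::rnorm(26 * 5), 26, 5)))
  data <- scores %*% t(basis)
  model <- fit_ssm(data)
  expect_equal(model$variance_proportions[1:5], props, tolerance = 1e-8)
  expect_equal(model$n_retained, 4L)  # cumulative 0.96 >= 0.95
  # dropping the last retained mode falls below the threshold
  expect_lt(sum(model$variance_proportions[1:3]), 0.95)
})

test_that("mode vectors are orthonormal and sign-pinned", {
  cohort <- tiny_cohort(n = 60, seed = 21)
  model <- fit_ssm(procrustes_align(landmarks_to_shapes(cohort$landmarks)))
  gram <- crossprod(model$modes)
  expect_lt(max(abs(gram - diag(ncol(model$modes)))), 1e-8)
  for (j in seq_len(ncol(model$modes))) {
    k <- which.max(abs(model$modes[, j]))
    expect_gt(model$modes[k, j], 0)
  }
  expect_equal(sum(model$variance_proportions), 1, tolerance = 1e-12)
  expect_true(all(diff(model$eigenvalues) <= 1e-15))
})

test_that("training Z-scores are standardized and shapes reconstruct", {
  cohort <- tiny_cohort(n = 50, seed = 33)
  fit <- procrustes_align(landmarks_to_shapes(cohort$landmarks))
  model <- fit_ssm(fit)
  z <- shape_zscores(model, landmarks_to_shapes(cohort$landmarks))
  per_mode <- z |>
    dplyr::group_by(mode) |>
    dplyr::summarise(m = mean(z), v = stats::var(z))
  expect_true(all(abs(per_mode$m) < 1e-8))
  expect_true(all(abs(per_mode$v - 1) < 1e-6))

  # full-rank reconstruction from all nonzero modes
  dev <- sweep(fit$aligned, 2, model$mean_shape)
  coefs <- dev %*% model$modes
  recon <- sweep(coefs %*% t(model$modes), 2, model$mean_shape, "+")
  expect_lt(max(abs(recon - fit$aligned)), 1e-8)
})

test_that("zscores and synthesize are mutually inverse", {
  cohort <- tiny_cohort(n = 40, seed = 12)
  model <- fit_ssm(procrustes_align(landmarks_to_shapes(cohort$landmarks)))

  z0 <- shape_zscores(model, model$mean_shape, align = FALSE)
  expect_true(all(abs(z0$z) < 1e-10))

  v <- model$mean_shape + sqrt(model$eigenvalues[1]) * model$modes[, 1]
  z1 <- shape_zscores(model, v, align = FALSE)
  expect_equal(z1$z, c(1, rep(0, model$n_retained - 1)), tolerance = 1e-8)

  for (m in seq_len(model$n_retained)) {
    zz <- shape_zscores(model, synthesize_shape(model, m, 2.5), align = FALSE)
    want <- rep(0, model$n_retained); want[m] <- 2.5
    expect_equal(zz$z, want, tolerance = 1e-8)
  }

  # +-a synthesized shapes mirror about the mean
  plus <- synthesize_shape(model, 2, 1.7)
  minus <- synthesize_shape(model, 2, -1.7)
  expect_equal((plus + minus) / 2, model$mean_shape, tolerance = 1e-12)
  expect_equal(synthesize_shape(model, 1, 0), model$mean_shape)
  expect_error(synthesize_shape(model, model$n_retained + 1, 1), "retained")
})

test_that("a serialized model restores to the same scores", {
  cohort <- tiny_cohort(n = 30, seed = 4)
  shapes <- landmarks_to_shapes(cohort$landmarks)
  model <- fit_ssm(procrustes_align(shapes))
  d <- withr::local_tempdir()
  write_shape_model(model, d)
  back <- read_shape_model(d)
  expect_equal(back$n_retained, model$n_retained)
  z1 <- shape_zscores(model, shapes)
  z2 <- shape_zscores(back, shapes)
  expect_equal(z2$z, z1$z, tolerance = 1e-12)
})

test_that("tidy, glance and autoplot expose the model summaries", {
  cohort <- tiny_cohort(n = 30, seed = 6)
  model <- fit_ssm(procrustes_align(landmarks_to_shapes(cohort$landmarks)))
  td <- tidy(model)
  expect_equal(td$cumulative_proportion[nrow(td)], 1, tolerance = 1e-12)
  expect_equal(sum(td$retained), model$n_retained)
  gl <- glance(model)
  expect_gte(gl$retained_variance, 0.95)
  expect_s3_class(autoplot(model), "ggplot")
  expect_s3_class(autoplot(model, type = "modes"), "ggplot")
})
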
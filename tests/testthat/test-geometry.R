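test_that("point 0 lies half the 4-12 chord distance up the ilium", {
  expect_equal(derive_point0(c(0, 0), c(6, 8), c(0, -1)), c(0, -5))
  expect_error(derive_point0(c(2, 2), c(2, 2), c(0, -1)), "degenerate")
  set.seed(5)
  for (i in 1:25) {
    p4 <- stats::runif(2, -10, 10)
    p12 <- stats::runif(2, -10, 10)
    ang <- stats::runif(1, 0, 2 * pi)
    dir <- c(cos(ang), sin(ang))
    p0 <- derive_point0(p4, p12, dir)
    expect_equal(sqrt(sum((p0 - p4)^2)), sqrt(sum((p4 - p12)^2)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("equal-spacing resampling places points at equal arc gaps", {
  seg <- rbind(c(0, 0), c(4, 0))
  pts <- resample_equal_spacing(seg, rbind(c(0, 0), c(4, 0)), 3)
  expect_equal(pts, rbind(c(1, 0), c(2, 0), c(3, 0)))

  expect_equal(nrow(resample_equal_spacing(seg, rbind(c(0, 0), c(4, 0)), 0)), 0)
  expect_error(resample_equal_spacing(seg, rbind(c(1, 0), c(1, 0)), 1),
               "degenerate")

  # dense semicircle: the single interior point is the arc midpoint
  th <- seq(0, pi, length.out = 2001)
  arc <- cbind(cos(th), sin(th))
  mid <- resample_equal_spacing(arc, rbind(c(1, 0), c(-1, 0)), 1)
  expect_equal(as.numeric(mid), c(cos(pi / 2), sin(pi / 2)), tolerance = 1e-5)
})

test_that("resampled gap lengths have negligible spread on smooth contours", {
  th <- seq(0.2, 2.3, length.out = 4001)
  arc <- cbind(3 * cos(th), 2 * sin(th))  # elliptical border, densely sampled
  inner <- resample_equal_spacing(arc, arc[c(1, nrow(arc)), ], 7)
  pts <- rbind(arc[1, ], inner, arc[nrow(arc), ])
  # independent arc-length positions: project each sample onto the dense
  # polyline segment by segment
  cum <- c(0, cumsum(sqrt(rowSums((arc[-1, ] - arc[-nrow(arc), ])^2))))
  pos <- apply(pts, 1, function(p) {
    best <- c(Inf, 0)
    for (i in seq_len(nrow(arc) - 1)) {
      ab <- arc[i + 1, ] - arc[i, ]
      t <- min(max(sum((p - arc[i, ]) * ab) / sum(ab^2), 0), 1)
      q <- arc[i, ] + t * ab
      d2 <- sum((p - q)^2)
      if (d2 < best[1]) best <- c(d2, cum[i] + t * (cum[i + 1] - cum[i]))
    }
    best[2]
  })
  gaps <- diff(pos)
  expect_lt(stats::sd(gaps) / mean(gaps), 1e-6)
})

test_that("coverage percent matches closed-form circular-segment cases", {
  p0 <- c(0, 0); p4 <- c(0, 10); ref <- c(5, 5)
  # centre on the line: half covered
  expect_equal(fhc_percent(p0, p4, c(0, 5), c(2, 5), ref)$percent, 50)
  # centre far on the covered side: fully covered
  expect_equal(fhc_percent(p0, p4, c(4, 5), c(4, 7), ref)$percent, 100)
  # centre far on the uncovered side: zero
  expect_equal(fhc_percent(p0, p4, c(-4, 5), c(-4, 7), ref)$percent, 0)
  # r = 1, centre at h = 0.5 on the uncovered side: circular-segment value
  res <- fhc_percent(p0, p4, c(-0.5, 5), c(-0.5, 6), ref)
  seg <- acos(0.5) - 0.5 * sqrt(0.75)
  expect_equal(res$percent, 100 * seg / pi, tolerance = 1e-12)
  expect_equal(round(res$percent, 2), 19.55)
})

test_that("coverage is monotone in the signed distance and antisymmetric", {
  p0 <- c(0, 0); p4 <- c(0, 10); ref <- c(5, 5)
  r <- 2
  ds <- seq(-1.9, 1.9, by = 0.1)
  pc <- vapply(ds, function(d) {
    fhc_percent(p0, p4, c(d, 5), c(d, 5 + r), ref)$percent
  }, numeric(1))
  expect_true(all(diff(pc) > 0))
  expect_equal(pc + rev(pc), rep(100, length(pc)), tolerance = 1e-10)
})

test_that("coverage agrees with the Monte-Carlo area oracle", {
  set.seed(31)
  for (i in 1:12) {
    p0 <- stats::runif(2, -5, 5)
    p4 <- p0 + stats::runif(2, 1, 5)
    r <- stats::runif(1, 0.5, 3)
    ab <- p4 - p0
    nrm <- c(-ab[2], ab[1]) / sqrt(sum(ab^2))
    ref <- (p0 + p4) / 2 + 4 * r * nrm
    d <- stats::runif(1, -0.95, 0.95) * r
    ctr <- (p0 + p4) / 2 + d * nrm
    got <- fhc_percent(p0, p4, ctr, ctr + c(r, 0), ref)$percent
    oracle <- mc_fhc_oracle(p0, p4, ctr, r, ref, grid = 400L)
    expect_lt(abs(got - oracle), 0.2)
  }
})

test_that("Morin categories follow the coverage cut-offs", {
  expect_identical(morin_category(24), 2L)
  expect_identical(morin_category(33), 1L)
  expect_identical(morin_category(58), 1L)
  expect_identical(morin_category(59), 0L)
  expect_error(morin_category(101), "0, 100")
  expect_error(morin_category(-1), "0, 100")
})

test_that("cohort coverage lands near the generator's targets", {
  cohort <- tiny_cohort(n = 30, seed = 3)
  fhc <- cohort_fhc(cohort$landmarks)
  expect_equal(nrow(fhc), 30)
  expect_true(all(fhc$fhc_percent >= 0 & fhc$fhc_percent <= 100))
  # placement inverts the coverage geometry up to landmark noise
  expect_lt(stats::median(abs(fhc$fhc_percent - cohort$truth$fhc_target)), 5)
})
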
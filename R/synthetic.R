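#' Template ilium-acetabulum contour
#'
#' The 13-point mean contour the generator deforms: a straight iliac segment
#' (points 0-4, vertical in image coordinates) joined at point 4 to a
#' circular-arc acetabular slope ending at point 12, with points 1-3 and
#' 5-11 equally spaced along their segments — the same construction the
#' annotation protocol prescribes. Dimensions are in pixels at a typical
#' ultrasound crop scale (iliac line ~31 px, acetabular chord ~61 px).
#'
#' @param ilium_top `c(x, y)` of point 4 (start of the acetabular slope).
#' @param arc_radius Radius of the acetabular arc (pixels).
#' @param arc_degrees Angular span of the arc.
#' @return A 26-component shape vector (protocol order, xy interleaved).
#' @export
hip_template <- function(ilium_top = c(50, 50), arc_radius = 40,
                         arc_degrees = 100) {
  p4 <- ilium_top
  centre <- p4 + c(arc_radius, 0)
  theta <- pi - seq(0, arc_degrees * pi / 180, length.out = 9)
  arc <- cbind(centre[1] + arc_radius * cos(theta),
               centre[2] + arc_radius * sin(theta))
  p12 <- arc[9, ]
  p0 <- derive_point0(p4, p12, c(0, -1))
  ilium <- cbind(seq(p0[1], p4[1], length.out = 5),
                 seq(p0[2], p4[2], length.out = 5))
  xy <- rbind(ilium, arc[-1, ])   # p4 shared between segments
  xy_to_vec(xy)
}

# orthonormal basis of the similarity-transform subspace at a template:
# x/y translation, rotation and scaling directions
similarity_basis <- function(template) {
  xy <- vec_to_xy(template)
  ctr <- sweep(xy, 2, colMeans(xy))
  n <- nrow(xy)
  b <- cbind(
    xy_to_vec(cbind(rep(1, n), rep(0, n))),
    xy_to_vec(cbind(rep(0, n), rep(1, n))),
    xy_to_vec(ctr),                       # scale
    xy_to_vec(cbind(-ctr[, 2], ctr[, 1])) # infinitesimal rotation
  )
  qr.Q(qr(b))
}

#' Planted orthonormal shape modes
#'
#' Draws deterministic-given-seed random directions and Gram-Schmidt
#' orthogonalizes them against each other and against the similarity
#' subspace at the template (translation, rotation and scale directions), so
#' the planted variation is pure shape: Procrustes alignment cannot absorb
#' any of it. Mode signs are pinned largest-magnitude-component-positive,
#' the same convention [fit_ssm()] uses.
#'
#' @param template 26-component template shape vector.
#' @param n_modes Number of modes (<= 22 once the similarity subspace is
#'   removed).
#' @param seed Integer seed.
#' @return A `26 x n_modes` matrix with orthonormal columns.
#' @export
make_modes <- function(template, n_modes, seed) {
  p <- length(template)
  stopifnot(n_modes >= 1, n_modes <= p - 4)
  sim <- similarity_basis(template)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  raw <- matrix(rnorm(p * n_modes), p, n_modes)
  basis <- sim
  modes <- matrix(0, p, n_modes)
  for (j in seq_len(n_modes)) {
    v <- raw[, j]
    v <- v - basis %*% crossprod(basis, v)
    v <- v / sqrt(sum(v^2))
    modes[, j] <- v
    basis <- cbind(basis, v)
  }
  for (j in seq_len(n_modes)) {
    k <- which.max(abs(modes[, j]))
    if (modes[k, j] < 0) modes[, j] <- -modes[, j]
  }
  modes
}

#' Synthetic-cohort configuration
#'
#' Ground-truth parameters for [synthetic_cohort()]. Defaults emulate the
#' cohort the pipeline targets: 92 decentered dysplastic infant hips, four
#' orthogonal shape modes carrying 59/23/10/3% of the total shape variance
#' (the remainder of the variance budget becomes isotropic per-landmark
#' annotation noise), a femoral-head-coverage distribution centred at
#' 24% +- 15%, an unfavorable-outcome rate of 57/92 through a logistic link
#' on the mode Z-scores with a planted mode-4 log-odds ratio of ln(1.8) and
#' null effects elsewhere, and the observed 12:13:32 split of the composite
#' outcome into open reduction / pelvic osteotomy / residual dysplasia.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; every generator draw derives from it.
#' @param template Template shape vector (default [hip_template()]).
#' @param n_modes Number of planted modes.
#' @param mode_variance_proportions Share of `total_shape_variance` carried
#'   by each mode; positive, summing to at most 1. The remainder
#'   `1 - sum(...)` is the isotropic noise floor.
#' @param total_shape_variance Total planted shape variance (pixels^2 summed
#'   over the 26 coordinates).
#' @param landmark_noise_sd Per-coordinate annotation noise SD in pixels;
#'   default derived from the noise-floor remainder,
#'   `sqrt((1 - sum(prop)) * total_shape_variance / 26)`.
#' @param rater_noise_sd Re-annotation noise SD (pixels) used by
#'   [reannotate()]; default 1.5 px, which puts the overall weighted ICC
#'   near 0.8 under the default variance spectrum.
#' @param outcome_intercept Log-odds intercept of the unfavorable-outcome
#'   link; default `qlogis(57/92)`.
#' @param outcome_coefficients Per-mode log-odds ratios; default
#'   `c(0, 0, 0, log(1.8))`.
#' @param fhc_mean,fhc_sd Femoral-head-coverage target distribution
#'   (percent), truncated to [0, 100].
#' @param head_radius Femoral-head radius in pixels.
#' @param component_split Relative frequencies of open reduction, pelvic
#'   osteotomy and residual dysplasia among unfavorable hips.
#' @param exclusion_tally Extra records to generate carrying each of the
#'   four exclusion flags (flowchart order), for exercising the inclusion
#'   flow; default none.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_patients = 92, seed = 1L,
                             template = hip_template(),
                             n_modes = 4,
                             mode_variance_proportions = c(0.59, 0.23, 0.10, 0.03),
                             total_shape_variance = 30,
                             landmark_noise_sd = NULL,
                             rater_noise_sd = 1.5,
                             outcome_intercept = stats::qlogis(57 / 92),
                             outcome_coefficients = c(0, 0, 0, log(1.8)),
                             fhc_mean = 24, fhc_sd = 15,
                             head_radius = 25,
                             component_split = c(open = 12, osteotomy = 13,
                                                 residual = 32),
                             exclusion_tally = c(0L, 0L, 0L, 0L)) {
  stopifnot(
    n_patients >= 1,
    length(mode_variance_proportions) == n_modes,
    all(mode_variance_proportions > 0),
    sum(mode_variance_proportions) <= 1,
    length(outcome_coefficients) == n_modes,
    total_shape_variance > 0, head_radius > 0,
    length(exclusion_tally) == 4
  )
  if (is.null(landmark_noise_sd)) {
    floor_var <- (1 - sum(mode_variance_proportions)) * total_shape_variance
    landmark_noise_sd <- sqrt(floor_var / length(template))
  }
  stopifnot(landmark_noise_sd >= 0, rater_noise_sd >= 0)
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         template = template, n_modes = as.integer(n_modes),
         mode_variance_proportions = mode_variance_proportions,
         total_shape_variance = total_shape_variance,
         landmark_noise_sd = landmark_noise_sd,
         rater_noise_sd = rater_noise_sd,
         outcome_intercept = outcome_intercept,
         outcome_coefficients = outcome_coefficients,
         fhc_mean = fhc_mean, fhc_sd = fhc_sd, head_radius = head_radius,
         component_split = component_split,
         exclusion_tally = as.integer(exclusion_tally)),
    class = "synthetic_config"
  )
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Place the femoral-head centre to hit a target coverage
#'
#' Inverts the coverage geometry: finds, by bisection on the signed
#' centre-to-line distance, the point at which a circle of radius `radius`
#' has the requested coverage with respect to the iliac line through `p0`
#' and `p4`. The centre is placed on the perpendicular through the p0-p4
#' midpoint.
#'
#' @param target_percent Coverage target in [0, 100].
#' @param radius Femoral-head radius (> 0).
#' @param p0,p4 Points defining the iliac line.
#' @param covered_side_ref A point on the covered (acetabular) side.
#' @param tol Convergence tolerance on the coverage percent.
#' @return `c(x, y)` of the head centre.
#' @export
invert_fhc <- function(target_percent, radius, p0, p4, covered_side_ref,
                       tol = 1e-6) {
  stopifnot(target_percent >= 0, target_percent <= 100, radius > 0)
  ab <- p4 - p0
  nrm <- c(-ab[2], ab[1]) / sqrt(sum(ab^2))
  if (sum((covered_side_ref - p0) * nrm) < 0) nrm <- -nrm
  base <- (p0 + p4) / 2
  # the coverage curve is flat at its ends, so saturated targets are placed
  # exactly at the tangency distance
  if (target_percent <= 0) return(base - radius * nrm)
  if (target_percent >= 100) return(base + radius * nrm)
  lo <- -radius; hi <- radius
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    f <- fhc_from_signed_distance(mid, radius)
    if (abs(f - target_percent) < tol) break
    if (f < target_percent) lo <- mid else hi <- mid
  }
  base + ((lo + hi) / 2) * nrm
}

#' Generate a synthetic annotated cohort with known ground truth
#'
#' Per patient: standard-normal mode scores `z` deform the template along
#' the planted orthonormal modes (mode m scaled by
#' `sqrt(proportion_m * total_shape_variance)`), isotropic Gaussian
#' annotation noise is added to every coordinate, femoral-head points are
#' placed by [invert_fhc()] to hit a truncated-normal coverage target, and
#' the composite unfavorable outcome is drawn from a logistic link on `z`;
#' unfavorable hips are split into open reduction, pelvic osteotomy or
#' residual dysplasia in the configured proportions, and the age-5
#' acetabular index is drawn consistently with the residual status.
#' Everything is reproducible bit-for-bit given the configuration.
#'
#' @param config A `"synthetic_config"`, or arguments passed on to
#'   [synthetic_config()] via `...`.
#' @param ... Used only when `config` is missing.
#' @return A list: `landmarks` (tidy 15-point annotations of the analysis
#'   set), `records` (patient metadata incl. any flagged exclusion records),
#'   `truth` (planted modes, per-patient `z`, mode SDs, outcome
#'   coefficients, coverage targets).
#' @export
synthetic_cohort <- function(config = NULL, ...) {
  if (is.null(config)) config <- synthetic_config(...)
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  modes <- make_modes(config$template, config$n_modes, config$seed)
  set.seed(config$seed + 1L)
  n <- config$n_patients
  p <- length(config$template)
  sd_m <- sqrt(config$mode_variance_proportions * config$total_shape_variance)
  z <- matrix(rnorm(n * config$n_modes), n, config$n_modes)
  noise <- matrix(rnorm(n * p, sd = config$landmark_noise_sd), n, p)
  shapes <- matrix(rep(config$template, each = n), n, p) +
    z %*% (t(modes) * sd_m) + noise
  ids <- sprintf("hip%03d", seq_len(n))
  rownames(shapes) <- ids

  # femoral-head placement toward a truncated-normal coverage target
  fhc_target <- rtruncnorm1(n, config$fhc_mean, config$fhc_sd, 0, 100)
  head_xy <- vapply(seq_len(n), function(i) {
    xy <- vec_to_xy(shapes[i, ])
    ctr <- invert_fhc(fhc_target[i], config$head_radius,
                      p0 = xy[1, ], p4 = xy[5, ], covered_side_ref = xy[13, ])
    dir <- (xy[5, ] - xy[1, ]) / sqrt(sum((xy[5, ] - xy[1, ])^2))
    c(ctr, ctr + config$head_radius * dir)
  }, numeric(4))
  head_rows <- tibble::tibble(
    hip_id = rep(ids, each = 2),
    point_index = rep(c(HEAD_CENTER_INDEX, HEAD_RIM_INDEX), n),
    x = as.numeric(rbind(head_xy[1, ], head_xy[3, ])),
    y = as.numeric(rbind(head_xy[2, ], head_xy[4, ]))
  )

  sides <- sample(c("left", "right"), n, replace = TRUE, prob = c(0.71, 0.29))
  landmarks <- shapes_to_landmarks(shapes) |>
    dplyr::bind_rows(
      head_rows |> dplyr::mutate(side = NA_character_, rater_id = "r1",
                                 session = 1L)
    ) |>
    dplyr::arrange(.data$hip_id, .data$point_index) |>
    dplyr::mutate(side = sides[match(.data$hip_id, ids)])

  # outcomes through the logistic link on the planted mode scores
  lin <- config$outcome_intercept +
    as.numeric(z %*% config$outcome_coefficients)
  unfavorable <- rbinom(n, 1, plogis(lin)) == 1
  split_probs <- config$component_split / sum(config$component_split)
  component <- rep(NA_character_, n)
  component[unfavorable] <- sample(names(split_probs),
                                   sum(unfavorable), replace = TRUE,
                                   prob = split_probs)
  open_red <- !is.na(component) & component == "open"
  osteotomy <- !is.na(component) & component == "osteotomy"
  residual <- !is.na(component) & component == "residual"
  ai <- numeric(n)
  ai[residual] <- rtruncnorm1(sum(residual), 25, 3, 21.001, 40)
  ai[!unfavorable] <- rtruncnorm1(sum(!unfavorable), 17, 3, 5, 21)
  ai[osteotomy] <- rnorm(sum(osteotomy), 20, 4)
  ai[open_red] <- NA_real_

  records <- tibble::tibble(
    hip_id = ids,
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.84, 0.16)),
    age_at_us = pmax(rnorm(n, 3.4, 1.2), 0.5),
    side = sides,
    graf_type = sample(c("D", "III", "IV"), n, replace = TRUE,
                       prob = c(0.11, 0.60, 0.29)),
    bilateral = runif(n) < 4 / 92,
    closed_reduction = TRUE,
    open_reduction = open_red,
    pelvic_osteotomy = osteotomy,
    acetabular_index_5y = ai,
    avn = runif(n) < 0.1,
    exclusion_flag = "none"
  )

  if (any(config$exclusion_tally > 0)) {
    flags <- rep(EXCLUSION_LEVELS, times = config$exclusion_tally)
    extra <- records[rep(1, length(flags)), ]
    extra$hip_id <- sprintf("exc%03d", seq_along(flags))
    extra$exclusion_flag <- flags
    records <- dplyr::bind_rows(records, extra)
  }

  list(
    landmarks = landmarks,
    records = records,
    truth = list(modes = modes, z = z, mode_sd = sd_m,
                 intercept = config$outcome_intercept,
                 coefficients = config$outcome_coefficients,
                 fhc_target = fhc_target, template = config$template,
                 unfavorable = unfavorable, component = component),
    config = config
  )
}

#' Simulate a re-annotation session
#'
#' Adds independent isotropic Gaussian noise to every landmark coordinate,
#' emulating a second annotation pass by the same or another rater;
#' optionally restricted to a random subset of hips (fraction rounded to the
#' nearest count, e.g. 20% of 92 hips selects 18).
#'
#' @param landmarks Tidy landmark table.
#' @param rater_noise_sd Per-coordinate noise SD in pixels.
#' @param seed Integer seed.
#' @param subset_fraction If non-`NULL`, fraction of hips to re-annotate.
#' @param rater_id,session Labels stamped on the new series.
#' @return A landmark table of the perturbed annotations.
#' @export
reannotate <- function(landmarks, rater_noise_sd, seed,
                       subset_fraction = NULL, rater_id = "r2",
                       session = 2L) {
  stopifnot(rater_noise_sd >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- landmarks
  if (!is.null(subset_fraction)) {
    ids <- unique(out$hip_id)
    keep <- sample(ids, round(subset_fraction * length(ids)))
    out <- out[out$hip_id %in% keep, , drop = FALSE]
  }
  m <- nrow(out)
  out$x <- out$x + rnorm(m, sd = rater_noise_sd)
  out$y <- out$y + rnorm(m, sd = rater_noise_sd)
  out$rater_id <- rater_id
  out$session <- as.integer(session)
  out
}
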
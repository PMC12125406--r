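# Shape vectors are length-26 numeric vectors, the (x, y) coordinates of
# contour points 0-12 interleaved in protocol order. These helpers move
# between the tidy landmark table, the n x 26 shape matrix, and the 13 x 2
# point matrix used by the planar geometry.

vec_to_xy <- function(v) matrix(v, ncol = 2, byrow = TRUE)
xy_to_vec <- function(m) as.numeric(t(m))

#' Convert a tidy landmark table to a shape matrix
#'
#' Extracts the 13 contour points of each hip (femoral-head points are not
#' part of the shape model) into one 26-component row per hip, coordinates
#' interleaved in protocol-point order.
#'
#' @param landmarks Tidy landmark table (see [read_landmarks()]).
#' @return Numeric matrix, one row per hip, `hip_id`s as row names.
#' @export
landmarks_to_shapes <- function(landmarks) {
  contour <- landmarks |>
    dplyr::filter(.data$point_index < N_CONTOUR) |>
    dplyr::arrange(.data$hip_id, .data$point_index)
  counts <- dplyr::count(contour, .data$hip_id)
  if (any(counts$n != N_CONTOUR)) {
    abort("every hip needs exactly 13 contour points")
  }
  ids <- unique(contour$hip_id)
  out <- matrix(NA_real_, nrow = length(ids), ncol = 2L * N_CONTOUR,
                dimnames = list(ids, NULL))
  for (id in ids) {
    g <- contour[contour$hip_id == id, ]
    out[id, ] <- xy_to_vec(cbind(g$x, g$y))
  }
  out
}

#' Convert a shape matrix back to a tidy landmark table
#'
#' @param shapes Numeric matrix of 26-component shape vectors (rows), row
#'   names used as `hip_id`.
#' @return Tidy landmark table with contour points 0-12.
#' @export
shapes_to_landmarks <- function(shapes) {
  ids <- rownames(shapes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(shapes)))
  n <- nrow(shapes)
  ix <- seq(1, 2 * N_CONTOUR, by = 2)
  tibble::tibble(
    hip_id = rep(ids, each = N_CONTOUR),
    side = NA_character_, rater_id = "r1", session = 1L,
    point_index = rep(0:(N_CONTOUR - 1L), n),
    x = as.numeric(t(shapes[, ix, drop = FALSE])),
    y = as.numeric(t(shapes[, ix + 1L, drop = FALSE]))
  )
}

centroid_size <- function(v) {
  xy <- vec_to_xy(v)
  ctr <- colMeans(xy)
  sqrt(sum(sweep(xy, 2, ctr)^2))
}

# similarity-align a single shape vector to a reference under the enabled
# transforms; closed-form planar solution
align_one <- function(v, ref, translate = TRUE, rotate = TRUE, scale = TRUE) {
  xy <- vec_to_xy(v)
  rxy <- vec_to_xy(ref)
  if (translate) {
    xy <- sweep(xy, 2, colMeans(xy))
    rxy <- sweep(rxy, 2, colMeans(rxy))
  }
  if (scale) {
    s <- sqrt(sum(xy^2))
    if (s == 0) abort("degenerate geometry: shape has zero centroid size")
    xy <- xy / s
  }
  if (rotate) {
    # optimal planar rotation of xy onto rxy
    a <- sum(xy * rxy)
    b <- sum(xy[, 2] * rxy[, 1] - xy[, 1] * rxy[, 2])
    theta <- atan2(b, a)
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    xy <- xy %*% rot
  }
  if (translate) {
    # re-place at the reference centroid (zero once the mean is centred)
    xy <- sweep(xy, 2, colMeans(vec_to_xy(ref)), FUN = "+")
  }
  xy_to_vec(xy)
}

# vectorized similarity alignment of every row of S to `ref`; same math as
# align_one, batched over the cohort
align_rows <- function(S, ref, translate = TRUE, rotate = TRUE, scale = TRUE) {
  p <- ncol(S) / 2
  ix <- seq(1, 2 * p, by = 2)
  iy <- ix + 1
  X <- S[, ix, drop = FALSE]
  Y <- S[, iy, drop = FALSE]
  rxy <- vec_to_xy(ref)
  rctr <- colMeans(rxy)
  rx <- rxy[, 1]; ry <- rxy[, 2]
  if (translate) {
    X <- X - rowMeans(X)
    Y <- Y - rowMeans(Y)
    rx <- rx - rctr[1]; ry <- ry - rctr[2]
  }
  if (scale) {
    s <- sqrt(rowSums(X^2) + rowSums(Y^2))
    if (any(s == 0)) abort("degenerate geometry: shape has zero centroid size")
    X <- X / s; Y <- Y / s
  }
  if (rotate) {
    a <- as.numeric(X %*% rx + Y %*% ry)
    b <- as.numeric(Y %*% rx - X %*% ry)
    theta <- atan2(b, a)
    ct <- cos(theta); st <- sin(theta)
    Xn <- X * ct + Y * st
    Y <- -X * st + Y * ct
    X <- Xn
  }
  if (translate) {
    X <- X + rctr[1]; Y <- Y + rctr[2]
  }
  out <- S
  out[, ix] <- X
  out[, iy] <- Y
  out
}

#' Generalized Procrustes alignment of a landmark cohort
#'
#' Iteratively aligns every shape to the running mean under the enabled
#' similarity transforms (default: translation + rotation + scaling), then
#' re-estimates the mean, until the mean moves less than `tol` or `max_iter`
#' iterations are reached. With scaling enabled every shape (and the
#' normalized mean) has unit centroid size, so pixel scale and probe pose
#' drop out before the shape decomposition.
#'
#' @param shapes Numeric matrix of shape vectors (one hip per row), e.g. from
#'   [landmarks_to_shapes()]. At least two shapes.
#' @param translate,rotate,scale Which similarity transforms to remove.
#' @param tol Convergence tolerance on the mean shape (Euclidean move).
#' @param max_iter Iteration cap.
#' @return A list of class `"procrustes_alignment"`: `aligned` (matrix, same
#'   dimensions as the input), `mean` (arithmetic mean of the aligned
#'   shapes), `config` (the transform switches), `iterations`.
#' @export
procrustes_align <- function(shapes, translate = TRUE, rotate = TRUE,
                             scale = TRUE, tol = 1e-10, max_iter = 100L) {
  stopifnot(is.matrix(shapes), nrow(shapes) >= 2)
  sizes <- apply(shapes, 1, centroid_size)
  if (any(sizes == 0)) {
    abort("degenerate geometry: a shape has all points identical")
  }
  config <- list(translate = translate, rotate = rotate, scale = scale)
  mean_shape <- shapes[1, ]
  aligned <- shapes
  iter <- 0L
  repeat {
    iter <- iter + 1L
    aligned <- align_rows(shapes, mean_shape, translate = translate,
                          rotate = rotate, scale = scale)
    new_mean <- colMeans(aligned)
    moved <- sqrt(sum((normalize_mean(new_mean, config) -
                         normalize_mean(mean_shape, config))^2))
    mean_shape <- normalize_mean(new_mean, config)
    if (moved < tol || iter >= max_iter) break
  }
  # final pass so each aligned shape is optimally posed w.r.t. the mean that
  # is actually reported
  aligned <- align_rows(shapes, mean_shape, translate = translate,
                        rotate = rotate, scale = scale)
  if (rotate) {
    # fix the rotation gauge from the data themselves (principal axis of the
    # mean, direction pinned by the point-0 -> point-12 chord), so the
    # result is invariant to a common rigid transform of the inputs
    theta <- canonical_angle(colMeans(aligned))
    aligned <- rotate_rows(aligned, theta)
    mean_shape <- normalize_mean(colMeans(aligned), config)
  }
  tangent_ref <- NULL
  if (scale) {
    # orthogonal projection onto the tangent space at the mean direction:
    # removes the radial curvature of the unit-size constraint, so small
    # planted variation stays linear
    tangent_ref <- normalize_mean(colMeans(aligned), config)
    radial <- as.numeric(aligned %*% tangent_ref)
    aligned <- aligned + (1 - radial) %o% tangent_ref
  }
  config$tangent_ref <- tangent_ref
  structure(
    list(aligned = aligned, mean = colMeans(aligned), config = config,
         iterations = iter),
    class = "procrustes_alignment"
  )
}

# rotation putting the mean's major principal axis on x, with the
# point-0 -> point-12 chord pointing toward positive x
canonical_angle <- function(mean_vec) {
  xy <- vec_to_xy(mean_vec)
  ctr <- sweep(xy, 2, colMeans(xy))
  ev <- eigen(crossprod(ctr), symmetric = TRUE)$vectors[, 1]
  theta <- -atan2(ev[2], ev[1])
  chord <- ctr[nrow(ctr), ] - ctr[1, ]
  if (cos(theta) * chord[1] - sin(theta) * chord[2] < 0) theta <- theta + pi
  theta
}

rotate_rows <- function(S, theta) {
  p <- ncol(S) / 2
  ix <- seq(1, 2 * p, by = 2)
  iy <- ix + 1
  X <- S[, ix, drop = FALSE]
  Y <- S[, iy, drop = FALSE]
  out <- S
  out[, ix] <- X * cos(theta) - Y * sin(theta)
  out[, iy] <- X * sin(theta) + Y * cos(theta)
  out
}

normalize_mean <- function(v, config) {
  if (config$translate) {
    xy <- sweep(vec_to_xy(v), 2, colMeans(vec_to_xy(v)))
    v <- xy_to_vec(xy)
  }
  if (config$scale) v <- v / sqrt(sum(vec_to_xy(v)^2))
  v
}

#' @export
print.procrustes_alignment <- function(x, ...) {
  cat("Generalized Procrustes alignment\n")
  cat(sprintf("  %d shapes, %d landmarks\n", nrow(x$aligned),
              ncol(x$aligned) / 2))
  on <- names(Filter(isTRUE, x$config))
  cat(sprintf("  transforms removed: %s\n", paste(on, collapse = " + ")))
  cat(sprintf("  converged in %d iteration(s)\n", x$iterations))
  invisible(x)
}
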
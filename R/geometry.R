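#' Derive protocol point 0 on the ilium
#'
#' Point 0 sits on the straight iliac line, proximal to point 4 at half the
#' Euclidean distance between points 4 and 12. The half-distance is read as
#' chord distance (not contour arc length): the ilium is straight, so the two
#' coincide there, and chord distance is reproducible from the two points
#' alone.
#'
#' @param p4,p12 Numeric length-2 vectors `c(x, y)`: the start of the
#'   acetabular-roof slope (point 4) and the deepest acetabular point (12).
#' @param ilium_dir Unit vector pointing proximally along the ilium, away
#'   from the acetabulum.
#' @return Numeric length-2 vector: point 0.
#' @examples
#' derive_point0(c(0, 0), c(6, 8), c(0, -1)) # c(0, -5)
#' @export
derive_point0 <- function(p4, p12, ilium_dir) {
  d <- sqrt(sum((p4 - p12)^2))
  if (d == 0) {
    abort("degenerate geometry: points 4 and 12 coincide")
  }
  if (abs(sqrt(sum(ilium_dir^2)) - 1) > 1e-8) {
    abort("ilium_dir must be a unit vector")
  }
  p4 + ilium_dir * d / 2
}

# cumulative arc length along a polyline (matrix of xy rows)
polyline_arclength <- function(v) {
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  if (any(seg == 0)) abort("degenerate geometry: repeated polyline vertices")
  c(0, cumsum(seg))
}

# arc-length position of the point on the polyline closest to p
project_arclength <- function(v, s, p) {
  best <- c(Inf, 0)
  for (i in seq_len(nrow(v) - 1)) {
    a <- v[i, ]; b <- v[i + 1, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    d2 <- sum((p - q)^2)
    if (d2 < best[1]) best <- c(d2, s[i] + t * (s[i + 1] - s[i]))
  }
  best[2]
}

# point at arc-length position t on the polyline
point_at_arclength <- function(v, s, t) {
  i <- findInterval(t, s, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(v) - 1L)
  f <- (t - s[i]) / (s[i + 1] - s[i])
  v[i, ] + f * (v[i + 1, ] - v[i, ])
}

#' Resample a contour with equal arc-length spacing
#'
#' Places `n_interior` points on a digitized contour strictly between two
#' anchor points so that consecutive arc-length gaps
#' (anchor, p1, ..., anchor) are all equal. This implements the protocol's
#' equal spacing of points 1-3 (between 0 and 4) and 5-11 (between 4 and 12)
#' along the acetabular border; "equal spacing" on a curved border is only
#' well defined by arc length, computed here along the polyline with linear
#' interpolation between vertices.
#'
#' @param contour Numeric matrix (rows `x, y`) with at least 2 vertices
#'   tracing the contour.
#' @param anchors 2x2 matrix (rows: start and end point); each anchor is
#'   projected onto the contour.
#' @param n_interior Number of interior points (>= 0).
#' @return An `n_interior` x 2 matrix of points, ordered from the start
#'   anchor toward the end anchor.
#' @examples
#' seg <- rbind(c(0, 0), c(4, 0))
#' resample_equal_spacing(seg, rbind(c(0, 0), c(4, 0)), 3)
#' @export
resample_equal_spacing <- function(contour, anchors, n_interior) {
  stopifnot(is.matrix(contour), ncol(contour) == 2, nrow(contour) >= 2,
            n_interior >= 0)
  s <- polyline_arclength(contour)
  t0 <- project_arclength(contour, s, anchors[1, ])
  t1 <- project_arclength(contour, s, anchors[2, ])
  if (abs(t1 - t0) < 1e-12) {
    abort("degenerate geometry: anchors project to the same arc position")
  }
  if (n_interior == 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  ts <- t0 + (t1 - t0) * seq_len(n_interior) / (n_interior + 1)
  t(vapply(ts, function(t) point_at_arclength(contour, s, t), numeric(2)))
}

# area of the circular segment cut off at distance h (0 <= h <= r) from the
# centre of a circle of radius r
circular_segment_area <- function(h, r) {
  h <- min(h, r)
  r^2 * acos(h / r) - h * sqrt(max(r^2 - h^2, 0))
}

# signed distance from `point` to the infinite line through a, b; positive on
# the side of `ref`
signed_line_distance <- function(point, a, b, ref) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) abort("degenerate geometry: line endpoints coincide")
  nrm <- c(-ab[2], ab[1]) / len
  side_ref <- sum((ref - a) * nrm)
  if (side_ref == 0) {
    abort("degenerate geometry: covered-side reference lies on the line")
  }
  sgn <- sign(side_ref)
  sum((point - a) * nrm) * sgn
}

#' Femoral head coverage from the ilium line
#'
#' The coverage index is the percentage of the femoral-head circle lying on
#' the acetabular ("covered") side of the infinite straight line through
#' protocol points 0 and 4 (the iliac line). The covered side is defined as
#' the side containing `covered_side_ref` (point 12, the deepest acetabular
#' point), which makes the definition independent of image orientation. The
#' covered fraction follows from circular-segment arithmetic: with the centre
#' at distance `h` from the line, the cut-off segment has area
#' \eqn{A(h) = r^2 \arccos(h/r) - h \sqrt{r^2 - h^2}}.
#'
#' @param p0,p4 Numeric length-2 vectors: the points defining the iliac line.
#' @param head_center Circle centre (protocol point 13).
#' @param head_rim A point on the circle rim (protocol point 14); the radius
#'   is the centre-rim distance.
#' @param covered_side_ref A point on the covered (acetabular) side of the
#'   line, conventionally point 12.
#' @return A one-row tibble with `percent` (in [0, 100]) and
#'   `morin_category` (see [morin_category()]).
#' @examples
#' # centre on the line: exactly half covered
#' fhc_percent(c(0, 0), c(0, 10), head_center = c(0, 5),
#'             head_rim = c(2, 5), covered_side_ref = c(5, 5))
#' @export
fhc_percent <- function(p0, p4, head_center, head_rim, covered_side_ref) {
  r <- sqrt(sum((head_rim - head_center)^2))
  if (r == 0) abort("degenerate geometry: zero femoral-head radius")
  d <- signed_line_distance(head_center, p0, p4, covered_side_ref)
  percent <- fhc_from_signed_distance(d, r)
  tibble::tibble(percent = percent, morin_category = morin_category(percent))
}

# coverage percent as a function of the signed centre-to-line distance
# (positive = covered side); continuous and strictly increasing on (-r, r)
fhc_from_signed_distance <- function(d, r) {
  h <- abs(d)
  if (h >= r) {
    return(if (d > 0) 100 else 0)
  }
  seg <- circular_segment_area(h, r)
  full <- pi * r^2
  if (d >= 0) 100 * (full - seg) / full else 100 * seg / full
}

#' Morin coverage categories
#'
#' Categorizes a femoral-head-coverage percentage into the Morin classes:
#' category 0 for coverage above 58%, category 1 for 33-58% (both bounds
#' included), category 2 below 33%. Higher categories mean poorer coverage.
#'
#' @param percent Coverage percentage(s) in [0, 100].
#' @return Integer vector of categories in {0, 1, 2}.
#' @export
morin_category <- function(percent) {
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent > 100)) {
    abort("coverage percent must lie in [0, 100]")
  }
  ifelse(percent > 58, 0L, ifelse(percent >= 33, 1L, 2L))
}

#' Coverage for every annotated hip in a landmark table
#'
#' Applies [fhc_percent()] to each hip that carries femoral-head points
#' (protocol points 13 and 14), using its own points 0, 4 and 12.
#'
#' @param landmarks Tidy landmark table (see [read_landmarks()]).
#' @return Tibble `hip_id`, `fhc_percent`, `morin_category`; hips without
#'   head points are omitted.
#' @export
cohort_fhc <- function(landmarks) {
  landmarks |>
    dplyr::group_by(.data$hip_id) |>
    dplyr::group_modify(function(g, key) {
      if (!all(c(HEAD_CENTER_INDEX, HEAD_RIM_INDEX) %in% g$point_index)) {
        return(tibble::tibble())
      }
      pt <- function(i) {
        row <- g[g$point_index == i, ]
        c(row$x[1], row$y[1])
      }
      res <- fhc_percent(pt(0L), pt(4L), pt(HEAD_CENTER_INDEX),
                         pt(HEAD_RIM_INDEX), covered_side_ref = pt(12L))
      tibble::tibble(fhc_percent = res$percent,
                     morin_category = res$morin_category)
    }) |>
    dplyr::ungroup()
}
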
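# Shared fixtures: tiny in-code cohorts and the Monte-Carlo coverage oracle.

# a minimal tidy landmark table for one or more hips from a shape matrix
tiny_landmarks <- function(shapes) hipshape::shapes_to_landmarks(shapes)

# a small synthetic analysis cohort; wraps the generator with test-sized n
tiny_cohort <- function(n = 40, seed = 42, ...) {
  hipshape::synthetic_cohort(hipshape::synthetic_config(
    n_patients = n, seed = seed, ...
  ))
}

# Monte-Carlo femoral-head-coverage oracle: fraction of the circle on the
# covered side of the line through p0-p4, from jittered-grid uniform samples
# over the bounding square (stratification cuts the variance far below the
# iid-binomial level while each cell still holds one uniform point).
mc_fhc_oracle <- function(p0, p4, center, r, ref, grid = 1000L) {
  g <- seq_len(grid) - 1
  gx <- rep(g, times = grid)
  gy <- rep(g, each = grid)
  n <- grid * grid
  px <- center[1] - r + (gx + stats::runif(n)) / grid * 2 * r
  py <- center[2] - r + (gy + stats::runif(n)) / grid * 2 * r
  inside <- (px - center[1])^2 + (py - center[2])^2 <= r^2
  ab <- p4 - p0
  nx <- -ab[2]; ny <- ab[1]
  side_ref <- sign((ref[1] - p0[1]) * nx + (ref[2] - p0[2]) * ny)
  covered <- ((px - p0[1]) * nx + (py - p0[2]) * ny) * side_ref >= 0
  100 * sum(inside & covered) / sum(inside)
}

# apply a common similarity transform to every row of a shape matrix
transform_shapes <- function(shapes, angle = 0, scale = 1, shift = c(0, 0)) {
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  t(apply(shapes, 1, function(v) {
    xy <- matrix(v, ncol = 2, byrow = TRUE) %*% rot * scale
    xy <- sweep(xy, 2, shift, "+")
    as.numeric(t(xy))
  }))
}
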
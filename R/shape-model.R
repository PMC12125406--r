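#' Fit a point distribution model to aligned shapes
#'
#' Principal-component decomposition of the sample covariance (denominator
#' n - 1) of aligned shape vectors about their mean. Modes are sorted by
#' eigenvalue; each mode vector's sign is pinned so its largest-magnitude
#' component is positive (the eigenvector sign is otherwise arbitrary, and an
#' unpinned sign would flip odds-ratio directions between runs). The number
#' of retained modes is the smallest count whose cumulative variance
#' proportion reaches `retention`.
#'
#' @param alignment A `"procrustes_alignment"` from [procrustes_align()], or
#'   a plain matrix of already-aligned shape vectors.
#' @param retention Fraction of total variance the retained modes must
#'   explain (default 0.95, threshold inclusive).
#' @return An object of class `"shape_model"`: `mean_shape`, `modes`
#'   (orthonormal columns), `eigenvalues`, `variance_proportions`,
#'   `n_retained`, `alignment_config`, `n_shapes`.
#' @seealso [shape_zscores()], [synthesize_shape()], [tidy.shape_model()]
#' @export
fit_ssm <- function(alignment, retention = 0.95) {
  stopifnot(retention > 0, retention <= 1)
  if (inherits(alignment, "procrustes_alignment")) {
    aligned <- alignment$aligned
    config <- alignment$config
  } else {
    aligned <- alignment
    config <- list(translate = TRUE, rotate = TRUE, scale = TRUE)
  }
  stopifnot(is.matrix(aligned), nrow(aligned) >= 2)
  pca <- prcomp(aligned, center = TRUE, scale. = FALSE)
  eig <- pca$sdev^2
  total <- sum(eig)
  if (total <= 0) abort("degenerate data: zero total shape variance")
  nonzero <- eig > total * 1e-12
  eig <- eig[nonzero]
  modes <- pca$rotation[, nonzero, drop = FALSE]
  # pin each mode's sign: largest-|component| positive
  for (j in seq_len(ncol(modes))) {
    k <- which.max(abs(modes[, j]))
    if (modes[k, j] < 0) modes[, j] <- -modes[, j]
  }
  props <- eig / sum(eig)
  n_retained <- which(cumsum(props) >= retention)[1]
  structure(
    list(
      mean_shape = as.numeric(pca$center),
      modes = unname(modes),
      eigenvalues = unname(eig),
      variance_proportions = unname(props),
      n_retained = as.integer(n_retained),
      retention = retention,
      alignment_config = config,
      n_shapes = nrow(aligned)
    ),
    class = "shape_model"
  )
}

#' @export
print.shape_model <- function(x, ...) {
  cat("Acetabular statistical shape model\n")
  cat(sprintf("  %d training shapes, %d landmarks\n", x$n_shapes,
              length(x$mean_shape) / 2))
  cat(sprintf("  %d mode(s) retained at the %.0f%% variance rule\n",
              x$n_retained, 100 * x$retention))
  p <- x$variance_proportions[seq_len(x$n_retained)]
  cat(sprintf("  retained variance shares: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * p), collapse = ", "),
              100 * sum(p)))
  invisible(x)
}

#' Per-mode summary of a shape model
#'
#' @param x A `"shape_model"`.
#' @param ... Unused.
#' @return A tibble with one row per nonzero mode: `mode`, `eigenvalue`,
#'   `variance_proportion`, `cumulative_proportion`, `retained`.
#' @method tidy shape_model
#' @export
tidy.shape_model <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_proportion = x$variance_proportions,
    cumulative_proportion = cumsum(x$variance_proportions),
    retained = seq_along(x$eigenvalues) <= x$n_retained
  )
}

#' One-row summary of a shape model
#'
#' @param x A `"shape_model"`.
#' @param ... Unused.
#' @return A one-row tibble: `n_shapes`, `n_landmarks`, `n_modes`,
#'   `n_retained`, `retained_variance`, `total_variance`.
#' @method glance shape_model
#' @export
glance.shape_model <- function(x, ...) {
  tibble::tibble(
    n_shapes = x$n_shapes,
    n_landmarks = length(x$mean_shape) / 2,
    n_modes = length(x$eigenvalues),
    n_retained = x$n_retained,
    retained_variance = sum(x$variance_proportions[seq_len(x$n_retained)]),
    total_variance = sum(x$eigenvalues)
  )
}

#' Mode Z-scores of shapes under a shape model
#'
#' Each query shape is first similarity-aligned to the model's mean shape
#' with the same transform family used in training (so scores from repeat
#' annotations live in one frame), then projected onto each retained mode;
#' the projection is divided by the mode's standard deviation
#' \eqn{\sqrt{\lambda_m}}. A Z-score of +1 on mode m therefore means the
#' shape sits one training-cohort standard deviation from the mean along
#' that mode.
#'
#' @param model A `"shape_model"`.
#' @param shapes Matrix of shape vectors (rows), a single shape vector, or a
#'   tidy landmark table.
#' @param align Re-align each query to the mean shape first (default TRUE;
#'   set FALSE only for shapes already expressed in the model frame).
#' @return A tibble in long format: `hip_id`, `mode`, `z`.
#' @export
shape_zscores <- function(model, shapes, align = TRUE) {
  stopifnot(inherits(model, "shape_model"))
  if (is.data.frame(shapes)) shapes <- landmarks_to_shapes(shapes)
  if (is.null(dim(shapes))) shapes <- matrix(shapes, nrow = 1)
  lam <- model$eigenvalues[seq_len(model$n_retained)]
  if (any(lam <= 0)) abort("degenerate model: retained mode with zero variance")
  cfg <- model$alignment_config
  ids <- rownames(shapes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(shapes)))
  purrr::map_dfr(seq_len(nrow(shapes)), function(i) {
    v <- shapes[i, ]
    if (align) {
      v <- align_one(v, model$mean_shape, translate = cfg$translate,
                     rotate = cfg$rotate, scale = cfg$scale)
      if (!is.null(cfg$tangent_ref)) {
        # same tangent-space projection the training alignment applied
        v <- v + (1 - sum(v * cfg$tangent_ref)) * cfg$tangent_ref
      }
    }
    proj <- as.numeric(crossprod(
      model$modes[, seq_len(model$n_retained), drop = FALSE],
      v - model$mean_shape
    ))
    tibble::tibble(hip_id = ids[i], mode = seq_len(model$n_retained),
                   z = proj / sqrt(lam))
  })
}

#' Synthesize a shape at a chosen mode deviation
#'
#' Returns `mean_shape + z * sqrt(eigenvalue[mode]) * mode_vector`: the shape
#' lying `z` standard deviations from the mean along a single mode, as used
#' to visualize what each mode encodes (e.g. at -2.5, 0 and +2.5 SD).
#'
#' @param model A `"shape_model"`.
#' @param mode Retained-mode index (1-based).
#' @param z Deviation in mode standard deviations.
#' @return A 26-component shape vector.
#' @export
synthesize_shape <- function(model, mode, z) {
  stopifnot(inherits(model, "shape_model"))
  if (mode < 1 || mode > model$n_retained) {
    abort(sprintf("mode %d outside the retained range 1..%d",
                  mode, model$n_retained))
  }
  model$mean_shape + z * sqrt(model$eigenvalues[mode]) * model$modes[, mode]
}

#' Synthesized mode shapes as a tidy table
#'
#' Evaluates [synthesize_shape()] on a grid of modes and deviations,
#' returning the landmark coordinates in long format, ready for plotting or
#' export.
#'
#' @param model A `"shape_model"`.
#' @param modes Mode indices (default: all retained).
#' @param z_values Deviations in SD units (default -2.5, 0, +2.5).
#' @return Tibble `mode`, `z`, `point_index`, `x`, `y`.
#' @export
synthesize_mode_table <- function(model, modes = seq_len(model$n_retained),
                                  z_values = c(-2.5, 0, 2.5)) {
  grid <- tidyr::expand_grid(mode = modes, z = z_values)
  purrr::pmap_dfr(grid, function(mode, z) {
    xy <- vec_to_xy(synthesize_shape(model, mode, z))
    tibble::tibble(mode = mode, z = z, point_index = 0:(nrow(xy) - 1L),
                   x = xy[, 1], y = xy[, 2])
  })
}

#' Plot a shape model
#'
#' `type = "scree"` draws the per-mode variance proportions with the
#' cumulative curve and the retention threshold; `type = "modes"` draws each
#' retained mode's synthesized contours at chosen deviations (y axis
#' reversed, matching the image convention of y growing downward).
#'
#' @param object A `"shape_model"`.
#' @param type `"scree"` or `"modes"`.
#' @param z_values Deviations used for `type = "modes"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_model
#' @export
autoplot.shape_model <- function(object, type = c("scree", "modes"),
                                 z_values = c(-2.5, 0, 2.5), ...) {
  type <- match.arg(type)
  if (type == "scree") {
    td <- tidy(object)
    ggplot2::ggplot(td, ggplot2::aes(x = .data$mode)) +
      ggplot2::geom_col(ggplot2::aes(y = .data$variance_proportion,
                                     fill = .data$retained)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_proportion)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_proportion)) +
      ggplot2::geom_hline(yintercept = object$retention, linetype = 2) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "grey70")) +
      ggplot2::labs(x = "shape mode", y = "variance proportion",
                    fill = "retained") +
      ggplot2::theme_minimal()
  } else {
    tab <- synthesize_mode_table(object, z_values = z_values)
    ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$y,
                                      group = factor(.data$z),
                                      colour = factor(.data$z))) +
      ggplot2::geom_path() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_y_reverse() +
      ggplot2::facet_wrap(~mode, labeller = ggplot2::label_both) +
      ggplot2::coord_fixed() +
      ggplot2::labs(colour = "SD", x = NULL, y = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Serialize a shape model to plain-text files
#'
#' Writes `mean.csv` (point index, x, y), `modes.csv` (component by mode),
#' `eigenvalues.csv`, and `model.yaml` (alignment switches, retention,
#' retained-mode count) under `dir`. [read_shape_model()] restores the
#' model.
#'
#' @param model A `"shape_model"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_shape_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xy <- vec_to_xy(model$mean_shape)
  readr::write_csv(
    tibble::tibble(point_index = 0:(nrow(xy) - 1L), x = xy[, 1], y = xy[, 2]),
    file.path(dir, "mean.csv"), progress = FALSE
  )
  modes_df <- as.data.frame(model$modes)
  names(modes_df) <- paste0("mode", seq_len(ncol(modes_df)))
  readr::write_csv(tibble::as_tibble(modes_df), file.path(dir, "modes.csv"),
                   progress = FALSE)
  readr::write_csv(
    tibble::tibble(mode = seq_along(model$eigenvalues),
                   eigenvalue = model$eigenvalues,
                   variance_proportion = model$variance_proportions),
    file.path(dir, "eigenvalues.csv"), progress = FALSE
  )
  cfg <- model$alignment_config
  if (!is.null(cfg$tangent_ref)) {
    readr::write_csv(tibble::tibble(tangent_ref = cfg$tangent_ref),
                     file.path(dir, "tangent.csv"), progress = FALSE)
    cfg$tangent_ref <- NULL
  }
  yaml::write_yaml(
    list(alignment = cfg, retention = model$retention,
         n_retained = model$n_retained, n_shapes = model$n_shapes),
    file.path(dir, "model.yaml")
  )
  invisible(dir)
}

#' Read a serialized shape model
#'
#' @param dir Directory written by [write_shape_model()].
#' @return A `"shape_model"`.
#' @export
read_shape_model <- function(dir) {
  mean_df <- readr::read_csv(file.path(dir, "mean.csv"),
                             show_col_types = FALSE, progress = FALSE)
  modes <- as.matrix(readr::read_csv(file.path(dir, "modes.csv"),
                                     show_col_types = FALSE, progress = FALSE))
  eig <- readr::read_csv(file.path(dir, "eigenvalues.csv"),
                         show_col_types = FALSE, progress = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  tangent_path <- file.path(dir, "tangent.csv")
  if (file.exists(tangent_path)) {
    meta$alignment$tangent_ref <- readr::read_csv(
      tangent_path, show_col_types = FALSE, progress = FALSE
    )$tangent_ref
  }
  structure(
    list(
      mean_shape = xy_to_vec(cbind(mean_df$x, mean_df$y)),
      modes = unname(modes),
      eigenvalues = eig$eigenvalue,
      variance_proportions = eig$variance_proportion,
      n_retained = as.integer(meta$n_retained),
      retention = meta$retention,
      alignment_config = meta$alignment,
      n_shapes = meta$n_shapes
    ),
    class = "shape_model"
  )
}
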
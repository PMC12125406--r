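#' Two-way absolute-agreement ICC (single measures)
#'
#' Intraclass correlation for a complete two-way layout of `n` subjects
#' (images) by `k` measurement sessions, under the two-way model with
#' absolute agreement, single measures — the coefficient that penalizes both
#' random disagreement and a systematic offset between sessions:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the rows (subjects), columns
#' (sessions) and residual mean squares of the two-way ANOVA decomposition.
#'
#' @param measurements Numeric `n x k` matrix, no missing cells, `n >= 2`,
#'   `k >= 2`.
#' @return The ICC (scalar, at most 1).
#' @examples
#' m <- cbind(1:6, 1:6 + 0.1)          # constant offset: ICC < 1
#' icc_absolute_agreement(m)
#' icc_absolute_agreement(cbind(1:6, 1:6)) # identical sessions: exactly 1
#' @export
icc_absolute_agreement <- function(measurements) {
  m <- as.matrix(measurements)
  if (any(is.na(m))) abort("missing cells are not supported")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("need at least 2 subjects and 2 sessions")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ms_rows <- k * sum((row_means - grand)^2) / (n - 1)
  ms_cols <- n * sum((col_means - grand)^2) / (k - 1)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - k * sum((row_means - grand)^2) -
    n * sum((col_means - grand)^2)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err)
  if (denom == 0) return(1)
  (ms_rows - ms_err) / denom
}

#' Variance-weighted overall ICC
#'
#' Weighted mean of per-mode ICCs, each mode weighted by its share of the
#' total shape variation (weights renormalized to sum to 1), yielding one
#' overall reliability coefficient for the whole shape model.
#'
#' @param per_mode Numeric vector of per-mode ICCs.
#' @param weights Positive weights, typically the retained modes' variance
#'   proportions.
#' @return The weighted mean ICC (scalar).
#' @export
overall_weighted_icc <- function(per_mode, weights) {
  stopifnot(length(per_mode) == length(weights), all(weights > 0))
  sum(weights * per_mode) / sum(weights)
}

#' Reliability study over repeat annotations
#'
#' Computes per-mode and overall reliability from repeated annotation series
#' of the same images. All series are projected onto one shape model (built
#' from the primary annotations — refitting per rater would change the modes
#' being compared), their mode Z-scores stacked as the `k` columns of one
#' two-way table per mode, and a single combined inter/intra-observer ICC is
#' reported per mode plus the variance-weighted overall coefficient.
#'
#' @param model The `"shape_model"` fitted to the primary annotations.
#' @param sessions A list of tidy landmark tables, one per annotation series
#'   (e.g. rater 1 session 1, rater 1 session 2, rater 2), covering the same
#'   `hip_id`s.
#' @return An object of class `"icc_reliability"`: `per_mode` tibble
#'   (`mode`, `icc`, `weight`), `overall`, `n_images`, `k_sessions`.
#' @export
reliability_study <- function(model, sessions) {
  stopifnot(inherits(model, "shape_model"), length(sessions) >= 2)
  z_tabs <- purrr::imap(sessions, function(lm_tbl, i) {
    shape_zscores(model, lm_tbl) |>
      dplyr::mutate(session = i)
  })
  ids <- Reduce(intersect, purrr::map(z_tabs, ~ unique(.x$hip_id)))
  if (length(ids) < 2) abort("need at least 2 images common to all sessions")
  long <- dplyr::bind_rows(z_tabs) |> dplyr::filter(.data$hip_id %in% ids)
  per_mode <- long |>
    dplyr::group_by(.data$mode) |>
    dplyr::group_modify(function(g, key) {
      wide <- tidyr::pivot_wider(g, id_cols = "hip_id",
                                 names_from = "session", values_from = "z")
      tibble::tibble(icc = icc_absolute_agreement(as.matrix(wide[, -1])))
    }) |>
    dplyr::ungroup()
  w <- model$variance_proportions[seq_len(model$n_retained)]
  w <- w / sum(w)
  per_mode$weight <- w[per_mode$mode]
  structure(
    list(per_mode = per_mode,
         overall = overall_weighted_icc(per_mode$icc, per_mode$weight),
         n_images = length(ids), k_sessions = length(sessions)),
    class = "icc_reliability"
  )
}

#' @export
print.icc_reliability <- function(x, ...) {
  cat(sprintf("Annotation reliability: %d images x %d sessions\n",
              x$n_images, x$k_sessions))
  for (i in seq_len(nrow(x$per_mode))) {
    cat(sprintf("  mode %d: ICC = %.3f (weight %.2f)\n",
                x$per_mode$mode[i], x$per_mode$icc[i], x$per_mode$weight[i]))
  }
  cat(sprintf("  overall (variance-weighted): %.3f\n", x$overall))
  invisible(x)
}

#' @method tidy icc_reliability
#' @export
tidy.icc_reliability <- function(x, ...) x$per_mode

#' @method glance icc_reliability
#' @export
glance.icc_reliability <- function(x, ...) {
  tibble::tibble(overall_icc = x$overall, n_images = x$n_images,
                 k_sessions = x$k_sessions)
}
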
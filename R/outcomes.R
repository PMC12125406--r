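#' Derive the four adverse outcomes from treatment history
#'
#' Outcome definitions (the initial closed reduction itself is never an
#' adverse outcome):
#' * `o1_open_reduction` — open reduction after failed closed reduction;
#' * `o2_surgery` — open reduction or pelvic osteotomy within 5 years;
#' * `o3_osteotomy_or_residual` — pelvic osteotomy or residual dysplasia at
#'   age 5, defined only for hips without open reduction (`NA` otherwise);
#' * `o4_unfavorable` — open reduction, pelvic osteotomy or residual
#'   dysplasia (the composite "unfavorable outcome").
#'
#' Residual dysplasia means an acetabular index strictly greater than
#' `ai_threshold` degrees on the age-5 radiograph. The index must be present
#' for hips with no surgical treatment; for surgical hips the surgery alone
#' already settles every outcome in which they participate.
#'
#' @param records Patient-record tibble (columns `hip_id`,
#'   `closed_reduction`, `open_reduction`, `pelvic_osteotomy`,
#'   `acetabular_index_5y`).
#' @param ai_threshold Residual-dysplasia threshold in degrees (default 21;
#'   an index of exactly 21 is not residual dysplasia).
#' @return Tibble `hip_id`, `o1_open_reduction`, `o2_surgery`,
#'   `o3_osteotomy_or_residual` (logical, `NA` where not applicable),
#'   `o4_unfavorable`.
#' @export
derive_outcomes <- function(records, ai_threshold = 21) {
  needed <- c("hip_id", "open_reduction", "pelvic_osteotomy",
              "acetabular_index_5y")
  stopifnot(all(needed %in% names(records)))
  no_surgery <- !records$open_reduction & !records$pelvic_osteotomy
  if (any(no_surgery & is.na(records$acetabular_index_5y))) {
    abort(paste0(
      "acetabular index missing for non-surgical hip(s): ",
      paste(records$hip_id[no_surgery & is.na(records$acetabular_index_5y)],
            collapse = ", ")
    ))
  }
  residual <- !is.na(records$acetabular_index_5y) &
    records$acetabular_index_5y > ai_threshold
  o1 <- records$open_reduction
  o2 <- o1 | records$pelvic_osteotomy
  o3 <- ifelse(o1, NA, records$pelvic_osteotomy | residual)
  o4 <- o2 | residual
  tibble::tibble(
    hip_id = records$hip_id,
    o1_open_reduction = o1,
    o2_surgery = o2,
    o3_osteotomy_or_residual = o3,
    o4_unfavorable = o4
  )
}

#' Quintile categorization of Z-scores
#'
#' Ranks the values ascending (ties broken by stable input order) and cuts
#' the ranking into five groups at cumulative boundaries `round(k * n / 5)`
#' for k = 1..4, using banker's rounding (round half to even). For n = 92
#' this yields group sizes 18, 19, 18, 19, 18. Labels run 0 (lowest fifth)
#' to 4 (highest); the reported cutpoints are the largest value in each of
#' the first four groups.
#'
#' @param values Numeric vector, length >= 5.
#' @return A list: `labels` (integer vector in 0..4, input order),
#'   `cutpoints` (numeric length 4), `sizes` (integer length 5).
#' @export
quintile_assign <- function(values) {
  n <- length(values)
  if (n < 5) abort("need at least 5 values to form quintiles")
  if (any(!is.finite(values))) abort("values must be finite")
  ord <- order(values)            # stable in R: ties keep input order
  bounds <- round(1:4 * n / 5)    # round() is round-half-even
  labels_sorted <- findInterval(seq_len(n), bounds + 1L) + 0L
  labels <- integer(n)
  labels[ord] <- labels_sorted
  sizes <- as.integer(tabulate(labels + 1L, nbins = 5L))
  cutpoints <- values[ord][bounds]
  list(labels = labels, cutpoints = cutpoints, sizes = sizes)
}

#' Per-mode quintile table for a Z-score table
#'
#' Applies [quintile_assign()] within each mode of a long Z-score table.
#'
#' @param zscores Tibble `hip_id`, `mode`, `z` (from [shape_zscores()]).
#' @return The input with a `quintile` column (0-4) added.
#' @export
zscore_quintiles <- function(zscores) {
  zscores |>
    dplyr::group_by(.data$mode) |>
    dplyr::mutate(quintile = quintile_assign(.data$z)$labels) |>
    dplyr::ungroup()
}
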
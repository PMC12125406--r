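#' Read landmark annotation files
#'
#' Reads per-hip landmark annotations in either of two plain-text dialects
#' and returns them as a tidy table, one row per landmark. Coordinates follow
#' the image convention: origin top-left, `x` increasing rightward, `y`
#' increasing downward, units pixels.
#'
#' Each hip must carry either 13 points (the ilium-acetabulum contour,
#' protocol indices 0-12) or 15 points (contour plus femoral-head centre and
#' rim, indices 13 and 14). Any other count is a format error.
#'
#' Dialects:
#' * `"csv"`: columns `hip_id, point_index, x, y`, optionally `side`,
#'   `rater_id`, `session`; one row per point.
#' * `"pts"`: the plain point-list format — a line `n_points: <k>` followed by
#'   `k` lines of `x y`, one block per file; `hip_id` is the file name stem.
#'
#' @param path File path (csv dialect) or path/vector of paths (pts dialect).
#' @param dialect `"csv"` or `"pts"`.
#' @return A tibble with columns `hip_id`, `side`, `rater_id`, `session`,
#'   `point_index` (0-based protocol index), `x`, `y`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_landmarks(synthetic_cohort(n_patients = 3, seed = 1)$landmarks, tf)
#' read_landmarks(tf)
#' @export
read_landmarks <- function(path, dialect = c("csv", "pts")) {
  dialect <- match.arg(dialect)
  tbl <- switch(dialect,
    csv = read_landmarks_csv(path),
    pts = read_landmarks_pts(path)
  )
  validate_landmarks(tbl)
  tbl
}

read_landmarks_csv <- function(path) {
  stopifnot(file.exists(path))
  # base read.csv: its strtod parse is correctly rounded, so write/read
  # round-trips coordinates bit-exactly
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("hip_id", "point_index", "x", "y")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("landmark csv lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"side" %in% names(tbl)) tbl$side <- NA_character_
  if (!"rater_id" %in% names(tbl)) tbl$rater_id <- "r1"
  if (!"session" %in% names(tbl)) tbl$session <- 1L
  dplyr::select(
    tbl, "hip_id", "side", "rater_id", "session", "point_index", "x", "y"
  ) |>
    dplyr::mutate(
      hip_id = as.character(.data$hip_id),
      point_index = as.integer(.data$point_index),
      session = as.integer(.data$session)
    )
}

read_landmarks_pts <- function(paths) {
  stopifnot(all(file.exists(paths)))
  purrr::map_dfr(paths, function(p) {
    lines <- trimws(readLines(p))
    lines <- lines[nzchar(lines)]
    header <- grepl("^n_points\\s*:", lines[1])
    if (!header) {
      abort(paste0("pts file ", p, " lacks an 'n_points:' header"))
    }
    n <- as.integer(sub("^n_points\\s*:\\s*", "", lines[1]))
    body <- lines[-1]
    # tolerate the bracketed block some point-list writers emit
    body <- body[!body %in% c("{", "}")]
    if (length(body) != n) {
      abort(paste0("pts file ", p, ": header says ", n, " points, found ",
                   length(body)))
    }
    xy <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
    tibble::tibble(
      hip_id = tools::file_path_sans_ext(basename(p)),
      side = NA_character_, rater_id = "r1", session = 1L,
      point_index = seq_len(n) - 1L,
      x = xy[, 1], y = xy[, 2]
    )
  })
}

validate_landmarks <- function(tbl) {
  if (any(!is.finite(tbl$x)) || any(!is.finite(tbl$y))) {
    abort("landmark coordinates must be finite")
  }
  counts <- dplyr::count(tbl, .data$hip_id, .data$rater_id, .data$session)
  bad <- counts$n != 13L & counts$n != 15L
  if (any(bad)) {
    abort(paste0(
      "hip(s) with a point count that is neither 13 nor 15: ",
      paste(unique(counts$hip_id[bad]), collapse = ", ")
    ))
  }
  full <- dplyr::filter(counts, .data$n == 15L)
  if (nrow(full) > 0) {
    heads <- dplyr::semi_join(
      tbl, full, by = c("hip_id", "rater_id", "session")
    ) |>
      dplyr::filter(.data$point_index >= HEAD_CENTER_INDEX) |>
      tidyr::pivot_wider(
        id_cols = c("hip_id", "rater_id", "session"),
        names_from = "point_index", values_from = c("x", "y")
      )
    same <- heads$x_13 == heads$x_14 & heads$y_13 == heads$y_14
    if (any(same)) {
      abort(paste0("femoral-head centre and rim coincide (zero radius) for: ",
                   paste(heads$hip_id[same], collapse = ", ")))
    }
  }
  invisible(tbl)
}

#' Write landmark annotations
#'
#' Inverse of [read_landmarks()]. The csv dialect round-trips coordinates
#' bit-exactly (full double precision).
#'
#' @param landmarks Tidy landmark table as returned by [read_landmarks()].
#' @param path Output file (csv dialect) or directory (pts dialect, one
#'   `<hip_id>.pts` file per hip).
#' @param dialect `"csv"` or `"pts"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, dialect = c("csv", "pts")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    out <- landmarks
    # full precision so read(write(x)) is bit-exact
    out$x <- sprintf("%.17g", out$x)
    out$y <- sprintf("%.17g", out$y)
    readr::write_csv(out, path, progress = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    landmarks |>
      dplyr::group_by(.data$hip_id) |>
      dplyr::group_walk(function(g, key) {
        g <- dplyr::arrange(g, .data$point_index)
        writeLines(
          c(sprintf("n_points: %d", nrow(g)),
            sprintf("%.17g %.17g", g$x, g$y)),
          file.path(path, paste0(key$hip_id, ".pts"))
        )
      })
  }
  invisible(path)
}

#' Read a cohort metadata table
#'
#' Reads the per-patient clinical record: sex, age at ultrasound, Graf type,
#' laterality, treatment history (closed/open reduction, pelvic osteotomy),
#' the acetabular index at the age-5 radiograph, avascular-necrosis status
#' and the exclusion flag used by [apply_inclusion_flow()].
#'
#' @param path CSV file with one row per hip.
#' @return A tibble of patient records.
#' @export
read_cohort <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("hip_id", "sex", "graf_type", "closed_reduction",
                "open_reduction", "pelvic_osteotomy", "acetabular_index_5y",
                "exclusion_flag")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("cohort csv lacks column(s): ", paste(missing, collapse = ", ")))
  }
  tbl |> dplyr::mutate(hip_id = as.character(.data$hip_id))
}

# flowchart order of exclusion reasons
EXCLUSION_LEVELS <- c("missing_baseline_us", "reclassified_stable",
                      "genetic_comorbidity", "lost_to_followup")

#' Apply the study inclusion/exclusion flow
#'
#' Splits retrieved records into the analysis set (exclusion flag `"none"`)
#' and a per-reason exclusion tally in flowchart order: missing/not-assessable
#' baseline ultrasound, hips reclassified as stable on re-evaluation, genetic
#' comorbidity, lost to follow-up.
#'
#' @param records Patient-record tibble with an `exclusion_flag` column.
#' @return A list with elements `included` (tibble of retained records) and
#'   `tally` (tibble `reason`, `n`, one row per exclusion reason plus a final
#'   `included` row). `n` always satisfies
#'   `sum(tally$n) == nrow(records)`.
#' @examples
#' rec <- tibble::tibble(
#'   hip_id = as.character(1:5),
#'   exclusion_flag = c("none", "none", "lost_to_followup", "none", "none")
#' )
#' apply_inclusion_flow(rec)$tally
#' @export
apply_inclusion_flow <- function(records) {
  flag <- records$exclusion_flag
  unknown <- setdiff(unique(flag), c("none", EXCLUSION_LEVELS))
  if (length(unknown) > 0) {
    abort(paste0("unknown exclusion flag(s): ", paste(unknown, collapse = ", ")))
  }
  tally <- tibble::tibble(
    reason = c(EXCLUSION_LEVELS, "included"),
    n = c(
      unname(vapply(EXCLUSION_LEVELS, function(l) sum(flag == l), integer(1))),
      sum(flag == "none")
    )
  )
  list(
    included = records[flag == "none", , drop = FALSE],
    tally = tally
  )
}

#' Select one hip per patient in bilateral cases
#'
#' Patients contributing both hips keep the one with the better image-quality
#' score; exact quality ties are broken by a seeded uniform draw. The
#' tie-break RNG stream is derived from `(seed, patient_id)`, so the choice
#' for one patient does not depend on cohort order or on other patients.
#'
#' @param hips Tibble with one row per hip: `patient_id`, `hip_id`, and a
#'   numeric `quality` score (higher is better).
#' @param seed Integer seed governing tie-breaks.
#' @return The input rows reduced to one per patient.
#' @export
select_bilateral_side <- function(hips, seed = 1L) {
  stopifnot(all(c("patient_id", "hip_id", "quality") %in% names(hips)))
  counts <- table(hips$patient_id)
  if (any(counts > 2)) {
    abort("each patient may contribute at most two hips")
  }
  hips |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) == 1L) return(g)
      g <- g[order(g$hip_id), , drop = FALSE]  # order-independent tie-break
      if (g$quality[1] != g$quality[2]) {
        return(g[which.max(g$quality), , drop = FALSE])
      }
      pick <- withr_seed_draw(hash32(as.character(key$patient_id), seed), nrow(g))
      g[pick, , drop = FALSE]
    }) |>
    dplyr::ungroup()
}

# draw one index in 1..n under a local RNG state, leaving the global
# stream untouched
withr_seed_draw <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(n, 1L)
}
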
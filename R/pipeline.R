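#' End-to-end acetabular shape analysis
#'
#' Runs the full pipeline on either a synthetic cohort or on-disk inputs:
#' inclusion/exclusion flow, femoral-head coverage, generalized Procrustes
#' alignment, shape-model fit with variance retention, per-hip mode
#' Z-scores, outcome derivation, the univariable / multivariable /
#' quintile-categorized association suite and (optionally) a three-session
#' reliability study, then writes every result table as CSV together with a
#' YAML manifest (configuration, seed, stage list, output checksums).
#'
#' Output files under `out_dir`: `inclusion_tally.csv`,
#' `cohort_characteristics.csv`, `fhc.csv`, `variance_proportions.csv`,
#' `zscores.csv`, `quintile_cutpoints.csv`, `outcomes.csv`,
#' `outcome_flow.csv`, `associations.csv`, `icc.csv` (when reliability is
#' run), `synthesized_modes.csv` (each retained mode at -2.5/0/+2.5 SD),
#' and `manifest.yaml`.
#'
#' @param landmarks Tidy landmark table, or `NULL` to generate one.
#' @param records Patient-record tibble, or `NULL` to generate one.
#' @param synthetic A `"synthetic_config"` used when `landmarks`/`records`
#'   are `NULL` (default: [synthetic_config()] with `seed`).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Integer seed for the synthetic cohort and reliability
#'   re-annotations.
#' @param retention Variance-retention fraction for the shape model.
#' @param ai_threshold Residual-dysplasia acetabular-index threshold
#'   (degrees).
#' @param translate,rotate,scale Procrustes transform switches.
#' @param reliability Run the reliability stage (two re-annotation series on
#'   a 20% subset)?
#' @param reliability_fraction Fraction of hips re-annotated.
#' @param verbose Log stage progress to stderr.
#' @return A list of class `"hipshape_run"` with every intermediate result:
#'   `tally`, `characteristics`, `fhc`, `alignment`, `model`, `zscores`,
#'   `quintiles`, `outcomes`, `outcome_flow`, `associations`,
#'   `reliability`, `synthesized`, `manifest`.
#' @export
run_pipeline <- function(landmarks = NULL, records = NULL, synthetic = NULL,
                         out_dir = NULL, seed = 1L, retention = 0.95,
                         ai_threshold = 21, translate = TRUE, rotate = TRUE,
                         scale = TRUE, reliability = TRUE,
                         reliability_fraction = 0.2, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(retention > 0, retention <= 1, ai_threshold > 0)

  if (is.null(landmarks) || is.null(records)) {
    if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
    say("stage simulate: n = %d, seed = %d", synthetic$n_patients,
        synthetic$seed)
    cohort <- synthetic_cohort(synthetic)
    landmarks <- cohort$landmarks
    records <- cohort$records
    rater_sd <- synthetic$rater_noise_sd
  } else {
    rater_sd <- NULL
  }

  say("stage inclusion: %d records retrieved", nrow(records))
  flow <- apply_inclusion_flow(records)
  included <- flow$included
  landmarks <- landmarks[landmarks$hip_id %in% included$hip_id, , drop = FALSE]

  say("stage fhc")
  fhc <- cohort_fhc(landmarks)

  say("stage alignment: %d shapes", length(unique(landmarks$hip_id)))
  shapes <- landmarks_to_shapes(landmarks)
  alignment <- procrustes_align(shapes, translate = translate,
                                rotate = rotate, scale = scale)

  say("stage shape model")
  model <- fit_ssm(alignment, retention = retention)
  zs <- shape_zscores(model, shapes)
  quint <- zscore_quintiles(zs)
  cutpoints <- zs |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(
      cutpoints = list(quintile_assign(.data$z)$cutpoints),
      sizes = list(quintile_assign(.data$z)$sizes),
      .groups = "drop"
    )

  say("stage outcomes")
  outcomes <- derive_outcomes(included, ai_threshold = ai_threshold)
  outcome_flow <- outcome_flow_table(outcomes)

  say("stage associations")
  assoc <- run_association_suite(zs, fhc, outcomes)

  rel <- NULL
  if (reliability) {
    say("stage reliability")
    sub_ids <- reannotate(landmarks, 0, seed = seed + 101L,
                          subset_fraction = reliability_fraction)$hip_id
    sub <- landmarks[landmarks$hip_id %in% unique(sub_ids), , drop = FALSE]
    sdr <- if (is.null(rater_sd)) 1.5 else rater_sd
    sessions <- list(
      sub,
      reannotate(sub, sdr, seed = seed + 102L, rater_id = "r1", session = 2L),
      reannotate(sub, sdr, seed = seed + 103L, rater_id = "r2", session = 1L)
    )
    rel <- reliability_study(model, sessions)
  }

  synth <- synthesize_mode_table(model)
  chars <- cohort_characteristics(included, fhc)

  result <- structure(
    list(tally = flow$tally, characteristics = chars, fhc = fhc,
         alignment = alignment, model = model, zscores = zs,
         quintiles = quint, cutpoints = cutpoints, outcomes = outcomes,
         outcome_flow = outcome_flow, associations = assoc,
         reliability = rel, synthesized = synth, seed = seed),
    class = "hipshape_run"
  )

  if (!is.null(out_dir)) {
    write_run_bundle(result, out_dir, verbose = verbose)
  }
  result
}

# report percentages rounded half away from zero, the convention of
# clinical tables (12/92 -> 13%)
percent_of <- function(count, total) {
  p <- 100 * count / total
  unname(floor(p + 0.5))
}

#' Outcome-component flow table
#'
#' Counts the mutually exclusive components of the composite unfavorable
#' outcome (open reduction; pelvic osteotomy without open reduction;
#' residual dysplasia alone), the composite itself and the favorable
#' remainder, with percentages of the included cohort (rounded half away
#' from zero, the clinical-table convention: 12/92 prints as 13%).
#'
#' @param outcomes Outcome tibble from [derive_outcomes()].
#' @return Tibble `component`, `n`, `total`, `percent`.
#' @export
outcome_flow_table <- function(outcomes) {
  n_total <- nrow(outcomes)
  counts <- c(
    open_reduction = sum(outcomes$o1_open_reduction),
    pelvic_osteotomy = sum(outcomes$o2_surgery & !outcomes$o1_open_reduction),
    residual_only = sum(outcomes$o4_unfavorable & !outcomes$o2_surgery),
    unfavorable = sum(outcomes$o4_unfavorable),
    favorable = sum(!outcomes$o4_unfavorable)
  )
  tibble::tibble(
    component = names(counts),
    n = as.integer(counts),
    total = n_total,
    percent = percent_of(counts, n_total)
  )
}

cohort_characteristics <- function(included, fhc) {
  n <- nrow(included)
  num_row <- function(label, v) {
    tibble::tibble(characteristic = label, n = sum(!is.na(v)),
                   percent = NA_real_,
                   mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE))
  }
  cat_row <- function(label, flag) {
    tibble::tibble(characteristic = label, n = sum(flag, na.rm = TRUE),
                   percent = percent_of(sum(flag, na.rm = TRUE), n),
                   mean = NA_real_, sd = NA_real_)
  }
  dplyr::bind_rows(
    cat_row("female", included$sex == "F"),
    if ("age_at_us" %in% names(included))
      num_row("age_at_us_months", included$age_at_us),
    if ("side" %in% names(included))
      cat_row("left_hip", included$side == "left"),
    cat_row("graf_D", included$graf_type == "D"),
    num_row("fhc_percent", fhc$fhc_percent)
  )
}

write_run_bundle <- function(result, out_dir, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tbl, name) {
    readr::write_csv(tbl, file.path(out_dir, name), progress = FALSE)
    name
  }
  files <- c(
    wr(result$tally, "inclusion_tally.csv"),
    wr(result$characteristics, "cohort_characteristics.csv"),
    wr(result$fhc, "fhc.csv"),
    wr(tidy(result$model), "variance_proportions.csv"),
    wr(result$zscores, "zscores.csv"),
    wr(tidyr::unnest_wider(result$cutpoints, c("cutpoints", "sizes"),
                           names_sep = "_"),
       "quintile_cutpoints.csv"),
    wr(result$outcomes, "outcomes.csv"),
    wr(result$outcome_flow, "outcome_flow.csv"),
    wr(result$associations, "associations.csv"),
    wr(result$synthesized, "synthesized_modes.csv")
  )
  if (!is.null(result$reliability)) {
    icc_tbl <- result$reliability$per_mode |>
      dplyr::mutate(overall = result$reliability$overall)
    files <- c(files, wr(icc_tbl, "icc.csv"))
  }
  stages <- c("inclusion", "fhc", "alignment", "shape_model", "zscores",
              "outcomes", "associations",
              if (!is.null(result$reliability)) "reliability", "export")
  manifest <- list(
    seed = result$seed,
    stages = stages,
    n_included = result$model$n_shapes,
    n_retained_modes = result$model$n_retained,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files
    ))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  if (verbose) message("wrote ", length(files) + 1, " files to ", out_dir)
  invisible(out_dir)
}

#' @export
print.hipshape_run <- function(x, ...) {
  cat("hipshape pipeline run\n")
  cat(sprintf("  included hips: %d\n", x$model$n_shapes))
  cat(sprintf("  retained modes: %d (%s)\n", x$model$n_retained,
              paste(sprintf("%.0f%%",
                            100 * x$model$variance_proportions[
                              seq_len(x$model$n_retained)]),
                    collapse = "/")))
  if (!is.null(x$reliability)) {
    cat(sprintf("  overall weighted ICC: %.3f\n", x$reliability$overall))
  }
  sig <- x$associations[!is.na(x$associations$p.value) &
                          x$associations$p.value < 0.05 &
                          !x$associations$separation, ]
  cat(sprintf("  association cells with p < 0.05: %d\n", nrow(sig)))
  invisible(x)
}
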
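#' Binary logistic regression with odds-ratio output
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()]) of a binary outcome on one or more covariates, reported
#' per covariate as an odds ratio with a 95% Wald confidence interval
#' (`exp(coef +- 1.959964 * SE)`, SE from the observed information) and a
#' two-sided Wald p-value, plus a model-level omnibus p-value from the
#' likelihood-ratio test against the intercept-only model.
#'
#' Complete or quasi-complete separation (a coefficient diverging beyond
#' `|coef| > 15` or a non-converged fit) is reported, not repaired: the
#' affected rows are flagged `separation = TRUE` and their interval bounds
#' are not interpretable — mirroring how such cells appear in clinical
#' tables as "0.00 [0.00, -]".
#'
#' @param data Data frame holding outcome and covariates.
#' @param outcome Name of the logical/0-1 outcome column.
#' @param covariates Character vector of covariate column names.
#' @return Tibble with one row per covariate term: `term`, `estimate`
#'   (log-odds coefficient), `odds_ratio`, `conf.low`, `conf.high` (OR
#'   scale), `std.error`, `p.value` (Wald), `omnibus_p` (repeated;
#'   model-level LRT), `separation`.
#' @examples
#' d <- data.frame(y = rep(c(1, 0, 1, 0), c(10, 10, 5, 15)),
#'                 x = rep(c(1, 1, 0, 0), c(10, 10, 5, 15)))
#' logistic_fit(d, "y", "x") # odds ratio 3 = (10 * 15) / (10 * 5)
#' @export
logistic_fit <- function(data, outcome, covariates) {
  y <- as.numeric(data[[outcome]])
  if (length(unique(y[!is.na(y)])) < 2) {
    abort(paste0("outcome '", outcome, "' does not have both classes"))
  }
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2) {
      abort(paste0("covariate '", cv, "' is constant"))
    }
  }
  fml <- stats::reformulate(covariates, response = outcome)
  fit <- suppressWarnings(
    glm(fml, data = data, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 50))
  )
  smry <- summary(fit)$coefficients
  terms <- setdiff(rownames(smry), "(Intercept)")
  est <- smry[terms, "Estimate"]
  se <- smry[terms, "Std. Error"]
  zcrit <- 1.959964
  omnibus <- pchisq(fit$null.deviance - fit$deviance,
                    df = fit$df.null - fit$df.residual, lower.tail = FALSE)
  separated <- !fit$converged | abs(est) > 15
  if (any(separated)) {
    warn(paste0("possible separation in terms: ",
                paste(terms[separated], collapse = ", ")))
  }
  tibble::tibble(
    term = terms,
    estimate = unname(est),
    odds_ratio = exp(unname(est)),
    conf.low = exp(unname(est) - zcrit * unname(se)),
    conf.high = exp(unname(est) + zcrit * unname(se)),
    std.error = unname(se),
    p.value = unname(smry[terms, "Pr(>|z|)"]),
    omnibus_p = omnibus,
    separation = unname(separated)
  )
}

#' Full association analysis between shape modes, coverage and outcomes
#'
#' For each of the four outcomes, fits:
#' * `univariable` — one logistic fit per retained mode on its continuous
#'   Z-score;
#' * `multivariable` — one fit with all retained-mode Z-scores plus the
#'   Morin coverage category entered as a single ordinal covariate, keeping
#'   the covariate count at 5 for the default 4-mode model (the rule-of-thumb
#'   limit for a cohort of ~90 events);
#' * `categorized` — one fit per mode on its quintile indicators (quintile
#'   0, the lowest fifth, is the reference; terms `Q1`-`Q4`).
#'
#' The osteotomy-or-residual outcome excludes open-reduction hips (their
#' rows carry `NA` and are dropped). A cell that cannot be fitted (one-class
#' outcome, separation, constant covariate) is flagged or skipped with a
#' note rather than aborting the suite.
#'
#' @param zscores Long Z-score table `hip_id`, `mode`, `z`.
#' @param fhc Tibble `hip_id`, `morin_category` (see [cohort_fhc()]).
#' @param outcomes Outcome tibble from [derive_outcomes()].
#' @return Tibble of association results: `outcome_id` (1-4),
#'   `model_form`, `mode`, `term`, OR columns as in [logistic_fit()], and
#'   `note` for skipped cells.
#' @export
run_association_suite <- function(zscores, fhc, outcomes) {
  zw <- tidyr::pivot_wider(zscores, id_cols = "hip_id",
                           names_from = "mode", values_from = "z",
                           names_prefix = "m")
  mode_cols <- setdiff(names(zw), "hip_id")
  qt <- zscore_quintiles(zscores)
  dat <- zw |>
    dplyr::inner_join(fhc[, c("hip_id", "morin_category")], by = "hip_id") |>
    dplyr::inner_join(outcomes, by = "hip_id")
  if (nrow(dat) == 0) abort("no hips shared across zscores, fhc and outcomes")
  outcome_cols <- c("o1_open_reduction", "o2_surgery",
                    "o3_osteotomy_or_residual", "o4_unfavorable")

  fit_cell <- function(d, outcome, covs, form, mode_label) {
    res <- tryCatch(
      suppressWarnings(logistic_fit(d, outcome, covs)),
      error = function(e) {
        tibble::tibble(term = covs, estimate = NA_real_,
                       odds_ratio = NA_real_, conf.low = NA_real_,
                       conf.high = NA_real_, std.error = NA_real_,
                       p.value = NA_real_, omnibus_p = NA_real_,
                       separation = NA, note = conditionMessage(e))
      }
    )
    if (!"note" %in% names(res)) res$note <- NA_character_
    res$model_form <- form
    res$mode <- mode_label
    res
  }

  purrr::map_dfr(seq_along(outcome_cols), function(k) {
    oc <- outcome_cols[k]
    d <- dat[!is.na(dat[[oc]]), , drop = FALSE]
    uni <- purrr::map_dfr(seq_along(mode_cols), function(m) {
      fit_cell(d, oc, mode_cols[m], "univariable", m)
    })
    multi <- fit_cell(d, oc, c(mode_cols, "morin_category"),
                      "multivariable", NA_integer_) |>
      dplyr::mutate(mode = match(.data$term, mode_cols))
    cat_fits <- purrr::map_dfr(seq_along(mode_cols), function(m) {
      qd <- qt[qt$mode == m, c("hip_id", "quintile")]
      dm <- dplyr::inner_join(d, qd, by = "hip_id")
      for (q in 1:4) dm[[paste0("Q", q)]] <- as.numeric(dm$quintile == q)
      fit_cell(dm, oc, paste0("Q", 1:4), "categorized", m)
    })
    dplyr::bind_rows(uni, multi, cat_fits) |>
      dplyr::mutate(outcome_id = k)
  }) |>
    dplyr::select("outcome_id", "model_form", "mode", "term",
                  "estimate", "odds_ratio", "conf.low", "conf.high",
                  "std.error", "p.value", "omnibus_p", "separation", "note")
}

#' Forest plot of association results
#'
#' @param object Result tibble from [run_association_suite()].
#' @param model_form Which model form to draw (default `"univariable"`).
#' @param ... Unused.
#' @return A ggplot object: odds ratios with 95% CIs per mode, faceted by
#'   outcome.
#' @export
plot_association <- function(object, model_form = "univariable", ...) {
  d <- object[object$model_form == model_form & !is.na(object$odds_ratio) &
                !is.na(object$mode), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio,
                                  y = factor(.data$mode))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~outcome_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "odds ratio (log scale)", y = "shape mode") +
    ggplot2::theme_minimal()
}
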
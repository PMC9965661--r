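#' Four-class marine biodegradability categories
#'
#' Ordered factor levels used by [classify_biodegradability()]:
#' `non` < `slightly` < `moderately` < `readily`.
#'
#' @format Character vector of the four level names.
#' @export
biodegradability_levels <- c("non", "slightly", "moderately", "readily")

#' Classify marine biodegradability from %C+
#'
#' Maps the BOD at the assessment day, expressed as a percentage of the
#' positive control (%C+), onto the four-class scheme:
#'
#' | %C+            | category     |
#' |----------------|--------------|
#' | > 60           | `readily`    |
#' | 20 < x <= 60   | `moderately` |
#' | 5 < x <= 20    | `slightly`   |
#' | <= 5           | `non`        |
#'
#' Boundaries follow the interval notation exactly: 5 is `non`, 20 is
#' `slightly`, 60 is `moderately`. Negative values (possible for
#' blank-dominated low-signal materials) map to `non`.
#'
#' @param pct_cplus Numeric vector of %C+ values; must be finite.
#' @return Ordered factor with levels [biodegradability_levels].
#' @export
#' @examples
#' classify_biodegradability(c(0.8, 17.6, 42.0, 75))
classify_biodegradability <- function(pct_cplus) {
  if (any(!is.finite(pct_cplus))) {
    abort_validation("%C+ values must be finite to be classified")
  }
  cut(pct_cplus, breaks = c(-Inf, 5, 20, 60, Inf),
      labels = biodegradability_levels,
      right = TRUE, ordered_result = TRUE)
}

#' Assess every test material in an experiment
#'
#' The full pipeline: blank correction, %C+ at the assessment day, kinetic
#' model selection ([select_model()]) on the pooled per-replicate corrected
#' points, classification, and QA gates. QA failures never block the
#' assessment; they are reported as flags.
#'
#' Classification uses the observed %C+ at the assessment day, not the
#' fitted asymptote: the class benchmarks are defined on the 28-day BOD.
#' The ultimate BOD (`bod_l`) is reported alongside as the
#' kinetics-independent estimate of ultimate biodegradability.
#'
#' @param exp A [bod_experiment()].
#' @param alpha F-test significance level for model selection.
#' @param variant Information-criterion variant, see [aicc()].
#' @param n_source Nitrogen source for the ThOD QA gate, see [thod()].
#' @return A tibble of class `bod_assessment`, one row per test material
#'   (sorted by `material_id`) with columns `material_id`, `label`,
#'   `pct_cplus`, `category`, `model`, `bod_l`, `bod_l_lo`, `bod_l_hi`,
#'   `b`, `b_lo`, `b_hi`, `fit_not_calculable`, `blank_pass`, `cplus_pass`.
#'   Attributes `fits` (named list of selected `kinetic_fit`s), `qa` (the
#'   [qa_gates()] row) and `assessment_day`.
#' @export
assess <- function(exp, alpha = 0.05, variant = c("aicc", "aic"),
                   n_source = c("nitrate", "ammonium")) {
  variant <- match.arg(variant)
  n_source <- match.arg(n_source)
  validate_experiment(exp)
  corrected <- blank_correct(exp)
  qa <- qa_gates(exp, n_source)
  pct <- pct_cplus(corrected, exp$assessment_day)

  sample_ids <- sort(unique(corrected$material_id[corrected$role == "sample"]))
  rows <- purrr::map(sample_ids, function(id) {
    dat <- dplyr::filter(corrected, .data$material_id == id)
    fit <- select_model(dat, alpha = alpha, variant = variant)
    p <- pct$pct_cplus[pct$material_id == id]
    meta <- dplyr::filter(exp$materials, .data$material_id == id)
    ci <- function(par, side) {
      if (par %in% rownames(fit$ci) && isTRUE(fit$ci_calculable[[par]])) {
        fit$ci[par, side]
      } else NA_real_
    }
    est <- function(par) {
      if (par %in% names(fit$coef)) unname(fit$coef[[par]]) else NA_real_
    }
    list(
      report = tibble(
        material_id = id,
        label = if (nrow(meta) == 1) meta$label else id,
        pct_cplus = p,
        category = classify_biodegradability(p),
        model = fit$model$form,
        bod_l = est("bod_l"), bod_l_lo = ci("bod_l", "lower"), bod_l_hi = ci("bod_l", "upper"),
        b = est("b"), b_lo = ci("b", "lower"), b_hi = ci("b", "upper"),
        fit_not_calculable = fit$refused,
        blank_pass = qa$blank_pass, cplus_pass = qa$cplus_pass
      ),
      fit = fit
    )
  })
  out <- dplyr::bind_rows(purrr::map(rows, "report"))
  fits <- setNames(purrr::map(rows, "fit"), sample_ids)
  structure(out, class = c("bod_assessment", class(out)),
            fits = fits, qa = qa, assessment_day = exp$assessment_day)
}

#' @export
print.bod_assessment <- function(x, ...) {
  cat("Marine biodegradability assessment (day",
      attr(x, "assessment_day"), ")\n")
  qa <- attr(x, "qa")
  cat(sprintf("QA: blank %.2f%% of C+ [%s]; C+ %s of ThOD [%s]\n\n",
              100 * qa$blank_fraction_of_cplus,
              if (isTRUE(qa$blank_pass)) "pass" else "FAIL",
              if (is.na(qa$cplus_fraction_of_thod)) "n.a."
              else sprintf("%.1f%%", 100 * qa$cplus_fraction_of_thod),
              if (is.na(qa$cplus_pass)) "indeterminate"
              else if (qa$cplus_pass) "pass" else "FAIL"))
  df <- as.data.frame(x)[, c("material_id", "pct_cplus", "category",
                             "model", "bod_l", "b")]
  df$pct_cplus <- sprintf("%.1f%%", df$pct_cplus)
  df$bod_l <- ifelse(is.na(df$bod_l), "n.c.", sprintf("%.1f", df$bod_l))
  df$b <- ifelse(is.na(df$b), "n.c.", sprintf("%.2f", df$b))
  print(df, row.names = FALSE)
  invisible(x)
}
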
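#' Interpolate bottle time courses onto a common time grid
#'
#' Linear interpolation of each bottle's cumulative BOD onto `grid`; exact
#' at observed times. Extrapolation beyond a bottle's observed range is
#' refused (cumulative BOD outside the recorded window is unknown).
#'
#' @param bottles Tibble of bottle readings (the `bottles` element of a
#'   [bod_experiment()], or any subset with `bottle_id`, `day`, `bod_mg_l`).
#' @param grid Numeric vector of days, each within every bottle's observed
#'   time range.
#' @return Tibble with one row per bottle per grid day: original identifier
#'   columns plus `day` and `bod_mg_l`.
#' @export
align_to_grid <- function(bottles, grid) {
  bottles <- as_tibble(bottles)
  grid <- sort(unique(as.numeric(grid)))
  id_cols <- intersect(c("bottle_id", "role", "material_id", "replicate"),
                       names(bottles))
  bottles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::group_modify(function(df, key) {
      if (min(grid) < min(df$day) || max(grid) > max(df$day)) {
        abort_validation(paste0(
          "grid extends outside the observed range [", min(df$day), ", ",
          max(df$day), "] of a bottle; refusing to extrapolate"))
      }
      tibble(day = grid,
             bod_mg_l = approx(df$day, df$bod_mg_l, xout = grid, ties = "ordered")$y)
    }) |>
    dplyr::ungroup()
}

#' Blank-correct treatment bottles
#'
#' For every non-blank bottle (positive controls included: they are
#' treatments too) the mean BOD of the blanks, interpolated to the bottle's
#' own reading times, is subtracted. Negative corrected values are retained,
#' not clipped, so replicate noise is not biased upward.
#'
#' @param exp A [bod_experiment()].
#' @return A tibble of class `bod_corrected` with one row per treatment
#'   bottle per reading: `material_id`, `role`, `replicate`, `day`,
#'   `bod_corrected` (mg O2/L).
#' @export
blank_correct <- function(exp) {
  validate_experiment(exp)
  blanks <- dplyr::filter(exp$bottles, .data$role == "blank")
  treats <- dplyr::filter(exp$bottles, .data$role != "blank")
  lo <- max(tapply(blanks$day, blanks$bottle_id, min))
  hi <- min(tapply(blanks$day, blanks$bottle_id, max))
  days_used <- sort(unique(treats$day[treats$day >= lo & treats$day <= hi]))
  if (length(days_used) == 0) {
    abort_validation("blanks and treatments share no common time support")
  }
  blank_mean <- align_to_grid(blanks, days_used) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(blank_bod = mean(.data$bod_mg_l), .groups = "drop")
  out <- treats |>
    dplyr::filter(.data$day >= lo, .data$day <= hi) |>
    dplyr::left_join(blank_mean, by = "day") |>
    dplyr::mutate(bod_corrected = .data$bod_mg_l - .data$blank_bod) |>
    dplyr::select("material_id", "role", "replicate", "day", "bod_corrected") |>
    dplyr::arrange(.data$material_id, .data$replicate, .data$day)
  class(out) <- c("bod_corrected", class(out))
  out
}

#' Summarise corrected series and normalise to the positive control
#'
#' Collapses replicate bottles to their arithmetic mean per day and
#' expresses each material's corrected BOD as a percentage of the
#' positive control's corrected BOD at the same day (%C+). The %C+ track
#' is defined only at days where both series have corrected values.
#'
#' @param corrected Output of [blank_correct()].
#' @return Tibble with `material_id`, `role`, `day`, `bod_corrected`
#'   (replicate mean), `n_replicates` and `pct_cplus`.
#' @export
pct_cplus_track <- function(corrected) {
  means <- corrected |>
    dplyr::group_by(.data$material_id, .data$role, .data$day) |>
    dplyr::summarise(bod_corrected = mean(.data$bod_corrected),
                     n_replicates = dplyr::n(), .groups = "drop")
  cplus <- means |>
    dplyr::filter(.data$role == "positive_control") |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(cplus_bod = mean(.data$bod_corrected), .groups = "drop")
  means |>
    dplyr::inner_join(cplus, by = "day") |>
    dplyr::mutate(pct_cplus = 100 * .data$bod_corrected / .data$cplus_bod) |>
    dplyr::select(-"cplus_bod") |>
    dplyr::arrange(.data$material_id, .data$day)
}

#' BOD as a percentage of the positive control at one day
#'
#' The headline biodegradability statistic: blank-corrected, replicate-mean
#' BOD of each material divided by the blank-corrected BOD of the positive
#' control at the same day, times 100.
#'
#' @param corrected Output of [blank_correct()].
#' @param day Day at which to evaluate (typically the assessment day, 28).
#'   Values between readings are linearly interpolated.
#' @return Tibble with `material_id`, `role` and `pct_cplus`.
#' @export
pct_cplus <- function(corrected, day = 28) {
  means <- corrected |>
    dplyr::group_by(.data$material_id, .data$role) |>
    dplyr::summarise(
      bod_at_day = interp_at(.data$day, .data$bod_corrected, !!day),
      .groups = "drop"
    )
  cplus_val <- mean(means$bod_at_day[means$role == "positive_control"])
  if (!is.finite(cplus_val)) {
    abort_validation(paste0("positive control has no corrected value at day ", day))
  }
  if (cplus_val <= 0) {
    abort_validation(paste0(
      "positive control corrected BOD is not positive at day ", day,
      "; the trial is degenerate and %C+ is undefined"))
  }
  means |>
    dplyr::mutate(pct_cplus = 100 * .data$bod_at_day / cplus_val) |>
    dplyr::select("material_id", "role", "pct_cplus")
}

# replicate-mean value at `at`, linearly interpolated; NA outside range
interp_at <- function(day, value, at) {
  m <- tapply(value, day, mean)
  d <- as.numeric(names(m))
  if (at < min(d) || at > max(d)) return(NA_real_)
  approx(d, as.numeric(m), xout = at, ties = "ordered")$y
}

atomic_mass <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007,
                 S = 32.06, P = 30.974)

parse_hill_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) abort_validation("empty formula")
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    abort_validation(paste0("cannot parse formula: ", formula))
  }
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Za-z]+", "", parts)
  n <- ifelse(nzchar(n), as.numeric(n), 1)
  counts <- tapply(n, el, sum)
  bad <- setdiff(names(counts), names(atomic_mass))
  if (length(bad) > 0) {
    abort_validation(paste0("unsupported element(s) in formula: ",
                            paste(bad, collapse = ", ")))
  }
  setNames(as.numeric(counts), names(counts))
}

#' Theoretical oxygen demand of a material
#'
#' Stoichiometric O2 required for complete aerobic oxidation of one gram of
#' material, computed from the elemental composition of its repeat unit
#' (carbon to CO2, hydrogen to H2O, sulfur to SO3, phosphorus to P2O5).
#' With the `nitrate` nitrogen source, organic N is oxidised to NO3-
#' (ThOD_NO3); with `ammonium` it remains reduced as NH3 (ThOD_NH3).
#'
#' For a repeat unit C_c H_h O_o N_n S_s P_p,
#' `ThOD = 32 (c + h/4 - o/2 + s + 1.25 p + t n) / MW` with `t = 1.25`
#' (nitrate) or `t = -0.75` (ammonium). For PHB's repeat unit C4H6O2 this
#' gives 1.673 g O2 per g.
#'
#' @param formula Hill-notation formula string, e.g. `"C4H6O2"`. Elements
#'   C, H, O, N, S, P are supported; the formula must contain carbon.
#' @param n_source `"nitrate"` (default; matches media where NO3- is the
#'   nitrogen source, so nitrogenous demand is counted to nitrate) or
#'   `"ammonium"`.
#' @return ThOD in g O2 per g material.
#' @export
#' @examples
#' thod("C4H6O2") # PHB repeat unit, 1.673
thod <- function(formula, n_source = c("nitrate", "ammonium")) {
  n_source <- match.arg(n_source)
  counts <- parse_hill_formula(formula)
  if (!"C" %in% names(counts) || counts[["C"]] <= 0) {
    abort_validation("formula must contain carbon")
  }
  get <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  n_term <- if (n_source == "nitrate") 1.25 else -0.75
  o2_mol <- get("C") + get("H") / 4 - get("O") / 2 + get("S") +
    1.25 * get("P") + n_term * get("N")
  mw <- sum(counts * atomic_mass[names(counts)])
  31.998 * o2_mol / mw
}

#' Quality-assurance gates for a respirometry trial
#'
#' Two acceptability checks at the assessment day: the blank signal must
#' stay below 2% of the raw positive-control BOD (high signal-to-noise),
#' and the blank-corrected positive-control BOD must exceed 60% of the
#' theoretical maximum implied by its mass concentration and ThOD (the
#' inoculum was active enough). Both thresholds are strict inequalities.
#' If the positive-control formula is unknown the ThOD gate is reported as
#' indeterminate (`NA`), not failed.
#'
#' @param exp A [bod_experiment()].
#' @param n_source Nitrogen source for the ThOD computation, see [thod()].
#' @return One-row tibble with `blank_fraction_of_cplus`,
#'   `cplus_fraction_of_thod`, `blank_pass`, `cplus_pass`.
#' @export
qa_gates <- function(exp, n_source = c("nitrate", "ammonium")) {
  n_source <- match.arg(n_source)
  validate_experiment(exp)
  day <- exp$assessment_day
  blanks <- dplyr::filter(exp$bottles, .data$role == "blank")
  cplus_raw <- dplyr::filter(exp$bottles, .data$role == "positive_control")
  blank_at <- blanks |>
    dplyr::group_by(.data$bottle_id) |>
    dplyr::summarise(v = interp_at(.data$day, .data$bod_mg_l, !!day), .groups = "drop")
  cplus_at <- cplus_raw |>
    dplyr::group_by(.data$bottle_id) |>
    dplyr::summarise(v = interp_at(.data$day, .data$bod_mg_l, !!day), .groups = "drop")
  blank_fraction <- mean(blank_at$v) / mean(cplus_at$v)

  corrected <- blank_correct(exp)
  cplus_corr <- corrected |>
    dplyr::filter(.data$role == "positive_control") |>
    dplyr::group_by(.data$material_id) |>
    dplyr::summarise(v = interp_at(.data$day, .data$bod_corrected, !!day), .groups = "drop")
  cplus_id <- cplus_corr$material_id[1]
  meta <- dplyr::filter(exp$materials, .data$material_id == cplus_id)
  if (nrow(meta) == 1 && !is.na(meta$formula)) {
    max_bod <- meta$mass_conc_mg_l * thod(meta$formula, n_source)
    cplus_fraction <- mean(cplus_corr$v) / max_bod
    cplus_pass <- cplus_fraction > 0.60
  } else {
    cplus_fraction <- NA_real_
    cplus_pass <- NA
  }
  tibble(
    blank_fraction_of_cplus = blank_fraction,
    cplus_fraction_of_thod = cplus_fraction,
    blank_pass = blank_fraction < 0.02,
    cplus_pass = cplus_pass
  )
}
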
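# small in-code fixtures shared across test files

# six-bottle experiment (2 blanks, 2 positive controls, 2 sample bottles)
# on a daily grid, built from exact logistic curves so expected values are
# known in closed form
tiny_experiment <- function(days = c(0, 7, 14, 21, 28),
                            blank = function(d) 0.02 * d,
                            cplus_curve = function(d) model_value(d, 100, 10, 1.4),
                            sample_curve = function(d) model_value(d, 21, 10, 1.4),
                            assessment_day = 28) {
  mk <- function(id, role, mat, rep, sig) {
    tibble::tibble(bottle_id = id, role = role, material_id = mat,
                   replicate = rep, day = days,
                   bod_mg_l = sig(days) + blank(days))
  }
  bottles <- dplyr::bind_rows(
    mk("BLK-1", "blank", "BLANK", 1L, function(d) 0),
    mk("BLK-2", "blank", "BLANK", 2L, function(d) 0),
    mk("C-1", "positive_control", "PHB", 1L, cplus_curve),
    mk("C-2", "positive_control", "PHB", 2L, cplus_curve),
    mk("S-1", "sample", "FILM", 1L, sample_curve),
    mk("S-2", "sample", "FILM", 2L, sample_curve)
  )
  materials <- tibble::tibble(
    material_id = c("PHB", "FILM"),
    label = c("Positive control", "Test film"),
    mass_conc_mg_l = 100,
    formula = c("C4H6O2", NA)
  )
  bod_experiment(bottles, materials, assessment_day)
}

# noiseless per-replicate series from a kinetic curve, as fit_kinetics input
noiseless_series <- function(bod_l, a, b, s = NA, days = 1:28, reps = 1) {
  d <- rep(days, reps)
  y <- if (is.na(s)) model_value(d, bod_l, a, b)
       else model_value(d, bod_l, a, b, s, form = "asymmetric")
  tibble::tibble(day = d, bod = y)
}

expect_rel_error <- function(est, truth, tol) {
  expect_lt(abs(est - truth) / abs(truth), tol)
}
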
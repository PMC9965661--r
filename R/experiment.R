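#' Construct a respirometry experiment
#'
#' A `bod_experiment` bundles the raw per-bottle BOD time courses of one
#' closed-bottle respirometry trial with the material metadata needed
#' downstream. Every trial must contain at least one blank (inoculated
#' bottle without test material) and one positive-control bottle (the
#' reference polymer, conventionally PHB).
#'
#' @param bottles Data frame with one row per bottle per reading and columns
#'   `bottle_id` (character), `role` (`"blank"`, `"positive_control"` or
#'   `"sample"`), `material_id` (character; blanks must use `"BLANK"`),
#'   `replicate` (positive integer), `day` (non-negative, strictly increasing
#'   within a bottle) and `bod_mg_l` (cumulative BOD, mg O2/L, non-negative).
#' @param materials Optional data frame of material metadata with columns
#'   `material_id`, `label`, `mass_conc_mg_l` (test-material concentration,
#'   default 100 mg/L) and `formula` (Hill-notation elemental composition of
#'   the repeat unit, e.g. `"C4H6O2"`, or `NA`). Missing entries for
#'   materials present in `bottles` are filled with defaults.
#' @param assessment_day Day at which the headline %C+ statistic is taken
#'   (default 28).
#'
#' @return An object of class `bod_experiment`: a list with tibbles
#'   `bottles` and `materials` plus `assessment_day`.
#' @seealso [read_experiment()], [simulate_experiment()], [assess()]
#' @export
#' @examples
#' bottles <- tibble::tibble(
#'   bottle_id = rep(c("B1", "C1", "S1"), each = 3),
#'   role = rep(c("blank", "positive_control", "sample"), each = 3),
#'   material_id = rep(c("BLANK", "PHB", "FILM"), each = 3),
#'   replicate = 1L,
#'   day = rep(c(0, 14, 28), 3),
#'   bod_mg_l = c(0, 0.5, 1, 0, 60, 100, 0, 12, 21)
#' )
#' exp <- bod_experiment(bottles)
bod_experiment <- function(bottles, materials = NULL, assessment_day = 28) {
  bottles <- as_tibble(bottles)
  required <- c("bottle_id", "role", "material_id", "replicate", "day", "bod_mg_l")
  missing_cols <- setdiff(required, names(bottles))
  if (length(missing_cols) > 0) {
    abort_format(paste0("bottle table is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  bottles <- bottles |>
    dplyr::select(dplyr::all_of(required)) |>
    dplyr::mutate(
      bottle_id = as.character(.data$bottle_id),
      role = as.character(.data$role),
      material_id = as.character(.data$material_id),
      replicate = as.integer(.data$replicate),
      day = as.numeric(.data$day),
      bod_mg_l = as.numeric(.data$bod_mg_l)
    ) |>
    dplyr::arrange(.data$bottle_id, .data$day)

  materials <- normalise_materials(materials, bottles)
  exp <- structure(
    list(bottles = bottles, materials = materials,
         assessment_day = as.numeric(assessment_day)),
    class = "bod_experiment"
  )
  validate_experiment(exp)
}

normalise_materials <- function(materials, bottles) {
  ids <- unique(bottles$material_id[bottles$role != "blank"])
  if (is.null(materials)) {
    materials <- tibble(material_id = character(), label = character(),
                        mass_conc_mg_l = numeric(), formula = character())
  }
  materials <- as_tibble(materials)
  if (!"material_id" %in% names(materials)) {
    abort_format("materials table is missing required column: material_id")
  }
  materials <- materials |>
    dplyr::mutate(
      material_id = as.character(.data$material_id),
      label = if ("label" %in% names(materials)) as.character(.data$label) else .data$material_id,
      mass_conc_mg_l = if ("mass_conc_mg_l" %in% names(materials)) as.numeric(.data$mass_conc_mg_l) else 100,
      formula = if ("formula" %in% names(materials)) as.character(.data$formula) else NA_character_
    ) |>
    dplyr::select("material_id", "label", "mass_conc_mg_l", "formula")
  filled <- tibble(
    material_id = setdiff(ids, materials$material_id)
  ) |>
    dplyr::mutate(label = .data$material_id, mass_conc_mg_l = 100,
                  formula = NA_character_)
  dplyr::bind_rows(materials, filled) |>
    dplyr::filter(.data$material_id %in% ids) |>
    dplyr::arrange(.data$material_id)
}

#' Validate a respirometry experiment
#'
#' Checks the structural invariants: known roles, `"BLANK"` reserved for
#' blanks, non-negative raw BOD, strictly increasing times with no
#' duplicated readings within a bottle, positive mass concentrations, and
#' presence of at least one blank and one positive-control bottle.
#'
#' @param exp A [bod_experiment()].
#' @return `exp`, invisibly unchanged, if valid; otherwise a classed
#'   validation error is raised.
#' @export
validate_experiment <- function(exp) {
  stopifnot(inherits(exp, "bod_experiment"))
  b <- exp$bottles
  if (nrow(b) == 0) abort_validation("experiment contains no bottle readings")
  bad_role <- setdiff(unique(b$role), c("blank", "positive_control", "sample"))
  if (length(bad_role) > 0) {
    abort_validation(paste0("unknown bottle role(s): ", paste(bad_role, collapse = ", ")))
  }
  if (any(b$role == "blank" & b$material_id != "BLANK")) {
    abort_validation("blank bottles must use material_id \"BLANK\"")
  }
  if (any(b$role != "blank" & b$material_id == "BLANK")) {
    abort_validation("material_id \"BLANK\" is reserved for blank bottles")
  }
  if (any(!is.finite(b$day)) || any(b$day < 0)) {
    abort_validation("days must be finite and non-negative")
  }
  if (any(!is.finite(b$bod_mg_l)) || any(b$bod_mg_l < 0)) {
    abort_validation("raw BOD readings must be finite and non-negative")
  }
  dup <- b |>
    dplyr::count(.data$bottle_id, .data$day) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_validation(paste0("duplicated (bottle_id, day) readings, e.g. bottle ",
                            dup$bottle_id[1], " day ", dup$day[1]))
  }
  roles_by_bottle <- b |> dplyr::distinct(.data$bottle_id, .data$role)
  if (anyDuplicated(roles_by_bottle$bottle_id) > 0) {
    abort_validation("a bottle_id appears with more than one role")
  }
  if (!"blank" %in% b$role) abort_validation("experiment has no blank bottle")
  if (!"positive_control" %in% b$role) {
    abort_validation("experiment has no positive-control bottle")
  }
  if (any(exp$materials$mass_conc_mg_l <= 0, na.rm = TRUE)) {
    abort_validation("mass_conc_mg_l must be positive")
  }
  missing_meta <- setdiff(unique(b$material_id[b$role != "blank"]),
                          exp$materials$material_id)
  if (length(missing_meta) > 0) {
    abort_validation(paste0("no material metadata for: ",
                            paste(missing_meta, collapse = ", ")))
  }
  if (!is.finite(exp$assessment_day) || exp$assessment_day <= 0) {
    abort_validation("assessment_day must be positive")
  }
  invisible(exp)
}

#' Read a respirometry experiment from CSV
#'
#' Expects the long dialect with exact header
#' `bottle_id,role,material_id,replicate,day,bod_mg_l` (one row per bottle
#' per reading; roles spelled `blank`, `positive_control`, `sample`).
#' An optional metadata sidecar CSV carries
#' `material_id,label,mass_conc_mg_l,formula` with Hill-notation formulas.
#'
#' @param path Path to the bottle-series CSV.
#' @param materials Optional path to the metadata sidecar CSV, or a data
#'   frame of metadata.
#' @inheritParams bod_experiment
#' @return A validated [bod_experiment()].
#' @export
read_experiment <- function(path, materials = NULL, assessment_day = 28) {
  if (!file.exists(path)) abort_io(paste0("input file not found: ", path))
  bottles <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(.default = readr::col_guess()))
  if (is.character(materials)) {
    if (!file.exists(materials)) {
      abort_io(paste0("materials file not found: ", materials))
    }
    materials <- readr::read_csv(materials, show_col_types = FALSE)
  }
  bod_experiment(bottles, materials, assessment_day)
}

#' Write a respirometry experiment to CSV
#'
#' Writes the documented long CSV dialect; the result round-trips through
#' [read_experiment()] without loss.
#'
#' @param exp A [bod_experiment()].
#' @param path Output path for the bottle-series CSV.
#' @param materials_path Optional output path for the metadata sidecar.
#' @return `exp`, invisibly.
#' @export
write_experiment <- function(exp, path, materials_path = NULL) {
  validate_experiment(exp)
  readr::write_csv(exp$bottles, path)
  if (!is.null(materials_path)) {
    readr::write_csv(exp$materials, materials_path)
  }
  invisible(exp)
}

#' @export
print.bod_experiment <- function(x, ...) {
  roles <- x$bottles |> dplyr::distinct(.data$bottle_id, .data$role) |>
    dplyr::count(.data$role)
  cat("<bod_experiment>\n")
  cat("  bottles:", nrow(dplyr::distinct(x$bottles, .data$bottle_id)),
      paste0("(", paste(sprintf("%s %d", roles$role, roles$n), collapse = ", "), ")"), "\n")
  cat("  readings:", nrow(x$bottles), "  days:",
      min(x$bottles$day), "-", max(x$bottles$day), "\n")
  cat("  materials:", paste(x$materials$material_id, collapse = ", "), "\n")
  cat("  assessment day:", x$assessment_day, "\n")
  invisible(x)
}
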
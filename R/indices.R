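#' Pressure-difference indices per beat and per case
#'
#' Computes the three CVP morphology indices for every beat with the required
#' vertices found — `v_minus_y` (V wave − Y descent), `x_minus_y` (X descent −
#' Y descent) and `c_minus_y` (C wave − Y descent), all in mmHg — and
#' aggregates them to the case level by the median, the representative value
#' of a case. A beat missing a required vertex is skipped for the affected
#' index; a case with no valid beat for an index gets `NA` there and is
#' excluded from any statistic using that index.
#'
#' @param vertices tibble from [detect_vertices()].
#' @param cases the `cases` table of the cohort (case_id, tr_grade, ...).
#' @return list of class `cvp_indices` with tibbles `beats` (per-beat values)
#'   and `cases` (per-case medians joined with the TR grade).
#' @export
compute_indices <- function(vertices, cases) {
  wide <- tidyr::pivot_wider(vertices,
    id_cols = c("case_id", "beat_index"),
    names_from = "vertex", values_from = c("found", "pressure_mmhg")
  )
  gv <- function(nm) if (nm %in% names(wide)) wide[[nm]] else rep(NA, nrow(wide))
  ok <- function(v) !is.na(gv(paste0("found_", v))) & gv(paste0("found_", v))
  p <- function(v) gv(paste0("pressure_mmhg_", v))
  beats <- tibble::tibble(
    case_id = wide$case_id, beat_index = wide$beat_index,
    v_minus_y = ifelse(ok("V") & ok("Y"), p("V") - p("Y"), NA_real_),
    x_minus_y = ifelse(ok("X") & ok("Y"), p("X") - p("Y"), NA_real_),
    c_minus_y = ifelse(ok("C") & ok("Y"), p("C") - p("Y"), NA_real_)
  )
  med <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  per_case <- dplyr::summarise(
    dplyr::group_by(beats, .data$case_id),
    v_minus_y = med(.data$v_minus_y),
    x_minus_y = med(.data$x_minus_y),
    c_minus_y = med(.data$c_minus_y),
    n_beats = dplyr::n(), .groups = "drop"
  )
  per_case <- dplyr::left_join(per_case,
    cases[, intersect(c("case_id", "tr_grade"), names(cases))], by = "case_id")
  structure(list(beats = beats, cases = per_case), class = "cvp_indices")
}
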
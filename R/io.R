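#' Read a cohort from its CSV tables
#'
#' Loads `cases.csv`, `waveforms.csv`, `landmarks.csv` (and `truth.csv` when
#' present) from `dir`, validating the schema: required columns, known TR
#' grades (case-insensitive), strictly increasing per-case R times, uniformly
#' spaced waveform times and unique (case_id, time_s) waveform rows.
#' Validation failures raise descriptive errors naming the offending rows.
#'
#' @param dir directory containing the tables (see [write_cohort()]).
#' @return a `cvp_cohort` object.
#' @export
read_cohort <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing cohort file: ", p)
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  cases <- need("cases.csv")
  waveforms <- need("waveforms.csv")
  landmarks <- need("landmarks.csv")
  check_cols <- function(df, cols, f) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(f, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  check_cols(cases, c("case_id", "tr_grade"), "cases.csv")
  check_cols(waveforms, c("case_id", "time_s", "cvp_mmhg"), "waveforms.csv")
  check_cols(landmarks, c("case_id", "kind", "time_s"), "landmarks.csv")
  cases$tr_grade <- parse_tr_grade(cases$tr_grade)
  if (!all(landmarks$kind %in% c("R", "Tapex")))
    stop("landmarks.csv: kind must be 'R' or 'Tapex'")
  dup <- duplicated(waveforms[, c("case_id", "time_s")])
  if (any(dup)) {
    stop("waveforms.csv: duplicated (case_id, time_s) at row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  }
  for (cid in unique(waveforms$case_id)) {
    tt <- waveforms$time_s[waveforms$case_id == cid]
    if (any(diff(tt) <= 0)) stop("waveforms.csv: non-increasing times for case ", cid)
    if (length(tt) > 2 && diff(range(diff(tt))) > 1e-6)
      stop("waveforms.csv: non-uniform sampling for case ", cid)
    rt <- landmarks$time_s[landmarks$case_id == cid & landmarks$kind == "R"]
    if (length(rt) > 1 && any(diff(rt) <= 0))
      stop("landmarks.csv: non-increasing R times for case ", cid)
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv"))) {
    truth <- readr::read_csv(file.path(dir, "truth.csv"),
                             show_col_types = FALSE, progress = FALSE)
  }
  out <- list(cases = cases, waveforms = waveforms, landmarks = landmarks,
              truth = truth)
  structure(out, class = "cvp_cohort")
}

#' Apply the cohort exclusion cascade
#'
#' Excludes cases sequentially: first AF/AFL rhythm, then absent TR
#' measurement, then absent pre-surgical CVP record. Each case is counted in
#' the first exclusion category that applies, and the flow arithmetic
#' invariant `included = screened - sum(excluded)` always holds.
#'
#' @param cases case table with a `case_id` column.
#' @param af_afl,tr_not_measured,no_presurgical_cvp logical exclusion flags,
#'   one per case.
#' @return list with `cases` (the included subset) and `flow`, a tibble of
#'   counts: screened, excluded_af_afl, excluded_no_tr_measure,
#'   excluded_no_cvp, included.
#' @export
apply_cohort_filters <- function(cases,
                                 af_afl = rep(FALSE, nrow(cases)),
                                 tr_not_measured = rep(FALSE, nrow(cases)),
                                 no_presurgical_cvp = rep(FALSE, nrow(cases))) {
  n <- nrow(cases)
  stopifnot(length(af_afl) == n, length(tr_not_measured) == n,
            length(no_presurgical_cvp) == n)
  e1 <- af_afl
  e2 <- !e1 & tr_not_measured
  e3 <- !e1 & !e2 & no_presurgical_cvp
  keep <- !e1 & !e2 & !e3
  flow <- tibble::tibble(
    screened = n,
    excluded_af_afl = sum(e1),
    excluded_no_tr_measure = sum(e2),
    excluded_no_cvp = sum(e3),
    included = sum(keep)
  )
  stopifnot(flow$included ==
              flow$screened - flow$excluded_af_afl -
              flow$excluded_no_tr_measure - flow$excluded_no_cvp)
  list(cases = cases[keep, , drop = FALSE], flow = flow)
}
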
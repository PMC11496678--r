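#' Strict local extrema of a sampled waveform
#'
#' Returns the interior local maxima and minima of `x`. A plateau of equal
#' values that is a strict extremum relative to its neighbours is collapsed to
#' its centre sample (floor rule for even plateaus). Endpoints are never
#' extrema.
#'
#' @param x numeric vector of length at least 3.
#' @return list with integer vectors `maxima` and `minima` (1-based indices).
#' @export
#' @examples
#' find_local_extrema(c(0, 1, 1, 0))$maxima  # plateau centre
find_local_extrema <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples to find local extrema")
  r <- rle(as.numeric(x))
  m <- length(r$values)
  if (m < 3) return(list(maxima = integer(0), minima = integer(0)))
  starts <- cumsum(c(1L, r$lengths[-m]))
  mid <- 2:(m - 1)
  v <- r$values
  centres <- as.integer(starts[mid] + (r$lengths[mid] - 1L) %/% 2L)
  is_max <- v[mid] > v[mid - 1L] & v[mid] > v[mid + 1L]
  is_min <- v[mid] < v[mid - 1L] & v[mid] < v[mid + 1L]
  list(maxima = centres[is_max], minima = centres[is_min])
}

moving_average <- function(x, width) {
  if (width <= 1) return(x)
  if (width %% 2 == 0) width <- width + 1
  pad <- (width - 1) %/% 2
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[(pad + 1):(pad + length(x))]
}

#' Detect the C, V, X and Y vertices on segmented beats
#'
#' Rules applied to each beat's raw (mmHg) samples using its ECG anchors:
#' the C wave is the first strict local maximum after the R wave; the V wave
#' is the first strict local maximum after the T apex; the X descent is the
#' global minimum strictly between the R wave and the V wave; the Y descent is
#' the global minimum strictly after the V wave, up to the window end. A rule
#' that cannot be satisfied sets `found = FALSE` for that vertex and its
#' dependents (X and Y depend on V; a beat without a T-apex landmark has no V).
#' Pressures are reported from the raw samples (mmHg), never normalized.
#'
#' @param beats a `cvp_beats` object from [segment_beats()].
#' @param smooth apply a centred moving average before extremum detection
#'   (default TRUE; suppresses spurious micro-extrema from measurement noise).
#'   Vertex pressures are still read from the unsmoothed samples.
#' @param smooth_width moving-average width in samples (default 11 = 44 ms at
#'   250 Hz; see the methods vignette for the choice).
#' @return tibble with case_id, beat_index, vertex (C/V/X/Y), found, time_s
#'   and pressure_mmhg.
#' @export
detect_vertices <- function(beats, smooth = TRUE, smooth_width = 11) {
  stopifnot(inherits(beats, "cvp_beats"))
  info <- beats$info
  nb <- nrow(info)
  nr <- 4L * nb
  found <- logical(nr); time_v <- rep(NA_real_, nr); press <- rep(NA_real_, nr)
  raw_start <- info$raw_start_s; fs_v <- info$fs
  r_times <- info$r_time; t_apexes <- info$t_apex_time; w_end <- info$window_end_s
  raws <- beats$raw
  for (i in seq_len(nb)) {
    x <- raws[[i]]
    tt <- raw_start[i] + (seq_along(x) - 1) / fs_v[i]
    xs <- if (smooth) moving_average(x, smooth_width) else x
    mx <- if (length(xs) >= 3) find_local_extrema(xs)$maxima else integer(0)
    o <- 4L * (i - 1L)
    r_time <- r_times[i]; t_apex <- t_apexes[i]
    # C: first local maximum strictly after the R wave
    c_cand <- mx[tt[mx] > r_time]
    if (length(c_cand)) {
      found[o + 1L] <- TRUE; time_v[o + 1L] <- tt[c_cand[1]]
      press[o + 1L] <- x[c_cand[1]]
    }
    # V: first local maximum strictly after the T apex
    v_cand <- if (is.na(t_apex)) integer(0) else mx[tt[mx] > t_apex]
    if (length(v_cand)) {
      found[o + 2L] <- TRUE; time_v[o + 2L] <- tt[v_cand[1]]
      press[o + 2L] <- x[v_cand[1]]
      t_v <- tt[v_cand[1]]
      xi <- which(tt > r_time & tt < t_v)        # X: global min in (R, V)
      if (length(xi)) {
        j <- xi[which.min(xs[xi])]
        found[o + 3L] <- TRUE; time_v[o + 3L] <- tt[j]; press[o + 3L] <- x[j]
      }
      yi <- which(tt > t_v & tt <= w_end[i])     # Y: global min after V
      if (length(yi)) {
        j <- yi[which.min(xs[yi])]
        found[o + 4L] <- TRUE; time_v[o + 4L] <- tt[j]; press[o + 4L] <- x[j]
      }
    }
  }
  tibble::tibble(
    case_id = rep(info$case_id, each = 4L),
    beat_index = rep(info$beat_index, each = 4L),
    vertex = rep(c("C", "V", "X", "Y"), nb),
    found = found, time_s = time_v, pressure_mmhg = press
  )
}

#' Per-case vertex detection rates
#'
#' Fraction of beats on which each vertex was found; used for quality gating
#' before the index statistics.
#'
#' @param vertices tibble from [detect_vertices()].
#' @return tibble with case_id, vertex, n_beats and rate. An empty input
#'   returns an empty table with a warning.
#' @export
summarize_detection <- function(vertices) {
  if (nrow(vertices) == 0) {
    warning("no beats to summarize")
    return(tibble::tibble(case_id = character(), vertex = character(),
                          n_beats = integer(), rate = numeric()))
  }
  dplyr::summarise(
    dplyr::group_by(vertices, .data$case_id, .data$vertex),
    n_beats = dplyr::n(), rate = mean(.data$found), .groups = "drop"
  )
}
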
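#' Segment a continuous CVP record into R-anchored beat windows
#'
#' For consecutive R times \eqn{R_i, R_{i+1}} with \eqn{RR = R_{i+1} - R_i},
#' each beat covers the window \eqn{[R_i - RR \cdot 5/16,\; R_{i+1} - RR \cdot 1/16]},
#' i.e. one full cycle from just before the P wave to just before the next
#' P wave with a margin. Window length is always \eqn{RR \cdot 20/16}. Beats
#' whose window extends past the recording are dropped. Each beat carries the
#' unique T-apex landmark falling strictly inside \eqn{(R_i, R_{i+1})} when one
#' exists; raw samples are taken half-open at the sample level, resampled to
#' `target_len` points by linear interpolation and min-max normalized.
#'
#' @param cohort a `cvp_cohort` (from [generate_cohort()] or [read_cohort()]).
#' @param case_ids optional subset of case ids to segment.
#' @param target_len length of the resampled beat (default 500).
#' @return An object of class `cvp_beats`: list with
#'   `info` (tibble: case_id, beat_index, window_start_s, window_end_s, r_time,
#'   next_r_time, t_apex_time), `raw` (list of mmHg sample vectors) and
#'   `norm` (matrix, one row per beat, `target_len` columns in \[0, 1\]).
#' @export
segment_beats <- function(cohort, case_ids = NULL, target_len = 500) {
  stopifnot(inherits(cohort, "cvp_cohort"))
  ids <- if (is.null(case_ids)) cohort$cases$case_id else case_ids
  info <- list(); raw <- list(); norm <- list()
  for (cid in ids) {
    wf <- cohort$waveforms[cohort$waveforms$case_id == cid, ]
    lm <- cohort$landmarks[cohort$landmarks$case_id == cid, ]
    r_times <- lm$time_s[lm$kind == "R"]
    t_times <- lm$time_s[lm$kind == "Tapex"]
    if (length(r_times) < 2) {
      warning("case ", cid, ": fewer than 2 R times; no beats segmented")
      next
    }
    if (any(diff(r_times) <= 0))
      stop("case ", cid, ": R times must be strictly increasing")
    seg <- segment_case(wf$time_s, wf$cvp_mmhg, r_times, t_times, cid, target_len)
    info[[cid]] <- seg$info; raw <- c(raw, seg$raw); norm[[cid]] <- seg$norm
  }
  info <- dplyr::bind_rows(info)
  norm <- do.call(rbind, norm)
  if (is.null(norm)) norm <- matrix(numeric(0), 0, target_len)
  structure(list(info = info, raw = raw, norm = norm), class = "cvp_beats")
}

segment_case <- function(time_s, cvp, r_times, t_times, case_id, target_len) {
  n <- length(time_s)
  t0 <- time_s[1]
  fs <- 1 / median(diff(time_s))
  nb <- length(r_times) - 1L
  beat_index <- integer(nb); ws_v <- we_v <- r1_v <- r2_v <- tap_v <- rs_v <- numeric(nb)
  raw <- vector("list", nb); norm <- vector("list", nb)
  kept <- 0L
  for (b in seq_len(nb)) {
    r1 <- r_times[b]; r2 <- r_times[b + 1L]
    rr <- r2 - r1
    ws <- r1 - rr * 5 / 16
    we <- r2 - rr * 1 / 16
    i0 <- ceiling((ws - t0) * fs - 1e-9) + 1L
    i1 <- ceiling((we - t0) * fs - 1e-9)  # half-open [ws, we) at the sample level
    if (i0 < 1L || i1 > n) next           # window extends past the recording
    x <- cvp[i0:i1]
    tap <- t_times[t_times > r1 & t_times < r2]
    kept <- kept + 1L
    beat_index[kept] <- b
    ws_v[kept] <- ws; we_v[kept] <- we; r1_v[kept] <- r1; r2_v[kept] <- r2
    tap_v[kept] <- if (length(tap) == 1) tap else NA_real_
    rs_v[kept] <- time_s[i0]
    raw[[kept]] <- x
    norm[[kept]] <- minmax_normalize(resample_beat(x, target_len))
  }
  keep <- seq_len(kept)
  list(
    info = tibble::tibble(
      case_id = case_id, beat_index = beat_index[keep],
      window_start_s = ws_v[keep], window_end_s = we_v[keep],
      r_time = r1_v[keep], next_r_time = r2_v[keep],
      t_apex_time = tap_v[keep], raw_start_s = rs_v[keep], fs = fs
    ),
    raw = raw[keep],
    norm = if (kept > 0) do.call(rbind, norm[keep]) else NULL
  )
}

#' Resample a beat to a fixed length by linear interpolation
#'
#' Interpolates the samples onto `target_len` uniformly spaced points spanning
#' the same window; endpoints are preserved, so linear ramps stay linear and a
#' length-`target_len` input is returned unchanged.
#'
#' @param raw numeric vector of at least 2 samples.
#' @param target_len output length (default 500).
#' @return numeric vector of length `target_len`.
#' @export
#' @examples
#' resample_beat(c(0, 10), target_len = 5)
resample_beat <- function(raw, target_len = 500) {
  if (length(raw) < 2) stop("resample_beat needs at least 2 samples")
  if (length(raw) == target_len) return(raw)
  approx(x = seq(0, 1, length.out = length(raw)), y = raw,
         xout = seq(0, 1, length.out = target_len))$y
}

#' Min-max normalize a sequence to \[0, 1\]
#'
#' Maps the minimum pressure to 0 and the maximum to 1 via
#' \eqn{(x - \min x) / (\max x - \min x)}. A constant sequence maps to all
#' zeros (such beats are also candidates for artifact rejection).
#'
#' @param x non-empty numeric vector.
#' @return numeric vector in \[0, 1\] of the same length.
#' @export
#' @examples
#' minmax_normalize(c(2, 6, 10))
minmax_normalize <- function(x) {
  if (length(x) == 0) stop("cannot normalize an empty sequence")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}
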
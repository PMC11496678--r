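#' Simulation configuration for synthetic CVP cohorts
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' generator writes 250 Hz CVP traces in which every cardiac cycle is a sum of
#' smooth Gaussian bumps (A, C and V waves) and troughs (X and Y descents) on a
#' baseline, together with sinus-rhythm R-wave and T-apex landmark times and a
#' ground-truth record of every programmed vertex. TR severity acts through
#' `grade_effects`: per-grade pressure offsets (mmHg) added to the C-wave
#' amplitude, the X-descent trough (raising it) and the V-wave amplitude, so
#' that the indices C-Y, X-Y and V-Y rise with grade.
#'
#' @param n_cases_per_grade integer; cases simulated per TR grade (length 1 or 5).
#' @param sampling_rate sampling frequency in Hz (default 250).
#' @param mean_rr mean RR interval in seconds.
#' @param rr_jitter fractional uniform jitter applied to each RR interval.
#' @param beats_per_case number of R waves per case; consecutive R pairs define
#'   `beats_per_case - 1` complete cycles.
#' @param grade_effects list with numeric vectors `c`, `x`, `v`, each of length
#'   5 (grades none..severe), giving the mmHg offset added to the C wave,
#'   X descent and V wave of that grade. Must be monotone non-decreasing.
#' @param noise_sd SD of additive white Gaussian pressure noise (mmHg).
#' @param case_sd SD of the per-case random offset applied to the C, X, V and Y
#'   amplitudes (between-case variability, mmHg).
#' @param beat_jitter fractional SD of per-beat amplitude jitter.
#' @param artifact_rate fraction of beats corrupted by an injected artifact.
#' @param artifact_kinds artifact kinds sampled for corrupted beats.
#' @param artifact_amplitude amplitude (mmHg) passed to [inject_artifact()].
#' @param t_frac T-apex placement as a fraction of the RR interval after R.
#' @param respiration_amp amplitude (mmHg) of an optional slow sinusoidal
#'   respiration drift; 0 disables it.
#' @param respiration_freq respiration frequency in Hz.
#' @param baseline mean CVP baseline (mmHg).
#' @param morphology data frame with columns `feature`, `frac`, `width`, `amp`:
#'   per-feature center and Gaussian width as fractions of RR, and amplitude in
#'   mmHg (negative for troughs). Defaults place A before the next R, C just
#'   after R, X between C and V, V after the T apex and Y after V.
#' @param seed integer RNG seed; the generator is deterministic given the seed.
#' @return An object of class `cvp_sim_config`.
#' @seealso [generate_cohort()], [write_cohort()]
#' @export
sim_config <- function(n_cases_per_grade = 6,
                       sampling_rate = 250,
                       mean_rr = 0.8,
                       rr_jitter = 0.05,
                       beats_per_case = 30,
                       grade_effects = default_grade_effects(),
                       noise_sd = 0.3,
                       case_sd = 0.8,
                       beat_jitter = 0.02,
                       artifact_rate = 0,
                       artifact_kinds = "spike",
                       artifact_amplitude = 20,
                       t_frac = 0.30,
                       respiration_amp = 0,
                       respiration_freq = 0.25,
                       baseline = 6,
                       morphology = default_morphology(),
                       seed = 1) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (artifact_rate < 0 || artifact_rate > 1) stop("artifact_rate must lie in [0, 1]")
  if (any(n_cases_per_grade < 0) || any(n_cases_per_grade != round(n_cases_per_grade)))
    stop("n_cases_per_grade must be non-negative integers")
  if (beats_per_case < 2) stop("beats_per_case must be at least 2")
  if (mean_rr <= 0) stop("mean_rr must be positive")
  if (rr_jitter < 0 || rr_jitter >= 1) stop("rr_jitter must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(is.list(grade_effects), all(c("c", "x", "v") %in% names(grade_effects)))
  for (nm in c("c", "x", "v")) {
    ge <- grade_effects[[nm]]
    if (length(ge) != 5) stop("grade_effects$", nm, " must have length 5")
    if (any(diff(ge) < 0))
      stop("grade_effects$", nm, " must be monotone non-decreasing across grades")
  }
  if (length(n_cases_per_grade) == 1) n_cases_per_grade <- rep(n_cases_per_grade, 5)
  if (length(n_cases_per_grade) != 5) stop("n_cases_per_grade must have length 1 or 5")
  stopifnot(all(artifact_kinds %in% c("spike", "flush", "damp")))
  cfg <- list(
    n_cases_per_grade = as.integer(n_cases_per_grade),
    sampling_rate = sampling_rate, mean_rr = mean_rr, rr_jitter = rr_jitter,
    beats_per_case = as.integer(beats_per_case), grade_effects = grade_effects,
    noise_sd = noise_sd, case_sd = case_sd, beat_jitter = beat_jitter,
    artifact_rate = artifact_rate, artifact_kinds = artifact_kinds,
    artifact_amplitude = artifact_amplitude, t_frac = t_frac,
    respiration_amp = respiration_amp, respiration_freq = respiration_freq,
    baseline = baseline, morphology = morphology, seed = as.integer(seed)
  )
  structure(cfg, class = "cvp_sim_config")
}

#' Default per-grade index offsets (mmHg)
#'
#' Monotone non-decreasing offsets added to the C wave, X descent and V wave
#' for grades none, trivial, mild, moderate and severe.
#' @return list with components `c`, `x`, `v`.
#' @export
default_grade_effects <- function() {
  list(
    c = c(0, 0.5, 1.0, 2.0, 3.0),
    x = c(0, 0.4, 0.9, 1.8, 3.0),
    v = c(0, 0.5, 1.2, 2.4, 4.0)
  )
}

#' Default beat morphology
#'
#' Gaussian component centers and widths as fractions of the RR interval,
#' amplitudes in mmHg (negative amplitudes are troughs). Placement satisfies the
#' vertex search windows by construction: A before the next R wave, C just
#' after R, X between C and V, V after the T apex (0.30 RR) and Y after V.
#' @return data frame with columns `feature`, `frac`, `width`, `amp`.
#' @export
default_morphology <- function() {
  data.frame(
    feature = c("A", "C", "X", "V", "Y"),
    frac    = c(0.88, 0.08, 0.25, 0.45, 0.65),
    width   = c(0.035, 0.030, 0.045, 0.050, 0.050),
    amp     = c(1.6, 2.2, -4.5, 2.2, -3.2)
  )
}

#' Generate a synthetic CVP cohort with ground truth
#'
#' Simulates `sum(n_cases_per_grade)` cases. Each case gets jittered sinus
#' R-wave times, T-apex landmarks at `t_frac` of each RR interval, and a CVP
#' trace built from the configured morphology with grade- and case-level
#' amplitude effects, optional respiration drift, white pressure noise and
#' injected artifacts. The returned `truth` table records, for every complete
#' cycle, the exact local extremum location/pressure of each programmed vertex
#' (computed on the noise-free trace) and an artifact flag.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `cvp_cohort`: a list with tibbles `cases`
#'   (case_id, tr_grade, age, sex), `waveforms` (case_id, time_s, cvp_mmhg),
#'   `landmarks` (case_id, kind, time_s) and `truth` (case_id, beat_index,
#'   vertex, time_s, pressure_mmhg, is_artifact).
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n_cases_per_grade = 1, beats_per_case = 5))
#' nrow(coh$cases)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cvp_sim_config"))
  with_seed(config$seed, {
    lev <- tr_grade_levels()
    cases <- list(); waves <- list(); marks <- list(); truth <- list()
    idx <- 0L
    for (g in seq_along(lev)) {
      for (r in seq_len(config$n_cases_per_grade[g])) {
        idx <- idx + 1L
        cid <- sprintf("case%03d", idx)
        rec <- simulate_case(cid, g - 1L, config)
        cases[[idx]] <- rec$case
        waves[[idx]] <- rec$waveform
        marks[[idx]] <- rec$landmarks
        truth[[idx]] <- rec$truth
      }
    }
    out <- list(
      cases = dplyr::bind_rows(cases),
      waveforms = dplyr::bind_rows(waves),
      landmarks = dplyr::bind_rows(marks),
      truth = dplyr::bind_rows(truth)
    )
    if (idx == 0L) out <- empty_cohort()
    structure(out, config = config, class = "cvp_cohort")
  })
}

empty_cohort <- function() {
  list(
    cases = tibble::tibble(case_id = character(), tr_grade = parse_tr_grade(character()),
                           age = numeric(), sex = character()),
    waveforms = tibble::tibble(case_id = character(), time_s = numeric(), cvp_mmhg = numeric()),
    landmarks = tibble::tibble(case_id = character(), kind = character(), time_s = numeric()),
    truth = tibble::tibble(case_id = character(), beat_index = integer(), vertex = character(),
                           time_s = numeric(), pressure_mmhg = numeric(), is_artifact = logical())
  )
}

# One case: landmark times, noise-free trace, truth vertices, then noise/artifacts.
simulate_case <- function(case_id, grade, config) {
  fs <- config$sampling_rate
  nrr <- config$beats_per_case - 1L
  rr <- config$mean_rr * (1 + config$rr_jitter * runif(nrr, -1, 1))
  lead_in <- 0.6
  r_times <- lead_in + c(0, cumsum(rr))
  t_apex <- r_times[seq_len(nrr)] + config$t_frac * rr
  duration <- r_times[length(r_times)] + 0.6
  n_samp <- floor(duration * fs) + 1L
  t <- (seq_len(n_samp) - 1) / fs

  base <- config$baseline + rnorm(1, 0, 1)
  case_eff <- c(A = 0, C = rnorm(1, 0, config$case_sd), X = rnorm(1, 0, config$case_sd),
                V = rnorm(1, 0, config$case_sd), Y = rnorm(1, 0, config$case_sd))
  ge <- config$grade_effects
  grade_eff <- c(A = 0, C = ge$c[grade + 1L], X = ge$x[grade + 1L],
                 V = ge$v[grade + 1L], Y = 0)

  morph <- config$morphology
  sig <- rep(base, n_samp)
  amps <- matrix(0, nrr, nrow(morph), dimnames = list(NULL, morph$feature))
  # leading A wave of the (virtual) cycle before the first R, so that the
  # first beat window carries the same pre-R morphology as every other beat
  fA <- match("A", morph$feature)
  if (!is.na(fA)) {
    centerA <- r_times[1] - (1 - morph$frac[fA]) * rr[1]
    wA <- morph$width[fA] * rr[1]
    loA <- max(1L, floor((centerA - 5 * wA) * fs) + 1L)
    hiA <- min(n_samp, ceiling((centerA + 5 * wA) * fs) + 1L)
    sig[loA:hiA] <- sig[loA:hiA] +
      morph$amp[fA] * exp(-(t[loA:hiA] - centerA)^2 / (2 * wA^2))
  }
  for (b in seq_len(nrr)) {
    for (f in seq_len(nrow(morph))) {
      feat <- morph$feature[f]
      amp <- (morph$amp[f] + grade_eff[[feat]] + case_eff[[feat]]) *
        (1 + rnorm(1, 0, config$beat_jitter))
      amps[b, f] <- amp
      center <- r_times[b] + morph$frac[f] * rr[b]
      w <- morph$width[f] * rr[b]
      lo <- max(1L, floor((center - 5 * w) * fs) + 1L)
      hi <- min(n_samp, ceiling((center + 5 * w) * fs) + 1L)
      tv <- t[lo:hi]
      sig[lo:hi] <- sig[lo:hi] + amp * exp(-(tv - center)^2 / (2 * w^2))
    }
  }
  if (config$respiration_amp > 0) {
    sig <- sig + config$respiration_amp * sin(2 * pi * config$respiration_freq * t)
  }

  # Truth: exact sampled extremum of the noise-free trace near each programmed center.
  is_art <- runif(nrr) < config$artifact_rate
  verts <- c("C", "X", "V", "Y")
  nt <- nrr * length(verts)
  t_beat <- integer(nt); t_vertex <- character(nt)
  t_time <- numeric(nt); t_press <- numeric(nt); t_art <- logical(nt)
  row <- 0L
  for (b in seq_len(nrr)) {
    for (feat in verts) {
      f <- match(feat, morph$feature)
      center <- r_times[b] + morph$frac[f] * rr[b]
      half <- 0.08 * rr[b]
      lo <- max(1L, floor((center - half) * fs) + 1L)
      hi <- min(n_samp, ceiling((center + half) * fs) + 1L)
      seg <- sig[lo:hi]
      k <- if (amps[b, f] >= 0) which.max(seg) else which.min(seg)
      i <- lo + k - 1L
      row <- row + 1L
      t_beat[row] <- b; t_vertex[row] <- feat
      t_time[row] <- t[i]; t_press[row] <- sig[i]; t_art[row] <- is_art[b]
    }
  }
  truth <- tibble::tibble(case_id = case_id, beat_index = t_beat,
                          vertex = t_vertex, time_s = t_time,
                          pressure_mmhg = t_press, is_artifact = t_art)

  if (config$noise_sd > 0) sig <- sig + rnorm(n_samp, 0, config$noise_sd)
  for (b in which(is_art)) {
    # corrupt the segmentation window of the beat so cleaning sees the artifact
    lo <- max(1L, floor((r_times[b] - rr[b] * 5 / 16) * fs) + 1L)
    hi <- min(n_samp, floor((r_times[b + 1L] - rr[b] / 16) * fs) + 1L)
    kind <- sample(config$artifact_kinds, 1)
    sig[lo:hi] <- inject_artifact(sig[lo:hi], kind,
                                  seed = sample.int(.Machine$integer.max, 1),
                                  amplitude = config$artifact_amplitude)
  }

  list(
    case = tibble::tibble(case_id = case_id, tr_grade = parse_tr_grade(grade),
                          age = round(runif(1, 30, 85)),
                          sex = sample(c("M", "F"), 1)),
    waveform = tibble::tibble(case_id = case_id, time_s = t, cvp_mmhg = sig),
    landmarks = tibble::tibble(
      case_id = case_id,
      kind = c(rep("R", length(r_times)), rep("Tapex", length(t_apex))),
      time_s = c(r_times, t_apex)
    ),
    truth = truth
  )
}

#' Inject an artifact into a beat's pressure samples
#'
#' Returns a corrupted copy of `x`; the input is not modified. `spike` adds a
#' narrow high-amplitude transient (the peak sample exceeds the original by
#' exactly `amplitude`), `flush` replaces a contiguous span with a high
#' plateau (as from a catheter flush), and `damp` low-pass-blurs the beat and
#' compresses its amplitude about the mean (over-damped line).
#'
#' @param x numeric pressure samples (mmHg), non-empty.
#' @param kind one of `"spike"`, `"flush"`, `"damp"`.
#' @param seed integer seed; the corruption is deterministic given the seed.
#' @param amplitude artifact amplitude in mmHg (spike height / flush level).
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' beat <- rep(10, 100)
#' spiky <- inject_artifact(beat, "spike", seed = 1)
#' sum(spiky > 10)
inject_artifact <- function(x, kind, seed = 1, amplitude = 20) {
  if (length(x) == 0) stop("beat samples must be non-empty")
  kind <- match.arg(kind, c("spike", "flush", "damp"))
  with_seed(seed, {
    n <- length(x)
    out <- x
    if (kind == "spike") {
      # central placement: beat windows of adjacent beats overlap by 20% on
      # each side, so artifacts stay inside their own beat's exclusive span
      c0 <- sample(seq(max(1L, floor(0.25 * n)), max(1L, ceiling(0.75 * n))), 1)
      out[c0] <- out[c0] + amplitude
      for (d in c(-1L, 1L)) {
        j <- c0 + d
        if (j >= 1L && j <= n) out[j] <- out[j] + amplitude / 2
      }
    } else if (kind == "flush") {
      len <- max(2L, floor(n * runif(1, 0.25, 0.45)))
      lo <- max(1L, floor(0.22 * n))
      hi <- max(lo, min(n - len + 1L, ceiling(0.78 * n) - len))
      start <- if (hi > lo) sample(lo:hi, 1) else lo
      out[start:(start + len - 1L)] <- max(x) + 0.75 * amplitude
    } else { # damp
      w <- max(3L, min(n - (n + 1L) %% 2L, 25L))
      if (w %% 2L == 0L) w <- w - 1L
      pad <- (w - 1L) %/% 2L
      xp <- c(rep(x[1], pad), x, rep(x[n], pad))
      sm <- as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(pad + 1L):(pad + n)]
      out <- mean(x) + 0.35 * (sm - mean(x))
    }
    out
  })
}

#' Write a cohort to CSV tables
#'
#' Emits `waveforms.csv`, `landmarks.csv`, `cases.csv` and (when ground truth
#' is present) `truth.csv` in the documented comma-separated, UTF-8, headered
#' dialect. The files round-trip through [read_cohort()].
#'
#' @param cohort a `cvp_cohort` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cvp_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  cases <- dplyr::mutate(cohort$cases, tr_grade = as.character(.data$tr_grade))
  readr::write_csv(cases, file.path(dir, "cases.csv"))
  readr::write_csv(cohort$waveforms, file.path(dir, "waveforms.csv"))
  readr::write_csv(cohort$landmarks, file.path(dir, "landmarks.csv"))
  if (!is.null(cohort$truth)) readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Per-beat index values implied by the ground-truth vertices
#'
#' Convenience accessor used in validation: computes `v_minus_y`, `x_minus_y`
#' and `c_minus_y` (mmHg) from the generator's truth table.
#'
#' @param cohort a `cvp_cohort` with a `truth` table.
#' @return tibble with case_id, beat_index, is_artifact and the three indices.
#' @export
truth_indices <- function(cohort) {
  stopifnot(inherits(cohort, "cvp_cohort"), !is.null(cohort$truth))
  wide <- tidyr::pivot_wider(cohort$truth,
    id_cols = c("case_id", "beat_index", "is_artifact"),
    names_from = "vertex", values_from = "pressure_mmhg"
  )
  dplyr::transmute(wide,
    case_id = .data$case_id, beat_index = .data$beat_index,
    is_artifact = .data$is_artifact,
    v_minus_y = .data$V - .data$Y,
    x_minus_y = .data$X - .data$Y,
    c_minus_y = .data$C - .data$Y
  )
}
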
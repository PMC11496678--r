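# Shared synthetic fixtures, built in code at test time.

quiet_cohort <- function(n_per_grade = 1, beats = 8, noise_sd = 0, seed = 5, ...) {
  generate_cohort(sim_config(
    n_cases_per_grade = n_per_grade, beats_per_case = beats,
    noise_sd = noise_sd, beat_jitter = 0, case_sd = 0, seed = seed, ...
  ))
}

# Two-class cohort for the classifier: severe beats get a 3x V-wave amplitude.
separable_cohort <- function(n_per_class, beats, seed = 11) {
  ge <- list(c = rep(0, 5), x = rep(0, 5), v = c(0, 0, 0, 0, 4.4))
  generate_cohort(sim_config(
    n_cases_per_grade = c(n_per_class, 0, 0, 0, n_per_class),
    beats_per_case = beats, grade_effects = ge, seed = seed
  ))
}

beats_and_labels <- function(cohort) {
  b <- segment_beats(cohort)
  cid <- b$info$case_id
  grade <- cohort$cases$tr_grade[match(cid, cohort$cases$case_id)]
  list(beats = b, case_id = cid,
       y = factor(ifelse(grade == "severe", "severe", "none"),
                  levels = c("none", "severe")))
}

# Brute-force SBD oracle: explicit max over all shifts of the normalized
# cross-correlation (independent of the FFT implementation).
sbd_bruteforce <- function(x, y) {
  zn <- function(v) if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v)
  x <- zn(x); y <- zn(y)
  L <- length(x)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(1)
  best <- -Inf
  for (s in -(L - 1):(L - 1)) {
    ys <- if (s >= 0) c(rep(0, s), y[seq_len(L - s)]) else c(y[(1 - s):L], rep(0, -s))
    best <- max(best, sum(x * ys))
  }
  1 - best / (nx * ny)
}
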
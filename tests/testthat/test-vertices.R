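test_that("local extrema: single peak, monotone ramp, plateau collapse", {
  expect_equal(find_local_extrema(c(0, 1, 0)),
               list(maxima = 2L, minima = integer(0)))
  expect_equal(find_local_extrema(1:10),
               list(maxima = integer(0), minima = integer(0)))
  expect_equal(find_local_extrema(c(0, 1, 1, 0))$maxima, 2L)  # floor rule
  expect_equal(find_local_extrema(c(0, 1, 1, 1, 0))$maxima, 3L)
  expect_equal(find_local_extrema(c(2, 0, 0, 2))$minima, 2L)
  expect_error(find_local_extrema(c(1, 2)), "at least 3")
})

test_that("plateau collapse matches an enumeration oracle on small sequences", {
  # oracle: compress runs, mark strict interior extrema, map to plateau centre
  oracle <- function(x) {
    r <- rle(x); st <- cumsum(c(1, head(r$lengths, -1)))
    mx <- integer(0); mn <- integer(0)
    if (length(r$values) >= 3) {
      for (j in 2:(length(r$values) - 1)) {
        ctr <- st[j] + (r$lengths[j] - 1) %/% 2
        if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1]) mx <- c(mx, ctr)
        if (r$values[j] < r$values[j - 1] && r$values[j] < r$values[j + 1]) mn <- c(mn, ctr)
      }
    }
    list(maxima = mx, minima = mn)
  }
  set.seed(6)
  for (i in 1:200) {
    x <- sample(0:2, sample(3:8, 1), replace = TRUE)
    expect_equal(find_local_extrema(x), oracle(x), ignore_attr = TRUE)
  }
})

test_that("noise-free synthetic beats are recovered within one sample", {
  coh <- quiet_cohort(n_per_grade = 1, beats = 8, seed = 5)
  b <- segment_beats(coh)
  v <- detect_vertices(b, smooth = FALSE)
  m <- merge(as.data.frame(v), as.data.frame(coh$truth),
             by = c("case_id", "beat_index", "vertex"))
  expect_true(all(m$found))
  expect_lte(max(abs(m$time_s.x - m$time_s.y)), 1 / 250 + 1e-9)
  expect_equal(m$pressure_mmhg.x, m$pressure_mmhg.y, tolerance = 1e-9)
})

test_that("vertex order and pressure invariants hold on noisy cohorts", {
  coh <- generate_cohort(sim_config(n_cases_per_grade = 1, beats_per_case = 12,
                                    seed = 23))
  b <- segment_beats(coh)
  v <- detect_vertices(b)
  w <- tidyr::pivot_wider(v, id_cols = c("case_id", "beat_index"),
                          names_from = "vertex",
                          values_from = c("found", "time_s", "pressure_mmhg"))
  ok <- w$found_C & w$found_V & w$found_X & w$found_Y
  i <- merge(w[ok, ], b$info, by = c("case_id", "beat_index"))
  expect_true(all(i$time_s_C > i$r_time))
  expect_true(all(i$time_s_V > i$t_apex_time))
  expect_true(all(i$time_s_X > i$r_time & i$time_s_X < i$time_s_V))
  expect_true(all(i$time_s_Y > i$time_s_V))
  expect_true(all(i$pressure_mmhg_X <= i$pressure_mmhg_C))
  expect_true(all(i$pressure_mmhg_Y <= i$pressure_mmhg_V))
})

test_that("a beat with no maximum after the T apex cascades missing flags", {
  # monotone decay after the T apex: V unsatisfiable, X and Y depend on it
  fs <- 250
  tt <- seq(0, 2, by = 1 / fs)
  x <- 10 - 3 * tt + 0.5 * exp(-((tt - 0.55) / 0.02)^2)  # one max after R only
  beats <- structure(list(
    info = tibble::tibble(case_id = "c", beat_index = 1L, window_start_s = 0,
                          window_end_s = 2, r_time = 0.5, next_r_time = 1.5,
                          t_apex_time = 0.8, raw_start_s = 0, fs = fs),
    raw = list(x), norm = matrix(minmax_normalize(x), 1)
  ), class = "cvp_beats")
  v <- detect_vertices(beats, smooth = FALSE)
  expect_true(v$found[v$vertex == "C"])
  expect_false(any(v$found[v$vertex %in% c("V", "X", "Y")]))
})

test_that("the closest maximum after an anchor is the first one", {
  fs <- 250
  tt <- seq(0, 1, by = 1 / fs)
  x <- exp(-((tt - 0.34) / 0.01)^2) + 2 * exp(-((tt - 0.42) / 0.01)^2)
  beats <- structure(list(
    info = tibble::tibble(case_id = "c", beat_index = 1L, window_start_s = 0,
                          window_end_s = 1, r_time = 0.3, next_r_time = 0.9,
                          t_apex_time = NA_real_, raw_start_s = 0, fs = fs),
    raw = list(x), norm = matrix(minmax_normalize(x), 1)
  ), class = "cvp_beats")
  v <- detect_vertices(beats, smooth = FALSE)
  # C at +40 ms, not the larger maximum at +120 ms
  expect_equal(v$time_s[v$vertex == "C"], 0.34, tolerance = 2 / fs)
})

test_that("detection-rate summaries respect the dependency structure", {
  v <- tibble::tibble(
    case_id = "c", beat_index = rep(1:4, each = 4),
    vertex = rep(c("C", "V", "X", "Y"), 4),
    found = rep(TRUE, 16), time_s = 1, pressure_mmhg = 5)
  v$found[v$beat_index == 2 & v$vertex %in% c("V", "X", "Y")] <- FALSE
  s <- summarize_detection(v)
  expect_equal(s$rate[s$vertex == "C"], 1)
  expect_equal(s$rate[s$vertex == "V"], 0.75)
  expect_lte(s$rate[s$vertex == "X"], 0.75)
  expect_warning(empty <- summarize_detection(v[0, ]), "no beats")
  expect_equal(nrow(empty), 0)
})
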
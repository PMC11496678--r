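test_that("per-beat indices subtract pressures and cases aggregate by median", {
  v <- tibble::tibble(
    case_id = "c1", beat_index = rep(1:3, each = 4),
    vertex = rep(c("C", "V", "X", "Y"), 3),
    found = TRUE,
    time_s = 1,
    pressure_mmhg = c(10, 12, 6, 4,   9, 11, 5, 4,   40, 104, 30, 4))
  v$found[v$beat_index == 2 & v$vertex == "Y"] <- FALSE  # drops all 3 indices
  idx <- compute_indices(v, tibble::tibble(case_id = "c1",
                                           tr_grade = parse_tr_grade("mild")))
  b1 <- idx$beats[idx$beats$beat_index == 1, ]
  expect_equal(b1$v_minus_y, 8)
  expect_equal(b1$x_minus_y, 2)
  expect_equal(b1$c_minus_y, 6)
  expect_true(all(is.na(idx$beats[idx$beats$beat_index == 2,
                                  c("v_minus_y", "x_minus_y", "c_minus_y")])))
  # median over beats 1 and 3: robust to the outlier beat
  expect_equal(idx$cases$v_minus_y, median(c(8, 100)))
  expect_equal(idx$cases$c_minus_y, median(c(6, 36)))
})

test_that("Jonckheere-Terpstra matches exact enumeration on canonical layouts", {
  r <- jonckheere_terpstra(c(1, 2, 3), gl(3, 1), method = "exact")
  expect_equal(r$J, 3)
  expect_equal(r$p_value, 1 / 6)
  rev <- jonckheere_terpstra(c(3, 2, 1), gl(3, 1), method = "exact")
  expect_equal(rev$J, 0)
  expect_equal(rev$p_value, 1)
  # normal approximation on the reversed trend: p near 1
  rn <- jonckheere_terpstra(c(3, 2, 1), gl(3, 1))
  expect_gte(rn$p_value, 0.8)
  expect_error(jonckheere_terpstra(1:4, gl(2, 2)), "3 non-empty groups")
})

test_that("the decreasing alternative mirrors the increasing one", {
  x <- c(5, 4, 4, 3, 2, 1)
  g <- gl(3, 2)
  inc <- jonckheere_terpstra(x, g, "increasing")
  dec <- jonckheere_terpstra(x, g, "decreasing")
  expect_lt(dec$p_value, 0.1)
  expect_gt(inc$p_value, 0.9)
})

test_that("Steel-Dwass: no separation, two-group reduction, extreme pair", {
  set.seed(12)
  x <- rnorm(30)
  g <- gl(3, 10)
  same <- steel_dwass(rep(x[1:10], 3), g)
  expect_true(all(same$p_value > 0.99))
  # two groups: adjusted p equals the two-sided normal Wilcoxon p
  x2 <- c(rnorm(8), rnorm(8, 1))
  g2 <- gl(2, 8)
  sd2 <- steel_dwass(x2, g2)
  r <- rank(x2); W <- sum(r[1:8])
  z <- (W - 8 * 17 / 2) / sqrt(8 * 8 / (16 * 15) * (sum(r^2) - 16 * 17^2 / 4))
  expect_equal(sd2$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-9)
  # the far pair has the smallest adjusted p
  x3 <- c(1, 2, 3, 101, 102, 103, 1.5, 2.5, 3.5)
  g3 <- factor(rep(c("a", "b", "c"), each = 3))
  sd3 <- steel_dwass(x3, g3)
  far <- sd3$p_value[sd3$group1 == "a" & sd3$group2 == "b"]
  expect_equal(far, min(sd3$p_value))
  expect_warning(steel_dwass(c(1, 2, 3, 4), factor(c("a", "a", "a", "b"))),
                 "skipped")
})

test_that("ROC: perfect separation, Youden ties, Hanley degeneracies", {
  r <- roc_analysis(c(0, 1, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_error(roc_analysis(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
  h1 <- hanley_ci(1, 10, 20)
  expect_equal(h1$se, 0)
  expect_equal(h1$ci, c(1, 1))
  h5 <- hanley_ci(0.5, 15, 15)
  expect_equal(mean(h5$ci), 0.5)  # symmetric about 0.5
})

test_that("ROC against pROC on random data (independent cross-check)", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:5) {
    v <- rnorm(40)
    lab <- runif(40) < 0.4
    if (!any(lab) || all(lab)) next
    ours <- roc_analysis(v, lab)
    ref <- pROC::roc(response = lab, predictor = v, direction = "<",
                     quiet = TRUE)
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
    yj <- pROC::coords(ref, "best", best.method = "youden", transpose = FALSE)
    expect_equal(ours$sensitivity + ours$specificity,
                 max(yj$sensitivity + yj$specificity), tolerance = 1e-10)
  }
})

test_that("index_statistics gates follow-up analyses on the trend p-value", {
  set.seed(33)
  grades <- parse_tr_grade(rep(0:4, each = 10))
  cases <- tibble::tibble(
    case_id = sprintf("c%02d", 1:50), tr_grade = grades,
    v_minus_y = rnorm(50),                              # no trend
    x_minus_y = as.integer(grades) + rnorm(50, 0, 0.3), # strong trend
    c_minus_y = as.integer(grades) + rnorm(50, 0, 0.5),
    n_beats = 10L)
  idx <- structure(list(beats = NULL, cases = cases), class = "cvp_indices")
  st <- index_statistics(idx)
  expect_equal(nrow(st$trend), 3)
  expect_true("x_minus_y" %in% names(st$roc))
  expect_false("v_minus_y" %in% names(st$roc))
  expect_equal(nrow(st$pairwise$x_minus_y), choose(5, 2))
})
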
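#' Jonckheere-Terpstra trend test across ordered groups
#'
#' Tests for a monotone trend of `x` across the ordered levels of `g`. The
#' statistic is \eqn{J = \sum_{i<j} [\#(x_a < x_b) + \tfrac12 \#(x_a = x_b)]}
#' over all pairs with \eqn{x_a} from the lower-ordered and \eqn{x_b} from the
#' higher-ordered group. Inference uses the normal approximation with the
#' tie-corrected null variance and (by default) a 0.5 continuity correction,
#' which keeps the approximation within 0.02 of the exact permutation p-value
#' down to very small samples; `method = "exact"` enumerates all distinct
#' label permutations (feasible for total n up to ~10) and is used as the
#' internal oracle.
#'
#' @param x numeric values.
#' @param g ordered grouping factor (or coercible); at least 3 non-empty
#'   groups are required.
#' @param alternative `"increasing"` (one-sided, the default: values rise with
#'   group order) or `"decreasing"`.
#' @param method `"normal"` or `"exact"`.
#' @param continuity apply the 0.5 continuity correction (normal method).
#' @return list of class `jt_test`: statistic `J`, `null_mean`, `null_var`
#'   (tie-corrected), `z`, one-sided `p_value`, `method`, `alternative`.
#' @export
#' @examples
#' jonckheere_terpstra(c(1, 2, 3), gl(3, 1), method = "exact")$p_value  # 1/6
jonckheere_terpstra <- function(x, g,
                                alternative = c("increasing", "decreasing"),
                                method = c("normal", "exact"),
                                continuity = TRUE) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  g <- if (is.factor(g)) droplevels(g) else factor(g)
  if (nlevels(g) < 3) stop("Jonckheere-Terpstra requires at least 3 non-empty groups")
  if (alternative == "decreasing") {
    g <- factor(g, levels = rev(levels(g)))
  }
  J <- jt_statistic(x, g)
  n <- as.numeric(table(g)); N <- length(x)
  EJ <- (N^2 - sum(n^2)) / 4
  tt <- as.numeric(table(x))
  VJ <- (N * (N - 1) * (2 * N + 5) - sum(n * (n - 1) * (2 * n + 5)) -
           sum(tt * (tt - 1) * (2 * tt + 5))) / 72 +
    sum(n * (n - 1) * (n - 2)) * sum(tt * (tt - 1) * (tt - 2)) /
      (36 * N * (N - 1) * (N - 2)) +
    sum(n * (n - 1)) * sum(tt * (tt - 1)) / (8 * N * (N - 1))
  if (method == "exact") {
    p <- jt_exact_p(x, g)
    z <- NA_real_
  } else {
    # continuity correction for the lattice statistic: P(J >= j) ~ P(Z >= (j - 1/2 - EJ)/sd)
    cc <- if (continuity) 0.5 else 0
    z <- if (VJ > 0) (J - cc - EJ) / sqrt(VJ) else 0
    p <- pnorm(z, lower.tail = FALSE)
  }
  structure(list(J = J, null_mean = EJ, null_var = VJ, z = z, p_value = p,
                 method = method, alternative = alternative,
                 group_sizes = n), class = "jt_test")
}

jt_statistic <- function(x, g) {
  lev <- levels(g)
  J <- 0
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (i < j) {
        xi <- x[g == lev[i]]; xj <- x[g == lev[j]]
        J <- J + sum(outer(xi, xj, "<")) + 0.5 * sum(outer(xi, xj, "=="))
      }
    }
  }
  J
}

# Exact permutation p-value P(J >= J_obs) by full enumeration of distinct
# assignments of the observations to the groups.
jt_exact_p <- function(x, g) {
  N <- length(x)
  if (N > 10) stop("exact enumeration is limited to total n <= 10")
  Cmat <- outer(x, x, "<") + 0.5 * outer(x, x, "==")
  gi <- as.integer(g)
  J0 <- sum(Cmat[outer(gi, gi, "<")])
  perms <- permutations_of(seq_len(N))
  Js <- apply(perms, 1, function(p) {
    gp <- gi[p]
    sum(Cmat[outer(gp, gp, "<")])
  })
  mean(Js >= J0 - 1e-9)
}

permutations_of <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1))
  out <- vector("list", n)
  for (k in seq_len(n)) out[[k]] <- cbind(v[k], permutations_of(v[-k]))
  do.call(rbind, out)
}

#' Steel-Dwass all-pairs nonparametric comparisons
#'
#' For every pair of groups the two-sample midrank (Wilcoxon) statistic is
#' standardized by its tie-corrected null variance, and the familywise
#' adjusted p-value is taken from the studentized-range distribution with `k`
#' groups and infinite degrees of freedom:
#' \eqn{p = P(Q_{k,\infty} \ge |t|\sqrt{2})}. With two groups this reduces to
#' the two-sided normal-approximation Wilcoxon test.
#'
#' @param x numeric values.
#' @param g grouping factor with at least 2 non-empty groups.
#' @return tibble with group1, group2, statistic (standardized), and adjusted
#'   `p_value`; a pair involving a group with fewer than 2 values is skipped
#'   with a warning.
#' @export
steel_dwass <- function(x, g) {
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(factor(g, levels = if (is.factor(g)) levels(g) else sort(unique(g))))
  lev <- levels(g)
  k <- length(lev)
  if (k < 2) stop("Steel-Dwass requires at least 2 groups")
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xi <- x[g == lev[i]]; xj <- x[g == lev[j]]
      if (length(xi) < 2 || length(xj) < 2) {
        warning("pair ", lev[i], " vs ", lev[j], " skipped: fewer than 2 values in a group")
        next
      }
      ni <- length(xi); nj <- length(xj); N <- ni + nj
      r <- rank(c(xi, xj))
      W <- sum(r[seq_len(ni)])
      E <- ni * (N + 1) / 2
      V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
      tstat <- if (V > 0) (W - E) / sqrt(V) else 0
      p <- ptukey(abs(tstat) * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
      out[[length(out) + 1]] <- tibble::tibble(
        group1 = lev[i], group2 = lev[j], statistic = tstat, p_value = p)
    }
  }
  dplyr::bind_rows(out)
}

#' ROC analysis with Youden cutoff and Hanley confidence interval
#'
#' Discriminates positives from negatives by a continuous marker where higher
#' values indicate the positive class. The AUC is computed by pairwise
#' comparison with ties counted 1/2 (equal to the trapezoidal area under the
#' empirical ROC curve); the cutoff maximizes the Youden index
#' (sensitivity + specificity − 1) over all midpoints between adjacent sorted
#' unique values, ties broken toward the lower cutoff; the 95% CI uses the
#' Hanley standard error ([hanley_ci()]).
#'
#' @param values numeric marker (e.g. per-case median index, mmHg).
#' @param positive logical vector, TRUE for the positive class (e.g. severe
#'   TR), same length as `values`.
#' @return list of class `roc_result`: `auc`, `ci` (lower, upper), `se`, `q1`,
#'   `q2`, `cutoff`, `sensitivity`, `specificity`, `youden`, `n_pos`, `n_neg`,
#'   and `points` (tibble of ROC coordinates, one row per candidate cutoff).
#' @export
roc_analysis <- function(values, positive) {
  stopifnot(length(values) == length(positive))
  keep <- !is.na(values) & !is.na(positive)
  values <- values[keep]; positive <- as.logical(positive)[keep]
  pos <- values[positive]; neg <- values[!positive]
  if (length(pos) == 0 || length(neg) == 0) stop("both classes must be non-empty")
  auc <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
  sv <- sort(unique(values))
  cuts <- c(min(sv) - 1,
            if (length(sv) > 1) (head(sv, -1) + tail(sv, -1)) / 2 else numeric(0),
            max(sv) + 1)
  pts <- lapply(cuts, function(ct) {
    tibble::tibble(cutoff = ct,
                   sensitivity = mean(pos > ct),
                   specificity = mean(neg <= ct))
  })
  pts <- dplyr::bind_rows(pts)
  pts$youden <- pts$sensitivity + pts$specificity - 1
  best <- which(pts$youden == max(pts$youden))[1]  # ties: lower cutoff
  ci <- hanley_ci(auc, length(pos), length(neg))
  structure(list(
    auc = auc, ci = ci$ci, se = ci$se, q1 = ci$q1, q2 = ci$q2,
    cutoff = pts$cutoff[best], sensitivity = pts$sensitivity[best],
    specificity = pts$specificity[best], youden = pts$youden[best],
    n_pos = length(pos), n_neg = length(neg), points = pts
  ), class = "roc_result")
}

#' Hanley standard error and 95% confidence interval for an AUC
#'
#' Uses \eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)} and
#' \deqn{SE = \sqrt{\frac{A(1-A) + (n_+-1)(Q_1-A^2) + (n_--1)(Q_2-A^2)}{n_+ n_-}}}
#' with the interval \eqn{A \pm 1.96\,SE} (not clamped to \[0, 1\]).
#'
#' @param auc area under the ROC curve, in \[0, 1\].
#' @param n_pos,n_neg positive / negative class sizes (at least 1 each).
#' @return list with `se`, `q1`, `q2` and `ci` = c(lower, upper).
#' @export
#' @examples
#' round(hanley_ci(0.83, 11, 425)$ci, 2)
hanley_ci <- function(auc, n_pos, n_neg) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  list(se = se, q1 = q1, q2 = q2, ci = c(auc - 1.96 * se, auc + 1.96 * se))
}

#' Run the full index statistics stage
#'
#' Applies the one-sided increasing-trend test to each index across the five
#' TR grades, the all-pairs comparisons for indices whose trend is significant
#' at `alpha`, and the ROC analysis of severe vs none-to-moderate for indices
#' with a significant trend.
#'
#' @param indices a `cvp_indices` object from [compute_indices()].
#' @param alpha significance level gating the follow-up analyses (default 0.05).
#' @return list with tibble `trend` (index, J, z, p_value), list `pairwise`
#'   (per significant index, the [steel_dwass()] table) and list `roc` (per
#'   significant index, the [roc_analysis()] result).
#' @export
index_statistics <- function(indices, alpha = 0.05) {
  stopifnot(inherits(indices, "cvp_indices"))
  cs <- indices$cases
  if (!"tr_grade" %in% names(cs)) stop("case table lacks tr_grade")
  idx_names <- c("v_minus_y", "x_minus_y", "c_minus_y")
  trend <- list(); pairwise <- list(); roc <- list()
  for (nm in idx_names) {
    ok <- !is.na(cs[[nm]]) & !is.na(cs$tr_grade)
    jt <- jonckheere_terpstra(cs[[nm]][ok], cs$tr_grade[ok])
    trend[[nm]] <- tibble::tibble(index = nm, J = jt$J, z = jt$z, p_value = jt$p_value)
    if (jt$p_value < alpha) {
      pairwise[[nm]] <- steel_dwass(cs[[nm]][ok], cs$tr_grade[ok])
      roc[[nm]] <- roc_analysis(cs[[nm]][ok], cs$tr_grade[ok] == "severe")
    }
  }
  list(trend = dplyr::bind_rows(trend), pairwise = pairwise, roc = roc)
}
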
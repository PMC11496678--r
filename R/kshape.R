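#' Shape-based distance (SBD) between two sequences
#'
#' Distance used by k-Shape: \eqn{1 - \max_w NCC_c(x, y; w)}, where
#' \eqn{NCC_c} is the cross-correlation normalized by \eqn{\|x\|\|y\|} over all
#' integer alignments \eqn{w}. Sequences are z-normalized first (k-Shape
#' convention), making the distance invariant to shift and positive scaling;
#' values lie in \[0, 2\]. A zero-norm (constant) input yields distance 1.
#'
#' @param x,y numeric vectors of equal length.
#' @param znorm z-normalize inputs before computing the distance (default TRUE).
#' @return a single distance in \[0, 2\].
#' @export
#' @examples
#' sbd(sin(1:100), 2 * sin(1:100))  # scale invariance: 0
sbd <- function(x, y, znorm = TRUE) {
  if (length(x) != length(y)) stop("sbd requires equal-length sequences")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("sbd requires finite inputs")
  if (znorm) { x <- znorm_seq(x); y <- znorm_seq(y) }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(1)
  1 - max(cross_correlate(x, y)) / (nx * ny)
}

znorm_seq <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Full cross-correlation sequence CC_w(x, y), w = -(L-1)..(L-1), via FFT.
# Element k of the result corresponds to shifting y right by w = k - L.
cross_correlate <- function(x, y) {
  L <- length(x)
  n <- 2^ceiling(log2(2 * L - 1))
  fx <- stats::fft(c(x, rep(0, n - L)))
  fy <- stats::fft(c(y, rep(0, n - L)))
  cc <- Re(stats::fft(fx * Conj(fy), inverse = TRUE)) / n
  c(cc[(n - L + 2):n], cc[1:L])  # order w = -(L-1) .. (L-1)
}

# Best alignment of y onto x: shift maximizing the cross-correlation.
sbd_shift <- function(x, y) {
  cc <- cross_correlate(x, y)
  which.max(cc) - length(x)
}

shift_seq <- function(y, s) {
  L <- length(y)
  if (s == 0) return(y)
  if (s > 0) c(rep(0, s), y[1:(L - s)]) else c(y[(1 - s):L], rep(0, -s))
}

# Shape extraction: centroid maximizing the summed squared NCC to the (aligned)
# cluster members = leading eigenvector of Q M Q with M = A'A and Q the
# centering projector. Computed by power iteration without forming Q M Q.
shape_extraction <- function(A, cur = NULL) {
  L <- ncol(A)
  if (nrow(A) == 0) return(rep(0, L))
  if (!is.null(cur) && any(cur != 0)) {
    A <- t(apply(A, 1, function(y) shift_seq(y, sbd_shift(cur, y))))
  }
  A <- t(apply(A, 1, znorm_seq))
  v <- if (!is.null(cur) && any(cur != 0)) cur else A[1, ]
  if (all(v == 0)) v <- rep(1, L)
  v <- v / sqrt(sum(v^2))
  for (it in 1:100) {
    w <- v - mean(v)               # Q v
    w <- as.numeric(crossprod(A, A %*% w))
    w <- w - mean(w)               # Q M Q v
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    if (sum((w - v)^2) < 1e-24 || sum((w + v)^2) < 1e-24) { v <- w; break }
    v <- w
  }
  cen <- znorm_seq(v)
  if (all(cen == 0)) return(cen)
  if (sum(A %*% cen) < 0) cen <- -cen  # sign: correlate positively with members
  cen
}

#' k-Shape clustering of fixed-length beat sequences
#'
#' Iterative partitional clustering under the shape-based distance:
#' assignment to the nearest centroid by [sbd()] alternates with
#' shape-extraction centroid updates until the assignment is stable or
#' `max_iter` is reached. Deterministic given `seed`. An empty cluster is
#' reseeded from the beat farthest from its current centroid.
#'
#' @param x numeric matrix, one sequence per row (all rows the same length).
#' @param k number of clusters, \eqn{1 \le k \le nrow(x)}.
#' @param seed integer seed for the random initial assignment.
#' @param max_iter maximum assignment/update iterations.
#' @return list with `cluster` (integer vector), `centroids` (k x L matrix of
#'   z-normalized shapes), `sbd` (distance of each row to its centroid) and
#'   `iterations`.
#' @export
kshape_cluster <- function(x, k, seed = 1, max_iter = 50) {
  x <- as.matrix(x)
  n <- nrow(x); L <- ncol(x)
  if (k < 1 || k > n) stop("k must lie in [1, nrow(x)]")
  xz <- t(apply(x, 1, znorm_seq))
  with_seed(seed, {
    cl <- sample(rep_len(seq_len(k), n))
    cen <- matrix(0, k, L)
    d <- matrix(0, n, k)
    iterations <- 0L
    for (it in seq_len(max_iter)) {
      iterations <- it
      for (j in seq_len(k)) {
        members <- xz[cl == j, , drop = FALSE]
        if (nrow(members) == 0) next
        cen[j, ] <- shape_extraction(members, if (it > 1) cen[j, ] else NULL)
      }
      for (j in seq_len(k)) d[, j] <- apply(xz, 1, function(r) sbd(r, cen[j, ], znorm = FALSE))
      new_cl <- apply(d, 1, which.min)
      for (j in seq_len(k)) {               # reseed empty clusters
        if (!any(new_cl == j)) {
          far <- which.max(d[cbind(seq_len(n), new_cl)])
          cen[j, ] <- xz[far, ]
          new_cl[far] <- j
        }
      }
      if (all(new_cl == cl) && it > 1) break
      cl <- new_cl
    }
    list(cluster = cl, centroids = cen,
         sbd = d[cbind(seq_len(n), cl)], iterations = iterations)
  })
}

#' Flag artifact beats from a k-Shape clustering
#'
#' A beat is flagged as an artifact if (a) it belongs to a minority cluster
#' whose size fraction is below `minority_frac`, or (b) its shape-based
#' distance to its own centroid exceeds the case-level
#' `median + mad_mult * MAD` (plus a small absolute floor so that numerically
#' identical clean beats are never flagged). If more than `max_flag_frac` of
#' the beats end up flagged a data-quality warning is raised.
#'
#' @param cluster integer cluster assignments for one case.
#' @param sbd_dist distance of each beat to its cluster centroid.
#' @param minority_frac clusters smaller than this fraction are artifacts.
#' @param mad_mult MAD multiplier for the distance rule.
#' @param max_flag_frac warn when the flagged fraction exceeds this.
#' @param floor_eps absolute slack added to the distance threshold.
#' @return logical vector of artifact flags.
#' @export
flag_artifacts <- function(cluster, sbd_dist, minority_frac = 0.2, mad_mult = 5,
                           max_flag_frac = 0.5, floor_eps = 0.01) {
  stopifnot(length(cluster) == length(sbd_dist))
  n <- length(cluster)
  if (n == 0) return(logical(0))
  sizes <- table(cluster)
  minority <- names(sizes)[as.numeric(sizes) / n < minority_frac]
  flags <- as.character(cluster) %in% minority
  thr <- median(sbd_dist) + mad_mult * mad(sbd_dist) + floor_eps
  flags <- flags | sbd_dist > thr
  if (mean(flags) > max_flag_frac) {
    warning("more than ", round(100 * max_flag_frac), "% of beats flagged as artifacts; ",
            "check signal quality")
  }
  flags
}

#' Remove artifact beats from a segmented cohort via k-Shape
#'
#' Runs [kshape_cluster()] per case on the normalized beats and applies
#' [flag_artifacts()]. Cases with fewer than `k` beats are left unflagged.
#'
#' @param beats a `cvp_beats` object from [segment_beats()].
#' @param k clusters per case (default 2: dominant shape vs. outliers).
#' @param seed integer seed.
#' @param minority_frac,mad_mult,max_flag_frac,floor_eps see [flag_artifacts()].
#' @return tibble with case_id, beat_index, cluster_id, sbd and is_artifact —
#'   the per-beat cleaning result.
#' @export
clean_beats <- function(beats, k = 2, seed = 1, minority_frac = 0.2, mad_mult = 5,
                        max_flag_frac = 0.5, floor_eps = 0.01) {
  stopifnot(inherits(beats, "cvp_beats"))
  out <- list()
  for (cid in unique(beats$info$case_id)) {
    sel <- which(beats$info$case_id == cid)
    xs <- beats$norm[sel, , drop = FALSE]
    if (length(sel) < max(k, 2)) {
      out[[cid]] <- tibble::tibble(case_id = cid,
                                   beat_index = beats$info$beat_index[sel],
                                   cluster_id = 1L, sbd = 0, is_artifact = FALSE)
      next
    }
    ks <- kshape_cluster(xs, k = k, seed = seed)
    flags <- flag_artifacts(ks$cluster, ks$sbd, minority_frac = minority_frac,
                            mad_mult = mad_mult, max_flag_frac = max_flag_frac,
                            floor_eps = floor_eps)
    out[[cid]] <- tibble::tibble(case_id = cid,
                                 beat_index = beats$info$beat_index[sel],
                                 cluster_id = as.integer(ks$cluster),
                                 sbd = ks$sbd, is_artifact = flags)
  }
  dplyr::bind_rows(out)
}

#' Drop flagged beats from a `cvp_beats` object
#'
#' @param beats a `cvp_beats` object.
#' @param cleaning the tibble returned by [clean_beats()].
#' @return a `cvp_beats` object containing only unflagged beats.
#' @export
drop_artifacts <- function(beats, cleaning) {
  key <- paste(beats$info$case_id, beats$info$beat_index)
  bad <- paste(cleaning$case_id, cleaning$beat_index)[cleaning$is_artifact]
  keep <- !(key %in% bad)
  structure(list(info = beats$info[keep, ], raw = beats$raw[keep],
                 norm = beats$norm[keep, , drop = FALSE]), class = "cvp_beats")
}
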
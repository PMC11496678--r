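#' Case-level stratified train/validation split
#'
#' Splits cases (never individual beats) into training and validation sets so
#' that all beats of a case land in exactly one split. The total training size
#' is `floor(train_fraction * n)`; it is allocated across classes
#' proportionally with largest-remainder rounding, and each class keeps at
#' least one case on each side. Deterministic given `seed`.
#'
#' @param case_ids character vector of case ids (unique).
#' @param labels class label per case (e.g. "none" / "severe").
#' @param train_fraction fraction of cases used for training, in (0, 1).
#' @param seed integer seed.
#' @return A `split_manifest`: tibble with case_id, label and
#'   split ("train"/"validation"), with the per-class/per-split count table in
#'   `attr(, "counts")`.
#' @export
split_cases <- function(case_ids, labels, train_fraction = 0.6, seed = 1) {
  if (anyDuplicated(case_ids)) stop("case_ids must be unique")
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  n_class <- table(labels)
  if (any(n_class < 2)) stop("every class needs at least 2 cases to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1 (both splits non-empty)")
  n <- length(case_ids)
  n_train <- floor(train_fraction * n)
  share <- as.numeric(n_class) * n_train / n
  base <- floor(share)
  rem <- n_train - sum(base)
  if (rem > 0) {
    frac <- share - base
    ord <- order(-frac, -as.numeric(n_class))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base <- pmin(pmax(base, 1), as.numeric(n_class) - 1)  # both splits non-empty per class
  with_seed(seed, {
    split <- rep("validation", n)
    for (k in seq_along(levels(labels))) {
      idx <- which(labels == levels(labels)[k])
      split[sample(idx, base[k])] <- "train"
    }
    manifest <- tibble::tibble(case_id = case_ids, label = labels, split = split)
    attr(manifest, "counts") <- table(manifest$label, manifest$split)
    class(manifest) <- c("split_manifest", class(manifest))
    manifest
  })
}

#' Count beats per class and split under a manifest
#'
#' Applies the manifest-count invariant: every beat belongs to exactly one
#' split (that of its case), so per-class split counts sum to the per-class
#' beat totals.
#'
#' @param manifest a `split_manifest` from [split_cases()].
#' @param beat_case_ids case id of every beat.
#' @return list with `per_split` (tibble label, split, n_beats) and
#'   `per_label` (tibble label, n_beats with the summed totals).
#' @export
count_beats_by_split <- function(manifest, beat_case_ids) {
  m <- match(beat_case_ids, manifest$case_id)
  if (anyNA(m)) stop("some beats belong to cases absent from the manifest")
  df <- tibble::tibble(label = manifest$label[m], split = manifest$split[m])
  per_split <- dplyr::summarise(dplyr::group_by(df, .data$label, .data$split),
                                n_beats = dplyr::n(), .groups = "drop")
  per_label <- dplyr::summarise(dplyr::group_by(per_split, .data$label),
                                n_beats = sum(.data$n_beats), .groups = "drop")
  list(per_split = per_split, per_label = per_label)
}
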
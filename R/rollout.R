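#' Attention rollout across encoder layers
#'
#' Propagates attention through the residual stream: each layer's
#' head-averaged attention matrix \eqn{A} is mixed with the identity,
#' \eqn{\hat A = \mathrm{normalize~rows}((A + I)/2)}, and the rollout is the
#' product \eqn{\hat A_L \cdots \hat A_1}. Per-position saliency is the column
#' mean of the rollout matrix (this architecture pools over positions and has
#' no class token, so the column mean attributes the pooled representation to
#' input positions).
#'
#' @param attn list of per-layer attention matrices (square, equal dimension,
#'   rows summing to 1 within 1e-5), ordered from the first layer to the last.
#' @return object of class `attention_explanation`: list with `rollout`
#'   (row-stochastic matrix), `saliency` (non-negative, length = sequence
#'   length) and `layers` (the residual-mixed per-layer matrices).
#' @export
#' @examples
#' a <- diag(4)
#' attention_rollout(list(a, a))$saliency  # uniform
attention_rollout <- function(attn) {
  if (!is.list(attn) || length(attn) == 0) stop("attn must be a non-empty list of matrices")
  L <- nrow(attn[[1]])
  hats <- lapply(attn, function(A) {
    A <- as.matrix(A)
    if (nrow(A) != ncol(A)) stop("attention matrices must be square")
    if (nrow(A) != L) stop("attention matrices must share one dimension")
    rs <- rowSums(A)
    if (any(abs(rs - 1) > 1e-5) || any(A < -1e-12))
      stop("attention matrices must be row-stochastic (rows sum to 1)")
    Ahat <- (A + diag(L)) / 2
    Ahat / rowSums(Ahat)
  })
  rollout <- hats[[length(hats)]]
  if (length(hats) > 1) {
    for (k in rev(seq_len(length(hats) - 1))) rollout <- rollout %*% hats[[k]]
  }
  structure(list(rollout = rollout, saliency = colMeans(rollout), layers = hats),
            class = "attention_explanation")
}

#' Per-beat attention-rollout saliency
#'
#' Runs each beat through the trained model, collects the head-averaged
#' attention of every encoder block and reduces it with [attention_rollout()].
#'
#' @param model a trained `tr_transformer` with at least one block.
#' @param x matrix of beats (rows).
#' @param batch_size beats processed per forward pass.
#' @return matrix (beats x positions) of non-negative saliency values; each
#'   row sums to 1.
#' @export
explain_beats <- function(model, x, batch_size = 16) {
  if (model$config$n_blocks < 1) stop("attention rollout needs at least one block")
  x <- matrix(x, ncol = model$seq_len)
  sal <- matrix(NA_real_, nrow(x), model$seq_len)
  nb <- ceiling(nrow(x) / batch_size)
  for (i in seq_len(nb)) {
    idx <- ((i - 1) * batch_size + 1):min(i * batch_size, nrow(x))
    pr <- predict(model, x[idx, , drop = FALSE], keep_attn = TRUE,
                  batch_size = batch_size)
    for (j in seq_along(idx)) {
      s <- attention_rollout(pr$attn[[j]])$saliency
      sal[idx[j], ] <- s / sum(s)
    }
  }
  sal
}
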
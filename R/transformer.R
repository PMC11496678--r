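#' Transformer beat-classifier configuration
#'
#' Hyperparameters of the Transformer encoder classifier. The defaults are the
#' reference configuration used for full-scale cohorts: six transformer
#' blocks, four attention heads of size 32, Adam with learning rate 5e-5,
#' weight decay 5e-4, batch size 256 and 50 epochs, and a 60/40 case-level
#' train/validation split. Desk-scale benchmarks use a reduced configuration
#' (see the package vignette).
#'
#' @param n_blocks number of transformer encoder blocks (0 = pooling + MLP only).
#' @param n_heads attention heads per block.
#' @param head_size dimensionality of each attention head.
#' @param ff_dim hidden width of the pointwise feed-forward network.
#' @param mlp_hidden hidden width of the MLP classification head.
#' @param dropout dropout rate inside the encoder blocks.
#' @param mlp_dropout dropout rate in the MLP head.
#' @param learning_rate,weight_decay Adam learning rate and decoupled weight
#'   decay.
#' @param batch_size,epochs minibatch size and training epochs.
#' @param train_fraction case fraction assigned to training by [split_cases()].
#' @param positional_encoding add a fixed sinusoidal positional bias to the
#'   input (off by default, matching the reference implementation style).
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(n_blocks = 6, n_heads = 4, head_size = 32,
                              ff_dim = 4, mlp_hidden = 128,
                              dropout = 0.25, mlp_dropout = 0.25,
                              learning_rate = 5e-5, weight_decay = 5e-4,
                              batch_size = 256, epochs = 50,
                              train_fraction = 0.6,
                              positional_encoding = FALSE, seed = 1) {
  stopifnot(n_blocks >= 0, n_heads >= 1, head_size >= 1, ff_dim >= 1,
            mlp_hidden >= 1, dropout >= 0, dropout < 1, mlp_dropout >= 0,
            mlp_dropout < 1, learning_rate > 0, weight_decay >= 0,
            batch_size >= 1, epochs >= 0)
  structure(list(
    n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
    head_size = as.integer(head_size), ff_dim = as.integer(ff_dim),
    mlp_hidden = as.integer(mlp_hidden), dropout = dropout,
    mlp_dropout = mlp_dropout, learning_rate = learning_rate,
    weight_decay = weight_decay, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), train_fraction = train_fraction,
    positional_encoding = positional_encoding, seed = as.integer(seed)
  ), class = "classifier_config")
}

glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

#' Build an untrained Transformer beat classifier
#'
#' Architecture (univariate length-`seq_len` input): `n_blocks` repeats of
#' \[layer norm -> multi-head self-attention -> dropout -> residual ->
#' layer norm -> pointwise feed-forward -> residual\], then global average
#' pooling over the channel axis (which, for a single channel, passes the
#' position vector through), a one-hidden-layer MLP and a 2-class softmax.
#' Layer normalization is computed along the sequence for the univariate
#' input. Parameter initialization is Glorot-uniform and deterministic given
#' the config seed; the parameter count is a pure function of the config.
#'
#' @param config a [classifier_config()].
#' @param seq_len input sequence length (default 500, the resampled beat).
#' @return object of class `tr_transformer` with elements `config`, `seq_len`,
#'   `params` (nested list) and `n_params`.
#' @export
build_model <- function(config, seq_len = 500) {
  stopifnot(inherits(config, "classifier_config"))
  with_seed(config$seed, {
    dk <- config$head_size
    blocks <- vector("list", config$n_blocks)
    for (k in seq_len(config$n_blocks)) {
      heads <- vector("list", config$n_heads)
      for (h in seq_len(config$n_heads)) {
        heads[[h]] <- list(
          wq = glorot(1, dk, dk), wk = glorot(1, dk, dk), wv = glorot(1, dk, dk),
          wo = glorot(config$n_heads * dk, 1, dk),
          bq = rep(0, dk), bk = rep(0, dk), bv = rep(0, dk)
        )
      }
      blocks[[k]] <- list(
        ln1 = list(g = 1, b = 0),
        heads = heads,
        bo = 0,
        ln2 = list(g = 1, b = 0),
        ffn = list(w1 = glorot(1, config$ff_dim, config$ff_dim),
                   b1 = rep(0, config$ff_dim),
                   w2 = glorot(config$ff_dim, 1, config$ff_dim),
                   b2 = 0)
      )
    }
    params <- list(
      blocks = blocks,
      mlp = list(
        W1 = matrix(glorot(seq_len, config$mlp_hidden, seq_len * config$mlp_hidden),
                    seq_len, config$mlp_hidden),
        b1 = rep(0, config$mlp_hidden),
        W2 = matrix(glorot(config$mlp_hidden, 2, config$mlp_hidden * 2),
                    config$mlp_hidden, 2),
        b2 = rep(0, 2)
      )
    )
    pe <- if (config$positional_encoding) {
      0.1 * sin(2 * pi * (seq_len(seq_len) - 1) / seq_len)
    } else NULL
    structure(list(config = config, seq_len = seq_len, params = params, pe = pe,
                   n_params = length(unlist(params))),
              class = "tr_transformer")
  })
}

ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + 1e-6)
  xhat <- xc * inv
  list(y = g * xhat + b, xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  dg <- sum(dy * cache$xhat)
  db <- sum(dy)
  dxh <- dy * g
  rm1 <- rowMeans(dxh)
  rm2 <- rowMeans(dxh * cache$xhat)
  dx <- (dxh - rm1 - cache$xhat * rm2) * cache$inv
  list(dx = dx, dg = dg, db = db)
}

head_scalars <- function(hp, dk) {
  s <- 1 / sqrt(dk)
  list(al = s * sum(hp$wq * hp$wk), be = s * sum(hp$wq * hp$bk),
       ga = s * sum(hp$bq * hp$wk), de = s * sum(hp$bq * hp$bk),
       cv = sum(hp$wv * hp$wo), c0 = sum(hp$bv * hp$wo))
}

drop_mask <- function(dim, p, training) {
  if (!training || p <= 0) return(NULL)
  matrix((runif(prod(dim)) >= p) / (1 - p), dim[1], dim[2])
}
apply_mask <- function(x, m) if (is.null(m)) x else x * m

# Full forward pass. X: B x L matrix of normalized beats. Returns class
# probabilities plus (when requested) the cache needed by model_backward and
# the per-item, per-layer head-averaged attention matrices.
model_forward <- function(model, X, training = FALSE, keep_attn = FALSE,
                          want_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  B <- nrow(X)
  x <- X
  if (!is.null(model$pe)) x <- x + rep(model$pe, each = B)
  caches <- vector("list", cfg$n_blocks)
  attn_layers <- if (keep_attn) vector("list", cfg$n_blocks) else NULL
  for (k in seq_len(cfg$n_blocks)) {
    bp <- p$blocks[[k]]
    ln1 <- ln_forward(x, bp$ln1$g, bp$ln1$b)
    aT <- t(ln1$y)
    out <- matrix(0, B, ncol(X))
    Gs <- vector("list", cfg$n_heads)
    const <- bp$bo
    if (keep_attn) item_attn <- NULL
    for (h in seq_len(cfg$n_heads)) {
      sc <- head_scalars(bp$heads[[h]], cfg$head_size)
      fw <- attn_uni_forward(aT, sc$al, sc$be, sc$ga, sc$de, keep_attn)
      Gs[[h]] <- fw$g
      out <- out + sc$cv * t(fw$g)
      const <- const + sc$c0
      if (keep_attn) {
        if (is.null(item_attn)) {
          item_attn <- fw$attn
        } else {
          item_attn <- lapply(seq_len(B), function(i) item_attn[[i]] + fw$attn[[i]])
        }
      }
    }
    out <- out + const
    if (keep_attn) attn_layers[[k]] <- lapply(item_attn, function(m) m / cfg$n_heads)
    m1 <- drop_mask(dim(out), cfg$dropout, training)
    x1 <- x + apply_mask(out, m1)
    ln2 <- ln_forward(x1, bp$ln2$g, bp$ln2$b)
    vb <- as.vector(ln2$y)                       # (B*L), column-major
    H <- outer(vb, bp$ffn$w1) + rep(bp$ffn$b1, each = length(vb))
    R <- H * (H > 0)
    f <- matrix(as.vector(R %*% bp$ffn$w2) + bp$ffn$b2, B, ncol(X))
    m2 <- drop_mask(dim(f), cfg$dropout, training)
    x2 <- x1 + apply_mask(f, m2)
    if (want_cache) {
      caches[[k]] <- list(ln1 = ln1, aT = aT, Gs = Gs, m1 = m1, x = x,
                          ln2 = ln2, vb = vb, Hpos = H > 0, R = R, m2 = m2)
    }
    x <- x2
  }
  pooled <- x                                     # channel-mean of 1 channel
  Z1 <- pooled %*% p$mlp$W1 + rep(p$mlp$b1, each = B)
  A1 <- Z1 * (Z1 > 0)
  m3 <- drop_mask(dim(A1), cfg$mlp_dropout, training)
  A1d <- apply_mask(A1, m3)
  logits <- A1d %*% p$mlp$W2 + rep(p$mlp$b2, each = B)
  lm <- apply(logits, 1, max)
  e <- exp(logits - lm)
  probs <- e / rowSums(e)
  list(probs = probs, logits = logits,
       cache = if (want_cache) list(blocks = caches, pooled = pooled, Z1 = Z1,
                                    A1d = A1d, m3 = m3) else NULL,
       attn = if (keep_attn) reorganize_attn(attn_layers, B) else NULL)
}

# attn_layers[[block]][[item]] -> per item: list over blocks
reorganize_attn <- function(attn_layers, B) {
  lapply(seq_len(B), function(i) lapply(attn_layers, function(layer) layer[[i]]))
}

# Cross-entropy backward through the whole network; returns nested gradients
# with exactly the structure of model$params.
model_backward <- function(model, fw, y) {
  cfg <- model$config
  p <- model$params
  B <- nrow(fw$probs)
  onehot <- matrix(0, B, 2)
  onehot[cbind(seq_len(B), y + 1L)] <- 1
  dlogits <- (fw$probs - onehot) / B
  cache <- fw$cache
  g_mlp <- list(
    W1 = NULL, b1 = NULL,
    W2 = crossprod(cache$A1d, dlogits),
    b2 = colSums(dlogits)
  )
  dA1d <- dlogits %*% t(p$mlp$W2)
  dZ1 <- apply_mask(dA1d, cache$m3) * (cache$Z1 > 0)
  g_mlp$W1 <- crossprod(cache$pooled, dZ1)
  g_mlp$b1 <- colSums(dZ1)
  dx <- dZ1 %*% t(p$mlp$W1)
  g_blocks <- vector("list", cfg$n_blocks)
  for (k in rev(seq_len(cfg$n_blocks))) {
    bp <- p$blocks[[k]]
    cc <- cache$blocks[[k]]
    # x2 = x1 + mask2 * f
    df <- apply_mask(dx, cc$m2)
    dx1 <- dx
    dfv <- as.vector(df)
    g_ffn <- list(
      w1 = NULL, b1 = NULL,
      w2 = as.numeric(crossprod(cc$R, dfv)),
      b2 = sum(dfv)
    )
    dR <- outer(dfv, bp$ffn$w2)
    dH <- dR * cc$Hpos
    g_ffn$w1 <- as.numeric(crossprod(dH, cc$vb))
    g_ffn$b1 <- colSums(dH)
    dvb <- as.numeric(dH %*% bp$ffn$w1)
    dln2y <- matrix(dvb, nrow(dx), ncol(dx))
    ln2b <- ln_backward(dln2y, cc$ln2, bp$ln2$g)
    dx1 <- dx1 + ln2b$dx
    # x1 = x + mask1 * out
    dout <- apply_mask(dx1, cc$m1)
    dxp <- dx1
    daT <- matrix(0, ncol(dx), nrow(dx))
    dc0 <- sum(dout)
    g_heads <- vector("list", cfg$n_heads)
    s <- 1 / sqrt(cfg$head_size)
    for (h in seq_len(cfg$n_heads)) {
      hp <- bp$heads[[h]]
      sc <- head_scalars(hp, cfg$head_size)
      dG <- t(dout) * sc$cv
      bw <- attn_uni_backward(cc$aT, cc$Gs[[h]], dG, sc$al, sc$be, sc$ga, sc$de)
      daT <- daT + bw$da
      dcv <- sum(dout * t(cc$Gs[[h]]))
      g_heads[[h]] <- list(
        wq = s * (bw$dal * hp$wk + bw$dbe * hp$bk),
        wk = s * (bw$dal * hp$wq + bw$dga * hp$bq),
        wv = dcv * hp$wo,
        wo = dcv * hp$wv + dc0 * hp$bv,
        bq = s * (bw$dga * hp$wk + bw$dde * hp$bk),
        bk = s * (bw$dbe * hp$wq + bw$dde * hp$bq),
        bv = dc0 * hp$wo
      )
    }
    ln1b <- ln_backward(t(daT), cc$ln1, bp$ln1$g)
    dx <- dxp + ln1b$dx
    g_blocks[[k]] <- list(
      ln1 = list(g = ln1b$dg, b = ln1b$db),
      heads = g_heads,
      bo = dc0,
      ln2 = list(g = ln2b$dg, b = ln2b$db),
      ffn = g_ffn
    )
  }
  list(blocks = g_blocks, mlp = g_mlp)
}

ce_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y + 1L)], 1e-12)))
}

#' Train the Transformer classifier and evaluate on the validation split
#'
#' Trains with Adam (decoupled weight decay) on the beats of the training
#' cases and reports validation accuracy, the confusion matrix and the
#' training loss curve. Beats are never split within a case: membership comes
#' from the case-level `manifest`. Fully deterministic given the config seed.
#'
#' @param x numeric matrix of normalized beats (rows = beats).
#' @param y class label per beat: 0/1, logical, or a 2-level factor whose
#'   second level is the positive class.
#' @param case_ids case id of every beat.
#' @param manifest a `split_manifest` from [split_cases()].
#' @param config a [classifier_config()].
#' @param verbose print per-epoch training loss.
#' @return list with `model` (trained `tr_transformer`), `accuracy`,
#'   `confusion` (2x2 table, truth in rows), `loss_history`, `n_train`,
#'   `n_validation` and the per-beat validation `predictions` tibble.
#' @export
train_and_evaluate <- function(x, y, case_ids, manifest, config, verbose = FALSE) {
  stopifnot(nrow(x) == length(case_ids))
  y <- encode_labels(y)
  stopifnot(length(y) == nrow(x))
  m <- match(case_ids, manifest$case_id)
  if (anyNA(m)) stop("beats reference cases absent from the manifest")
  split <- manifest$split[m]
  tr <- which(split == "train"); va <- which(split == "validation")
  if (length(tr) == 0 || length(va) == 0) stop("both splits must contain beats")
  model <- build_model(config, seq_len = ncol(x))
  skel <- model$params
  flat <- unlist(skel)
  adam_m <- numeric(length(flat)); adam_v <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  loss_hist <- numeric(0)
  if (config$epochs > 0) {
    with_seed(config$seed + 1L, {
      for (ep in seq_len(config$epochs)) {
        ord <- sample(tr)
        nb <- ceiling(length(ord) / config$batch_size)
        ep_loss <- 0
        for (i in seq_len(nb)) {
          idx <- ord[((i - 1) * config$batch_size + 1):min(i * config$batch_size, length(ord))]
          fw <- model_forward(model, x[idx, , drop = FALSE], training = TRUE,
                              want_cache = TRUE)
          ep_loss <- ep_loss + ce_loss(fw$probs, y[idx]) * length(idx)
          gr <- model_backward(model, fw, y[idx])
          gflat <- unlist(gr)
          step <- step + 1L
          adam_m <- b1 * adam_m + (1 - b1) * gflat
          adam_v <- b2 * adam_v + (1 - b2) * gflat^2
          mh <- adam_m / (1 - b1^step)
          vh <- adam_v / (1 - b2^step)
          flat <- flat - config$learning_rate *
            (mh / (sqrt(vh) + eps) + config$weight_decay * flat)
          model$params <- utils::relist(flat, skel)
        }
        loss_hist <- c(loss_hist, ep_loss / length(ord))
        if (verbose) message(sprintf("epoch %d/%d  loss %.4f", ep, config$epochs,
                                     loss_hist[ep]))
      }
    })
  }
  pv <- predict(model, x[va, , drop = FALSE])
  pred <- max.col(pv) - 1L
  truth <- y[va]
  confusion <- table(factor(truth, levels = 0:1), factor(pred, levels = 0:1),
                     dnn = c("truth", "predicted"))
  list(
    model = model,
    accuracy = mean(pred == truth),
    confusion = confusion,
    loss_history = loss_hist,
    n_train = length(tr), n_validation = length(va),
    predictions = tibble::tibble(case_id = case_ids[va], truth = truth,
                                 predicted = pred, p_positive = pv[, 2])
  )
}

encode_labels <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) > 2) stop("exactly 2 classes are supported")
    return(as.integer(droplevels(y)) - 1L)
  }
  if (is.numeric(y)) {
    if (!all(y %in% 0:1)) stop("numeric labels must be 0/1")
    return(as.integer(y))
  }
  encode_labels(factor(y))
}

#' Predict class probabilities for beats
#'
#' @param object a `tr_transformer`.
#' @param newdata matrix of beats (rows), same length as the model input.
#' @param keep_attn also return the per-beat, per-layer head-averaged
#'   attention matrices (memory-heavy; use small batches).
#' @param batch_size prediction batch size.
#' @param ... unused.
#' @return matrix of class probabilities (columns: class 0, class 1); with
#'   `keep_attn = TRUE`, a list with `probs` and `attn`.
#' @export
predict.tr_transformer <- function(object, newdata, keep_attn = FALSE,
                                   batch_size = 256, ...) {
  newdata <- matrix(newdata, ncol = object$seq_len)
  nb <- ceiling(nrow(newdata) / batch_size)
  probs <- NULL; attn <- list()
  for (i in seq_len(nb)) {
    idx <- ((i - 1) * batch_size + 1):min(i * batch_size, nrow(newdata))
    fw <- model_forward(object, newdata[idx, , drop = FALSE], training = FALSE,
                        keep_attn = keep_attn)
    probs <- rbind(probs, fw$probs)
    if (keep_attn) attn <- c(attn, fw$attn)
  }
  if (keep_attn) list(probs = probs, attn = attn) else probs
}
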
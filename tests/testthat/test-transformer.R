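tiny_config <- function(...) {
  classifier_config(n_blocks = 1, n_heads = 2, head_size = 4, ff_dim = 3,
                    mlp_hidden = 8, dropout = 0, mlp_dropout = 0,
                    learning_rate = 1e-3, batch_size = 16, epochs = 0,
                    seed = 7, ...)
}

test_that("case splits are stratified, deterministic and case-disjoint", {
  ids <- sprintf("c%02d", 1:20)
  lab <- rep(c("none", "severe"), each = 10)
  m1 <- split_cases(ids, lab, 0.5, seed = 1)
  m2 <- split_cases(ids, lab, 0.5, seed = 1)
  m3 <- split_cases(ids, lab, 0.5, seed = 2)
  expect_identical(m1$split, m2$split)
  expect_false(identical(m1$split, m3$split))   # different membership
  expect_equal(table(m1$label, m1$split), table(m3$label, m3$split))  # same counts
  expect_equal(sum(m1$split == "train"), 10)
  expect_error(split_cases(ids, lab, 1.0), "strictly between")
  expect_error(split_cases(ids[1:3], c("a", "a", "b")), "at least 2 cases")
})

test_that("largest-remainder allocation splits 31 + 11 cases into 25 train", {
  ids <- sprintf("c%02d", 1:42)
  lab <- rep(c("none", "severe"), c(31, 11))
  m <- split_cases(ids, lab, 0.6, seed = 4)
  counts <- table(m$label, m$split)
  expect_equal(sum(counts[, "train"]), floor(0.6 * 42))
  expect_equal(sum(counts), 42)
  # allocation is proportional within +-1 case per class
  expect_lte(abs(counts["none", "train"] - 31 * 25 / 42), 1)
  expect_lte(abs(counts["severe", "train"] - 11 * 25 / 42), 1)
})

test_that("beat counts aggregate by split under the manifest invariant", {
  man <- split_cases(c("a", "b", "c", "d"), c("x", "x", "y", "y"), 0.5, seed = 1)
  beats <- c(rep("a", 5), rep("b", 3), rep("c", 7), rep("d", 2))
  ct <- count_beats_by_split(man, beats)
  expect_equal(sum(ct$per_split$n_beats), 17)
  expect_equal(ct$per_label$n_beats[ct$per_label$label == "x"], 8)
  expect_equal(ct$per_label$n_beats[ct$per_label$label == "y"], 9)
  expect_error(count_beats_by_split(man, c("a", "zz")), "absent")
})

test_that("model building is deterministic and the forward pass is a softmax", {
  cfg <- tiny_config()
  m1 <- build_model(cfg, seq_len = 30)
  m2 <- build_model(cfg, seq_len = 30)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$n_params, length(unlist(m1$params)))
  X0 <- matrix(0, 4, 30)
  p <- predict(m1, X0)
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 4))
  # ablation: no encoder blocks, still a working classifier head
  m0 <- build_model(classifier_config(n_blocks = 0, seed = 1), seq_len = 30)
  p0 <- predict(m0, matrix(runif(60), 2, 30))
  expect_equal(rowSums(p0), rep(1, 2))
})

test_that("the univariate attention kernel equals a dense multi-head oracle", {
  set.seed(14)
  L <- 24; dk <- 5
  a <- rnorm(L)
  hp <- list(wq = rnorm(dk), wk = rnorm(dk), wv = rnorm(dk), wo = rnorm(dk),
             bq = rnorm(dk), bk = rnorm(dk), bv = rnorm(dk))
  # dense route: explicit Q, K, V matrices
  Q <- outer(a, hp$wq) + matrix(hp$bq, L, dk, byrow = TRUE)
  K <- outer(a, hp$wk) + matrix(hp$bk, L, dk, byrow = TRUE)
  V <- outer(a, hp$wv) + matrix(hp$bv, L, dk, byrow = TRUE)
  S <- Q %*% t(K) / sqrt(dk)
  A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
  dense_out <- as.numeric((A %*% V) %*% hp$wo)
  # kernel route through the scalar contractions
  sc <- cvpwave:::head_scalars(hp, dk)
  fw <- cvpwave:::attn_uni_forward(matrix(a, L, 1), sc$al, sc$be, sc$ga, sc$de,
                                   TRUE)
  kern_out <- sc$cv * fw$g[, 1] + sc$c0
  expect_equal(kern_out, dense_out, tolerance = 1e-10)
  expect_equal(fw$attn[[1]], A, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_config()
  L <- 10; B <- 4
  model <- build_model(cfg, seq_len = L)
  set.seed(42)
  X <- matrix(runif(B * L), B, L)
  y <- c(0L, 1L, 1L, 0L)
  loss_at <- function(flat) {
    m <- model; m$params <- utils::relist(flat, model$params)
    fw <- cvpwave:::model_forward(m, X, want_cache = FALSE)
    cvpwave:::ce_loss(fw$probs, y)
  }
  fw <- cvpwave:::model_forward(model, X, want_cache = TRUE)
  g <- unlist(cvpwave:::model_backward(model, fw, y))
  flat <- unlist(model$params)
  expect_identical(names(g), names(flat))
  set.seed(2)
  for (i in sample(length(flat), 40)) {
    fp <- flat; fp[i] <- fp[i] + 1e-6
    fm <- flat; fm[i] <- fm[i] - 1e-6
    num <- (loss_at(fp) - loss_at(fm)) / 2e-6
    expect_equal(g[i], num, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("an untrained model conserves confusion-matrix counts", {
  coh <- separable_cohort(3, 7, seed = 19)
  bl <- beats_and_labels(coh)
  ct <- unique(data.frame(id = bl$case_id, lab = as.character(bl$y)))
  man <- split_cases(ct$id, ct$lab, 0.5, seed = 1)
  fit <- train_and_evaluate(bl$beats$norm, bl$y, bl$case_id, man,
                            tiny_config())
  expect_equal(sum(fit$confusion), fit$n_validation)
  expect_equal(as.numeric(rowSums(fit$confusion)),
               as.numeric(table(factor(fit$predictions$truth, levels = 0:1))))
  expect_length(fit$loss_history, 0)
})

test_that("a small model learns a separable two-class problem", {
  # short sequences: class 1 carries a mid-sequence bump
  set.seed(77)
  L <- 40; n <- 240
  y <- rep(0:1, each = n / 2)
  X <- t(sapply(y, function(lab) {
    tt <- seq(0, 1, length.out = L)
    minmax_normalize(sin(2 * pi * tt) + lab * 2.5 * exp(-((tt - 0.6) / 0.08)^2) +
                       rnorm(L, 0, 0.2))
  }))
  cid <- rep(sprintf("c%02d", 1:24), each = 10)
  lab_case <- tapply(y, cid, max)
  man <- split_cases(names(lab_case), ifelse(lab_case == 1, "pos", "neg"),
                     0.5, seed = 3)
  cfg <- classifier_config(n_blocks = 1, n_heads = 2, head_size = 8, ff_dim = 3,
                           mlp_hidden = 16, dropout = 0.1, mlp_dropout = 0.1,
                           learning_rate = 2e-3, batch_size = 32, epochs = 20,
                           seed = 5)
  fit <- train_and_evaluate(X, y, cid, man, cfg)
  expect_gte(fit$accuracy, 0.85)
  # training is deterministic given the seed
  fit2 <- train_and_evaluate(X, y, cid, man, cfg)
  expect_equal(fit$accuracy, fit2$accuracy)
  expect_equal(fit$loss_history, fit2$loss_history)
  # no case contributes to both splits
  tr_cases <- unique(cid[man$split[match(cid, man$case_id)] == "train"])
  va_cases <- unique(fit$predictions$case_id)
  expect_length(intersect(tr_cases, va_cases), 0)
})

test_that("attention rollout follows the residual-mixed matrix product", {
  # identity attention is a fixed point with uniform saliency
  I4 <- diag(4)
  ro <- attention_rollout(list(I4, I4, I4))
  expect_equal(ro$rollout, I4)
  expect_equal(ro$saliency, rep(0.25, 4))
  # one uniform layer: closed form (0.5 uniform + 0.5 identity)
  U <- matrix(1 / 4, 4, 4)
  ro_u <- attention_rollout(list(U))
  expect_equal(ro_u$rollout, (U + I4) / 2)
  # random stochastic layers vs the explicit product oracle
  set.seed(15)
  layers <- replicate(3, {
    A <- matrix(runif(36), 6, 6); A / rowSums(A)
  }, simplify = FALSE)
  hat <- lapply(layers, function(A) {
    H <- (A + diag(6)) / 2; H / rowSums(H)
  })
  oracle <- hat[[3]] %*% hat[[2]] %*% hat[[1]]
  ro_r <- attention_rollout(layers)
  expect_equal(ro_r$rollout, oracle, tolerance = 1e-6)
  expect_equal(rowSums(ro_r$rollout), rep(1, 6), tolerance = 1e-5)
  expect_true(all(ro_r$saliency >= 0))
  bad <- matrix(runif(16), 4, 4)
  expect_error(attention_rollout(list(bad)), "row-stochastic")
  expect_error(attention_rollout(list(matrix(1, 2, 3))), "square")
})

test_that("per-beat saliency maps are normalized and non-negative", {
  cfg <- tiny_config()
  model <- build_model(cfg, seq_len = 25)
  X <- matrix(runif(3 * 25), 3, 25)
  sal <- explain_beats(model, X)
  expect_equal(dim(sal), c(3, 25))
  expect_true(all(sal >= 0))
  expect_equal(rowSums(sal), rep(1, 3))
})
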
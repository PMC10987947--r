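test_that("rotary embedding matches the rotation-matrix oracle and preserves norms", {
  set.seed(1)
  for (d in c(4, 8)) {
    v <- matrix(rnorm(6 * d), 6)
    pos <- c(0, 1, 2, 5, 9, 30)
    r <- rope_rotate(v, pos)
    expect_equal(r, rope_oracle(v, pos, 10000), tolerance = 1e-12)
    # orthogonality: row norms unchanged
    expect_equal(sqrt(rowSums(r^2)), sqrt(rowSums(v^2)), tolerance = 1e-9)
  }
  # zero vector stays zero; position 0 is the identity
  expect_equal(rope_rotate(matrix(0, 2, 4), c(3, 9)), matrix(0, 2, 4))
  v <- matrix(rnorm(4), 1)
  expect_equal(rope_rotate(v, 0), v)
  expect_error(rope_rotate(matrix(0, 1, 3), 0), "even")
})

test_that("attention logits depend only on relative position", {
  set.seed(42)
  for (d in c(4, 8)) {
    for (rep in 1:5) {
      q <- matrix(rnorm(d), 1)
      k <- matrix(rnorm(d), 1)
      m <- sample(0:20, 1); n <- sample(0:20, 1); s <- sample(1:15, 1)
      dot0 <- sum(rope_rotate(q, m) * rope_rotate(k, n))
      dot1 <- sum(rope_rotate(q, m + s) * rope_rotate(k, n + s))
      expect_equal(dot0, dot1, tolerance = 1e-6)
      # and against the explicit oracle
      expect_equal(dot0,
                   sum(rope_oracle(q, m, 10000) * rope_oracle(k, n, 10000)),
                   tolerance = 1e-9)
    }
  }
})

test_that("scaled dot-product attention matches a double-loop oracle", {
  # seq_len 1: softmax of a scalar is 1, output equals the single V row
  Q <- matrix(rnorm(4), 1); K <- matrix(rnorm(4), 1); V <- matrix(rnorm(4), 1)
  expect_equal(scaled_dot_attention(Q, K, V), V)

  # identical K rows: uniform weights, output rows equal column means of V
  K2 <- matrix(1, 3, 2)
  V2 <- matrix(rnorm(6), 3)
  out <- scaled_dot_attention(matrix(rnorm(6), 3), K2, V2)
  expect_equal(out, matrix(colMeans(V2), 3, 2, byrow = TRUE),
               tolerance = 1e-12)

  # fixed 2-position instance vs an independently coded double loop
  set.seed(7)
  Q3 <- matrix(rnorm(4), 2); K3 <- matrix(rnorm(4), 2); V3 <- matrix(rnorm(4), 2)
  ref <- matrix(0, 2, 2)
  for (i in 1:2) {
    logits <- numeric(2)
    for (j in 1:2) logits[j] <- sum(Q3[i, ] * K3[j, ]) / sqrt(2)
    w <- exp(logits) / sum(exp(logits))
    for (j in 1:2) ref[i, ] <- ref[i, ] + w[j] * V3[j, ]
  }
  got <- scaled_dot_attention(Q3, K3, V3, return_weights = TRUE)
  expect_equal(unname(got[, ]), ref, tolerance = 1e-8)
  expect_equal(rowSums(attr(got, "weights")), c(1, 1), tolerance = 1e-6)
  expect_error(scaled_dot_attention(Q3, K3[, 1, drop = FALSE], V3), "widths")
})

test_that("multi-head attention degenerates to single-head and is position-aware", {
  cfg1 <- attention_config(d_model = 4, n_heads = 1, n_layers = 1,
                           mlp_hidden = 8)
  w <- init_encoder_weights(cfg1, seed = 3)
  Z <- matrix(rnorm(12), 3)
  got <- multi_head_attention(Z, cfg1, w, positions = NULL)
  qkv <- Z %*% w$l1_h1_Wqkv
  ref <- scaled_dot_attention(qkv[, 1:4], qkv[, 5:8], qkv[, 9:12]) %*% w$l1_Wmsa
  expect_equal(got, ref, tolerance = 1e-12)

  # identity-like weights on a 2 x 4 input reproduce hand-computed values
  cfg <- attention_config(d_model = 4, n_heads = 1, n_layers = 1)
  wid <- w
  wid$l1_h1_Wqkv <- cbind(diag(4), diag(4), diag(4))
  wid$l1_Wmsa <- diag(4)
  Z2 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0), 2, byrow = TRUE)
  got2 <- multi_head_attention(Z2, cfg, wid, positions = NULL)
  # logits = Z Z'/2: diag 0.5, off 0; weights softmax([.5,0]) per row
  a <- exp(0.5) / (exp(0.5) + 1)
  ref2 <- rbind(a * Z2[1, ] + (1 - a) * Z2[2, ],
                (1 - a) * Z2[1, ] + a * Z2[2, ])
  expect_equal(got2, ref2, tolerance = 1e-10)

  # with RoPE, permuting positions changes outputs; without, it permutes them
  cfg2 <- attention_config(d_model = 8, n_heads = 2, n_layers = 1)
  w2 <- init_encoder_weights(cfg2, seed = 5)
  Z3 <- matrix(rnorm(4 * 8), 4)
  perm <- c(3, 1, 4, 2)
  with_rope <- multi_head_attention(Z3, cfg2, w2, positions = 0:3)
  with_rope_p <- multi_head_attention(Z3[perm, ], cfg2, w2, positions = 0:3)
  expect_gt(max(abs(with_rope_p - with_rope[perm, ])), 1e-4)
  no_rope <- multi_head_attention(Z3, cfg2, w2, positions = NULL)
  no_rope_p <- multi_head_attention(Z3[perm, ], cfg2, w2, positions = NULL)
  expect_equal(no_rope_p, no_rope[perm, ], tolerance = 1e-10)

  expect_error(attention_config(d_model = 42, n_heads = 5, n_layers = 1),
               "must equal d_model")
})

test_that("the encoder stack matches a straight-line reimplementation", {
  cfg <- tiny_attention_config(L = 1L)
  w <- init_encoder_weights(cfg, seed = 11)
  set.seed(11)
  Xp <- matrix(rnorm(5 * 8), 5)
  expect_equal(encoder_forward(Xp, cfg, w), encoder_oracle(Xp, cfg, w),
               tolerance = 1e-6)

  # L = 0 degenerates to the identity
  cfg0 <- tiny_attention_config(L = 0L)
  expect_equal(encoder_forward(Xp, cfg0, list()), Xp)

  # all-zero weights leave only the residual paths: output equals input
  wz <- lapply(w, function(m) m * 0)
  expect_equal(encoder_forward(Xp, cfg, wz), Xp, tolerance = 1e-12)
})

test_that("position information is injected at every layer, not once", {
  cfg <- tiny_attention_config(L = 2L)
  w <- init_encoder_weights(cfg, seed = 13)
  set.seed(13)
  Xp <- matrix(rnorm(6 * 8), 6)
  full <- encoder_forward(Xp, cfg, w)
  no_l2 <- encoder_forward(Xp, cfg, w, rope_layers = 1L)
  expect_gt(max(abs(full - no_l2)), 1e-6)
})
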
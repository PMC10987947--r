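test_that("construction is deterministic and validates the spec", {
  spec <- tiny_roformer_spec()
  a <- build_regressor(spec, seed = 5)
  b <- build_regressor(spec, seed = 5)
  expect_identical(a$params, b$params)
  c <- build_regressor(spec, seed = 6)
  expect_gt(max(abs(a$params$conv_W - c$params$conv_W)), 0)

  # five heads divide d_model = 40 but not 42
  expect_s3_class(regressor_spec("roformer", d_model = 40, n_heads = 5),
                  "regressor_spec")
  expect_error(regressor_spec("roformer", d_model = 42, n_heads = 5),
               "d_model")
  expect_error(regressor_spec("roformer", position_embedding = "sinusoidal"),
               "position_embedding")
})

test_that("parameter count of a tiny spec equals the hand-counted total", {
  # conv: (3 taps * 2 ch) * 4 + 4 bias = 28
  # per layer: ln1 4+4=8, Wqkv 4*(3*2)=24 per head * 2 heads = 48,
  #            Wmsa 16, ln2 8, W1 4*8+8=40, W2 8*4+4=36 -> 156
  # head: 4*3+3 = 15, out: 3*2+2 = 8
  spec <- regressor_spec("roformer", n_channels = 2, n_outputs = 2,
                         d_model = 4, n_heads = 2, n_layers = 1,
                         mlp_hidden = 8, head_hidden = 3)
  reg <- build_regressor(spec, 1)
  expect_identical(reg$n_params, 28L + 156L + 15L + 8L)
})

test_that("every family satisfies the shared forward contract", {
  specs <- list(
    tiny_roformer_spec(),
    regressor_spec("transformer_abs_pe", n_channels = 3, n_outputs = 2,
                   d_model = 8, n_heads = 2, n_layers = 1, mlp_hidden = 16,
                   head_hidden = 6),
    regressor_spec("lstm", n_channels = 3, n_outputs = 2, lstm_layers = 2,
                   lstm_hidden = 8, head_hidden = 6),
    regressor_spec("tcn", n_channels = 3, n_outputs = 2,
                   tcn_channels = c(8, 6), head_hidden = 6),
    regressor_spec("cnn_attention", n_channels = 3, n_outputs = 2,
                   cnn_branch_channels = 4, cnn_att_blocks = 1,
                   head_hidden = 6))
  set.seed(10)
  X <- matrix(rnorm(12 * 3), 12)
  for (spec in specs) {
    reg <- build_regressor(spec, seed = 2)
    out <- predict(reg, X)
    expect_identical(dim(out), c(12L, 2L))
    expect_true(all(is.finite(out)))
    # identical inputs give identical outputs (stateless forward)
    expect_identical(predict(reg, X), out)
    # the penultimate-feature handle has the configured width everywhere
    feats <- predict(reg, X, type = "features")
    expect_identical(dim(feats), c(12L, 6L))
    expect_error(predict(reg, X[, 1:2]), "channels")
  }
})

test_that("zero input maps identical rows to identical outputs", {
  reg <- build_regressor(tiny_roformer_spec(), seed = 3)
  out <- predict(reg, matrix(0, 6, 3))
  expect_true(all(is.finite(out)))
  # an all-equal input sequence is position-marked by RoPE only through
  # Q/K rotation, which cannot distinguish identical content rows
  expect_lt(max(abs(sweep(out, 2, out[1, ]))), 1e-9)
})

test_that("RoPE makes the rotary model order-sensitive", {
  reg <- build_regressor(tiny_roformer_spec(), seed = 4)
  set.seed(20)
  X <- matrix(rnorm(8 * 3), 8)
  perm <- sample(8)
  out <- predict(reg, X)
  out_p <- predict(reg, X[perm, ])
  expect_gt(max(abs(out_p - out[perm, ])), 1e-6)
})

test_that("training descends, is reproducible, and honors the lr schedule", {
  set.seed(30)
  X <- matrix(abs(rnorm(200 * 3)), 200)
  Y <- X %*% matrix(rnorm(6), 3) + 40
  fs <- feature_series(X, Y, 100, 50,
                       list(subject_id = "s", movement_id = 1, trial_id = 1))
  cfg <- train_config(batch_size = 4, epochs = 20, lr_init = 2e-3,
                      lr_halve_at = 15, seq_len = 25, seed = 9)
  reg <- build_regressor(tiny_roformer_spec(), seed = 9)
  tr1 <- train_regressor(reg, fs, cfg)
  expect_lt(tr1$history$loss[20], tr1$history$loss[1])
  expect_identical(nrow(tr1$history), 20L)
  # schedule: halved exactly from the configured epoch on
  expect_equal(tr1$history$lr[1:14], rep(2e-3, 14))
  expect_equal(tr1$history$lr[15:20], rep(1e-3, 6))
  # bit-reproducible for identical seeds on one device
  tr2 <- train_regressor(reg, fs, cfg)
  expect_identical(tr1$params, tr2$params)
})

test_that("a linear feature-to-angle mapping is fit to near-perfect training CC", {
  set.seed(31)
  X <- matrix(abs(rnorm(240 * 3)), 240)
  Y <- X %*% matrix(rnorm(6), 3) + 40  # exactly linear, head can express it
  fs <- feature_series(X, Y, 100, 50,
                       list(subject_id = "s", movement_id = 1, trial_id = 1))
  cfg <- train_config(batch_size = 4, epochs = 120, lr_init = 3e-3,
                      lr_halve_at = 90, seq_len = 30, seed = 11)
  tr <- train_regressor(build_regressor(tiny_roformer_spec(), seed = 11),
                        fs, cfg)
  pred <- predict(tr, X)
  ccs <- vapply(1:2, function(j) pearson_cc(Y[, j], pred[, j]), 0)
  expect_gt(min(ccs), 0.99)
})

test_that("checkpoints round-trip weights, spec and label scaling exactly", {
  set.seed(40)
  X <- matrix(abs(rnorm(120 * 3)), 120)
  Y <- X %*% matrix(rnorm(6), 3) + 25
  fs <- feature_series(X, Y, 100, 50,
                       list(subject_id = "s", movement_id = 1, trial_id = 1))
  cfg <- train_config(batch_size = 4, epochs = 3, lr_init = 1e-3,
                      lr_halve_at = 2, seq_len = 30, seed = 13)
  tr <- train_regressor(build_regressor(tiny_roformer_spec(), seed = 13),
                        fs, cfg)
  p <- withr::local_tempfile(fileext = ".txt")
  save_regressor(tr, p)
  back <- load_regressor(p)
  expect_identical(names(back$params), names(tr$params))
  expect_equal(back$params, tr$params, tolerance = 0)
  expect_equal(predict(back, X), predict(tr, X), tolerance = 1e-12)
  expect_error(load_regressor(p, n_channels = 12), "channels")
})

test_that("absolute-embedding variants differ only in the embedding component", {
  mk <- function(pe) regressor_spec("transformer_abs_pe", n_channels = 3,
                                    n_outputs = 2, d_model = 8, n_heads = 2,
                                    n_layers = 1, mlp_hidden = 16,
                                    head_hidden = 6, position_embedding = pe)
  rope_spec <- tiny_roformer_spec()
  sin_reg <- build_regressor(mk("sinusoidal"), 1)
  lrn_reg <- build_regressor(mk("learnable"), 1)
  rope_reg <- build_regressor(rope_spec, 1)
  base_names <- names(sin_reg$params)
  expect_identical(setdiff(names(lrn_reg$params), base_names), "pe")
  expect_identical(names(rope_reg$params), base_names)
  for (nm in base_names) {
    expect_identical(dim(sin_reg$params[[nm]]), dim(lrn_reg$params[[nm]]))
    expect_identical(dim(sin_reg$params[[nm]]), dim(rope_reg$params[[nm]]))
  }
})
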
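test_that("adversarial losses match their closed forms", {
  # maximal confusion: both domains scored 0.5
  expect_equal(dd_loss(0.5, 0.5), 2 * log(2), tolerance = 1e-12)
  # perfect discrimination drives the loss to zero
  expect_lt(dd_loss(1 - 1e-9, 1e-9), 1e-6)
  expect_equal(dd_loss(0.8, 0.4), -log(0.8) - log(0.6), tolerance = 1e-9)
  expect_equal(dd_loss(0.8, 0.4), 0.73397, tolerance = 1e-4)

  expect_equal(mapping_loss(0.5), log(2), tolerance = 1e-12)
  expect_lt(mapping_loss(1 - 1e-9), 1e-6)
  expect_equal(mapping_loss(0.25), log(4), tolerance = 1e-9)

  expect_error(dd_loss(numeric(0), 0.5), "empty")
  expect_error(mapping_loss(numeric(0)), "empty")
})

test_that("the reweighted subject loss follows its worked example", {
  p <- matrix(0, 1, 10); l <- matrix(2, 1, 10)  # ten joint errors of 2
  expect_equal(subject_loss(p, l, w = 0.5), 20.0)
  expect_equal(subject_loss(l, l, w = 3), 0)
  expect_equal(subject_loss(p, l, w = 0), 0)
  expect_error(subject_loss(p, l[, 1:5]), "mismatch")
  # total loss is the exact sum, rechecked by recomposition
  expect_equal(total_loss(1.0, 0.5, 0.25), 1.75)
  expect_equal(total_loss(0, 0, 0), 0)
  set.seed(7)
  ps <- runif(8, 0.1, 0.9); pt <- runif(8, 0.1, 0.9)
  pr <- matrix(rnorm(80), 8); lb <- matrix(rnorm(80), 8)
  expect_equal(total_loss(dd_loss(ps, pt), mapping_loss(pt),
                          subject_loss(pr, lb, 0.7)),
               dd_loss(ps, pt) + mapping_loss(pt) +
                 subject_loss(pr, lb, 0.7),
               tolerance = 1e-9)
})

test_that("the domain discriminator outputs probabilities deterministically", {
  dd1 <- build_discriminator(6, hidden = c(8, 8), seed = 3)
  dd2 <- build_discriminator(6, hidden = c(8, 8), seed = 3)
  expect_identical(dd1$params, dd2$params)
  p <- predict(dd1, matrix(rnorm(60), 10))
  expect_length(p, 10)
  expect_true(all(p > 0 & p < 1))
})

# a small trained source model shared by the calibration tests; the source
# task is a smooth linear feature-to-angle mapping the model masters, so
# calibration effects are measured against a high-quality source network
source_fixture <- function() {
  cached("transfer_source", {
    set.seed(77)
    B <- matrix(rnorm(120, sd = 2), 12, 10)
    mk <- function(trial) {
      X <- matrix(runif(160 * 12), 160) - 0.5
      feature_series(X, X %*% B, 100, 50,
                     list(subject_id = "src", movement_id = 1,
                          trial_id = trial))
    }
    train <- lapply(1:3, mk)
    test <- list(mk(4))
    cfg <- train_config(batch_size = 4, epochs = 120, lr_init = 3e-3,
                        lr_halve_at = 90, seq_len = 40, seed = 2)
    model <- train_regressor(build_regressor(tiny_roformer_spec(
      n_channels = 12, n_outputs = 10, d_model = 16, mlp_hidden = 32,
      head_hidden = 16), seed = 2), train, cfg)
    list(model = model, data = list(train = train, test = test))
  })
}

test_that("fine-tuning updates only the head and still descends", {
  fx <- source_fixture()
  cc <- calibration_config(epochs = 8, lr = 1e-3, batch_size = 4, seed = 5)
  ft <- ft_calibrate(fx$model, fx$data$train, cc)
  head_names <- c("head_Wf", "head_bf", "head_Wo", "head_bo")
  for (nm in names(ft$params)) {
    if (nm %in% head_names) {
      expect_gt(max(abs(ft$params[[nm]] - fx$model$params[[nm]])), 0)
    } else {
      expect_identical(ft$params[[nm]], fx$model$params[[nm]])
    }
  }
  expect_lte(tail(ft$calibration_log$loss, 1), ft$calibration_log$loss[1])
})

test_that("a label-rescaling shift is absorbed by the head alone", {
  fx <- source_fixture()
  # target subject: same features, output mapping scaled by 0.5
  tgt <- lapply(fx$data$train, function(d) {
    d$labels <- 0.5 * d$labels
    d
  })
  tgt_test <- lapply(fx$data$test, function(d) {
    d$labels <- 0.5 * d$labels
    d
  })
  cc <- calibration_config(epochs = 30, lr = 1e-3, batch_size = 4, seed = 6)
  ft <- ft_calibrate(fx$model, tgt, cc)
  rep_ft <- evaluate_model(ft, tgt_test)
  expect_gt(rep_ft$averaged["cc"], 0.9)
  # and the rescaling visibly hurt the uncalibrated R2, which FT repairs
  rep_raw <- evaluate_model(fx$model, tgt_test)
  expect_gt(rep_ft$averaged["r2"], rep_raw$averaged["r2"])
})

test_that("adversarial calibration freezes the source and logs a recomposable loss", {
  fx <- source_fixture()
  ns <- asNamespace("rofemg")
  digest_before <- ns$weights_digest(fx$model$params)
  cc <- calibration_config(epochs = 4, lr = 1e-3, batch_size = 4, seed = 8)
  cal <- atl_calibrate(fx$model, fx$data$train, fx$data$train, cc)
  expect_identical(ns$weights_digest(fx$model$params), digest_before)
  lg <- cal$calibration_log
  expect_identical(nrow(lg), 4L)
  expect_equal(lg$l_total, lg$l_dd + lg$l_mapping + lg$l_subject,
               tolerance = 1e-9)
  expect_s3_class(cal, "emg_regressor")
  expect_identical(cal$calibration, "ATL")
})

test_that("with w = 0 the supervised term is annihilated during calibration", {
  fx <- source_fixture()
  cc <- calibration_config(epochs = 3, lr = 1e-3, batch_size = 4, w = 0,
                           seed = 9)
  cal <- atl_calibrate(fx$model, fx$data$train, fx$data$train, cc)
  expect_equal(cal$calibration_log$l_subject, rep(0, 3), tolerance = 1e-12)
})
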
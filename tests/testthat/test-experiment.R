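# a deliberately tiny profile so the orchestration tests run in seconds
fast_profile <- function(seed = 1) {
  p <- desk_profile(seed)
  p$model <- utils::modifyList(p$model, list(d_model = 8, mlp_hidden = 16,
                                             head_hidden = 6))
  p$train <- train_config(batch_size = 4, epochs = 4, lr_init = 2e-3,
                          lr_halve_at = 3, seq_len = 30, seed = seed)
  p$calib <- calibration_config(epochs = 2, lr = 1e-3, batch_size = 4,
                                seed = seed)
  p
}

test_that("the subject-specific condition produces one report per subject", {
  coh <- small_cohort(n_subjects = 2, n_movements = 1, seed = 55,
                      trial_duration_s = 2)
  res <- run_subject_specific(coh, profile = fast_profile(), seed = 1)
  expect_s3_class(res, "experiment_result")
  expect_identical(sort(names(res$reports)),
                   c("s01/roformer", "s02/roformer"))
  for (r in res$reports) {
    expect_true(all(r$per_joint$cc >= -1 & r$per_joint$cc <= 1))
    expect_true(all(r$per_joint$nrmse >= 0))
    expect_true(all(r$per_joint$r2 <= 1))
  }
  # every subject contributes 4 train and 2 test trials per movement
  tab <- table(res$access_log$subject_id, res$access_log$role)
  expect_true(all(tab[, "train"] == 4))
  expect_true(all(tab[, "test"] == 2))
})

test_that("cross-subject pooling uses the sum of per-subject training windows", {
  coh <- small_cohort(n_subjects = 2, n_movements = 1, seed = 55,
                      trial_duration_s = 2)
  ns <- asNamespace("rofemg")
  sp_all <- ns$prepare_split(coh$recordings, 1, 100, 50)
  per_subject <- vapply(c("s01", "s02", "new"), function(sid) {
    sp <- ns$prepare_split(ns$subset_recordings(coh$recordings, sid),
                           1, 100, 50)
    sum(vapply(sp$train, function(d) nrow(d$features), 0))
  }, 0)
  expect_identical(sum(vapply(sp_all$train, function(d) nrow(d$features), 0)),
                   sum(per_subject))

  res <- run_cross_subject(coh, profile = fast_profile(), seed = 1)
  expect_identical(sort(names(res$reports)),
                   c("s01/roformer", "s02/roformer"))
  expect_length(res$models, 1L)
})

test_that("the transfer condition guards leakage and compares on identical trials", {
  coh <- small_cohort(n_subjects = 2, n_movements = 1, seed = 56,
                      trial_duration_s = 2)
  res <- run_transfer(coh, profile = fast_profile(), seed = 1)
  expect_s3_class(res, "transfer_result")
  expect_setequal(names(res$reports), c("noTL", "FT", "ATL"))
  # noTL never touches the held-out subject's training trials
  expect_length(res$target_train_used$noTL, 0L)
  # FT and ATL calibrate on exactly the same target training trials
  expect_identical(res$target_train_used$FT, res$target_train_used$ATL)
  # calibration trials and test trials are disjoint
  expect_length(intersect(res$target_train_used$FT, res$test_keys), 0L)
  # all approaches are scored on the identical held-out test trials
  expect_identical(length(res$test_keys), 2L)
  # the source pool never contains the held-out subject
  src <- res$access_log[res$access_log$domain == "source", ]
  expect_false("new" %in% src$subject_id)
})

test_that("identical configs and seeds reproduce identical metric CSVs", {
  coh <- small_cohort(n_subjects = 1, n_movements = 1, seed = 57,
                      trial_duration_s = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_subject_specific(coh, profile = fast_profile(3), seed = 3)
  r2 <- run_subject_specific(coh, profile = fast_profile(3), seed = 3)
  write_experiment_reports(r1, d1)
  write_experiment_reports(r2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
})

test_that("the companding-parameter sweep stacks one summary row per mu", {
  coh <- small_cohort(n_subjects = 1, n_movements = 1, seed = 57,
                      trial_duration_s = 2)
  tab <- run_mu_sweep(coh, mu_values = c(256, 2^20),
                      profile = fast_profile(), seed = 1)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$mu, c(256, 2^20))
  expect_true(all(is.finite(tab$cc_mean)))
})

test_that("normalization condition is recorded and affects the feature path", {
  coh <- small_cohort(n_subjects = 1, n_movements = 1, seed = 57,
                      trial_duration_s = 2)
  r_mu <- run_subject_specific(coh, normalization = "mu_law",
                               profile = fast_profile(), seed = 1)
  r_z <- run_subject_specific(coh, normalization = "zscore",
                              profile = fast_profile(), seed = 1)
  expect_identical(r_mu$normalization, "mu_law")
  expect_identical(r_z$normalization, "zscore")
  # same split and seeds, different normalization: different metrics
  expect_false(isTRUE(all.equal(r_mu$table$cc_mean, r_z$table$cc_mean)))
})
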
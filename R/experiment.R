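# Orchestration of the three experimental conditions: subject-specific
# models, one cross-subject model over a pooled cohort, and transfer of a
# cross-subject model to a held-out subject (noTL / FT / ATL comparison).

#' Scale profiles for experiments
#'
#' `desk_profile()` is the default small-scale setting (tiny encoder, short
#' sequences, tens of epochs) sized so a full simulate-train-evaluate cycle
#' runs in minutes on one CPU; `paper_profile()` carries the full-scale
#' protocol sizes (d_model 40, 5 heads, 2 layers, batch 64, 400 epochs with
#' the rate halved at epoch 200, 50-epoch calibration at 1e-3).
#'
#' @param seed base seed threaded into the training configs.
#' @return List with `model` (regressor-spec overrides), `train`
#'   (a [train_config()]), `calib` (a [calibration_config()]) and the RMS
#'   window geometry.
#' @export
desk_profile <- function(seed = 1) {
  list(model = list(d_model = 16, n_heads = 2, n_layers = 1,
                    mlp_hidden = 32, head_hidden = 16,
                    lstm_layers = 2, lstm_hidden = 16,
                    tcn_channels = c(16, 16, 10),
                    cnn_branch_channels = 8, cnn_att_blocks = 1),
       train = train_config(batch_size = 4, epochs = 150, lr_init = 2e-3,
                            lr_halve_at = 110, seq_len = 40, seed = seed),
       calib = calibration_config(epochs = 50, lr = 1e-3, batch_size = 8,
                                  w = 1, seed = seed),
       window_ms = 100, step_ms = 50)
}

#' @rdname desk_profile
#' @export
paper_profile <- function(seed = 1) {
  list(model = list(d_model = 40, n_heads = 5, n_layers = 2,
                    mlp_hidden = 160, head_hidden = 32),
       train = train_config(batch_size = 64, epochs = 400, lr_init = 1e-4,
                            lr_halve_at = 200, seq_len = 150, seed = seed),
       calib = calibration_config(epochs = 50, lr = 1e-3, batch_size = 64,
                                  w = 1, seed = seed),
       window_ms = 100, step_ms = 50)
}

subject_seed_offset <- function(subject_id) {
  sum(utf8ToInt(as.character(subject_id))) %% 10000L
}

# group a recording list by subject id
recordings_by_subject <- function(recordings) {
  split(recordings, vapply(recordings, function(r) as.character(r$subject_id), ""))
}

# per-subject 4/2 trial split (one partition per subject, shared across its
# movements), raw RMS feature extraction, and an access log of which trials
# landed where
prepare_split <- function(recordings, split_seed, window_ms, step_ms,
                          n_train = 4, n_test = 2) {
  by_subj <- recordings_by_subject(recordings)
  train <- list(); test <- list(); log <- list()
  for (sid in names(by_subj)) {
    recs <- by_subj[[sid]]
    trials <- sort(unique(vapply(recs, function(r) r$trial_id, 0L)))
    part <- split_trials(trials, n_train, n_test,
                         seed = split_seed + subject_seed_offset(sid))
    for (r in recs) {
      fs <- make_feature_series(r, window_ms, step_ms)
      role <- if (r$trial_id %in% part$train) "train" else "test"
      if (role == "train") train[[length(train) + 1L]] <- fs
      else test[[length(test) + 1L]] <- fs
      log[[length(log) + 1L]] <- data.frame(
        subject_id = sid, movement_id = r$movement_id,
        trial_id = r$trial_id, role = role)
    }
  }
  list(train = train, test = test, log = do.call(rbind, log))
}

# fit the normalization on pooled training features only, apply to both
normalize_split <- function(train_fs, test_fs, method = "mu_law",
                            mu = 2^20) {
  pooled <- do.call(rbind, lapply(train_fs, function(d) d$features))
  spec <- fit_normalization(pooled, method, mu = mu)
  renorm <- function(d) {
    feature_series(apply_normalization(d$features, spec), d$labels,
                   d$window_ms, d$step_ms, d$provenance, spec$hash)
  }
  list(train = lapply(train_fs, renorm), test = lapply(test_fs, renorm),
       norm_spec = spec)
}

make_family_spec <- function(family, model_args) {
  do.call(regressor_spec, c(list(family = family), model_args))
}

subset_recordings <- function(recordings, subject_ids) {
  Filter(function(r) as.character(r$subject_id) %in% subject_ids, recordings)
}

cohort_subject_ids <- function(cohort) {
  vapply(cohort$subject_specs, function(s) as.character(s$subject_id), "")
}

#' Subject-specific condition: one model per subject
#'
#' For every subject: a seeded 4/2 trial split, normalization fitted on the
#' subject's own training trials, a model trained on them and evaluated on
#' the two held-out trials.
#'
#' @param cohort a `synthetic_cohort` (or plain list of
#'   [subject_recording()] under `$recordings`).
#' @param families regressor families to run (default `"roformer"`).
#' @param normalization `"mu_law"` or `"zscore"`.
#' @param profile a scale profile, see [desk_profile()].
#' @param seed experiment seed (controls the split and training).
#' @param subjects subject ids to include (default: all cohort subjects,
#'   excluding the held-out `"new"` subject).
#' @param mu companding parameter when `normalization = "mu_law"`.
#' @return Object of class `experiment_result`: `reports` (named
#'   `metrics_report` list, `subject/family` keys), `table` (summary
#'   data.frame), `access_log`, and the condition metadata.
#' @export
run_subject_specific <- function(cohort, families = "roformer",
                                 normalization = "mu_law",
                                 profile = desk_profile(), seed = 1,
                                 subjects = NULL, mu = 2^20) {
  recs <- if (inherits(cohort, "synthetic_cohort")) cohort$recordings else cohort$recordings
  if (is.null(subjects)) {
    subjects <- if (inherits(cohort, "synthetic_cohort"))
      cohort_subject_ids(cohort)
    else unique(vapply(recs, function(r) as.character(r$subject_id), ""))
  }
  reports <- list(); logs <- list()
  for (sid in subjects) {
    sp <- prepare_split(subset_recordings(recs, sid), split_seed = seed,
                        window_ms = profile$window_ms,
                        step_ms = profile$step_ms)
    nm <- normalize_split(sp$train, sp$test, normalization, mu)
    logs[[sid]] <- sp$log
    for (fam in families) {
      spec <- make_family_spec(fam, profile$model)
      tc <- profile$train
      tc$seed <- seed + subject_seed_offset(sid)
      model <- build_regressor(spec, seed = tc$seed)
      model <- train_regressor(model, nm$train, tc)
      reports[[paste(sid, fam, sep = "/")]] <-
        evaluate_model(model, nm$test)
    }
  }
  structure(list(condition = "subject_specific", reports = reports,
                 table = summarize_reports(reports),
                 access_log = do.call(rbind, logs),
                 normalization = normalization, seed = seed),
            class = "experiment_result")
}

#' Cross-subject condition: one model on the pooled cohort
#'
#' Pools the training trials of all requested subjects (normalization fitted
#' on the pooled training features), trains a single model, and evaluates it
#' per subject on that subject's held-out trials.
#'
#' @inheritParams run_subject_specific
#' @return `experiment_result`; reports are keyed `subject/family`. The
#'   trained models are attached under `models` (one per family).
#' @export
run_cross_subject <- function(cohort, families = "roformer",
                              normalization = "mu_law",
                              profile = desk_profile(), seed = 1,
                              subjects = NULL, mu = 2^20) {
  recs <- cohort$recordings
  if (is.null(subjects)) {
    subjects <- if (inherits(cohort, "synthetic_cohort"))
      cohort_subject_ids(cohort)
    else unique(vapply(recs, function(r) as.character(r$subject_id), ""))
  }
  sp <- prepare_split(subset_recordings(recs, subjects), split_seed = seed,
                      window_ms = profile$window_ms,
                      step_ms = profile$step_ms)
  nm <- normalize_split(sp$train, sp$test, normalization, mu)
  reports <- list(); models <- list()
  for (fam in families) {
    spec <- make_family_spec(fam, profile$model)
    tc <- profile$train
    tc$seed <- seed
    model <- build_regressor(spec, seed = seed)
    model <- train_regressor(model, nm$train, tc)
    models[[fam]] <- model
    for (sid in subjects) {
      keep <- Filter(function(d) d$provenance$subject_id == sid, nm$test)
      reports[[paste(sid, fam, sep = "/")]] <- evaluate_model(model, keep)
    }
  }
  structure(list(condition = "cross_subject", reports = reports,
                 table = summarize_reports(reports),
                 access_log = sp$log, models = models,
                 norm_spec = nm$norm_spec,
                 normalization = normalization, seed = seed),
            class = "experiment_result")
}

#' Transfer condition: adapt a cross-subject model to a held-out subject
#'
#' Trains the cross-subject model on the source subjects only (the held-out
#' subject must not appear in the pool), then compares the requested
#' approaches on identical target test trials: `noTL` evaluates the pooled
#' model directly (the target training trials are never touched), `FT`
#' fine-tunes the head on the target training trials, and `ATL` runs the
#' adversarial calibration against source-feature batches.
#'
#' @inheritParams run_subject_specific
#' @param approaches subset of `c("noTL", "FT", "ATL")`.
#' @param target_subject id of the held-out subject (default `"new"`).
#' @param source_model optional pre-trained cross-subject `emg_regressor`
#'   plus its normalization spec, as returned in a previous result's
#'   `source_model`/`norm_spec`; skips the pooled training.
#' @return Object of class `transfer_result`: per-approach
#'   `metrics_report`s, the comparison `table`, the `access_log`, the frozen
#'   `source_model` and the calibrated models.
#' @export
run_transfer <- function(cohort, approaches = c("noTL", "FT", "ATL"),
                         families = "roformer", normalization = "mu_law",
                         profile = desk_profile(), seed = 1,
                         target_subject = "new", mu = 2^20,
                         source_model = NULL) {
  fam <- families[1L]
  recs <- cohort$recordings
  source_ids <- if (inherits(cohort, "synthetic_cohort"))
    cohort_subject_ids(cohort)
  else setdiff(unique(vapply(recs, function(r) as.character(r$subject_id), "")),
               target_subject)
  if (target_subject %in% source_ids) {
    stop("held-out subject found in the source training pool")
  }
  sp_src <- prepare_split(subset_recordings(recs, source_ids),
                          split_seed = seed, window_ms = profile$window_ms,
                          step_ms = profile$step_ms)
  sp_tgt <- prepare_split(subset_recordings(recs, target_subject),
                          split_seed = seed, window_ms = profile$window_ms,
                          step_ms = profile$step_ms)
  log <- rbind(cbind(sp_src$log, domain = "source"),
               cbind(sp_tgt$log, domain = "target"))

  if (is.null(source_model)) {
    nm_src <- normalize_split(sp_src$train, sp_src$test, normalization, mu)
    tc <- profile$train
    tc$seed <- seed
    model <- build_regressor(make_family_spec(fam, profile$model),
                             seed = seed)
    model <- train_regressor(model, nm_src$train, tc)
    norm_spec <- nm_src$norm_spec
    src_train_norm <- nm_src$train
  } else {
    model <- source_model$model
    norm_spec <- source_model$norm_spec
    src_train_norm <- lapply(sp_src$train, function(d)
      feature_series(apply_normalization(d$features, norm_spec), d$labels,
                     d$window_ms, d$step_ms, d$provenance, norm_spec$hash))
  }
  # target features pass through the frozen source normalization
  renorm <- function(d) feature_series(
    apply_normalization(d$features, norm_spec), d$labels, d$window_ms,
    d$step_ms, d$provenance, norm_spec$hash)
  tgt_train <- lapply(sp_tgt$train, renorm)
  tgt_test <- lapply(sp_tgt$test, renorm)

  used <- list()
  reports <- list(); calibrated <- list()
  for (ap in approaches) {
    if (ap == "noTL") {
      reports[["noTL"]] <- evaluate_model(model, tgt_test)
      used[["noTL"]] <- character(0)  # target training trials untouched
    } else if (ap == "FT") {
      cc <- profile$calib
      cc$seed <- seed
      ftm <- ft_calibrate(model, tgt_train, cc)
      reports[["FT"]] <- evaluate_model(ftm, tgt_test)
      calibrated[["FT"]] <- ftm
      used[["FT"]] <- trial_keys(tgt_train)
    } else if (ap == "ATL") {
      cc <- profile$calib
      cc$seed <- seed
      atm <- atl_calibrate(model, tgt_train, src_train_norm, cc)
      reports[["ATL"]] <- evaluate_model(atm, tgt_test)
      calibrated[["ATL"]] <- atm
      used[["ATL"]] <- trial_keys(tgt_train)
    } else {
      stop("unknown transfer approach: ", ap)
    }
  }
  structure(list(condition = "transfer", reports = reports,
                 table = summarize_reports(reports), access_log = log,
                 target_train_used = used,
                 source_model = list(model = model, norm_spec = norm_spec),
                 calibrated = calibrated, family = fam,
                 test_keys = trial_keys(tgt_test),
                 normalization = normalization, seed = seed),
            class = "transfer_result")
}

#' Sweep the mu-law companding parameter
#'
#' Runs the subject-specific condition once per candidate `mu` (the
#' reference protocol searched 256 up to `2^20`) and stacks the summary
#' tables for comparison.
#'
#' @inheritParams run_subject_specific
#' @param mu_values companding parameters to try.
#' @return data.frame: one summary row per (mu, subject/family) condition.
#' @export
run_mu_sweep <- function(cohort, mu_values = c(256, 2^10, 2^15, 2^20),
                         families = "roformer", profile = desk_profile(),
                         seed = 1, subjects = NULL) {
  rows <- lapply(mu_values, function(mu) {
    res <- run_subject_specific(cohort, families = families,
                                normalization = "mu_law", profile = profile,
                                seed = seed, subjects = subjects, mu = mu)
    cbind(mu = mu, res$table)
  })
  do.call(rbind, rows)
}

trial_keys <- function(fs_list) {
  vapply(fs_list, function(d) paste(d$provenance$subject_id,
                                    d$provenance$movement_id,
                                    d$provenance$trial_id, sep = "/"), "")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> condition %s, %d reports\n",
              x$condition, length(x$reports)))
  print(x$table)
  invisible(x)
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("<transfer_result> approaches:",
      paste(names(x$reports), collapse = ", "), "\n")
  print(x$table)
  invisible(x)
}

#' Write the metric tables of an experiment to CSV files
#'
#' One per-joint CSV per report plus a `summary.csv` in the model x
#' Ave.CC / Ave.NRMSE / Ave.R2 layout.
#'
#' @param result an `experiment_result` or `transfer_result`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_experiment_reports <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(result$reports)) {
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".csv"))
    write_metrics_report(result$reports[[nm]], p)
    paths <- c(paths, p)
  }
  sp <- file.path(dir, "summary.csv")
  utils::write.csv(result$table, sp, row.names = FALSE)
  paths <- c(paths, sp)
  # calibration run logs (per-epoch losses and discriminator accuracy)
  for (nm in names(if (is.null(result$calibrated)) list() else result$calibrated)) {
    lg <- result$calibrated[[nm]]$calibration_log
    if (!is.null(lg)) {
      p <- file.path(dir, paste0("calibration_log_", nm, ".csv"))
      utils::write.csv(lg, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
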
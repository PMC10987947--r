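# Evaluation metrics: Pearson correlation, range-normalized RMSE and R^2,
# computed per joint and aggregated into a metrics report.

#' Pearson correlation between measured and estimated trajectories
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return Sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("series lengths differ")
  if (length(y_true) < 2L) stop("need at least 2 samples")
  if (stats::sd(y_true) == 0) stop("y_true has zero variance")
  if (stats::sd(y_pred) == 0) stop("y_pred has zero variance")
  stats::cor(y_true, y_pred)
}

#' Range-normalized root-mean-square error
#'
#' RMSE divided by the observed range `max(y_true) - min(y_true)`, so that
#' errors are scaled uniformly across joints with different excursions; an
#' in-range predictor scores in `[0, 1]`.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
nrmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("series lengths differ")
  rng <- max(y_true) - min(y_true)
  if (rng <= 0) stop("y_true is constant: NRMSE undefined")
  sqrt(mean((y_true - y_pred)^2)) / rng
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`. Values below zero (worse than predicting the mean)
#' are reported as-is rather than clipped, so failure modes stay visible.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("series lengths differ")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("y_true has zero variance")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Per-joint metrics between a label matrix and a prediction matrix
#'
#' @param labels,preds windows x joints matrices.
#' @return data.frame with one row per joint: `joint`, `cc`, `nrmse`, `r2`.
#' @export
joint_metrics <- function(labels, preds) {
  labels <- as.matrix(labels); preds <- as.matrix(preds)
  if (!all(dim(labels) == dim(preds))) stop("label/prediction shape mismatch")
  data.frame(
    joint = seq_len(ncol(labels)),
    cc = vapply(seq_len(ncol(labels)), function(j)
      pearson_cc(labels[, j], preds[, j]), 0),
    nrmse = vapply(seq_len(ncol(labels)), function(j)
      nrmse(labels[, j], preds[, j]), 0),
    r2 = vapply(seq_len(ncol(labels)), function(j)
      r_squared(labels[, j], preds[, j]), 0))
}

#' Evaluate a regressor on held-out feature series
#'
#' Test windows are concatenated per (subject, movement) group, predictions
#' computed with the model, and CC / NRMSE / R^2 computed per joint within
#' each group, then averaged over joints, and finally over groups.
#'
#' @param model a trained regressor ([train_regressor()]) or any object with
#'   a `predict` method mapping a windows x channels matrix to a windows x
#'   joints matrix.
#' @param test_data a `feature_series` or list of them.
#' @param check_norm if TRUE (default), error when the model records a
#'   normalization-spec hash different from the data's.
#' @return An object of class `metrics_report`: `per_joint` (data.frame with
#'   subject, movement, joint and the three metrics), `by_group` (metrics
#'   averaged over joints per group) and `averaged` (means over everything).
#' @export
evaluate_model <- function(model, test_data, check_norm = TRUE) {
  if (inherits(test_data, "feature_series")) test_data <- list(test_data)
  if (!length(test_data)) stop("no test data")
  if (check_norm && !is.null(model$norm_hash) && !is.na(model$norm_hash)) {
    hashes <- vapply(test_data, function(d) as.character(d$norm_hash), "")
    bad <- hashes[!is.na(hashes)] != model$norm_hash
    if (any(bad)) {
      stop("normalization-spec hash mismatch between model and test data; ",
           "apply the model's stored spec to the test features")
    }
  }
  key <- vapply(test_data, function(d)
    paste(d$provenance$subject_id, d$provenance$movement_id, sep = "\r"), "")
  groups <- split(test_data, key)
  rows <- list()
  for (g in groups) {
    feats <- do.call(rbind, lapply(g, function(d) d$features))
    labs <- do.call(rbind, lapply(g, function(d) d$labels))
    preds <- stats::predict(model, feats)
    jm <- joint_metrics(labs, preds)
    jm$subject_id <- g[[1]]$provenance$subject_id
    jm$movement_id <- g[[1]]$provenance$movement_id
    rows[[length(rows) + 1L]] <- jm
  }
  per_joint <- do.call(rbind, rows)
  per_joint <- per_joint[, c("subject_id", "movement_id", "joint",
                             "cc", "nrmse", "r2")]
  agg <- stats::aggregate(per_joint[, c("cc", "nrmse", "r2")],
                          by = per_joint[, c("subject_id", "movement_id")],
                          FUN = mean)
  structure(
    list(per_joint = per_joint,
         by_group = agg,
         averaged = c(cc = mean(per_joint$cc),
                      nrmse = mean(per_joint$nrmse),
                      r2 = mean(per_joint$r2)),
         n_windows = sum(vapply(test_data,
                                function(d) nrow(d$features), 0L))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> %d joint rows, %d groups | Ave.CC %.4f  Ave.NRMSE %.4f  Ave.R2 %.4f\n",
    nrow(x$per_joint), nrow(x$by_group),
    x$averaged["cc"], x$averaged["nrmse"], x$averaged["r2"]))
  invisible(x)
}

#' Summarize a set of metrics reports as mean +/- sd rows
#'
#' One row per condition label with the across-report mean and standard
#' deviation of the joint-averaged metrics, in the layout of a model x
#' Ave.CC / Ave.NRMSE / Ave.R2 comparison table.
#'
#' @param reports named list of `metrics_report` objects (or list of lists,
#'   one inner list per condition).
#' @return data.frame with columns condition, cc_mean, cc_sd, nrmse_mean,
#'   nrmse_sd, r2_mean, r2_sd, n.
#' @export
summarize_reports <- function(reports) {
  rows <- lapply(names(reports), function(nm) {
    rs <- reports[[nm]]
    if (inherits(rs, "metrics_report")) rs <- list(rs)
    m <- t(vapply(rs, function(r) r$averaged, c(cc = 0, nrmse = 0, r2 = 0)))
    data.frame(condition = nm,
               cc_mean = mean(m[, "cc"]), cc_sd = stats::sd(m[, "cc"]),
               nrmse_mean = mean(m[, "nrmse"]), nrmse_sd = stats::sd(m[, "nrmse"]),
               r2_mean = mean(m[, "r2"]), r2_sd = stats::sd(m[, "r2"]),
               n = nrow(m))
  })
  do.call(rbind, rows)
}

#' Write a metrics report to CSV
#'
#' @param report a `metrics_report`.
#' @param path output CSV path (per-joint long format).
#' @return Invisibly, `path`.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  utils::write.csv(report$per_joint, path, row.names = FALSE)
  invisible(path)
}
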
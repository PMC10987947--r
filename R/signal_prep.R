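# Feature extraction and normalization: raw paired sEMG/angle recordings are
# converted into windowed RMS envelope features with time-aligned joint-angle
# labels, normalized either by mu-law companding or per-channel Z-scoring.

#' One subject/movement/trial of paired sEMG and glove angles
#'
#' Container for a raw recording: a multi-channel sEMG matrix sampled at
#' `fs_emg` and a joint-angle matrix (degrees) sampled at `fs_angles`.
#'
#' @param subject_id,movement_id opaque identifiers.
#' @param trial_id integer trial index (1..6 in the standard protocol).
#' @param emg numeric matrix, samples x channels.
#' @param angles numeric matrix, samples x joints, degrees.
#' @param fs_emg,fs_angles sampling rates in Hz.
#' @return An object of class `subject_recording`.
#' @export
subject_recording <- function(subject_id, movement_id, trial_id,
                              emg, angles, fs_emg, fs_angles) {
  emg <- as.matrix(emg); angles <- as.matrix(angles)
  if (!all(is.finite(emg))) stop("emg contains non-finite values")
  if (!all(is.finite(angles))) stop("angles contain non-finite values")
  if (fs_emg <= 0 || fs_angles <= 0) stop("sampling rates must be positive")
  dur_emg <- nrow(emg) / fs_emg
  dur_ang <- nrow(angles) / fs_angles
  if (abs(dur_emg - dur_ang) > 1.5 / fs_angles) {
    stop(sprintf(
      "emg (%.3f s) and angle (%.3f s) durations disagree by more than one label period",
      dur_emg, dur_ang))
  }
  structure(
    list(subject_id = subject_id, movement_id = movement_id,
         trial_id = as.integer(trial_id), emg = emg, angles = angles,
         fs_emg = fs_emg, fs_angles = fs_angles),
    class = "subject_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf(
    "<subject_recording> subject %s, movement %s, trial %d: %d x %d emg @ %g Hz, %d x %d angles @ %g Hz\n",
    x$subject_id, x$movement_id, x$trial_id,
    nrow(x$emg), ncol(x$emg), x$fs_emg,
    nrow(x$angles), ncol(x$angles), x$fs_angles))
  invisible(x)
}

#' Sliding-window RMS envelope of a multi-channel signal
#'
#' Computes the root-mean-square of each channel over a sliding window.
#' Windows are indexed 0-based over half-open sample intervals
#' `[w*S, w*S + W)`; the number of windows is `floor((n - W)/S) + 1`.
#'
#' @param emg numeric matrix, samples x channels.
#' @param fs sampling rate in Hz.
#' @param window_ms window duration in milliseconds (default 100).
#' @param step_ms step between window starts in milliseconds (default 50).
#' @return Matrix of RMS values, windows x channels.
#' @export
compute_rms_windows <- function(emg, fs, window_ms = 100, step_ms = 50) {
  emg <- as.matrix(emg)
  W <- max(1L, as.integer(round(window_ms / 1000 * fs)))
  S <- max(1L, as.integer(round(step_ms / 1000 * fs)))
  n <- nrow(emg)
  if (n < W) {
    stop(sprintf("signal has %d samples but one window needs %d", n, W))
  }
  n_win <- (n - W) %/% S + 1L
  # cumulative sums of squares give each window sum in O(1)
  cs <- apply(emg * emg, 2L, cumsum)
  cs <- rbind(0, cs)
  starts <- (seq_len(n_win) - 1L) * S
  sums <- cs[starts + W + 1L, , drop = FALSE] - cs[starts + 1L, , drop = FALSE]
  sums[sums < 0] <- 0  # guard tiny negative rounding residue
  out <- sqrt(sums / W)
  colnames(out) <- colnames(emg)
  out
}

#' Mu-law companding normalization
#'
#' Odd logarithmic compander `F(x) = sign(x) ln(1 + mu |x|) / ln(1 + mu)`,
#' which amplifies small amplitudes while keeping the output in `[-1, 1]`.
#' Inputs must already lie in `[-1, 1]` (see [fit_normalization()] for the
#' per-channel prescaling that guarantees this for RMS features).
#'
#' @param x numeric vector or matrix with `|x| <= 1`.
#' @param mu positive companding parameter; default `2^20`.
#' @return Object of the same shape as `x`, values in `[-1, 1]`.
#' @seealso [mu_law_inverse()]
#' @export
mu_law_normalize <- function(x, mu = 2^20) {
  if (mu <= 0) stop("mu must be positive")
  mx <- max(abs(x))
  if (mx > 1 + 1e-12) {
    stop(sprintf("mu-law input must lie in [-1, 1]; max |x| = %.6g (prescale misconfigured)", mx))
  }
  sign(x) * log1p(mu * abs(x)) / log1p(mu)
}

#' Inverse of mu-law companding
#'
#' @param y numeric vector or matrix with `|y| <= 1`.
#' @param mu positive companding parameter used by [mu_law_normalize()].
#' @return The expanded signal, `sign(y) ((1 + mu)^|y| - 1) / mu`.
#' @export
mu_law_inverse <- function(y, mu = 2^20) {
  if (mu <= 0) stop("mu must be positive")
  my <- max(abs(y))
  if (my > 1 + 1e-12) {
    stop(sprintf("mu-law inverse input must lie in [-1, 1]; max |y| = %.6g", my))
  }
  sign(y) * expm1(abs(y) * log1p(mu)) / mu
}

#' Per-channel Z-score normalization
#'
#' @param x numeric matrix, samples x channels.
#' @param mean,std per-channel statistics (fitted on training data only).
#' @return `(x - mean) / std` column-wise.
#' @export
zscore_normalize <- function(x, mean, std) {
  x <- as.matrix(x)
  if (length(mean) != ncol(x) || length(std) != ncol(x)) {
    stop("mean/std length must equal the number of channels")
  }
  bad <- which(std <= 0)
  if (length(bad)) {
    stop("zero or negative standard deviation in channel(s) ",
         paste(bad, collapse = ", "))
  }
  sweep(sweep(x, 2L, mean, "-"), 2L, std, "/")
}

#' Fit a normalization specification on training features
#'
#' For `method = "mu_law"` the prescale is the per-channel maximum absolute
#' value of the training features, so that the companding precondition
#' `|x| <= 1` holds on the data it was fitted on; at apply time out-of-range
#' values are clipped to `[-1, 1]`. For `method = "zscore"` the per-channel
#' mean and standard deviation are recorded. Statistics are frozen: apply the
#' same spec to validation/test/target data.
#'
#' @param features training feature matrix, windows x channels.
#' @param method `"mu_law"` or `"zscore"`.
#' @param mu companding parameter for the mu-law method (default `2^20`).
#' @return An object of class `normalization_spec`.
#' @export
fit_normalization <- function(features, method = c("mu_law", "zscore"),
                              mu = 2^20) {
  method <- match.arg(method)
  features <- as.matrix(features)
  spec <- list(method = method, mu = mu, n_channels = ncol(features))
  if (method == "mu_law") {
    pre <- apply(abs(features), 2L, max)
    pre[pre == 0] <- 1  # silent channel: any scale keeps it at zero
    spec$prescale <- pre
  } else {
    spec$zscore_mean <- colMeans(features)
    spec$zscore_std <- apply(features, 2L, stats::sd)
    bad <- which(spec$zscore_std <= 0)
    if (length(bad)) {
      stop("constant training channel(s) ", paste(bad, collapse = ", "),
           ": Z-score undefined")
    }
  }
  spec$hash <- spec_hash(spec[setdiff(names(spec), "hash")])
  class(spec) <- "normalization_spec"
  spec
}

#' Apply a fitted normalization specification
#'
#' @param features feature matrix, windows x channels.
#' @param spec a `normalization_spec` from [fit_normalization()].
#' @return Normalized feature matrix of the same shape.
#' @export
apply_normalization <- function(features, spec) {
  stopifnot(inherits(spec, "normalization_spec"))
  features <- as.matrix(features)
  if (ncol(features) != spec$n_channels) {
    stop(sprintf("spec fitted on %d channels, data has %d",
                 spec$n_channels, ncol(features)))
  }
  if (spec$method == "mu_law") {
    x <- sweep(features, 2L, spec$prescale, "/")
    x <- pmin(pmax(x, -1), 1)  # clip unseen out-of-range amplitudes
    mu_law_normalize(x, spec$mu)
  } else {
    zscore_normalize(features, spec$zscore_mean, spec$zscore_std)
  }
}

# order-insensitive-enough structural hash for spec provenance checks
spec_hash <- function(obj) {
  s <- paste(utils::capture.output(utils::str(obj, digits.d = 10)),
             collapse = "\n")
  v <- utf8ToInt(s)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h <- (h * 33 + sum(chunk * (seq_along(chunk) %% 251 + 1))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Linearly resample a label series to a higher rate
#'
#' @param angles numeric matrix, samples x joints.
#' @param fs_from,fs_to source and target sampling rates, `fs_to >= fs_from`.
#' @return Matrix with `round(nrow(angles) * fs_to / fs_from)` rows.
#' @export
resample_labels <- function(angles, fs_from, fs_to) {
  angles <- as.matrix(angles)
  if (nrow(angles) < 2L) stop("need at least 2 label samples to resample")
  if (fs_to < fs_from) stop("fs_to must be >= fs_from")
  if (!all(is.finite(angles))) stop("angles contain non-finite values")
  m <- nrow(angles)
  t_src <- (seq_len(m) - 1L) / fs_from
  n_out <- as.integer(round(m * fs_to / fs_from))
  # output grid spans exactly the recorded interval, so no extrapolation
  t_out <- seq(0, t_src[m], length.out = n_out)
  out <- matrix(0, n_out, ncol(angles))
  for (j in seq_len(ncol(angles))) {
    out[, j] <- stats::approx(t_src, angles[, j], xout = t_out, rule = 2)$y
  }
  colnames(out) <- colnames(angles)
  out
}

#' Split the six trials of a movement into train and test sets
#'
#' Reproducible seeded 4/2 partition of trial identifiers. The same seed
#' yields the same partition, so all movements of a subject can share one
#' split.
#'
#' @param trials vector of exactly `n_train + n_test` trial ids.
#' @param n_train,n_test partition sizes (defaults 4 and 2).
#' @param seed integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_trials <- function(trials, n_train = 4, n_test = 2, seed) {
  trials <- unique(trials)
  if (length(trials) != n_train + n_test) {
    stop(sprintf("expected %d distinct trials, got %d",
                 n_train + n_test, length(trials)))
  }
  if (missing(seed)) stop("seed is required for a reproducible split")
  tr <- with_seed(seed, sort(sample(trials, n_train)))
  list(train = tr, test = sort(setdiff(trials, tr)))
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Windowed, normalized features with aligned labels for one recording
#'
#' Computes sliding-window RMS features from the sEMG, resamples the angle
#' labels to the sEMG rate, and picks one label row per feature window at the
#' window-center timestamp. If `norm_spec` is supplied the features are
#' normalized with it; otherwise raw RMS values are returned (normalize later
#' with a spec fitted on training data only).
#'
#' @param recording a [subject_recording()].
#' @param window_ms,step_ms RMS window and step durations in milliseconds.
#' @param norm_spec optional `normalization_spec`.
#' @return An object of class `feature_series` with matrices `features`
#'   (windows x channels) and `labels` (windows x joints, degrees).
#' @export
make_feature_series <- function(recording, window_ms = 100, step_ms = 50,
                                norm_spec = NULL) {
  stopifnot(inherits(recording, "subject_recording"))
  feats <- compute_rms_windows(recording$emg, recording$fs_emg,
                               window_ms, step_ms)
  fs <- recording$fs_emg
  lab_hi <- if (recording$fs_angles < fs) {
    resample_labels(recording$angles, recording$fs_angles, fs)
  } else {
    recording$angles
  }
  W <- max(1L, as.integer(round(window_ms / 1000 * fs)))
  S <- max(1L, as.integer(round(step_ms / 1000 * fs)))
  centers <- (seq_len(nrow(feats)) - 1L) * S + (W - 1) / 2  # 0-based sample
  lab_idx <- pmin(pmax(round(centers) + 1L, 1L), nrow(lab_hi))
  labels <- lab_hi[lab_idx, , drop = FALSE]
  if (!is.null(norm_spec)) feats <- apply_normalization(feats, norm_spec)
  feature_series(
    features = feats, labels = labels,
    window_ms = window_ms, step_ms = step_ms,
    provenance = list(subject_id = recording$subject_id,
                      movement_id = recording$movement_id,
                      trial_id = recording$trial_id),
    norm_hash = if (is.null(norm_spec)) NA_character_ else norm_spec$hash)
}

#' Construct a feature series
#'
#' @param features windows x channels matrix.
#' @param labels windows x joints matrix (degrees).
#' @param window_ms,step_ms window geometry used to build the features.
#' @param provenance list with `subject_id`, `movement_id`, `trial_id`.
#' @param norm_hash hash of the normalization spec applied (NA if raw).
#' @return Object of class `feature_series`.
#' @export
feature_series <- function(features, labels, window_ms, step_ms,
                           provenance, norm_hash = NA_character_) {
  features <- as.matrix(features); labels <- as.matrix(labels)
  if (nrow(features) != nrow(labels)) {
    stop("features and labels must have the same number of windows")
  }
  if (anyNA(features) || anyNA(labels)) stop("missing values not allowed")
  structure(
    list(features = features, labels = labels, window_ms = window_ms,
         step_ms = step_ms, provenance = provenance, norm_hash = norm_hash),
    class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<feature_series> subject %s, movement %s, trial %s: %d windows x %d channels, %d joints (window %g ms, step %g ms)\n",
    p$subject_id, p$movement_id, p$trial_id, nrow(x$features),
    ncol(x$features), ncol(x$labels), x$window_ms, x$step_ms))
  invisible(x)
}

#' Write a feature series as a CSV pair with a metadata sidecar
#'
#' Creates `<prefix>_features.csv` (channels `ch01..`), `<prefix>_labels.csv`
#' (joints `j01..`) and `<prefix>_meta.txt` (key: value lines recording the
#' window geometry, provenance and normalization hash).
#'
#' @param x a `feature_series`.
#' @param prefix path prefix for the three files.
#' @return Invisibly, the three file paths.
#' @export
write_feature_series <- function(x, prefix) {
  stopifnot(inherits(x, "feature_series"))
  f <- x$features; l <- x$labels
  colnames(f) <- sprintf("ch%02d", seq_len(ncol(f)))
  colnames(l) <- sprintf("j%02d", seq_len(ncol(l)))
  pf <- paste0(prefix, "_features.csv")
  pl <- paste0(prefix, "_labels.csv")
  pm <- paste0(prefix, "_meta.txt")
  utils::write.csv(as.data.frame(f), pf, row.names = FALSE)
  utils::write.csv(as.data.frame(l), pl, row.names = FALSE)
  meta <- c(
    sprintf("subject_id: %s", x$provenance$subject_id),
    sprintf("movement_id: %s", x$provenance$movement_id),
    sprintf("trial_id: %s", x$provenance$trial_id),
    sprintf("window_ms: %g", x$window_ms),
    sprintf("step_ms: %g", x$step_ms),
    sprintf("norm_hash: %s", x$norm_hash))
  writeLines(meta, pm)
  invisible(c(pf, pl, pm))
}

#' Read a feature series written by [write_feature_series()]
#'
#' @param prefix path prefix used when writing.
#' @return A `feature_series`.
#' @export
read_feature_series <- function(prefix) {
  f <- as.matrix(utils::read.csv(paste0(prefix, "_features.csv")))
  l <- as.matrix(utils::read.csv(paste0(prefix, "_labels.csv")))
  meta <- readLines(paste0(prefix, "_meta.txt"))
  kv <- strsplit(meta, ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  feature_series(
    features = f, labels = l,
    window_ms = as.numeric(vals[["window_ms"]]),
    step_ms = as.numeric(vals[["step_ms"]]),
    provenance = list(subject_id = vals[["subject_id"]],
                      movement_id = vals[["movement_id"]],
                      trial_id = vals[["trial_id"]]),
    norm_hash = vals[["norm_hash"]])
}
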
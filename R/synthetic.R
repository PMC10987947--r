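# Seeded simulator of paired sEMG/kinematics cohorts.
#
# Each subject is a set of per-channel gains, a non-negative muscle-synergy
# mixing matrix and a per-muscle activation nonlinearity. A trial is built in
# three stages: (1) smooth sigmoidal joint-angle trajectories from rest to a
# movement-specific posture and back, with trial-level timing jitter; (2)
# non-negative muscle activations read out from normalized angles and
# angular speeds, raised to the subject's nonlinearity exponent; (3) sEMG as
# a band-limited zero-mean noise carrier amplitude-modulated by the mixed
# activations, plus additive sensor noise. Inter-subject domain shift is a
# multiplicative perturbation of the mixing, gains and exponents; the
# held-out "new" subject is perturbed from the cohort mean by
# `shift_magnitude` (0 = identical domains).

#' Cohort-level simulation parameters
#'
#' Defaults mirror the standard acquisition protocol: 10 subjects, 6 grasp
#' movements, 6 trials each, 12 sEMG channels at 2 kHz and glove angles at
#' 20 Hz with 10 joints.
#'
#' @param n_subjects training-cohort size (default 10).
#' @param n_movements distinct movements (default 6).
#' @param n_trials trials per movement (default 6).
#' @param trial_duration_s trial length in seconds (default 5).
#' @param fs_emg,fs_angles sampling rates in Hz (defaults 2000 and 20).
#' @param n_joints glove joints (default 10).
#' @param n_channels sEMG channels (default 12).
#' @param n_muscles latent muscles in the synergy model (default 10).
#' @param shift_magnitude log-scale of the held-out subject's perturbation
#'   from the cohort mean (default 0 = identical domains).
#' @param subject_sd log-scale of within-cohort subject variability
#'   (default 0.08).
#' @param noise_sd additive sensor-noise standard deviation, in carrier
#'   units (default 0.02).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10, n_movements = 6, n_trials = 6,
                        trial_duration_s = 5, fs_emg = 2000, fs_angles = 20,
                        n_joints = 10, n_channels = 12, n_muscles = 10,
                        shift_magnitude = 0, subject_sd = 0.08,
                        noise_sd = 0.02) {
  if (any(c(n_subjects, n_movements, n_trials, trial_duration_s, fs_emg,
            fs_angles, n_joints, n_channels, n_muscles) <= 0)) {
    stop("all counts, durations and rates must be positive")
  }
  if (shift_magnitude < 0) stop("shift_magnitude must be >= 0")
  structure(list(n_subjects = n_subjects, n_movements = n_movements,
                 n_trials = n_trials, trial_duration_s = trial_duration_s,
                 fs_emg = fs_emg, fs_angles = fs_angles,
                 n_joints = n_joints, n_channels = n_channels,
                 n_muscles = n_muscles, shift_magnitude = shift_magnitude,
                 subject_sd = subject_sd, noise_sd = noise_sd),
            class = "cohort_spec")
}

#' Cohort-shared structure: postures, synergy read-outs, mean subject
#'
#' Deterministic in `master_seed`: movement target postures (degrees, within
#' the physiological 0-90 range), the non-negative angle/velocity read-out
#' weights of each latent muscle, and the cohort-mean subject (structured
#' mixing matrix, unit gains, exponent 1).
#'
#' @param spec a [cohort_spec()].
#' @param master_seed integer seed.
#' @return List with `targets` (movements x joints), `rest` (resting angle),
#'   `W_ang`, `W_vel` (muscles x joints) and `mean_subject`.
#' @export
cohort_base <- function(spec, master_seed) {
  with_seed(master_seed, {
    targets <- matrix(stats::runif(spec$n_movements * spec$n_joints, 20, 80),
                      spec$n_movements, spec$n_joints)
    # each (movement, joint) pair gets its own excursion center and
    # half-width, so per-joint trajectories are not scaled copies of one
    # profile and decoding them requires the channel pattern, not just the
    # gross envelope
    exc_center <- matrix(stats::runif(spec$n_movements * spec$n_joints,
                                      0.30, 0.70),
                         spec$n_movements, spec$n_joints)
    exc_halfwidth <- matrix(stats::runif(spec$n_movements * spec$n_joints,
                                         0.08, 0.20),
                            spec$n_movements, spec$n_joints)
    # each muscle is recruited primarily by one joint (cycling when counts
    # differ) with a little random spill-over, so the angle -> envelope map
    # is informative enough to be invertible in principle
    spill <- matrix(stats::runif(spec$n_muscles * spec$n_joints),
                    spec$n_muscles, spec$n_joints)
    spill[spill < 0.6] <- 0
    spill <- 0.3 * spill / pmax(rowSums(spill), 1e-8)
    W_ang <- spill
    for (mu in seq_len(spec$n_muscles)) {
      W_ang[mu, (mu - 1L) %% spec$n_joints + 1L] <-
        W_ang[mu, (mu - 1L) %% spec$n_joints + 1L] + 0.7
    }
    W_ang <- W_ang / rowSums(W_ang)
    W_vel <- matrix(stats::runif(spec$n_muscles * spec$n_joints),
                    spec$n_muscles, spec$n_joints)
    W_vel[W_vel < 0.6] <- 0
    W_vel <- 0.5 * W_vel / pmax(rowSums(W_vel), 1e-8)
    # each channel dominated by one muscle with spill-over to a neighbour
    mixing <- matrix(0, spec$n_channels, spec$n_muscles)
    for (c in seq_len(spec$n_channels)) {
      m1 <- (c - 1L) %% spec$n_muscles + 1L
      m2 <- c %% spec$n_muscles + 1L
      mixing[c, m1] <- 1
      mixing[c, m2] <- 0.3
    }
    mean_subject <- synthetic_subject_spec(
      subject_id = "mean",
      mixing = mixing,
      gain = rep(1, spec$n_channels),
      noise_sd = rep(spec$noise_sd, spec$n_channels),
      exponent = rep(1, spec$n_muscles),
      seed = master_seed,
      W_ang = W_ang, W_vel = W_vel)
    list(targets = targets, exc_center = exc_center,
         exc_halfwidth = exc_halfwidth, rest = 5,
         W_ang = W_ang, W_vel = W_vel, mean_subject = mean_subject)
  })
}

#' Per-subject simulation parameters
#'
#' @param subject_id opaque identifier.
#' @param mixing channels x muscles non-negative synergy weights; every
#'   channel must receive at least one non-zero weight.
#' @param gain per-channel positive amplitude gain.
#' @param noise_sd per-channel additive-noise standard deviation.
#' @param exponent per-muscle activation nonlinearity exponent (near 1).
#' @param seed subject-level seed.
#' @param W_ang,W_vel optional subject-specific muscle recruitment read-outs
#'   (muscles x joints, non-negative); `NULL` falls back to the cohort-level
#'   read-outs, i.e. cohort-average recruitment.
#' @return Object of class `synthetic_subject_spec`.
#' @export
synthetic_subject_spec <- function(subject_id, mixing, gain, noise_sd,
                                   exponent, seed, W_ang = NULL,
                                   W_vel = NULL) {
  mixing <- as.matrix(mixing)
  if (any(mixing < 0)) stop("mixing weights must be non-negative")
  if (any(rowSums(mixing) == 0)) {
    stop("every channel needs at least one non-zero mixing weight")
  }
  if (any(gain <= 0)) stop("gains must be positive")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (!is.null(W_ang) && any(W_ang < 0)) stop("W_ang must be non-negative")
  structure(list(subject_id = subject_id, mixing = mixing, gain = gain,
                 noise_sd = noise_sd, exponent = exponent, seed = seed,
                 W_ang = W_ang, W_vel = W_vel),
            class = "synthetic_subject_spec")
}

# Perturbation of the mean subject by magnitude `sd`; sd = 0 returns the
# mean subject exactly. Three components model the empirical sources of
# inter-subject difference: (1) amplitude idiosyncrasy, a log-normal jitter
# of mixing weights, gains and activation exponents; (2) electrode-placement
# idiosyncrasy, an interpolation of the synergy routing toward a
# subject-specific random channel-to-muscle assignment; (3) recruitment
# idiosyncrasy, the same interpolation applied to the angle/velocity
# read-outs that define which joints drive which muscles.
perturb_subject <- function(base_subject, sd, subject_id, seed) {
  with_seed(seed, {
    m <- base_subject$mixing
    n_ch <- nrow(m); n_mu <- ncol(m)
    m_jit <- m * exp(sd * stats::rnorm(length(m)))
    m_rand <- matrix(0, n_ch, n_mu)
    for (c in seq_len(n_ch)) {
      m1 <- sample.int(n_mu, 1L)
      m_rand[c, m1] <- 1
      m_rand[c, m1 %% n_mu + 1L] <- 0.3
    }
    a <- min(sd, 1)
    m2 <- (1 - a) * m_jit + a * m_rand
    g2 <- base_subject$gain * exp(sd * stats::rnorm(length(base_subject$gain)))
    e2 <- pmin(pmax(base_subject$exponent +
                      0.5 * sd * stats::rnorm(length(base_subject$exponent)),
                    0.5), 1.8)
    rand_readout <- function(W, thresh, floor_w) {
      Wr <- matrix(stats::runif(length(W)), nrow(W))
      Wr[Wr < thresh] <- 0
      Wr <- Wr + floor_w
      Wr / pmax(rowSums(Wr), 1e-8)
    }
    Wa2 <- (1 - a) * base_subject$W_ang +
      a * rand_readout(base_subject$W_ang, 0.5, 0.05)
    Wv_rand <- rand_readout(base_subject$W_vel, 0.6, 0)
    Wv2 <- (1 - a) * base_subject$W_vel + a * Wv_rand
    synthetic_subject_spec(subject_id, m2, g2, base_subject$noise_sd, e2,
                           seed, W_ang = Wa2, W_vel = Wv2)
  })
}

sigmoid_num <- function(x) 1 / (1 + exp(-x))

trial_seed <- function(subject_seed, movement_id, trial_id) {
  as.integer((abs(subject_seed) * 7919 + movement_id * 131 + trial_id) %%
               2147483641)
}

#' Simulate one trial of one subject
#'
#' @param subject_spec a [synthetic_subject_spec()].
#' @param movement_id movement index (row of `base$targets`).
#' @param trial_id trial index.
#' @param spec the [cohort_spec()].
#' @param base the [cohort_base()] shared structure.
#' @return A [subject_recording()]; bit-identical for equal arguments.
#' @export
generate_trial <- function(subject_spec, movement_id, trial_id, spec, base) {
  stopifnot(inherits(subject_spec, "synthetic_subject_spec"),
            inherits(spec, "cohort_spec"))
  seed <- trial_seed(subject_spec$seed, movement_id, trial_id)
  with_seed(seed, {
    D <- spec$trial_duration_s
    m <- as.integer(round(D * spec$fs_angles))
    t <- (seq_len(m) - 1L) / spec$fs_angles
    # hold-rise-hold-fall posture profile with timing and amplitude jitter
    # trial-level jitter shifts and stretches the whole movement a little;
    # the per-joint excursion timing itself is a movement property
    t_shift <- D * stats::runif(1, -0.04, 0.04)
    tau <- D * 0.05
    amp_jit <- stats::runif(spec$n_joints, 0.92, 1.08)
    tgt <- base$targets[movement_id, ] * amp_jit
    angles <- matrix(0, m, spec$n_joints)
    for (j in seq_len(spec$n_joints)) {
      c_j <- D * base$exc_center[movement_id, j] + t_shift
      h_j <- D * base$exc_halfwidth[movement_id, j]
      prof <- sigmoid_num((t - (c_j - h_j)) / tau) -
        sigmoid_num((t - (c_j + h_j)) / tau)
      angles[, j] <- base$rest + (tgt[j] - base$rest) * prof
    }

    # muscle activations from normalized angles and angular speeds
    ang_norm <- angles / 90
    vel <- rbind(0, diff(angles)) * spec$fs_angles  # deg/s
    vel_norm <- abs(vel) / 200  # ~unit scale for a 1 s excursion
    Wa <- if (is.null(subject_spec$W_ang)) base$W_ang else subject_spec$W_ang
    Wv <- if (is.null(subject_spec$W_vel)) base$W_vel else subject_spec$W_vel
    act <- ang_norm %*% t(Wa) + vel_norm %*% t(Wv)
    act[act < 0] <- 0
    act <- sweep(act, 2L, subject_spec$exponent, `^`)

    # per-channel envelope, upsampled to the sEMG rate
    env <- act %*% t(subject_spec$mixing)
    env <- sweep(env, 2L, subject_spec$gain, "*")
    env_hi <- resample_labels(env, spec$fs_angles, spec$fs_emg)
    n <- nrow(env_hi)

    # band-limited carrier in the standard surface-EMG energy band
    lo <- 20 / (spec$fs_emg / 2)
    hi <- min(450 / (spec$fs_emg / 2), 0.98)
    bf <- signal::butter(4, c(lo, hi), type = "pass")
    carrier <- matrix(stats::rnorm(n * spec$n_channels), n)
    for (ch in seq_len(spec$n_channels)) {
      x <- signal::filtfilt(bf, carrier[, ch])
      s <- stats::sd(x)
      carrier[, ch] <- if (s > 0) x / s else x
    }
    emg <- env_hi * carrier +
      matrix(stats::rnorm(n * spec$n_channels), n) *
        rep(subject_spec$noise_sd, each = n)

    subject_recording(subject_spec$subject_id, movement_id, trial_id,
                      emg, angles, spec$fs_emg, spec$fs_angles)
  })
}

#' Simulate a full cohort plus a shifted held-out subject
#'
#' Draws `n_subjects` subjects around the cohort mean (log-normal
#' variability `subject_sd`) and one additional held-out subject
#' (`subject_id` `"new"`) perturbed from the mean by `shift_magnitude`, then
#' generates the complete movements x trials grid for every subject.
#'
#' @param spec a [cohort_spec()].
#' @param master_seed integer seed; all trial-level randomness derives from
#'   it, so cohorts regenerate exactly.
#' @return Object of class `synthetic_cohort`: `recordings` (list of
#'   [subject_recording()]), `subject_specs`, `held_out_spec`, `base`,
#'   `spec`, `master_seed`.
#' @export
generate_cohort <- function(spec, master_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- cohort_base(spec, master_seed)
  subj_specs <- lapply(seq_len(spec$n_subjects), function(i) {
    perturb_subject(base$mean_subject, spec$subject_sd,
                    subject_id = sprintf("s%02d", i),
                    seed = (master_seed + 97L * i) %% 2147483641)
  })
  held_out <- perturb_subject(base$mean_subject, spec$shift_magnitude,
                              subject_id = "new",
                              seed = (master_seed + 31337L) %% 2147483641)
  all_specs <- c(subj_specs, list(held_out))
  recordings <- list()
  for (ss in all_specs) {
    for (mv in seq_len(spec$n_movements)) {
      for (tr in seq_len(spec$n_trials)) {
        recordings[[length(recordings) + 1L]] <-
          generate_trial(ss, mv, tr, spec, base)
      }
    }
  }
  structure(list(recordings = recordings, subject_specs = subj_specs,
                 held_out_spec = held_out, base = base, spec = spec,
                 master_seed = master_seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d+1 subjects x %d movements x %d trials (%d recordings), shift %.2f, seed %d\n",
    x$spec$n_subjects, x$spec$n_movements, x$spec$n_trials,
    length(x$recordings), x$spec$shift_magnitude, x$master_seed))
  invisible(x)
}

#' Write a cohort manifest for exact regeneration
#'
#' Structured-text (key: value) file with every cohort-spec field and the
#' master seed; [read_cohort_manifest()] regenerates the identical cohort.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  sp <- cohort$spec
  lines <- c(sprintf("master_seed: %d", cohort$master_seed),
             vapply(names(unclass(sp)), function(nm)
               sprintf("%s: %.10g", nm, sp[[nm]]), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Regenerate a cohort from its manifest
#'
#' @param path manifest written by [write_cohort_manifest()].
#' @return The regenerated `synthetic_cohort`.
#' @export
read_cohort_manifest <- function(path) {
  kv <- strsplit(readLines(path), ": ", fixed = TRUE)
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                          vapply(kv, `[`, "", 1L))
  sp <- do.call(cohort_spec, as.list(vals[setdiff(names(vals), "master_seed")]))
  generate_cohort(sp, as.integer(vals[["master_seed"]]))
}
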
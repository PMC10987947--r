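# Calibrating a multi-subject model to a new subject.
#
# Two routes: adversarial transfer learning (ATL), where a domain
# discriminator (DD) is trained to tell the frozen source network's
# penultimate features from the target network's while the target network
# learns to fool it and to fit the new subject's labels; and plain
# fine-tuning (FT) of the final head only.

DD_EPS <- 1e-7

#' Domain-discriminator loss
#'
#' Binary cross-entropy of the discriminator on both domains: the batch mean
#' of `-log p_source - log(1 - p_target)`. Probabilities are clamped to
#' `[eps, 1 - eps]` before the logarithm.
#'
#' @param p_source discriminator outputs on source-domain features.
#' @param p_target discriminator outputs on target-domain features.
#' @return Non-negative scalar; `2 log 2` at maximal confusion (both 0.5).
#' @export
dd_loss <- function(p_source, p_target) {
  if (!length(p_source) || !length(p_target)) stop("empty probability batch")
  ps <- pmin(pmax(p_source, DD_EPS), 1 - DD_EPS)
  pt <- pmin(pmax(p_target, DD_EPS), 1 - DD_EPS)
  mean(-log(ps)) + mean(-log(1 - pt))
}

#' Feature-mapping loss of the target network
#'
#' Batch mean of `-log p_target`: the target network is rewarded when the
#' discriminator believes its features came from the source domain.
#'
#' @param p_target discriminator outputs on target-domain features.
#' @return Non-negative scalar; `log 2` at 0.5, 0 at perfect confusion.
#' @export
mapping_loss <- function(p_target) {
  if (!length(p_target)) stop("empty probability batch")
  pt <- pmin(pmax(p_target, DD_EPS), 1 - DD_EPS)
  mean(-log(pt))
}

#' Reweighted supervised loss on the new subject
#'
#' `w` times the batch mean of the squared error summed over the N joints.
#'
#' @param pred,labels batch x N matrices of estimated and measured angles.
#' @param w non-negative weighting coefficient.
#' @return Non-negative scalar.
#' @export
subject_loss <- function(pred, labels, w = 1) {
  pred <- as.matrix(pred); labels <- as.matrix(labels)
  if (!all(dim(pred) == dim(labels))) stop("pred/label shape mismatch")
  if (w < 0) stop("w must be >= 0")
  w * mean(rowSums((pred - labels)^2))
}

#' Total adversarial-calibration loss
#'
#' Exact sum of the discriminator, mapping and subject components.
#'
#' @param l_dd,l_mapping,l_subject the three component losses.
#' @return Their sum.
#' @export
total_loss <- function(l_dd, l_mapping, l_subject) {
  stopifnot(is.finite(l_dd), is.finite(l_mapping), is.finite(l_subject))
  l_dd + l_mapping + l_subject
}

#' Build a domain discriminator
#'
#' A small MLP (two Mish hidden layers, sigmoid output) mapping a
#' penultimate-feature vector to the probability that it came from the
#' source domain.
#'
#' @param input_width feature width (the regressor's `head_hidden`).
#' @param hidden widths of the hidden layers (default `c(64, 64)`).
#' @param seed initialization seed.
#' @return Object of class `domain_discriminator` holding the weight list.
#' @export
build_discriminator <- function(input_width, hidden = c(64, 64), seed = 1) {
  params <- with_seed(seed, {
    p <- list()
    n_in <- input_width
    for (l in seq_along(hidden)) {
      p[[sprintf("W%d", l)]] <- init_matrix(n_in, hidden[l])
      p[[sprintf("b%d", l)]] <- matrix(0, 1L, hidden[l])
      n_in <- hidden[l]
    }
    p$Wout <- init_matrix(n_in, 1L)
    p$bout <- matrix(0, 1L, 1L)
    p
  })
  structure(list(params = params, input_width = input_width,
                 hidden = hidden),
            class = "domain_discriminator")
}

dd_forward_tape <- function(tape, leaves, n_hidden, F) {
  z <- F
  for (l in seq_len(n_hidden)) {
    z <- ad_mish(tape, ad_add_bias(tape,
      ad_matmul(tape, z, leaves[[sprintf("W%d", l)]]),
      leaves[[sprintf("b%d", l)]]))
  }
  ad_sigmoid(tape, ad_add_bias(tape, ad_matmul(tape, z, leaves$Wout),
                               leaves$bout))
}

#' Discriminator probabilities for a feature matrix
#'
#' @param object a `domain_discriminator`.
#' @param features rows of penultimate-layer features.
#' @param ... unused.
#' @return Vector of probabilities strictly inside (0, 1).
#' @export
predict.domain_discriminator <- function(object, features, ...) {
  tape <- ad_tape()
  leaves <- param_leaves(tape, object$params)
  p <- dd_forward_tape(tape, leaves, length(object$hidden),
                       ad_const(tape, as.matrix(features)))
  pmin(pmax(as.numeric(p$val), DD_EPS), 1 - DD_EPS)
}

#' Calibration configuration for the transfer routes
#'
#' @param epochs calibration epochs (default 50).
#' @param lr learning rate (default 1e-3).
#' @param batch_size sequences per step (default 64).
#' @param w weight of the supervised subject loss (default 1).
#' @param dd_hidden discriminator hidden widths (default `c(64, 64)`).
#' @param dd_steps discriminator updates per target-network update
#'   (default 1).
#' @param seed RNG seed.
#' @return Object of class `calibration_config`.
#' @export
calibration_config <- function(epochs = 50, lr = 1e-3, batch_size = 64,
                               w = 1, dd_hidden = c(64, 64), dd_steps = 1,
                               seed = 1) {
  structure(list(epochs = epochs, lr = lr, batch_size = batch_size, w = w,
                 dd_hidden = dd_hidden, dd_steps = dd_steps, seed = seed),
            class = "calibration_config")
}

# digest of a weight list, used for frozen-source assertions
weights_digest <- function(params) {
  spec_hash(lapply(params, function(p) c(dim(p), sum(p), sum(p * p),
                                         as.numeric(p[1L]))))
}

#' Adversarial transfer-learning calibration of a cross-subject model
#'
#' The frozen source network (`multi_s_net`) supplies source-domain features
#' from pooled multi-subject batches; a target copy (`new_t_net`,
#' initialized from the source weights) is trained on the new subject's
#' data. Per batch the routine alternates (a) a discriminator step
#' minimizing the domain-classification loss against the two feature sets
#' and (b) a target-network step minimizing the mapping loss plus the
#' reweighted supervised loss on the target labels. GAN-style two-optimizer
#' updates are used rather than a gradient-reversal layer, matching the
#' separate discriminator/generator objectives.
#'
#' @param multi_s_net trained `emg_regressor` (never modified).
#' @param target_train `feature_series` list: the new subject's training
#'   trials.
#' @param source_pool `feature_series` list: training data of the source
#'   subjects, sampled for discriminator batches.
#' @param config a [calibration_config()].
#' @return The calibrated `emg_regressor` (the target network), with a
#'   `calibration_log` data.frame of per-epoch `l_dd`, `l_mapping`,
#'   `l_subject`, `l_total` and discriminator accuracy, and the final
#'   discriminator under `discriminator`.
#' @export
atl_calibrate <- function(multi_s_net, target_train, source_pool,
                          config = calibration_config()) {
  stopifnot(inherits(multi_s_net, "emg_regressor"))
  spec <- multi_s_net$spec
  seq_len_ <- if (is.na(multi_s_net$seq_len)) config$batch_size
              else multi_s_net$seq_len
  if (inherits(target_train, "feature_series")) target_train <- list(target_train)
  if (inherits(source_pool, "feature_series")) source_pool <- list(source_pool)
  # the supervised term operates in the source model's standardized label
  # space, consistent with how the source network was trained
  tgt_seqs <- chunk_sequences(scale_labels_like(multi_s_net, target_train),
                              seq_len_)
  src_seqs <- chunk_sequences(source_pool, seq_len_)
  new_t <- multi_s_net  # value copy: initialization from the source weights
  dd <- build_discriminator(spec$head_hidden, config$dd_hidden,
                            seed = config$seed + 1L)
  dd_opt <- adam_state(dd$params, config$lr)
  t_opt <- adam_state(new_t$params, config$lr)
  log <- data.frame()
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(tgt_seqs))
      ep <- c(l_dd = 0, l_mapping = 0, l_subject = 0, l_total = 0,
              dd_acc = 0)
      n_b <- 0L
      for (bs in seq(1L, length(ord), by = config$batch_size)) {
        batch <- tgt_seqs[ord[bs:min(bs + config$batch_size - 1L,
                                     length(ord))]]
        src_batch <- src_seqs[sample.int(length(src_seqs),
                                         min(length(batch), length(src_seqs)))]
        # frozen source features and current target features (values only)
        F_s <- do.call(rbind, lapply(src_batch, function(sq)
          predict(multi_s_net, sq$x, type = "features")))
        F_t_val <- do.call(rbind, lapply(batch, function(sq)
          predict(new_t, sq$x, type = "features")))

        # (a) discriminator step(s): minimize the DD loss, DD params only
        for (k in seq_len(config$dd_steps)) {
          tape <- ad_tape()
          dlv <- param_leaves(tape, dd$params)
          ps <- dd_forward_tape(tape, dlv, length(dd$hidden),
                                ad_const(tape, F_s))
          pt <- dd_forward_tape(tape, dlv, length(dd$hidden),
                                ad_const(tape, F_t_val))
          ls <- ad_scale(tape, ad_sum_all(tape,
                  ad_log(tape, clamp_node(tape, ps))), -1 / nrow(F_s))
          lt <- ad_scale(tape, ad_sum_all(tape,
                  ad_log(tape, clamp_node(tape, one_minus(tape, pt)))),
                  -1 / nrow(F_t_val))
          l_dd_node <- ad_add(tape, ls, lt)
          if (!is.finite(l_dd_node$val[1L])) {
            stop(sprintf("discriminator loss non-finite at epoch %d", epoch))
          }
          ad_backward(tape, l_dd_node)
          dd$params <- adam_step(dd_opt, dd$params,
                                 lapply(dlv, function(l) l$grad))
        }

        # (b) target-network step: mapping + reweighted subject loss
        tape <- ad_tape()
        tlv <- param_leaves(tape, new_t$params)
        dlv <- param_leaves(tape, dd$params)  # constants: grads discarded
        map_terms <- NULL
        subj_terms <- NULL
        n_feat_rows <- 0L
        n_seq <- length(batch)
        for (sq in batch) {
          fw <- forward_one(tape, tlv, spec, sq$x)
          pt_node <- dd_forward_tape(tape, dlv, length(dd$hidden), fw$feat)
          mt <- ad_scale(tape, ad_sum_all(tape,
                  ad_log(tape, clamp_node(tape, pt_node))), -1)
          map_terms <- if (is.null(map_terms)) mt
                       else ad_add(tape, map_terms, mt)
          n_feat_rows <- n_feat_rows + nrow(sq$x)
          diff <- ad_sub(tape, fw$out, ad_const(tape, sq$y))
          st <- ad_sum_all(tape, ad_mul(tape, diff, diff))
          subj_terms <- if (is.null(subj_terms)) st
                        else ad_add(tape, subj_terms, st)
        }
        l_map_node <- ad_scale(tape, map_terms, 1 / n_feat_rows)
        # batch mean over windows of the per-window sum over joints
        l_subj_node <- ad_scale(tape, subj_terms, config$w / n_feat_rows)
        l_t <- ad_add(tape, l_map_node, l_subj_node)
        if (!is.finite(l_t$val[1L])) {
          stop(sprintf("target-network loss non-finite at epoch %d", epoch))
        }
        ad_backward(tape, l_t)
        new_t$params <- adam_step(t_opt, new_t$params,
                                  lapply(tlv, function(l) l$grad))

        ps_v <- predict(dd, F_s)
        pt_v <- predict(dd, F_t_val)
        l_dd_v <- dd_loss(ps_v, pt_v)
        l_map_v <- l_map_node$val[1L]
        l_sub_v <- l_subj_node$val[1L]
        ep <- ep + c(l_dd_v, l_map_v, l_sub_v,
                     total_loss(l_dd_v, l_map_v, l_sub_v),
                     (mean(ps_v > 0.5) + mean(pt_v <= 0.5)) / 2)
        n_b <- n_b + 1L
      }
      log <- rbind(log, data.frame(epoch = epoch, t(ep / n_b)))
    }
  })
  names(log) <- c("epoch", "l_dd", "l_mapping", "l_subject", "l_total",
                  "dd_acc")
  new_t$calibration_log <- log
  new_t$discriminator <- dd
  new_t$calibration <- "ATL"
  new_t
}

clamp_node <- function(tape, p) {
  v <- pmin(pmax(p$val, DD_EPS), 1 - DD_EPS)
  inside <- (p$val > DD_EPS) & (p$val < 1 - DD_EPS)
  ad_node(tape, v, list(p), list(function(g) g * inside))
}

one_minus <- function(tape, p) {
  ad_node(tape, 1 - p$val, list(p), list(function(g) -g))
}

#' Fine-tuning calibration: update the head only
#'
#' Copies the cross-subject model, freezes everything except the final
#' two-layer head (the Mish feature layer and the output linear layer), and
#' minimizes the mean squared error on the new subject's training data.
#'
#' @param multi_s_net trained `emg_regressor` (never modified).
#' @param target_train `feature_series` list for the new subject.
#' @param config a [calibration_config()]; `w`, `dd_*` fields are ignored.
#' @return The fine-tuned `emg_regressor`.
#' @export
ft_calibrate <- function(multi_s_net, target_train,
                         config = calibration_config()) {
  stopifnot(inherits(multi_s_net, "emg_regressor"))
  seq_len_ <- if (is.na(multi_s_net$seq_len)) 64L else multi_s_net$seq_len
  if (inherits(target_train, "feature_series")) target_train <- list(target_train)
  seqs <- chunk_sequences(scale_labels_like(multi_s_net, target_train),
                          seq_len_)
  head_names <- c("head_Wf", "head_bf", "head_Wo", "head_bo")
  new_t <- multi_s_net
  fit <- fit_supervised(new_t$params, new_t$spec, seqs,
                        epochs = config$epochs, batch_size = config$batch_size,
                        lr_init = config$lr, lr_halve_at = config$epochs + 1L,
                        seed = config$seed, trainable = head_names)
  new_t$params <- fit$params
  new_t$calibration_log <- fit$history
  new_t$calibration <- "FT"
  new_t
}
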
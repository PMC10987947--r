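# The five regressor families and the supervised training loop.
#
# All families share one contract: forward maps a [seq_len x n_channels]
# normalized feature sequence to [seq_len x n_outputs] joint-angle estimates,
# and every family ends in the same two-layer head (linear -> Mish feature
# layer, then a linear output layer). The Mish feature layer is the
# "penultimate fully connected layer" whose activations feed the domain
# discriminator during adversarial calibration, so transfer and metrics code
# is family-agnostic.

#' Specification of a regressor architecture
#'
#' @param family one of `"roformer"`, `"lstm"`, `"tcn"`,
#'   `"transformer_abs_pe"`, `"cnn_attention"`.
#' @param n_channels input sEMG channels (default 12).
#' @param n_outputs estimated joints (default 10).
#' @param position_embedding position-information source: `"rope"` (rotary,
#'   the roformer default), `"sinusoidal"`, `"learnable"` (both absolute,
#'   added once at the input) or `"none"`. Only the attention families use
#'   it.
#' @param d_model encoder width for the attention families (default 40).
#' @param n_heads attention heads (default 5).
#' @param n_layers encoder depth (default 2).
#' @param mlp_hidden encoder MLP width (default `4 * d_model`).
#' @param rope_base rotary frequency base (default 10000).
#' @param conv_kernel kernel of the 1-D convolutional front layer placed
#'   before the attention encoders (default 3, stride 1, same padding).
#' @param head_hidden width of the shared Mish feature layer (default 32);
#'   this is the width of the features seen by the domain discriminator.
#' @param lstm_layers,lstm_hidden stacked-LSTM depth and hidden width
#'   (defaults 5 and 32).
#' @param tcn_channels dilated-conv channel sizes (default
#'   `c(32, 64, 64, 32, 10)`), kernel `tcn_kernel` (default 3), dilations
#'   doubling per layer.
#' @param cnn_branch_channels channels per multi-scale branch (kernels 3, 5
#'   and 7; default 16), `cnn_pool_width` average-pooling width (default 2),
#'   `cnn_att_blocks` stacked attention blocks (default 3) with
#'   `cnn_att_heads` single heads each (default 3).
#' @param tcn_kernel,cnn_pool_width,cnn_att_blocks,cnn_att_heads see above.
#' @param max_seq_len longest sequence supported by learnable position
#'   embeddings (default 512).
#' @return An object of class `regressor_spec`.
#' @export
regressor_spec <- function(family = c("roformer", "lstm", "tcn",
                                      "transformer_abs_pe", "cnn_attention"),
                           n_channels = 12, n_outputs = 10,
                           position_embedding = NULL,
                           d_model = 40, n_heads = 5, n_layers = 2,
                           mlp_hidden = 4 * d_model, rope_base = 10000,
                           conv_kernel = 3, head_hidden = 32,
                           lstm_layers = 5, lstm_hidden = 32,
                           tcn_channels = c(32, 64, 64, 32, 10),
                           tcn_kernel = 3,
                           cnn_branch_channels = 16, cnn_pool_width = 2,
                           cnn_att_blocks = 3, cnn_att_heads = 3,
                           max_seq_len = 512) {
  family <- match.arg(family)
  if (is.null(position_embedding)) {
    position_embedding <- switch(family,
      roformer = "rope", transformer_abs_pe = "sinusoidal", "none")
  }
  position_embedding <- match.arg(position_embedding,
                                  c("rope", "sinusoidal", "learnable", "none"))
  if (family == "roformer" && position_embedding != "rope") {
    stop("field position_embedding: the roformer family uses \"rope\"")
  }
  if (family == "transformer_abs_pe" && position_embedding == "rope") {
    stop("field position_embedding: transformer_abs_pe uses an absolute embedding or none")
  }
  if (family %in% c("roformer", "transformer_abs_pe")) {
    if (d_model %% n_heads != 0) {
      stop(sprintf("field d_model: %d not divisible by n_heads = %d",
                   d_model, n_heads))
    }
    if ((d_model %/% n_heads) %% 2 != 0) {
      stop("field d_model: per-head width must be even for rotary pairs")
    }
  }
  if (family == "cnn_attention") {
    d_att <- 3 * cnn_branch_channels
    if (d_att %% cnn_att_heads != 0) {
      stop("field cnn_branch_channels: 3*channels must be divisible by cnn_att_heads")
    }
  }
  structure(
    list(family = family, n_channels = n_channels, n_outputs = n_outputs,
         position_embedding = position_embedding, d_model = d_model,
         n_heads = n_heads, n_layers = n_layers, mlp_hidden = mlp_hidden,
         rope_base = rope_base, conv_kernel = conv_kernel,
         head_hidden = head_hidden, lstm_layers = lstm_layers,
         lstm_hidden = lstm_hidden, tcn_channels = tcn_channels,
         tcn_kernel = tcn_kernel,
         cnn_branch_channels = cnn_branch_channels,
         cnn_pool_width = cnn_pool_width, cnn_att_blocks = cnn_att_blocks,
         cnn_att_heads = cnn_att_heads, max_seq_len = max_seq_len),
    class = "regressor_spec")
}

# width of the backbone output feeding the shared head
backbone_width <- function(spec) {
  switch(spec$family,
    roformer = spec$d_model,
    transformer_abs_pe = spec$d_model,
    lstm = spec$lstm_hidden,
    tcn = spec$tcn_channels[length(spec$tcn_channels)],
    cnn_attention = 3 * spec$cnn_branch_channels)
}

# sinusoidal absolute position embedding table [T x d]
sinusoidal_pe <- function(T, d) {
  pos <- seq_len(T) - 1L
  pe <- matrix(0, T, d)
  half <- (d + 1L) %/% 2L
  freq <- 10000^(-2 * (seq_len(half) - 1L) / d)
  ang <- outer(pos, freq)
  pe[, seq(1L, d, 2L)] <- sin(ang[, seq_len(length(seq(1L, d, 2L))), drop = FALSE])
  pe[, seq(2L, d, 2L)] <- cos(ang[, seq_len(length(seq(2L, d, 2L))), drop = FALSE])
  pe
}

init_regressor_params <- function(spec) {
  p <- list()
  hh <- spec$head_hidden
  if (spec$family %in% c("roformer", "transformer_abs_pe")) {
    k <- spec$conv_kernel
    p$conv_W <- init_matrix(k * spec$n_channels, spec$d_model)
    p$conv_b <- matrix(0, 1L, spec$d_model)
    cfg <- attention_config(spec$d_model, spec$n_heads, spec$n_layers,
                            rope_base = spec$rope_base,
                            mlp_hidden = spec$mlp_hidden)
    # seed already set by the caller; draw encoder weights inline
    d <- cfg$d_model
    for (l in seq_len(cfg$n_layers)) {
      p[[sprintf("l%d_ln1_g", l)]] <- matrix(1, 1L, d)
      p[[sprintf("l%d_ln1_b", l)]] <- matrix(0, 1L, d)
      for (h in seq_len(cfg$n_heads)) {
        p[[sprintf("l%d_h%d_Wqkv", l, h)]] <- init_matrix(d, 3L * cfg$d_head)
      }
      p[[sprintf("l%d_Wmsa", l)]] <- init_matrix(d, d)
      p[[sprintf("l%d_ln2_g", l)]] <- matrix(1, 1L, d)
      p[[sprintf("l%d_ln2_b", l)]] <- matrix(0, 1L, d)
      p[[sprintf("l%d_W1", l)]] <- init_matrix(d, cfg$mlp_hidden)
      p[[sprintf("l%d_b1", l)]] <- matrix(0, 1L, cfg$mlp_hidden)
      p[[sprintf("l%d_W2", l)]] <- init_matrix(cfg$mlp_hidden, d)
      p[[sprintf("l%d_b2", l)]] <- matrix(0, 1L, d)
    }
    if (spec$position_embedding == "learnable") {
      p$pe <- init_matrix(spec$max_seq_len, spec$d_model, scale = 0.02)
    }
  } else if (spec$family == "lstm") {
    H <- spec$lstm_hidden
    for (l in seq_len(spec$lstm_layers)) {
      n_in <- if (l == 1L) spec$n_channels else H
      p[[sprintf("l%d_W", l)]] <- init_matrix(n_in, 4L * H)
      p[[sprintf("l%d_U", l)]] <- init_matrix(H, 4L * H)
      b <- matrix(0, 1L, 4L * H)
      b[1L, (H + 1L):(2L * H)] <- 1  # forget-gate bias opens the memory path
      p[[sprintf("l%d_b", l)]] <- b
    }
  } else if (spec$family == "tcn") {
    ch <- spec$tcn_channels
    k <- spec$tcn_kernel
    c_in <- spec$n_channels
    for (l in seq_along(ch)) {
      p[[sprintf("l%d_W", l)]] <- init_matrix(k * c_in, ch[l])
      p[[sprintf("l%d_b", l)]] <- matrix(0, 1L, ch[l])
      if (c_in != ch[l]) {
        p[[sprintf("l%d_Wres", l)]] <- init_matrix(c_in, ch[l])
      }
      c_in <- ch[l]
    }
  } else if (spec$family == "cnn_attention") {
    cb <- spec$cnn_branch_channels
    for (k in c(3L, 5L, 7L)) {
      p[[sprintf("br%d_W", k)]] <- init_matrix(k * spec$n_channels, cb)
      p[[sprintf("br%d_b", k)]] <- matrix(0, 1L, cb)
    }
    d <- 3L * cb
    dh <- d %/% spec$cnn_att_heads
    for (l in seq_len(spec$cnn_att_blocks)) {
      p[[sprintf("a%d_ln_g", l)]] <- matrix(1, 1L, d)
      p[[sprintf("a%d_ln_b", l)]] <- matrix(0, 1L, d)
      for (h in seq_len(spec$cnn_att_heads)) {
        p[[sprintf("a%d_h%d_Wqkv", l, h)]] <- init_matrix(d, 3L * dh)
      }
      p[[sprintf("a%d_Wmsa", l)]] <- init_matrix(d, d)
    }
  }
  bw <- backbone_width(spec)
  p$head_Wf <- init_matrix(bw, hh)
  p$head_bf <- matrix(0, 1L, hh)
  p$head_Wo <- init_matrix(hh, spec$n_outputs)
  p$head_bo <- matrix(0, 1L, spec$n_outputs)
  p
}

#' Build an untrained regressor
#'
#' Construction is deterministic for equal seeds: two builds with the same
#' spec and seed have identical initial weights.
#'
#' @param spec a [regressor_spec()].
#' @param seed integer initialization seed.
#' @return An object of class `emg_regressor` with fields `spec`, `params`
#'   (named weight list), `n_params` and `seed`.
#' @export
build_regressor <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "regressor_spec"))
  params <- with_seed(seed, init_regressor_params(spec))
  structure(
    list(spec = spec, params = params,
         n_params = sum(vapply(params, length, 0L)),
         seed = seed, history = NULL, seq_len = NA_integer_,
         norm_hash = NA_character_),
    class = "emg_regressor")
}

#' @export
print.emg_regressor <- function(x, ...) {
  cat(sprintf("<emg_regressor> family %s: %d parameters%s\n",
              x$spec$family, x$n_params,
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs (final loss %.4g)",
                        nrow(x$history), x$history$loss[nrow(x$history)])))
  invisible(x)
}

## ---- family forwards on the tape -------------------------------------------

# multi-head self-attention block on the tape; weights named by `prefix`
ad_msa <- function(tape, Z, leaves, prefix, n_heads, d_head,
                   positions = NULL, rope_base = 10000) {
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    qkv <- ad_matmul(tape, Z, leaves[[sprintf("%s_h%d_Wqkv", prefix, h)]])
    q <- ad_slice_cols(tape, qkv, 1:d_head)
    k <- ad_slice_cols(tape, qkv, (d_head + 1):(2 * d_head))
    v <- ad_slice_cols(tape, qkv, (2 * d_head + 1):(3 * d_head))
    if (!is.null(positions)) {
      q <- ad_rope(tape, q, positions, rope_base)
      k <- ad_rope(tape, k, positions, rope_base)
    }
    logits <- ad_scale(tape, ad_matmul_bt(tape, q, k), 1 / sqrt(d_head))
    w <- ad_softmax_rows(tape, logits)
    heads[[h]] <- ad_matmul(tape, w, v)
  }
  ad_matmul(tape, ad_concat_cols(tape, heads),
            leaves[[sprintf("%s_Wmsa", prefix)]])
}

forward_attention_family <- function(tape, leaves, spec, X) {
  T <- nrow(X)
  idx <- conv_gather_idx(T, spec$conv_kernel, 1L, "same")
  xn <- ad_leaf(tape, X)
  xc <- ad_im2col(tape, xn, idx)
  Z <- ad_add_bias(tape, ad_matmul(tape, xc, leaves$conv_W), leaves$conv_b)
  positions <- NULL
  if (spec$position_embedding == "rope") {
    positions <- seq_len(T) - 1L
  } else if (spec$position_embedding == "sinusoidal") {
    Z <- ad_add(tape, Z, ad_const(tape, sinusoidal_pe(T, spec$d_model)))
  } else if (spec$position_embedding == "learnable") {
    if (T > spec$max_seq_len) {
      stop(sprintf("sequence length %d exceeds max_seq_len %d", T,
                   spec$max_seq_len))
    }
    Z <- ad_add(tape, Z, ad_slice_rows(tape, leaves$pe, seq_len(T)))
  }
  dh <- spec$d_model %/% spec$n_heads
  for (l in seq_len(spec$n_layers)) {
    zn <- ad_layernorm(tape, Z, leaves[[sprintf("l%d_ln1_g", l)]],
                       leaves[[sprintf("l%d_ln1_b", l)]])
    a <- ad_msa(tape, zn, leaves, sprintf("l%d", l), spec$n_heads, dh,
                positions, spec$rope_base)
    Zp <- ad_add(tape, a, Z)
    h <- ad_layernorm(tape, Zp, leaves[[sprintf("l%d_ln2_g", l)]],
                      leaves[[sprintf("l%d_ln2_b", l)]])
    h <- ad_mish(tape, ad_add_bias(tape, ad_matmul(tape, h, leaves[[sprintf("l%d_W1", l)]]),
                                   leaves[[sprintf("l%d_b1", l)]]))
    m <- ad_add_bias(tape, ad_matmul(tape, h, leaves[[sprintf("l%d_W2", l)]]),
                     leaves[[sprintf("l%d_b2", l)]])
    Z <- ad_add(tape, m, Zp)
  }
  Z
}

forward_lstm <- function(tape, leaves, spec, X) {
  T <- nrow(X)
  H <- spec$lstm_hidden
  inp <- ad_leaf(tape, X)
  for (l in seq_len(spec$lstm_layers)) {
    XW <- ad_add_bias(tape,
                      ad_matmul(tape, inp, leaves[[sprintf("l%d_W", l)]]),
                      leaves[[sprintf("l%d_b", l)]])
    U <- leaves[[sprintf("l%d_U", l)]]
    h <- ad_const(tape, matrix(0, 1L, H))
    cc <- ad_const(tape, matrix(0, 1L, H))
    hs <- vector("list", T)
    for (t in seq_len(T)) {
      g <- ad_add(tape, ad_slice_rows(tape, XW, t), ad_matmul(tape, h, U))
      i <- ad_sigmoid(tape, ad_slice_cols(tape, g, 1:H))
      f <- ad_sigmoid(tape, ad_slice_cols(tape, g, (H + 1):(2 * H)))
      gg <- ad_tanh(tape, ad_slice_cols(tape, g, (2 * H + 1):(3 * H)))
      o <- ad_sigmoid(tape, ad_slice_cols(tape, g, (3 * H + 1):(4 * H)))
      cc <- ad_add(tape, ad_mul(tape, f, cc), ad_mul(tape, i, gg))
      h <- ad_mul(tape, o, ad_tanh(tape, cc))
      hs[[t]] <- h
    }
    inp <- ad_rbind(tape, hs)
  }
  inp
}

forward_tcn <- function(tape, leaves, spec, X) {
  T <- nrow(X)
  k <- spec$tcn_kernel
  x <- ad_leaf(tape, X)
  c_in <- spec$n_channels
  for (l in seq_along(spec$tcn_channels)) {
    dil <- 2L^(l - 1L)
    idx <- conv_gather_idx(T, k, dil, "causal")
    y <- ad_add_bias(tape,
                     ad_matmul(tape, ad_im2col(tape, x, idx),
                               leaves[[sprintf("l%d_W", l)]]),
                     leaves[[sprintf("l%d_b", l)]])
    r <- if (c_in == spec$tcn_channels[l]) x
         else ad_matmul(tape, x, leaves[[sprintf("l%d_Wres", l)]])
    x <- ad_relu(tape, ad_add(tape, y, r))
    c_in <- spec$tcn_channels[l]
  }
  x
}

forward_cnn_attention <- function(tape, leaves, spec, X) {
  T <- nrow(X)
  xn <- ad_leaf(tape, X)
  branches <- lapply(c(3L, 5L, 7L), function(k) {
    idx <- conv_gather_idx(T, k, 1L, "same")
    ad_relu(tape, ad_add_bias(tape,
      ad_matmul(tape, ad_im2col(tape, xn, idx), leaves[[sprintf("br%d_W", k)]]),
      leaves[[sprintf("br%d_b", k)]]))
  })
  Z <- ad_concat_cols(tape, branches)
  pw <- spec$cnn_pool_width
  Z <- ad_avgpool_rows(tape, Z, pw)
  d <- 3L * spec$cnn_branch_channels
  Z <- ad_add(tape, Z, ad_const(tape, sinusoidal_pe(nrow(Z$val), d)))
  dh <- d %/% spec$cnn_att_heads
  for (l in seq_len(spec$cnn_att_blocks)) {
    zn <- ad_layernorm(tape, Z, leaves[[sprintf("a%d_ln_g", l)]],
                       leaves[[sprintf("a%d_ln_b", l)]])
    a <- ad_msa(tape, zn, leaves, sprintf("a%d", l), spec$cnn_att_heads, dh)
    Z <- ad_add(tape, a, Z)
  }
  ad_repeat_rows(tape, Z, pw, T)
}

# full forward for one sequence; returns output and penultimate-feature nodes
forward_one <- function(tape, leaves, spec, X) {
  if (ncol(X) != spec$n_channels) {
    stop(sprintf("input has %d channels, spec expects %d",
                 ncol(X), spec$n_channels))
  }
  B <- switch(spec$family,
    roformer = forward_attention_family(tape, leaves, spec, X),
    transformer_abs_pe = forward_attention_family(tape, leaves, spec, X),
    lstm = forward_lstm(tape, leaves, spec, X),
    tcn = forward_tcn(tape, leaves, spec, X),
    cnn_attention = forward_cnn_attention(tape, leaves, spec, X))
  feat <- ad_mish(tape, ad_add_bias(tape, ad_matmul(tape, B, leaves$head_Wf),
                                    leaves$head_bf))
  out <- ad_add_bias(tape, ad_matmul(tape, feat, leaves$head_Wo),
                     leaves$head_bo)
  list(out = out, feat = feat)
}

param_leaves <- function(tape, params) {
  lapply(params, function(p) ad_leaf(tape, p))
}

#' Predict joint angles (or penultimate features) for a feature sequence
#'
#' Long series are processed in non-overlapping chunks of the sequence
#' length the model was trained with, matching the attention context seen
#' during training.
#'
#' @param object an `emg_regressor`.
#' @param features windows x channels matrix, or a `feature_series`.
#' @param type `"angles"` (default) or `"features"` (output of the
#'   penultimate fully connected layer).
#' @param ... unused.
#' @return windows x n_outputs (or windows x head_hidden) matrix.
#' @export
predict.emg_regressor <- function(object, features, type = c("angles", "features"),
                                  ...) {
  type <- match.arg(type)
  if (inherits(features, "feature_series")) features <- features$features
  features <- as.matrix(features)
  chunk <- if (is.na(object$seq_len)) nrow(features) else object$seq_len
  starts <- seq(1L, nrow(features), by = chunk)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    e <- min(s + chunk - 1L, nrow(features))
    tape <- ad_tape()
    leaves <- param_leaves(tape, object$params)
    fw <- forward_one(tape, leaves, object$spec,
                      features[s:e, , drop = FALSE])
    out[[i]] <- if (type == "angles") fw$out$val else fw$feat$val
  }
  res <- do.call(rbind, out)
  if (!all(is.finite(res))) stop("non-finite model outputs")
  if (type == "angles" && !is.null(object$label_center)) {
    res <- sweep(res * object$label_scale, 2L, object$label_center, "+")
  }
  res
}

# apply a trained model's internal label standardization to a data list
scale_labels_like <- function(model, data_list) {
  if (is.null(model$label_center)) return(data_list)
  lapply(data_list, function(d) {
    d$labels <- sweep(d$labels, 2L, model$label_center) / model$label_scale
    d
  })
}

#' Save a regressor as a self-describing text checkpoint
#'
#' The file embeds the architecture spec, the initialization seed, the
#' normalization-spec hash and the label standardization alongside every
#' weight matrix at full precision, so a checkpoint can be reloaded and
#' validated without external context.
#'
#' @param regressor an `emg_regressor`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
save_regressor <- function(regressor, path) {
  stopifnot(inherits(regressor, "emg_regressor"))
  con <- file(path, "w")
  on.exit(close(con))
  sp <- regressor$spec
  writeLines(c(
    "rofemg_checkpoint 1",
    paste0("spec: ", paste(deparse(unclass(sp), control = "all"),
                           collapse = " ")),
    paste0("seed: ", regressor$seed),
    paste0("norm_hash: ", regressor$norm_hash),
    paste0("seq_len: ", regressor$seq_len),
    paste0("label_center: ",
           paste(sprintf("%.17g", regressor$label_center), collapse = " ")),
    paste0("label_scale: ",
           sprintf("%.17g", if (is.null(regressor$label_scale)) NA_real_
                   else regressor$label_scale))), con)
  for (nm in names(regressor$params)) {
    p <- regressor$params[[nm]]
    writeLines(sprintf("param %s %d %d", nm, nrow(p), ncol(p)), con)
    writeLines(paste(sprintf("%.17g", as.numeric(p)), collapse = " "), con)
  }
  invisible(path)
}

#' Load a regressor checkpoint written by [save_regressor()]
#'
#' @param path checkpoint file path.
#' @param n_channels if given, the loader refuses a checkpoint whose input
#'   dimensionality differs (guards against mismatched feature pipelines).
#' @return The reconstructed `emg_regressor`.
#' @export
load_regressor <- function(path, n_channels = NULL) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "rofemg_checkpoint")) {
    stop("not a rofemg checkpoint: ", path)
  }
  val_of <- function(key) sub(paste0("^", key, ": "), "",
                              grep(paste0("^", key, ": "), lines,
                                   value = TRUE)[1])
  spec <- eval(parse(text = val_of("spec")))
  class(spec) <- "regressor_spec"
  if (!is.null(n_channels) && spec$n_channels != n_channels) {
    stop(sprintf("checkpoint expects %d input channels, pipeline has %d",
                 spec$n_channels, n_channels))
  }
  ctr <- suppressWarnings(as.numeric(strsplit(val_of("label_center"),
                                              " ")[[1]]))
  scl <- suppressWarnings(as.numeric(val_of("label_scale")))
  params <- list()
  i <- which(startsWith(lines, "param "))
  for (k in i) {
    hdr <- strsplit(lines[k], " ")[[1]]
    vals <- as.numeric(strsplit(lines[k + 1L], " ")[[1]])
    params[[hdr[2]]] <- matrix(vals, as.integer(hdr[3]), as.integer(hdr[4]))
  }
  reg <- structure(
    list(spec = spec, params = params,
         n_params = sum(vapply(params, length, 0L)),
         seed = suppressWarnings(as.integer(val_of("seed"))),
         history = NULL,
         seq_len = suppressWarnings(as.integer(val_of("seq_len"))),
         norm_hash = val_of("norm_hash")),
    class = "emg_regressor")
  if (!anyNA(ctr)) reg$label_center <- ctr
  if (!is.na(scl)) reg$label_scale <- scl
  reg
}

#' Training configuration
#'
#' Defaults follow the full-scale protocol (batch 64, 400 epochs, learning
#' rate halved from epoch 200 on, Adam); desk-scale runs pass smaller values.
#'
#' @param batch_size sequences per gradient step (default 64).
#' @param epochs training epochs (default 400).
#' @param lr_init initial Adam learning rate (default 1e-4, the cross-subject
#'   setting; subject-specific runs conventionally use 3e-4).
#' @param lr_halve_at epoch from which the rate is halved (default 200).
#' @param seq_len windows per training sequence; trials are chunked
#'   non-overlapping (default 150).
#' @param seed RNG seed for shuffling (and any stochastic layer).
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 64, epochs = 400, lr_init = 1e-4,
                         lr_halve_at = 200, seq_len = 150, seed = 1) {
  if (lr_init <= 0) stop("lr_init must be positive")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(batch_size = batch_size, epochs = epochs, lr_init = lr_init,
                 lr_halve_at = lr_halve_at, seq_len = seq_len, seed = seed),
            class = "train_config")
}

# chunk feature series into training sequences of at most seq_len windows
chunk_sequences <- function(train_data, seq_len) {
  if (inherits(train_data, "feature_series")) train_data <- list(train_data)
  seqs <- list()
  for (d in train_data) {
    n <- nrow(d$features)
    starts <- seq(1L, n, by = seq_len)
    for (s in starts) {
      e <- min(s + seq_len - 1L, n)
      if (e - s + 1L < 2L) next  # a 1-window tail carries no sequence signal
      seqs[[length(seqs) + 1L]] <- list(
        x = d$features[s:e, , drop = FALSE],
        y = d$labels[s:e, , drop = FALSE])
    }
  }
  if (!length(seqs)) stop("no training sequences after chunking")
  seqs
}

# one supervised epoch pass shared by train_regressor and the calibrators;
# `trainable` restricts which parameters receive updates
fit_supervised <- function(params, spec, seqs, epochs, batch_size, lr_init,
                           lr_halve_at, seed, trainable = names(params)) {
  opt <- adam_state(params[trainable], lr_init)
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      lr <- if (epoch >= lr_halve_at) lr_init / 2 else lr_init
      opt$lr <- lr
      ord <- sample.int(length(seqs))
      ep_loss <- 0; n_b <- 0L
      for (bs in seq(1L, length(ord), by = batch_size)) {
        batch <- seqs[ord[bs:min(bs + batch_size - 1L, length(ord))]]
        tape <- ad_tape()
        leaves <- param_leaves(tape, params)
        total <- NULL
        n_entries <- 0L
        for (sq in batch) {
          fw <- forward_one(tape, leaves, spec, sq$x)
          diff <- ad_sub(tape, fw$out, ad_const(tape, sq$y))
          ss <- ad_sum_all(tape, ad_mul(tape, diff, diff))
          total <- if (is.null(total)) ss else ad_add(tape, total, ss)
          n_entries <- n_entries + length(sq$y)
        }
        loss <- ad_scale(tape, total, 1 / n_entries)
        if (!is.finite(loss$val[1L])) {
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        }
        ad_backward(tape, loss)
        grads <- lapply(leaves[trainable], function(l) l$grad)
        params[trainable] <- adam_step(opt, params[trainable], grads)
        ep_loss <- ep_loss + loss$val[1L]
        n_b <- n_b + 1L
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = ep_loss / n_b, lr = lr))
    }
  })
  list(params = params, history = history)
}

#' Train a regressor with the supervised mean-square objective
#'
#' Minimizes the mean squared error over all joints with Adam, batching
#' non-overlapping sequence chunks of the training series; the learning rate
#' is halved from `lr_halve_at` on. Runs with equal seeds, data and config
#' are reproducible on one device.
#'
#' @param regressor an `emg_regressor` from [build_regressor()].
#' @param train_data a `feature_series` or list of them (normalized).
#' @param config a [train_config()].
#' @return The trained `emg_regressor`, with `history` (per-epoch loss and
#'   learning rate) and the training sequence length recorded.
#' @export
train_regressor <- function(regressor, train_data, config = train_config()) {
  stopifnot(inherits(regressor, "emg_regressor"),
            inherits(config, "train_config"))
  if (inherits(train_data, "feature_series")) train_data <- list(train_data)
  # labels are standardized internally (per-joint centre, one shared scale)
  # so the optimizer sees unit-variance targets; predictions are mapped back,
  # and the shared scale keeps the relative joint weighting of the MSE intact
  all_y <- do.call(rbind, lapply(train_data, function(d) d$labels))
  ctr <- colMeans(all_y)
  scl <- stats::sd(sweep(all_y, 2L, ctr))
  if (!is.finite(scl) || scl == 0) scl <- 1
  regressor$label_center <- ctr
  regressor$label_scale <- scl
  train_data <- lapply(train_data, function(d) {
    d$labels <- sweep(d$labels, 2L, ctr) / scl
    d
  })
  seqs <- chunk_sequences(train_data, config$seq_len)
  fit <- fit_supervised(regressor$params, regressor$spec, seqs,
                        config$epochs, config$batch_size, config$lr_init,
                        config$lr_halve_at, config$seed)
  regressor$params <- fit$params
  regressor$history <- fit$history
  regressor$seq_len <- config$seq_len
  hashes <- unique(vapply(
    if (inherits(train_data, "feature_series")) list(train_data) else train_data,
    function(d) as.character(d$norm_hash), ""))
  if (length(hashes) == 1L) regressor$norm_hash <- hashes
  regressor$train_config <- config
  regressor
}
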
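# Rotary position embedding and the pre-norm transformer encoder mathematics.
#
# These functions operate on plain matrices with an explicit weight list, so
# the attention arithmetic can be inspected and tested in isolation; the
# trainable models in models.R run the same weight layout through the
# autodiff tape and are tested for equivalence against this path.

#' Configuration of a rotary-attention encoder stack
#'
#' @param d_model embedding width of the encoder stream.
#' @param n_heads number of attention heads H.
#' @param n_layers encoder depth L (0 is allowed and degenerates to the
#'   identity, useful for testing).
#' @param d_head per-head width; must be even (RoPE rotates coordinate
#'   pairs) and satisfy `n_heads * d_head == d_model`.
#' @param rope_base base of the rotation-frequency geometric series;
#'   pair `i` (0-based) of a width-`d` head rotates at angle
#'   `m * rope_base^(-2i/d)` for position `m`.
#' @param mlp_hidden width of the first MLP linear layer (default
#'   `4 * d_model`).
#' @return An object of class `attention_config`.
#' @export
attention_config <- function(d_model, n_heads, n_layers,
                             d_head = d_model %/% n_heads,
                             rope_base = 10000, mlp_hidden = 4 * d_model) {
  if (n_heads * d_head != d_model) {
    stop(sprintf("n_heads (%d) * d_head (%d) must equal d_model (%d)",
                 n_heads, d_head, d_model))
  }
  if (d_head %% 2L != 0L) {
    stop("d_head must be even: RoPE rotates coordinate pairs")
  }
  if (n_layers < 0) stop("n_layers must be >= 0")
  if (rope_base <= 0) stop("rope_base must be positive")
  structure(list(d_model = d_model, n_heads = n_heads, d_head = d_head,
                 n_layers = n_layers, rope_base = rope_base,
                 mlp_hidden = mlp_hidden),
            class = "attention_config")
}

#' Rotary position embedding of a sequence of head vectors
#'
#' Rotates coordinate pair `(2i, 2i+1)` (0-based) of the row at position `m`
#' by angle `m * rope_base^(-2i/d_head)`. The map is orthogonal, so row norms
#' are preserved, and inner products between rotated queries and keys depend
#' only on their position difference.
#'
#' @param vectors matrix, seq_len x d_head (d_head even).
#' @param positions non-negative integer position of each row.
#' @param rope_base rotation-frequency base (default 10000).
#' @return Matrix of the same shape with rotated rows.
#' @export
rope_rotate <- function(vectors, positions, rope_base = 10000) {
  vectors <- as.matrix(vectors)
  d <- ncol(vectors)
  if (d %% 2L != 0L) stop("rope_rotate requires an even head width, got ", d)
  if (length(positions) != nrow(vectors)) {
    stop("one position per row is required")
  }
  if (any(positions < 0)) stop("positions must be non-negative")
  ang <- outer(positions, rope_theta(d, rope_base))
  co <- cos(ang); si <- sin(ang)
  odd <- seq(1L, d, 2L); evn <- odd + 1L
  out <- vectors
  out[, odd] <- vectors[, odd] * co - vectors[, evn] * si
  out[, evn] <- vectors[, odd] * si + vectors[, evn] * co
  out
}

#' Scaled dot-product self-attention
#'
#' `softmax(Q K' / sqrt(d_h)) V` with no causal mask: the encoder attends to
#' past and future windows alike. Softmax rows are computed with max
#' subtraction and sum to one.
#'
#' @param Q,K,V matrices; `Q` is n_q x d_h, `K` and `V` are n_k x d_h.
#' @param return_weights if TRUE, attach the attention-weight matrix as
#'   attribute `"weights"`.
#' @return Matrix n_q x d_h of attention outputs.
#' @export
scaled_dot_attention <- function(Q, K, V, return_weights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K widths differ")
  if (nrow(K) != nrow(V)) stop("K and V row counts differ")
  logits <- Q %*% t(K) / sqrt(ncol(Q))
  w <- exp(logits - apply(logits, 1L, max))
  w <- w / rowSums(w)
  out <- w %*% V
  if (return_weights) attr(out, "weights") <- w
  out
}

# Gaussian init scaled like torch's default for linear layers
init_matrix <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

#' Initialize encoder weights for a configuration
#'
#' Per layer `l` the weight list holds layer norms `ln1_g/ln1_b` and
#' `ln2_g/ln2_b`, one combined projection `Wqkv_h` of width `3 d_head` per
#' head, the output projection `Wmsa`, and the MLP matrices `W1/b1/W2/b2`.
#'
#' @param config an [attention_config()].
#' @param seed integer seed for reproducible initialization.
#' @return Named list of weight matrices.
#' @export
init_encoder_weights <- function(config, seed = 1) {
  with_seed(seed, {
    w <- list()
    d <- config$d_model
    for (l in seq_len(config$n_layers)) {
      w[[sprintf("l%d_ln1_g", l)]] <- matrix(1, 1L, d)
      w[[sprintf("l%d_ln1_b", l)]] <- matrix(0, 1L, d)
      for (h in seq_len(config$n_heads)) {
        w[[sprintf("l%d_h%d_Wqkv", l, h)]] <- init_matrix(d, 3L * config$d_head)
      }
      w[[sprintf("l%d_Wmsa", l)]] <- init_matrix(d, d)
      w[[sprintf("l%d_ln2_g", l)]] <- matrix(1, 1L, d)
      w[[sprintf("l%d_ln2_b", l)]] <- matrix(0, 1L, d)
      w[[sprintf("l%d_W1", l)]] <- init_matrix(d, config$mlp_hidden)
      w[[sprintf("l%d_b1", l)]] <- matrix(0, 1L, config$mlp_hidden)
      w[[sprintf("l%d_W2", l)]] <- init_matrix(config$mlp_hidden, d)
      w[[sprintf("l%d_b2", l)]] <- matrix(0, 1L, d)
    }
    w
  })
}

#' Multi-head self-attention over one embedded sequence
#'
#' Each head projects the stream with its own `Wqkv`, applies RoPE to the
#' queries and keys (never the values, which therefore carry no positional
#' information), runs scaled dot-product attention, and the concatenated head
#' outputs are projected by `Wmsa`.
#'
#' @param Z matrix, seq_len x d_model.
#' @param config an [attention_config()].
#' @param weights weight list as in [init_encoder_weights()].
#' @param layer which layer's weights to use (default 1).
#' @param positions 0-based window positions; `NULL` disables RoPE.
#' @return Matrix seq_len x d_model.
#' @export
multi_head_attention <- function(Z, config, weights, layer = 1L,
                                 positions = seq_len(nrow(Z)) - 1L) {
  Z <- as.matrix(Z)
  if (ncol(Z) != config$d_model) {
    stop(sprintf("input width %d != d_model %d", ncol(Z), config$d_model))
  }
  dh <- config$d_head
  heads <- vector("list", config$n_heads)
  for (h in seq_len(config$n_heads)) {
    qkv <- Z %*% weights[[sprintf("l%d_h%d_Wqkv", layer, h)]]
    Q <- qkv[, 1:dh, drop = FALSE]
    K <- qkv[, (dh + 1):(2 * dh), drop = FALSE]
    V <- qkv[, (2 * dh + 1):(3 * dh), drop = FALSE]
    if (!is.null(positions)) {
      Q <- rope_rotate(Q, positions, config$rope_base)
      K <- rope_rotate(K, positions, config$rope_base)
    }
    heads[[h]] <- scaled_dot_attention(Q, K, V)
  }
  do.call(cbind, heads) %*% weights[[sprintf("l%d_Wmsa", layer)]]
}

layer_norm_rows <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  ctr <- x - mu
  v <- rowMeans(ctr * ctr)
  sweep(sweep(ctr / sqrt(v + eps), 2L, as.numeric(g), "*"),
        2L, as.numeric(b), "+")
}

mish <- function(x) x * tanh(pmax(x, 0) + log1p(exp(-abs(x))))

#' Forward pass through a pre-norm rotary encoder stack
#'
#' Starting from the projected input, each layer applies
#' `Z' = MSA(LayerNorm(Z)) + Z` followed by `Z_l = MLP(LayerNorm(Z')) + Z'`,
#' where the MLP is linear -> Mish -> linear and the MSA queries/keys are
#' RoPE-rotated in every layer. Position information therefore enters at each
#' layer's attention, not once at the input.
#'
#' @param X_p matrix, seq_len x d_model (already linearly projected).
#' @param config an [attention_config()].
#' @param weights weight list as in [init_encoder_weights()].
#' @param positions 0-based window positions; `NULL` disables RoPE.
#' @param rope_layers which layers apply RoPE (default all); exposed for
#'   ablation testing.
#' @return Matrix seq_len x d_model, the last layer's output.
#' @export
encoder_forward <- function(X_p, config, weights,
                            positions = seq_len(nrow(X_p)) - 1L,
                            rope_layers = seq_len(config$n_layers)) {
  Z <- as.matrix(X_p)
  if (ncol(Z) != config$d_model) {
    stop(sprintf("input width %d != d_model %d", ncol(Z), config$d_model))
  }
  for (l in seq_len(config$n_layers)) {
    pos_l <- if (l %in% rope_layers) positions else NULL
    a <- multi_head_attention(
      layer_norm_rows(Z, weights[[sprintf("l%d_ln1_g", l)]],
                      weights[[sprintf("l%d_ln1_b", l)]]),
      config, weights, layer = l, positions = pos_l)
    Zp <- a + Z
    h <- layer_norm_rows(Zp, weights[[sprintf("l%d_ln2_g", l)]],
                         weights[[sprintf("l%d_ln2_b", l)]])
    h <- mish(sweep(h %*% weights[[sprintf("l%d_W1", l)]], 2L,
                    as.numeric(weights[[sprintf("l%d_b1", l)]]), "+"))
    m <- sweep(h %*% weights[[sprintf("l%d_W2", l)]], 2L,
               as.numeric(weights[[sprintf("l%d_b2", l)]]), "+")
    Z <- m + Zp
    if (!all(is.finite(Z))) {
      stop(sprintf("non-finite activations after encoder layer %d", l))
    }
  }
  Z
}
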
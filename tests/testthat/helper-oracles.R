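# Independent straight-line oracles used by both the unit and the
# acceptance tests. Everything here is loop-based and written directly from
# the defining formulas, sharing no code with the implementation.

# rotate each coordinate pair of each row with an explicit 2x2 rotation
rope_oracle <- function(v, positions, base) {
  d <- ncol(v)
  out <- v
  for (r in seq_len(nrow(v))) {
    for (i in seq_len(d / 2)) {
      th <- positions[r] * base^(-2 * (i - 1) / d)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      out[r, c(2 * i - 1, 2 * i)] <- R %*% v[r, c(2 * i - 1, 2 * i)]
    }
  }
  out
}

# loop-based pre-norm rotary encoder stack
encoder_oracle <- function(Xp, cfg, w) {
  mish_ref <- function(x) x * tanh(log(1 + exp(x)))
  ln_ref <- function(x, g, b) {
    out <- x
    for (r in seq_len(nrow(x))) {
      mu <- mean(x[r, ]); v <- mean((x[r, ] - mu)^2)
      out[r, ] <- (x[r, ] - mu) / sqrt(v + 1e-5) * as.numeric(g) +
        as.numeric(b)
    }
    out
  }
  Z <- Xp
  for (l in seq_len(cfg$n_layers)) {
    zn <- ln_ref(Z, w[[sprintf("l%d_ln1_g", l)]], w[[sprintf("l%d_ln1_b", l)]])
    heads <- NULL
    for (h in seq_len(cfg$n_heads)) {
      qkv <- zn %*% w[[sprintf("l%d_h%d_Wqkv", l, h)]]
      dh <- cfg$d_head
      Q <- rope_oracle(qkv[, 1:dh, drop = FALSE], seq_len(nrow(Z)) - 1,
                       cfg$rope_base)
      K <- rope_oracle(qkv[, (dh + 1):(2 * dh), drop = FALSE],
                       seq_len(nrow(Z)) - 1, cfg$rope_base)
      V <- qkv[, (2 * dh + 1):(3 * dh), drop = FALSE]
      o <- matrix(0, nrow(Z), dh)
      for (i in seq_len(nrow(Z))) {
        logits <- numeric(nrow(Z))
        for (j in seq_len(nrow(Z))) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dh)
        wgt <- exp(logits - max(logits)); wgt <- wgt / sum(wgt)
        for (j in seq_len(nrow(Z))) o[i, ] <- o[i, ] + wgt[j] * V[j, ]
      }
      heads <- cbind(heads, o)
    }
    Zp <- heads %*% w[[sprintf("l%d_Wmsa", l)]] + Z
    hn <- ln_ref(Zp, w[[sprintf("l%d_ln2_g", l)]], w[[sprintf("l%d_ln2_b", l)]])
    h1 <- mish_ref(sweep(hn %*% w[[sprintf("l%d_W1", l)]], 2,
                         as.numeric(w[[sprintf("l%d_b1", l)]]), "+"))
    Z <- sweep(h1 %*% w[[sprintf("l%d_W2", l)]], 2,
               as.numeric(w[[sprintf("l%d_b2", l)]]), "+") + Zp
  }
  Z
}
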
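# Reverse-mode automatic differentiation on a flat tape.
#
# Every value is a dense numeric matrix (scalars are 1x1, biases 1xd rows).
# A node is an environment holding the value, an accumulated gradient, its
# parent nodes and one pull-back closure per parent. Nodes are appended to the
# tape in creation order; the backward pass walks the tape in reverse, so no
# explicit topological sort is needed. Gradients are verified against central
# finite differences in the test suite.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, val, parents = list(), pb = list()) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$pb <- pb
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd$id <- tape$n
  nd
}

ad_leaf <- function(tape, val) {
  if (!is.matrix(val)) val <- matrix(val, nrow = 1L)
  ad_node(tape, val)
}

ad_const <- ad_leaf

# Seed `node` (usually a 1x1 loss) with gradient 1 and sweep the tape.
ad_backward <- function(tape, node, seed = NULL) {
  if (is.null(seed)) seed <- matrix(1, nrow(node$val), ncol(node$val))
  node$grad <- seed
  for (i in seq(node$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || length(nd$parents) == 0L) next
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      g <- nd$pb[[j]](nd$grad)
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(node)
}

## ---- arithmetic -----------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$val %*% b$val, list(a, b), list(
    function(g) g %*% t(b$val),
    function(g) t(a$val) %*% g
  ))
}

# a %*% t(b), used for attention logits Q K'
ad_matmul_bt <- function(tape, a, b) {
  ad_node(tape, tcrossprod(a$val, b$val), list(a, b), list(
    function(g) g %*% b$val,
    function(g) crossprod(g, a$val)
  ))
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$val + b$val, list(a, b),
          list(function(g) g, function(g) g))
}

# x [n x d] plus a 1 x d bias row, broadcast over rows
ad_add_bias <- function(tape, x, b) {
  bv <- b$val
  ad_node(tape, sweep(x$val, 2L, as.numeric(bv), "+"), list(x, b), list(
    function(g) g,
    function(g) matrix(colSums(g), 1L)
  ))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$val - b$val, list(a, b),
          list(function(g) g, function(g) -g))
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$val * b$val, list(a, b), list(
    function(g) g * b$val,
    function(g) g * a$val
  ))
}

# multiply by a plain numeric scalar
ad_scale <- function(tape, a, s) {
  ad_node(tape, a$val * s, list(a), list(function(g) g * s))
}

## ---- activations ----------------------------------------------------------

ad_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-a$val))
  ad_node(tape, y, list(a), list(function(g) g * y * (1 - y)))
}

ad_tanh <- function(tape, a) {
  y <- tanh(a$val)
  ad_node(tape, y, list(a), list(function(g) g * (1 - y * y)))
}

ad_relu <- function(tape, a) {
  y <- pmax(a$val, 0)
  ad_node(tape, y, list(a), list(function(g) g * (a$val > 0)))
}

# Mish: x * tanh(softplus(x)); softplus computed overflow-safe
ad_mish <- function(tape, a) {
  x <- a$val
  sp <- pmax(x, 0) + log1p(exp(-abs(x)))
  tsp <- tanh(sp)
  sig <- 1 / (1 + exp(-x))
  ad_node(tape, x * tsp, list(a), list(
    function(g) g * (tsp + x * (1 - tsp * tsp) * sig)
  ))
}

ad_log <- function(tape, a) {
  ad_node(tape, log(a$val), list(a), list(function(g) g / a$val))
}

## ---- row-wise normalizations ----------------------------------------------

# softmax over each row, with max subtraction for stability
ad_softmax_rows <- function(tape, a) {
  x <- a$val
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  y <- e / rowSums(e)
  ad_node(tape, y, list(a), list(
    function(g) y * (g - rowSums(g * y))
  ))
}

# layer normalization over each row with learnable 1xd gain/offset
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  v <- x$val
  d <- ncol(v)
  mu <- rowMeans(v)
  ctr <- v - mu
  var <- rowMeans(ctr * ctr)
  inv <- 1 / sqrt(var + eps)
  xhat <- ctr * inv
  gv <- as.numeric(gamma$val)
  bv <- as.numeric(beta$val)
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ad_node(tape, y, list(x, gamma, beta), list(
    function(g) {
      dxhat <- sweep(g, 2L, gv, "*")
      (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    },
    function(g) matrix(colSums(g * xhat), 1L),
    function(g) matrix(colSums(g), 1L)
  ))
}

## ---- structural ops --------------------------------------------------------

ad_concat_cols <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$val)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  pbs <- lapply(seq_along(nodes), function(j) {
    s <- starts[j]; e <- ends[j]
    function(g) g[, s:e, drop = FALSE]
  })
  ad_node(tape, do.call(cbind, vals), nodes, pbs)
}

ad_slice_cols <- function(tape, a, cols) {
  nc <- ncol(a$val)
  ad_node(tape, a$val[, cols, drop = FALSE], list(a), list(
    function(g) {
      out <- matrix(0, nrow(g), nc)
      out[, cols] <- g
      out
    }
  ))
}

ad_rbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$val)
  heights <- vapply(vals, nrow, 1L)
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  pbs <- lapply(seq_along(nodes), function(j) {
    s <- starts[j]; e <- ends[j]
    function(g) g[s:e, , drop = FALSE]
  })
  ad_node(tape, do.call(rbind, vals), nodes, pbs)
}

ad_slice_rows <- function(tape, a, rows) {
  nr <- nrow(a$val)
  ad_node(tape, a$val[rows, , drop = FALSE], list(a), list(
    function(g) {
      out <- matrix(0, nr, ncol(g))
      out[rows, ] <- g
      out
    }
  ))
}

## ---- reductions ------------------------------------------------------------

ad_mean_all <- function(tape, a) {
  n <- length(a$val)
  ad_node(tape, matrix(mean(a$val), 1L, 1L), list(a), list(
    function(g) matrix(g[1L] / n, nrow(a$val), ncol(a$val))
  ))
}

ad_sum_all <- function(tape, a) {
  ad_node(tape, matrix(sum(a$val), 1L, 1L), list(a), list(
    function(g) matrix(g[1L], nrow(a$val), ncol(a$val))
  ))
}

## ---- rotary position embedding ---------------------------------------------

# Rotation angles for a head width d (even): theta_i = base^(-2(i-1)/d),
# one angle column per coordinate pair.
rope_theta <- function(d, base) {
  base^(-2 * (seq_len(d %/% 2L) - 1L) / d)
}

# Rotate each row of x (position positions[r]) pairwise by m * theta_i.
# Linear and orthogonal, so the pull-back is rotation by the negated angles.
ad_rope <- function(tape, x, positions, base = 10000) {
  d <- ncol(x$val)
  if (d %% 2L != 0L) stop("rope rotation requires an even head width, got ", d)
  ang <- outer(positions, rope_theta(d, base))
  co <- cos(ang); si <- sin(ang)
  odd <- seq(1L, d, 2L); evn <- odd + 1L
  rot <- function(v, co, si) {
    y <- v
    y[, odd] <- v[, odd] * co - v[, evn] * si
    y[, evn] <- v[, odd] * si + v[, evn] * co
    y
  }
  ad_node(tape, rot(x$val, co, si), list(x), list(
    function(g) rot(g, co, -si)
  ))
}

## ---- 1-D convolution via im2col --------------------------------------------

# Row indices gathered for each output step of a 1-D conv along the rows of a
# [T x C] sequence. "same" centres the kernel; "causal" looks back only.
# NA marks zero padding.
conv_gather_idx <- function(T, k, dilation = 1L, mode = c("same", "causal")) {
  mode <- match.arg(mode)
  span <- (k - 1L) * dilation
  off <- if (mode == "same") seq(-span %/% 2L, by = dilation, length.out = k)
         else seq(-span, by = dilation, length.out = k)
  idx <- outer(seq_len(T), off, "+")
  idx[idx < 1L | idx > T] <- NA_integer_
  idx
}

# x [T x C]  ->  [T x k*C]; column block j holds the rows of x at tap j.
ad_im2col <- function(tape, x, idx) {
  v <- x$val
  T <- nrow(v); C <- ncol(v); k <- ncol(idx)
  out <- matrix(0, T, k * C)
  for (j in seq_len(k)) {
    ok <- !is.na(idx[, j])
    out[ok, ((j - 1L) * C + 1L):(j * C)] <- v[idx[ok, j], , drop = FALSE]
  }
  ad_node(tape, out, list(x), list(
    function(g) {
      dx <- matrix(0, T, C)
      for (j in seq_len(k)) {
        ok <- which(!is.na(idx[, j]))
        blk <- g[ok, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
        tgt <- idx[ok, j]
        dx[tgt, ] <- dx[tgt, ] + blk
      }
      dx
    }
  ))
}

# non-overlapping average pooling over rows; trailing remainder rows dropped
ad_avgpool_rows <- function(tape, x, width) {
  v <- x$val
  Tout <- nrow(v) %/% width
  if (Tout < 1L) stop("sequence shorter than pooling width")
  grp <- rep(seq_len(Tout), each = width)
  used <- seq_len(Tout * width)
  y <- rowsum(v[used, , drop = FALSE], grp) / width
  ad_node(tape, y, list(x), list(
    function(g) {
      dx <- matrix(0, nrow(v), ncol(v))
      dx[used, ] <- g[grp, , drop = FALSE] / width
      dx
    }
  ))
}

# repeat each row `times` times (nearest-neighbour upsampling), then trim/pad
# to `out_len` rows so pooled sequences return to their original length
ad_repeat_rows <- function(tape, x, times, out_len) {
  v <- x$val
  rep_idx <- rep(seq_len(nrow(v)), each = times)
  if (length(rep_idx) < out_len) {
    rep_idx <- c(rep_idx, rep(nrow(v), out_len - length(rep_idx)))
  } else {
    rep_idx <- rep_idx[seq_len(out_len)]
  }
  ad_node(tape, v[rep_idx, , drop = FALSE], list(x), list(
    function(g) {
      dx <- rowsum(g, rep_idx)
      out <- matrix(0, nrow(v), ncol(v))
      out[as.integer(rownames(dx)), ] <- dx
      out
    }
  ))
}

## ---- optimizer --------------------------------------------------------------

# Adam with the conventional moment defaults; state is keyed by parameter name.
adam_state <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim = dim(as.matrix(p))))
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mhat <- st$m[[nm]] / corr1
    vhat <- st$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  params
}
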
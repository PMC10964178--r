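# Differentiable tensor operations built on the autodiff tape.
#
# Image-like activations are H x W x C arrays (column-major, 0-based pixel
# (0,0) at the top-left); token sequences are N x d matrices. Convolutions are
# lowered to matrix multiplies through the im2col/col2im kernels in src/.

op_add <- function(a, b) {
  nd_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

op_scale <- function(a, k) {
  nd_op(a$value * k, list(a), function(g) list(g * k))
}

op_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  nd_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

op_reshape <- function(a, dims) {
  od <- dim(a$value)
  v <- a$value
  dim(v) <- dims
  nd_op(v, list(a), function(g) { dim(g) <- od; list(g) })
}

op_rbind <- function(a, b) {
  na <- nrow(a$value)
  nd_op(rbind(a$value, b$value), list(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

# Row gather by index (used for window partition / cyclic shift / slicing).
# When `idx` is a permutation or subset, backward scatter-adds into the source.
op_gather_rows <- function(a, idx) {
  nr <- nrow(a$value); nc <- ncol(a$value)
  nd_op(a$value[idx, , drop = FALSE], list(a), function(g) {
    gi <- matrix(0, nr, nc)
    # accumulate (idx may repeat in principle)
    gacc <- rowsum(g, group = idx, reorder = FALSE)
    gi[as.integer(rownames(gacc)), ] <- gacc
    list(gi)
  })
}

# column-wise max over rows (1 x d); gradient routed to the argmax rows
op_colmax_rows <- function(a) {
  v <- a$value
  idx <- max.col(t(v), ties.method = "first")  # argmax row per column
  nc <- ncol(v); nr <- nrow(v)
  mx <- v[cbind(idx, seq_len(nc))]
  nd_op(matrix(mx, 1L), list(a), function(g) {
    gi <- matrix(0, nr, nc)
    gi[cbind(idx, seq_len(nc))] <- g
    list(gi)
  })
}

op_cbind <- function(a, b) {
  na <- ncol(a$value)
  nd_op(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

op_mean_rows <- function(a) {
  n <- nrow(a$value)
  nd_op(matrix(colMeans(a$value), 1L), list(a), function(g) {
    list(matrix(rep(g / n, each = n), n))
  })
}

op_concat_ch <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[1] == db[1], da[2] == db[2])
  v <- array(c(a$value, b$value), c(da[1], da[2], da[3] + db[3]))
  nd_op(v, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

# ---- activations ----

op_relu <- function(a) {
  m <- a$value > 0
  nd_op(a$value * m, list(a), function(g) list(g * m))
}

op_lrelu <- function(a, slope = 0.2) {
  v <- a$value
  d <- (v > 0) + slope * (v <= 0)
  nd_op(v * d, list(a), function(g) list(g * d))
}

op_gelu <- function(a) {
  x <- a$value
  ph <- stats::pnorm(x)
  nd_op(x * ph, list(a), function(g) list(g * (ph + x * stats::dnorm(x))))
}

op_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  nd_op(y, list(a), function(g) list(g * y * (1 - y)))
}

# non-overlapping f x f average pooling of an H x W x C grid
op_avgpool <- function(a, f) {
  if (f == 1L) return(a)
  dm <- dim(a$value)
  h2 <- dm[1] %/% f; w2 <- dm[2] %/% f; C <- dm[3]
  s1 <- colMeans(array(a$value, c(f, h2 * f * w2 * C)))   # over pixel rows
  m2 <- aperm(array(s1, c(h2, f, w2 * C)), c(2L, 1L, 3L))
  out <- colMeans(array(m2, c(f, h2 * w2 * C)))           # over pixel cols
  dim(out) <- c(h2, w2, C)
  nd_op(out, list(a), function(g) {
    gi <- g[rep(seq_len(h2), each = f), rep(seq_len(w2), each = f), ,
            drop = FALSE] / f^2
    list(gi)
  })
}

# ---- dense / matmul ----

op_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  nd_op(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

op_dense <- function(x, w, b = NULL) {
  xv <- x$value; wv <- w$value
  out <- xv %*% wv
  if (!is.null(b)) out <- out + rep(b$value, each = nrow(out))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  nd_op(out, parents, function(g) {
    gs <- list(g %*% t(wv), crossprod(xv, g))
    if (!is.null(b)) gs <- c(gs, list(colSums(g)))
    gs
  })
}

# ---- normalization ----

# Layer normalization over each row of an N x d matrix.
op_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xh <- xc * istd
  n <- nrow(xv)
  gv <- gamma$value
  out <- xh * rep(gv, each = n) + rep(beta$value, each = n)
  nd_op(out, list(x, gamma, beta), function(g) {
    gg <- g * rep(gv, each = n)
    gx <- istd * (gg - rowMeans(gg) - xh * rowMeans(gg * xh))
    list(gx, colSums(g * xh), colSums(g))
  })
}

# Instance normalization of an H x W x C activation: each channel is
# normalized over its spatial extent, then scaled/shifted per channel.
# (column-wise vector recycling with rep(each = m) avoids sweep overhead)
op_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  dm <- dim(x$value)
  m <- dm[1] * dm[2]
  C <- dm[3]
  xm <- matrix(x$value, m, C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = m)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xh <- xc * rep(istd, each = m)
  gv <- gamma$value
  out <- xh * rep(gv, each = m) + rep(beta$value, each = m)
  dim(out) <- dm
  nd_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, m, C)
    gg <- gm * rep(gv, each = m)
    gx <- (gg - rep(colMeans(gg), each = m) -
             xh * rep(colMeans(gg * xh), each = m)) * rep(istd, each = m)
    dim(gx) <- dm
    list(gx, colSums(gm * xh), colSums(gm))
  })
}

# ---- convolutions ----

# 2D convolution, kernel array w of dim (k, k, Cin, Cout), bias length Cout.
# Lowered to a matrix product through im2col; the lowering is recomputed in
# the backward pass rather than kept on the tape.
op_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  xv <- x$value
  dmx <- dim(xv)
  dw <- dim(w$value)
  k <- dw[1]
  stopifnot(dw[3] == dmx[3])
  ho <- (dmx[1] + 2L * pad - k) %/% stride + 1L
  wo <- (dmx[2] + 2L * pad - k) %/% stride + 1L
  cols <- im2col_cpp(xv, dmx[1], dmx[2], dmx[3], k, stride, pad)
  wm <- matrix(w$value, ncol = dw[4])
  outm <- crossprod(cols, wm)
  outm <- outm + rep(b$value, each = ho * wo)
  out <- array(outm, c(ho, wo, dw[4]))
  need_gx <- needs_grad(x)
  if (!need_gx) xv <- NULL
  nd_op(out, list(x, w, b), function(g) {
    gm <- matrix(g, ho * wo, dw[4])
    gwm <- cols %*% gm
    dim(gwm) <- dw
    gx <- if (need_gx)
      col2im_cpp(tcrossprod(wm, gm), dmx[1], dmx[2], dmx[3], k, stride, pad)
    list(gx, gwm, colSums(gm))
  })
}

# Transposed 2D convolution for 2x upsampling (kernel 4, stride 2, pad 1).
# Kernel array w has dim (k, k, Cout, Cin); forward is the adjoint of the
# corresponding strided convolution, realized through col2im.
op_convt2d <- function(x, w, b, stride = 2L, pad = 1L) {
  xv <- x$value
  dmx <- dim(xv)
  dw <- dim(w$value)
  k <- dw[1]; cout <- dw[3]; cin <- dw[4]
  stopifnot(cin == dmx[3])
  h2 <- (dmx[1] - 1L) * stride - 2L * pad + k
  w2 <- (dmx[2] - 1L) * stride - 2L * pad + k
  wm <- matrix(w$value, ncol = cin)        # (k*k*Cout) x Cin
  xm <- matrix(xv, dmx[1] * dmx[2], cin)   # HW x Cin
  out <- col2im_cpp(tcrossprod(wm, xm), h2, w2, cout, k, stride, pad)
  out <- out + rep(b$value, each = h2 * w2)
  dim(out) <- c(h2, w2, cout)
  need_gx <- needs_grad(x)
  nd_op(out, list(x, w, b), function(g) {
    gcols <- im2col_cpp(g, h2, w2, cout, k, stride, pad)  # (k*k*Cout) x HW
    gxm <- NULL
    if (need_gx) {
      gxm <- crossprod(gcols, wm)                         # HW x Cin
      dim(gxm) <- dmx
    }
    gwm <- gcols %*% xm
    dim(gwm) <- dw
    gb <- colSums(matrix(g, h2 * w2, cout))
    list(gxm, gwm, gb)
  })
}

# ---- multi-head windowed self-attention (composite op) ----
#
# x: (nw * N) x C stacked window tokens. Each head computes
# SoftMax(Q K' / sqrt(dh) + B + M) V inside every window; heads are
# concatenated and passed through the output projection wo. B is a learnable
# relative-position bias shared across windows (indexed by `bias_idx`), M an
# optional additive mask (one N x N matrix per window, used by shifted
# windows).
op_mha <- function(x, nw, n_heads, p, bias_idx = NULL, mask = NULL) {
  X <- x$value
  C <- ncol(X)
  N <- nrow(X) %/% nw
  dh <- C %/% n_heads
  sc <- 1 / sqrt(dh)
  Wq <- p$wq$value; Wk <- p$wk$value; Wv <- p$wv$value; Wo <- p$wo$value
  nr <- nrow(X)
  Q <- X %*% Wq + rep(p$bq$value, each = nr)
  K <- X %*% Wk + rep(p$bk$value, each = nr)
  V <- X %*% Wv + rep(p$bv$value, each = nr)
  has_bias <- !is.null(p$bias) && !is.null(bias_idx)
  Bh <- NULL
  if (has_bias) {
    Bh <- lapply(seq_len(n_heads), function(h) matrix(p$bias$value[bias_idx, h], N, N))
  }
  Plist <- vector("list", nw * n_heads)
  O <- matrix(0, nrow(X), C)
  for (w in seq_len(nw)) {
    rows <- ((w - 1L) * N + 1L):(w * N)
    for (h in seq_len(n_heads)) {
      cls <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[rows, cls, drop = FALSE], K[rows, cls, drop = FALSE]) * sc
      if (has_bias) S <- S + Bh[[h]]
      if (!is.null(mask)) S <- S + mask[[w]]
      S <- S - S[cbind(seq_len(N), max.col(S, ties.method = "first"))]
      P <- exp(S)
      P <- P / rowSums(P)
      Plist[[(w - 1L) * n_heads + h]] <- P
      O[rows, cls] <- P %*% V[rows, cls, drop = FALSE]
    }
  }
  out <- O %*% Wo + rep(p$bo$value, each = nr)
  parents <- list(x, p$wq, p$wk, p$wv, p$wo, p$bq, p$bk, p$bv, p$bo)
  if (has_bias) parents <- c(parents, list(p$bias))
  nd_op(out, parents, function(g) {
    gWo <- crossprod(O, g)
    gbo <- colSums(g)
    gO <- g %*% t(Wo)
    gQ <- matrix(0, nrow(X), C); gK <- gQ; gV <- gQ
    gBh <- if (has_bias) replicate(n_heads, matrix(0, N, N), simplify = FALSE)
    for (w in seq_len(nw)) {
      rows <- ((w - 1L) * N + 1L):(w * N)
      for (h in seq_len(n_heads)) {
        cls <- ((h - 1L) * dh + 1L):(h * dh)
        P <- Plist[[(w - 1L) * n_heads + h]]
        gOh <- gO[rows, cls, drop = FALSE]
        Vh <- V[rows, cls, drop = FALSE]
        gP <- tcrossprod(gOh, Vh)
        gVh <- crossprod(P, gOh)
        gS <- (gP - rowSums(gP * P)) * P
        if (has_bias) gBh[[h]] <- gBh[[h]] + gS
        gQ[rows, cls] <- gS %*% K[rows, cls, drop = FALSE] * sc
        gK[rows, cls] <- crossprod(gS, Q[rows, cls, drop = FALSE]) * sc
        gV[rows, cls] <- gVh
      }
    }
    gX <- gQ %*% t(Wq) + gK %*% t(Wk) + gV %*% t(Wv)
    gs <- list(gX,
               crossprod(X, gQ), crossprod(X, gK), crossprod(X, gV), gWo,
               colSums(gQ), colSums(gK), colSums(gV), gbo)
    if (has_bias) {
      ntab <- nrow(p$bias$value)
      gtab <- matrix(0, ntab, n_heads)
      for (h in seq_len(n_heads)) {
        acc <- rowsum(as.vector(gBh[[h]]), group = bias_idx, reorder = FALSE)
        gtab[as.integer(rownames(acc)), h] <- acc
      }
      gs <- c(gs, list(gtab))
    }
    gs
  })
}

# ---- scalar reductions / losses ----

op_mean <- function(a) {
  n <- length(a$value)
  dm <- dim(a$value)
  nd_op(mean(a$value), list(a), function(g) {
    gi <- array(g / n, if (is.null(dm)) n else dm)
    list(gi)
  })
}

# mean((a - c)^2) for a constant target c (scalar)
op_mean_shift_sq <- function(a, c0) {
  d <- a$value - c0
  n <- length(d)
  dm <- dim(a$value)
  nd_op(mean(d * d), list(a), function(g) {
    gi <- 2 * g * d / n
    if (!is.null(dm)) dim(gi) <- dm
    list(gi)
  })
}

# mean(|a - b|); b may be a node or a constant array
op_mean_abs_diff <- function(a, b) {
  bn <- is_node(b)
  bv <- if (bn) b$value else b
  d <- a$value - bv
  n <- length(d)
  dm <- dim(d)
  s <- sign(d)
  parents <- if (bn) list(a, b) else list(a)
  nd_op(mean(abs(d)), parents, function(g) {
    gi <- g * s / n
    if (!is.null(dm)) dim(gi) <- dm
    if (bn) list(gi, -gi) else list(gi)
  })
}

# Weighted sum of scalar nodes: sum(w_i * x_i)
op_wsum <- function(nodes, weights) {
  v <- sum(vapply(nodes, function(n) n$value, numeric(1)) * weights)
  nd_op(v, nodes, function(g) as.list(g * weights))
}

# Binary cross-entropy from a logit (numerically stable softplus form):
# mean over elements of softplus(z) - z * y.
op_bce_logit <- function(z, y) {
  zv <- z$value
  n <- length(zv)
  sp <- ifelse(zv > 0, zv + log1p(exp(-zv)), log1p(exp(zv)))
  p <- 1 / (1 + exp(-zv))
  nd_op(mean(sp - zv * y), list(z), function(g) {
    gi <- g * (p - y) / n
    if (!is.null(dim(zv))) dim(gi) <- dim(zv)
    list(gi)
  })
}

# Class-weighted softmax cross-entropy over token logits.
# logits: N x K node; wts: N x K non-negative weights (e.g. pixel counts per
# token and class under nearest-neighbor upsampling); total: normalizer.
# Loss = sum_nk wts[n,k] * (-log softmax(logits)[n,k]) / total.
op_ce_weighted <- function(logits, wts, total) {
  z <- logits$value
  zmax <- apply(z, 1L, max)
  ez <- exp(z - zmax)
  p <- ez / rowSums(ez)
  loss <- -sum(wts * (z - zmax - log(rowSums(ez)))) / total
  rw <- rowSums(wts)
  nd_op(loss, list(logits), function(g) {
    list(g * (p * rw - wts) / total)
  })
}
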
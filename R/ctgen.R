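# Convolutional transformer generator: a U-Net style multi-scale extractor
# whose deepest features pass through windowed-attention (Swin-style)
# transformer blocks and the structure/pathology head before being merged and
# up-sampled into the target staining domain.

#' Generator configuration
#'
#' @param in_channels,out_channels Image channel counts (1 for OCT, 3 for H&E).
#' @param image_size Side of the (square) training patches in pixels; position
#'   embeddings and attention caches are laid out for this size.
#' @param base_width Channel count of the first convolutional scale; deeper
#'   scales use 1.5x and 2x this width.
#' @param n_scales Number of stride-2 encoder stages (3, mirrored by three
#'   transposed-convolution stages in the decoder).
#' @param window_size Side length of the attention windows, in tokens; a
#'   window therefore holds `window_size^2` tokens.
#' @param d_model Channel width inside the transformer blocks and the
#'   structure/pathology head; must be divisible by `n_heads`.
#' @param n_rstb Number of residual Swin transformer sub-blocks.
#' @param n_stl_per_rstb Swin transformer layers per sub-block; every second
#'   layer uses shifted windows.
#' @param n_heads Attention heads.
#' @param mlp_ratio Hidden width of the token MLP relative to `d_model`.
#' @param scpa_patch Patch side used when the head re-tokenizes the deepest
#'   feature grid.
#' @param n_enc,n_dec Encoder/decoder depth of the structure/pathology head.
#' @param output_activation Only `"sigmoid"` is supported, enforcing outputs
#'   in \[0, 1\].
#' @return A validated configuration object.
#' @export
generator_config <- function(in_channels = 1L, out_channels = 3L,
                             image_size = 64L, base_width = 6L, n_scales = 3L,
                             window_size = 4L, d_model = 24L, n_rstb = 1L,
                             n_stl_per_rstb = 2L, n_heads = 3L, mlp_ratio = 2,
                             scpa_patch = 1L, n_enc = 2L, n_dec = 2L,
                             output_activation = "sigmoid") {
  output_activation <- match.arg(output_activation, "sigmoid")
  if (d_model %% n_heads != 0L) stop("d_model must be divisible by n_heads")
  if (image_size %% (2L^n_scales) != 0L)
    stop("image_size must be divisible by 2^n_scales")
  deep <- image_size %/% (2L^n_scales)
  if (deep %% scpa_patch != 0L)
    stop("deepest feature side must be divisible by scpa_patch")
  cfg <- list(
    in_channels = as.integer(in_channels), out_channels = as.integer(out_channels),
    image_size = as.integer(image_size), base_width = as.integer(base_width),
    n_scales = as.integer(n_scales), window_size = as.integer(window_size),
    d_model = as.integer(d_model), n_rstb = as.integer(n_rstb),
    n_stl_per_rstb = as.integer(n_stl_per_rstb), n_heads = as.integer(n_heads),
    mlp_ratio = mlp_ratio, scpa_patch = as.integer(scpa_patch),
    n_enc = as.integer(n_enc), n_dec = as.integer(n_dec),
    output_activation = output_activation
  )
  cfg$widths <- c(cfg$base_width, round(1.5 * cfg$base_width), 2L * cfg$base_width)
  structure(cfg, class = "octstain_gen_config")
}

#' Paper-faithful generator preset (368 x 368 patches)
#'
#' Desk-scale work uses [generator_config()] defaults; this preset keeps the
#' published patch size and the depths/widths used at full scale.
#' @param in_channels,out_channels Image channel counts.
#' @return A configuration object.
#' @export
generator_config_paper <- function(in_channels = 1L, out_channels = 3L) {
  generator_config(in_channels, out_channels, image_size = 368L,
                   base_width = 32L, window_size = 4L, d_model = 96L,
                   n_rstb = 2L, n_stl_per_rstb = 2L, n_heads = 3L,
                   mlp_ratio = 4, n_enc = 2L, n_dec = 2L)
}

# ---- window bookkeeping ----

#' Partition a feature grid into non-overlapping token windows
#'
#' Tokens within a window and windows themselves are ordered row-major. Grids
#' whose sides are not divisible by the window are zero-padded on the
#' bottom/right edges when `pad = TRUE` (the inverse crops the padding away).
#'
#' @param grid H x W x C array.
#' @param window Window side length in tokens.
#' @param pad Zero-pad non-divisible grids instead of failing.
#' @return List with `windows` (a list of `window^2` x C token matrices),
#'   plus the bookkeeping needed by [window_reassemble()].
#' @export
window_partition <- function(grid, window, pad = FALSE) {
  grid <- as_image(grid)
  dm <- dim(grid)
  H <- dm[1]; W <- dm[2]; C <- dm[3]
  H2 <- ceiling(H / window) * window
  W2 <- ceiling(W / window) * window
  if ((H2 != H || W2 != W)) {
    if (!pad) stop("grid sides must be divisible by the window (or set pad = TRUE)")
    g2 <- array(0, c(H2, W2, C))
    g2[seq_len(H), seq_len(W), ] <- grid
    grid <- g2
  }
  idx <- window_gather_index(H2, W2, window)
  gm <- matrix(grid, H2 * W2, C)
  stacked <- gm[idx, , drop = FALSE]
  nw <- (H2 %/% window) * (W2 %/% window)
  n <- window^2
  windows <- lapply(seq_len(nw), function(w) {
    stacked[((w - 1L) * n + 1L):(w * n), , drop = FALSE]
  })
  list(windows = windows, height = H, width = W, padded_height = H2,
       padded_width = W2, window = window, channels = C, index = idx)
}

#' Reassemble a window partition into the original grid
#' @param part Object from [window_partition()]; its `windows` may have been
#'   replaced by transformed token blocks of the same shape.
#' @return The H x W x C grid (padding cropped away).
#' @export
window_reassemble <- function(part) {
  stacked <- do.call(rbind, part$windows)
  gm <- matrix(0, part$padded_height * part$padded_width, part$channels)
  gm[part$index, ] <- stacked
  g <- array(gm, c(part$padded_height, part$padded_width, part$channels))
  g[seq_len(part$height), seq_len(part$width), , drop = FALSE]
}

# gather index mapping window-stacked token order -> grid row (i + H*(j-1))
window_gather_index <- function(H, W, s) {
  nbh <- H %/% s; nbw <- W %/% s
  idx <- integer(H * W)
  p <- 0L
  for (bi in seq_len(nbh)) for (bj in seq_len(nbw)) {
    for (ti in seq_len(s)) for (tj in seq_len(s)) {
      p <- p + 1L
      idx[p] <- (bi - 1L) * s + ti + H * ((bj - 1L) * s + tj - 1L)
    }
  }
  idx
}

# relative-position index table: (s^2 x s^2) entries into a (2s-1)^2 table
rel_pos_index <- function(s) {
  n <- s * s
  ti <- (seq_len(n) - 1L) %/% s
  tj <- (seq_len(n) - 1L) %% s
  di <- outer(ti, ti, `-`) + s - 1L
  dj <- outer(tj, tj, `-`) + s - 1L
  di * (2L * s - 1L) + dj + 1L
}

# additive attention masks for shifted windows (Swin region bookkeeping)
shift_attn_mask <- function(H, W, s, shift) {
  bounds <- function(L) {
    # region labels along one axis for the shifted frame
    lab <- integer(L)
    cuts <- c(L - s, L - shift)
    lab[seq_len(L)] <- 0L
    if (L - s >= 1) lab[seq_len(L - s)] <- 0L
    if (L - s + 1 <= L - shift) lab[(L - s + 1):(L - shift)] <- 1L
    lab[(L - shift + 1):L] <- 2L
    lab
  }
  hl <- bounds(H); wl <- bounds(W)
  ids <- outer(hl, wl, function(a, b) a * 3L + b)
  idx <- window_gather_index(H, W, s)
  idv <- as.vector(ids)[idx]
  nw <- (H %/% s) * (W %/% s)
  n <- s * s
  lapply(seq_len(nw), function(w) {
    v <- idv[((w - 1L) * n + 1L):(w * n)]
    m <- outer(v, v, `!=`) * -1e9
    m
  })
}

# cyclic roll gather index on grid rows: output (i,j) = input (i+shift, j+shift)
roll_index <- function(H, W, shift) {
  i <- ((seq_len(H) - 1L + shift) %% H) + 1L
  j <- ((seq_len(W) - 1L + shift) %% W) + 1L
  as.vector(outer(i, H * (j - 1L), `+`))
}

# cache of all index structures for one (H, W, window) geometry
stb_cache <- function(model, H, W) {
  key <- paste(H, W, sep = "x")
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  s <- model$config$window_size
  shift <- s %/% 2L
  idx <- window_gather_index(H, W, s)
  inv <- integer(length(idx)); inv[idx] <- seq_along(idx)
  ridx <- roll_index(H, W, shift)
  uidx <- roll_index(H, W, -shift)
  cc <- list(
    nw = (H %/% s) * (W %/% s), n = s * s,
    idx = idx, inv = inv,
    idx_shift = ridx[idx], relidx = as.vector(rel_pos_index(s)),
    mask = shift_attn_mask(H, W, s, shift)
  )
  inv_s <- integer(length(idx)); inv_s[cc$idx_shift] <- seq_along(idx)
  cc$inv_shift <- inv_s
  model$cache[[key]] <- cc
  cc
}

# ---- public windowed attention (specification surface, no output proj) ----

#' Windowed multi-head self-attention on one token block
#'
#' Computes `SoftMax(Q K' / sqrt(d) + B) V` per head with `Q = X P_Q`,
#' `K = X P_K`, `V = X P_V`, heads concatenated. The relative-position bias
#' `B` is shared across windows by construction (it is part of `params`).
#'
#' @param X N x C token matrix for one window.
#' @param params List with projection matrices `P_Q`, `P_K`, `P_V` (C x C),
#'   optional per-head bias list `B` (each N x N, or a single matrix for one
#'   head) and `n_heads`.
#' @return N x C output tokens; attribute `"attention"` holds the per-head
#'   softmax weight matrices (rows sum to one).
#' @export
window_attention <- function(X, params) {
  if (any(!is.finite(X))) stop("non-finite values in attention input")
  n_heads <- if (is.null(params$n_heads)) 1L else params$n_heads
  C <- ncol(X)
  dh <- C %/% n_heads
  Q <- X %*% params$P_Q
  K <- X %*% params$P_K
  V <- X %*% params$P_V
  B <- params$B
  if (!is.null(B) && !is.list(B)) B <- list(B)
  out <- matrix(0, nrow(X), C)
  wts <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cls <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, cls, drop = FALSE], K[, cls, drop = FALSE]) / sqrt(dh)
    if (!is.null(B)) S <- S + B[[min(h, length(B))]]
    P <- softmax_rows(S)
    wts[[h]] <- P
    out[, cls] <- P %*% V[, cls, drop = FALSE]
  }
  attr(out, "attention") <- wts
  out
}

# ---- Swin transformer layer / residual block ----

stl_new <- function(cfg, shifted) {
  d <- cfg$d_model
  hidden <- round(cfg$mlp_ratio * d)
  list(
    shifted = shifted,
    ln1 = ln_layer(d), mha = mha_layer(d, cfg$n_heads, win = cfg$window_size),
    ln2 = ln_layer(d), fc1 = dense_layer(d, hidden), fc2 = dense_layer(hidden, d)
  )
}

# x: (H*W) x d token node in grid (column-major) row order
stl_forward_node <- function(x, stl, cc, cfg) {
  h <- op_layernorm(x, stl$ln1$g, stl$ln1$b)
  if (stl$shifted) {
    hw <- op_gather_rows(h, cc$idx_shift)
    a <- op_mha(hw, cc$nw, cfg$n_heads, stl$mha, bias_idx = cc$relidx, mask = cc$mask)
    a <- op_gather_rows(a, cc$inv_shift)
  } else {
    hw <- op_gather_rows(h, cc$idx)
    a <- op_mha(hw, cc$nw, cfg$n_heads, stl$mha, bias_idx = cc$relidx)
    a <- op_gather_rows(a, cc$inv)
  }
  x <- op_add(x, a)
  h2 <- op_layernorm(x, stl$ln2$g, stl$ln2$b)
  m <- op_dense(h2, stl$fc1$w, stl$fc1$b)
  m <- op_gelu(m)
  m <- op_dense(m, stl$fc2$w, stl$fc2$b)
  op_add(x, m)
}

#' Apply one Swin transformer layer to a feature grid
#'
#' Pre-norm residual composition: `x + MHA(LN(x))` followed by
#' `x + MLP(LN(x))`, with windowed attention (cyclically shifted when the
#' layer is a shifted one).
#' @param grid H x W x d array (H, W divisible by the window).
#' @param model A generator from [generator_new()].
#' @param rstb,stl Indices selecting the layer.
#' @return H x W x d array.
#' @export
stl_forward <- function(grid, model, rstb = 1L, stl = 1L) {
  grid <- as_image(grid)
  dm <- dim(grid)
  cc <- stb_cache(model, dm[1], dm[2])
  x <- nd_const(matrix(grid, dm[1] * dm[2], dm[3]))
  out <- stl_forward_node(x, model$rstbs[[rstb]]$stls[[stl]],
                          cc, model$config)
  array(out$value, dm)
}

rstb_new <- function(cfg) {
  stls <- lapply(seq_len(cfg$n_stl_per_rstb), function(i) {
    stl_new(cfg, shifted = (i %% 2L == 0L))
  })
  list(stls = stls, conv = conv_layer(3L, cfg$d_model, cfg$d_model))
}

# T_RSTB = Conv3x3(F_STL + T_IN): the layer stack is residual, so chaining
# the STLs over T_IN already carries T_IN through to the sum; the 3x3
# convolution closes the block.
rstb_forward_node <- function(t_in, rstb, H, W, model) {
  cfg <- model$config
  cc <- stb_cache(model, H, W)
  x <- op_reshape(t_in, c(H * W, cfg$d_model))
  for (stl in rstb$stls) x <- stl_forward_node(x, stl, cc, cfg)
  f <- op_reshape(x, c(H, W, cfg$d_model))
  op_conv2d(f, rstb$conv$w, rstb$conv$b, 1L, 1L)
}

#' Apply one residual Swin transformer sub-block to a feature grid
#' @param grid H x W x d array.
#' @param model Generator from [generator_new()].
#' @param rstb Block index.
#' @return H x W x d array equal to `Conv3x3(F_STL + T_IN)`.
#' @export
rstb_forward <- function(grid, model, rstb = 1L) {
  grid <- as_image(grid)
  dm <- dim(grid)
  out <- rstb_forward_node(nd_const(grid), model$rstbs[[rstb]], dm[1], dm[2], model)
  out$value
}

# ---- the full generator ----

#' Build a convolutional transformer generator
#'
#' @param config From [generator_config()].
#' @param seed Integer seed controlling parameter initialization.
#' @return A generator model (its structure/pathology head included).
#' @export
generator_new <- function(config, seed = 1L) {
  stopifnot(inherits(config, "octstain_gen_config"))
  w <- config$widths
  d <- config$d_model
  model <- local_seed(seed, {
    m <- list(
      config = config,
      inconv = conv_layer(3L, config$in_channels, w[1]),
      down1 = conv_layer(3L, w[1], w[2]), in1 = in_layer(w[2]),
      down2 = conv_layer(3L, w[2], w[3]), in2 = in_layer(w[3]),
      down3 = conv_layer(3L, w[3], d), in3 = in_layer(d),
      rstbs = lapply(seq_len(config$n_rstb), function(i) rstb_new(config)),
      merge = conv_layer(3L, 2L * d, d), inm = in_layer(d),
      up3 = convt_layer(4L, w[3], d), inu3 = in_layer(w[3]),
      dec2 = conv_layer(3L, 2L * w[3], w[3]), ind2 = in_layer(w[3]),
      up2 = convt_layer(4L, w[2], w[3]), inu2 = in_layer(w[2]),
      dec1 = conv_layer(3L, 2L * w[2], w[2]), ind1 = in_layer(w[2]),
      up1 = convt_layer(4L, w[1], w[2]), inu1 = in_layer(w[1]),
      dec0 = conv_layer(3L, 2L * w[1], w[1]), ind0 = in_layer(w[1]),
      outconv = conv_layer(3L, w[1], config$out_channels),
      scpa = scpa_new(config)
    )
    m
  })
  model$cache <- new.env(parent = emptyenv())
  class(model) <- "octstain_generator"
  model
}

conv_in_act <- function(x, layer, norm, stride) {
  h <- op_conv2d(x, layer$w, layer$b, stride, 1L)
  if (!is.null(norm)) h <- op_instnorm(h, norm$g, norm$b)
  op_lrelu(h)
}

# encoder only: returns pyramid list (e0..e3); e3 is the bottleneck embedding
generator_encode <- function(model, x) {
  e0 <- op_lrelu(op_conv2d(x, model$inconv$w, model$inconv$b, 1L, 1L))
  e1 <- conv_in_act(e0, model$down1, model$in1, 2L)
  e2 <- conv_in_act(e1, model$down2, model$in2, 2L)
  e3 <- conv_in_act(e2, model$down3, model$in3, 2L)
  list(e0, e1, e2, e3)
}

# fuse the pyramid for the structure/pathology head: every level is
# average-pooled onto the deepest grid and concatenated channel-wise
scpa_fuse_pyramid <- function(pyr, n_scales) {
  fused <- op_avgpool(pyr[[1]], 2L^n_scales)
  for (i in seq_len(n_scales)) {
    fused <- op_concat_ch(fused, op_avgpool(pyr[[i + 1L]], 2L^(n_scales - i)))
  }
  fused
}

#' Channel count of the fused multi-scale grid the head tokenizes
#' @param config A [generator_config()].
#' @return Integer channel count.
#' @export
scpa_input_channels <- function(config) {
  sum(config$widths) + config$d_model
}

#' Run the generator on one image
#'
#' @param image H x W x C array with values in \[0, 1\] (or an internal node).
#' @param model Generator from [generator_new()].
#' @param scpa_on When `FALSE` the structure/pathology head is bypassed and
#'   zeros are concatenated in its place (ablation switch).
#' @return List with `output` (translated image node; `$value` is the H x W x
#'   out_channels array in \[0, 1\]), `pyramid` (multi-scale encoder feature
#'   nodes), `scpa` (head outputs: `seg_logits`, `cls_logit`, `z_m`, token
#'   geometry) and `embedding` (the deepest encoder feature node).
#' @export
generator_forward <- function(image, model, scpa_on = TRUE) {
  cfg <- model$config
  x <- if (is_node(image)) image else nd_const(as_image(image))
  dmx <- dim(x$value)
  if (dmx[3] != cfg$in_channels) stop("channel mismatch with generator config")
  if (dmx[1] %% (2L^cfg$n_scales) != 0L || dmx[2] %% (2L^cfg$n_scales) != 0L)
    stop("image sides must be divisible by 2^n_scales")
  pyr <- generator_encode(model, x)
  e3 <- pyr[[4]]
  h3 <- dmx[1] %/% (2L^cfg$n_scales); w3 <- dmx[2] %/% (2L^cfg$n_scales)
  if (h3 %% cfg$window_size != 0L || w3 %% cfg$window_size != 0L)
    stop("deepest feature grid must be divisible by the window size")
  t <- e3
  for (rstb in model$rstbs) t <- rstb_forward_node(t, rstb, h3, w3, model)
  if (scpa_on) {
    sc <- scpa_forward_node(scpa_fuse_pyramid(pyr, cfg$n_scales), model$scpa, cfg)
    zg <- op_gather_rows(sc$z_m, scpa_grid_index(h3, w3, cfg$scpa_patch))
    zg <- op_reshape(zg, c(h3, w3, cfg$d_model))
  } else {
    sc <- NULL
    zg <- nd_const(array(0, c(h3, w3, cfg$d_model)))
  }
  m <- conv_in_act(op_concat_ch(t, zg), model$merge, model$inm, 1L)
  u <- op_lrelu(op_instnorm(op_convt2d(m, model$up3$w, model$up3$b), model$inu3$g, model$inu3$b))
  u <- conv_in_act(op_concat_ch(u, pyr[[3]]), model$dec2, model$ind2, 1L)
  u <- op_lrelu(op_instnorm(op_convt2d(u, model$up2$w, model$up2$b), model$inu2$g, model$inu2$b))
  u <- conv_in_act(op_concat_ch(u, pyr[[2]]), model$dec1, model$ind1, 1L)
  u <- op_lrelu(op_instnorm(op_convt2d(u, model$up1$w, model$up1$b), model$inu1$g, model$inu1$b))
  u <- conv_in_act(op_concat_ch(u, pyr[[1]]), model$dec0, model$ind0, 1L)
  out <- op_sigmoid(op_conv2d(u, model$outconv$w, model$outconv$b, 1L, 1L))
  list(output = out, pyramid = pyr, scpa = sc, embedding = e3)
}

#' Translate an image without recording gradients
#' @param image H x W x C array in \[0, 1\].
#' @param model Generator.
#' @param scpa_on Ablation switch (see [generator_forward()]).
#' @return The translated H x W x out_channels array.
#' @export
translate <- function(image, model, scpa_on = TRUE) {
  generator_forward(image, model, scpa_on)$output$value
}

# bottleneck embedding of an image (deepest encoder feature, no decode)
generator_embed <- function(image, model) {
  x <- if (is_node(image)) image else nd_const(as_image(image))
  generator_encode(model, x)[[4]]
}
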
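# Structure-constraint / pathology-awareness head: a transformer
# encoder-decoder over patches of the deepest feature grid. It produces
# (i) a 3-class layer segmentation via scalar products between patch
# embeddings and learned class embeddings, (ii) a normal/pathological
# probability from a two-level MLP over pooled patch embeddings, and
# (iii) the patch embeddings z_M that are concatenated back into the
# generator's up-sampling path.

SCPA_K <- 3L  # intima, media, adventitia

# one pre-norm transformer layer with full (unwindowed) attention
tf_layer_new <- function(d, n_heads, mlp_ratio = 2) {
  hidden <- round(mlp_ratio * d)
  list(ln1 = ln_layer(d), mha = mha_layer(d, n_heads),
       ln2 = ln_layer(d), fc1 = dense_layer(d, hidden), fc2 = dense_layer(hidden, d))
}

tf_layer_forward <- function(x, ly, n_heads) {
  h <- op_layernorm(x, ly$ln1$g, ly$ln1$b)
  a <- op_mha(h, 1L, n_heads, ly$mha)
  x <- op_add(x, a)
  h2 <- op_layernorm(x, ly$ln2$g, ly$ln2$b)
  m <- op_dense(h2, ly$fc1$w, ly$fc1$b)
  m <- op_gelu(m)
  m <- op_dense(m, ly$fc2$w, ly$fc2$b)
  op_add(x, m)
}

scpa_new <- function(cfg) {
  d <- cfg$d_model
  P <- cfg$scpa_patch
  deep <- cfg$image_size %/% (2L^cfg$n_scales)
  n_tok <- (deep %/% P)^2
  in_ch <- sum(cfg$widths) + d  # fused multi-scale grid
  list(
    patch = P, d = d, n_heads = cfg$n_heads, in_channels = in_ch,
    embed = dense_layer(P * P * in_ch, d),
    pos = nd_param(matrix(stats::rnorm(n_tok * d, sd = 0.02), n_tok, d)),
    enc = lapply(seq_len(cfg$n_enc), function(i) tf_layer_new(d, cfg$n_heads)),
    dec = lapply(seq_len(cfg$n_dec), function(i) tf_layer_new(d, cfg$n_heads)),
    cls_embed = nd_param(matrix(stats::rnorm(SCPA_K * d, sd = 0.02), SCPA_K, d)),
    ln_f = ln_layer(d),
    # two-level classification MLP over pooled patch embeddings; mean pooling
    # alone washes out focal lesions once segmentation training aligns tokens
    # with the class embeddings, so the max-pooled profile is concatenated
    mlp1 = dense_layer(2L * d, d), mlp2 = dense_layer(d, 1L)
  )
}

# row-major patch order: patch t = (pi-1)*npw + pj
patchify_index <- function(H, W, P) {
  nph <- H %/% P; npw <- W %/% P
  idx <- integer(nph * npw * P * P)
  p <- 0L
  for (pi in seq_len(nph)) for (pj in seq_len(npw)) {
    for (ii in seq_len(P)) for (jj in seq_len(P)) {
      p <- p + 1L
      idx[p] <- (pi - 1L) * P + ii + H * ((pj - 1L) * P + jj - 1L)
    }
  }
  idx
}

# map grid row (column-major pixel) -> owning token index (nearest upsample)
scpa_grid_index <- function(H, W, P) {
  r <- seq_len(H * W)
  i <- ((r - 1L) %% H) + 1L
  j <- ((r - 1L) %/% H) + 1L
  pi <- (i - 1L) %/% P
  pj <- (j - 1L) %/% P
  pi * (W %/% P) + pj + 1L
}

# split grid into flattened patch rows: N x (P^2 * C), pixel index fastest
op_patchify <- function(grid, P) {
  dm <- dim(grid$value)
  H <- dm[1]; W <- dm[2]; C <- dm[3]
  if (P == 1L) {  # fast path: a pure row permutation
    idx <- patchify_index(H, W, 1L)
    gm <- matrix(grid$value, H * W, C)
    return(nd_op(gm[idx, , drop = FALSE], list(grid), function(g) {
      gg <- matrix(0, H * W, C)
      gg[idx, ] <- g
      dim(gg) <- dm
      list(gg)
    }))
  }
  idx <- patchify_index(H, W, P)
  n <- (H %/% P) * (W %/% P)
  gm <- matrix(grid$value, H * W, C)
  sub <- gm[idx, , drop = FALSE]                      # (N*P^2) x C, patch-major
  arr <- aperm(array(sub, c(P * P, n, C)), c(2L, 1L, 3L))
  out <- matrix(arr, n, P * P * C)
  nd_op(out, list(grid), function(g) {
    ga <- array(g, c(n, P * P, C))
    gsub <- matrix(aperm(ga, c(2L, 1L, 3L)), n * P * P, C)
    gg <- matrix(0, H * W, C)
    gg[idx, ] <- gsub
    dim(gg) <- dm
    list(gg)
  })
}

#' Cut a feature grid into embedded patch tokens
#'
#' Patches are taken in row-major order, flattened, linearly embedded and
#' summed with learnable position embeddings (`z0 = x0 + pos`).
#' @param features H x W x C array.
#' @param model A generator (its head holds the embedding and positions), or
#'   a head created internally.
#' @return List with `x` (N x P^2C flattened patches), `x0` (embedded
#'   sequence), `pos`, and `z0 = x0 + pos`.
#' @export
patchify_embed <- function(features, model) {
  head <- if (inherits(model, "octstain_generator")) model$scpa else model
  features <- as_image(features)
  dm <- dim(features)
  if (dm[1] %% head$patch != 0L || dm[2] %% head$patch != 0L)
    stop("feature grid sides must be divisible by the patch size")
  x <- op_patchify(nd_const(features), head$patch)
  x0 <- op_dense(x, head$embed$w, head$embed$b)
  n <- nrow(x0$value)
  if (n != nrow(head$pos$value))
    stop("token count does not match the configured position embeddings")
  z0 <- op_add(x0, head$pos)
  list(x = x$value, x0 = x0$value, pos = head$pos$value, z0 = z0$value)
}

# full head pass on the deepest feature grid (node-level, differentiable)
scpa_forward_node <- function(features, head, cfg) {
  dm <- dim(features$value)
  x <- op_patchify(features, head$patch)
  x0 <- op_dense(x, head$embed$w, head$embed$b)
  z <- op_add(x0, head$pos)
  for (ly in head$enc) z <- tf_layer_forward(z, ly, head$n_heads)
  n <- nrow(z$value)
  zc <- op_rbind(z, head$cls_embed)
  for (ly in head$dec) zc <- tf_layer_forward(zc, ly, head$n_heads)
  zc <- op_layernorm(zc, head$ln_f$g, head$ln_f$b)
  z_m <- op_gather_rows(zc, seq_len(n))
  cemb <- op_gather_rows(zc, n + seq_len(SCPA_K))
  seg_logits <- op_matmul(z_m, nd_op(t(cemb$value), list(cemb),
                                     function(g) list(t(g))))
  pooled <- op_cbind(op_mean_rows(z_m), op_colmax_rows(z_m))
  h <- op_gelu(op_dense(pooled, head$mlp1$w, head$mlp1$b))
  cls_logit <- op_dense(h, head$mlp2$w, head$mlp2$b)
  list(seg_logits = seg_logits, cls_logit = cls_logit, z_m = z_m,
       z_l = z, nph = dm[1] %/% head$patch, npw = dm[2] %/% head$patch,
       patch = head$patch)
}

#' Run the structure/pathology head on a feature grid
#'
#' @param features H x W x d array (normally the deepest pyramid level of a
#'   generator pass).
#' @param model Generator whose head to use.
#' @return List with `segmentation` (H x W x 3 per-pixel class probabilities,
#'   nearest-upsampled from token logits then softmaxed), `pathology`
#'   (probability the image is pathological), `z_m` (N x d patch embeddings)
#'   and `seg_logits` (N x 3 token logits).
#' @export
scpa_forward <- function(features, model) {
  head <- if (inherits(model, "octstain_generator")) model$scpa else model
  features <- as_image(features)
  out <- scpa_forward_node(nd_const(features), head,
                           if (inherits(model, "octstain_generator")) model$config else NULL)
  seg <- seg_probabilities(out)
  p <- 1 / (1 + exp(-out$cls_logit$value[1]))
  list(segmentation = seg, pathology = p, z_m = out$z_m$value,
       seg_logits = out$seg_logits$value)
}

# token logits -> pixel probability grid (nearest upsample, then softmax)
seg_probabilities <- function(sc, upscale = 1L) {
  lg <- sc$seg_logits$value
  nph <- sc$nph; npw <- sc$npw; P <- sc$patch * upscale
  H <- nph * P; W <- npw * P
  gidx <- scpa_grid_index(H, W, P)
  px <- lg[gidx, , drop = FALSE]
  pr <- softmax_rows(px)
  array(pr, c(H, W, SCPA_K))
}

#' Hard segmentation labels from the head's probability grid
#' @param seg H x W x 3 probability array.
#' @return H x W integer matrix of class codes (0 = intima, 1 = media,
#'   2 = adventitia).
#' @export
seg_classes <- function(seg) {
  dm <- dim(seg)
  m <- matrix(seg, dm[1] * dm[2], dm[3])
  matrix(max.col(m, ties.method = "first") - 1L, dm[1], dm[2])
}
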
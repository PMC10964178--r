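test_that("window partition and reassembly are inverse bijections", {
  set.seed(1)
  g8 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  p <- window_partition(g8, 4)
  expect_length(p$windows, 4L)
  expect_identical(dim(p$windows[[1]]), c(16L, 3L))
  expect_identical(window_reassemble(p), g8)
  expect_identical(sum(vapply(p$windows, nrow, integer(1))), 64L)

  g4 <- array(rnorm(16), c(4, 4, 1))
  p4 <- window_partition(g4, 4)
  expect_length(p4$windows, 1L)
  # tokens are the row-major pixels
  rowmajor <- as.vector(t(g4[, , 1]))
  expect_equal(as.vector(p4$windows[[1]]), rowmajor)
})

test_that("non-divisible grids pad then crop back exactly", {
  set.seed(2)
  g6 <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  expect_error(window_partition(g6, 4), "divisible")
  p <- window_partition(g6, 4, pad = TRUE)
  expect_identical(p$padded_height, 8)
  expect_length(p$windows, 4L)
  expect_identical(window_reassemble(p), g6)
  # direct index bookkeeping: token 1 of window 1 is pixel (1,1)
  expect_equal(p$windows[[1]][1, ], g6[1, 1, ])
  # padded tokens are zero: window 4 holds rows/cols 5:8, so its last token
  # (row 8, col 8) lies fully in the padding
  expect_equal(p$windows[[4]][16, ], c(0, 0))
})

test_that("attention weights are a proper softmax and N=1 reduces to X P_V", {
  set.seed(3)
  X1 <- matrix(rnorm(6), 1, 6)
  params <- list(P_Q = diag(6), P_K = diag(6), P_V = matrix(rnorm(36), 6), B = NULL,
                 n_heads = 1L)
  out <- window_attention(X1, params)
  expect_equal(unclass(out)[, ], (X1 %*% params$P_V)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  X <- matrix(rnorm(9 * 6), 9, 6)
  out2 <- window_attention(X, list(P_Q = matrix(rnorm(36), 6),
                                   P_K = matrix(rnorm(36), 6),
                                   P_V = matrix(rnorm(36), 6),
                                   B = matrix(rnorm(81), 9), n_heads = 2L))
  for (wts in attr(out2, "attention")) {
    expect_true(all(wts >= 0))
    expect_equal(rowSums(wts), rep(1, 9), tolerance = 1e-6)
  }
  expect_error(window_attention(X * NA, params), "finite")
})

test_that("windowed attention matches a literal three-loop oracle", {
  # brute-force: per head, per query, per key, evaluate
  # SoftMax(Q K' / sqrt(d) + B) V with explicit loops
  brute <- function(X, PQ, PK, PV, B, n_heads) {
    C <- ncol(X); N <- nrow(X); dh <- C / n_heads
    out <- matrix(0, N, C)
    Q <- X %*% PQ; K <- X %*% PK; V <- X %*% PV
    for (h in seq_len(n_heads)) {
      cls <- ((h - 1) * dh + 1):(h * dh)
      for (q in seq_len(N)) {
        logits <- numeric(N)
        for (k in seq_len(N)) {
          logits[k] <- sum(Q[q, cls] * K[k, cls]) / sqrt(dh) + B[q, k]
        }
        w <- exp(logits - max(logits)); w <- w / sum(w)
        for (k in seq_len(N)) out[q, cls] <- out[q, cls] + w[k] * V[k, cls]
      }
    }
    out
  }
  set.seed(4)
  for (rep in 1:20) {
    n_heads <- sample(c(1L, 2L), 1)
    C <- sample(c(4L, 6L), 1)
    N <- sample(c(4L, 9L), 1)
    X <- matrix(rnorm(N * C), N, C)
    PQ <- matrix(rnorm(C * C), C); PK <- matrix(rnorm(C * C), C)
    PV <- matrix(rnorm(C * C), C)
    B <- matrix(rnorm(N * N, sd = 0.5), N, N)
    got <- window_attention(X, list(P_Q = PQ, P_K = PK, P_V = PV,
                                    B = replicate(n_heads, B, simplify = FALSE),
                                    n_heads = n_heads))
    expect_equal(unclass(got), brute(X, PQ, PK, PV, B, n_heads),
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("a Swin layer with zeroed output projections is the identity", {
  model <- generator_new(tiny_gen_config(size = 32L), seed = 2)
  stl <- model$rstbs[[1]]$stls[[1]]
  stl$mha$wo$value[] <- 0
  stl$mha$bo$value[] <- 0
  stl$fc2$w$value[] <- 0
  stl$fc2$b$value[] <- 0
  model$rstbs[[1]]$stls[[1]] <- stl
  set.seed(5)
  g <- array(rnorm(4 * 4 * 12), c(4, 4, 12))
  expect_equal(stl_forward(g, model, 1, 1), g, tolerance = 1e-12)
  # shape preservation with live weights
  model2 <- generator_new(tiny_gen_config(size = 32L), seed = 3)
  out <- stl_forward(g, model2, 1, 1)
  expect_identical(dim(out), dim(g))
})

test_that("shifted windows change the computation", {
  model <- generator_new(tiny_gen_config(size = 64L), seed = 4)
  set.seed(6)
  g <- array(rnorm(8 * 8 * 12), c(8, 8, 12))
  # layer 2 is the shifted twin of layer 1; give it layer 1's weights so the
  # only difference is the shift itself
  model$rstbs[[1]]$stls[[2]] <- within(model$rstbs[[1]]$stls[[1]], shifted <- TRUE)
  plain <- stl_forward(g, model, 1, 1)
  shifted <- stl_forward(g, model, 1, 2)
  expect_gt(max(abs(plain - shifted)), 1e-6)
})

test_that("an RSTB computes Conv(F_STL + T_IN) literally", {
  model <- generator_new(tiny_gen_config(size = 32L), seed = 7)
  # zero both STLs' residual branches and set the conv to the identity kernel
  for (i in 1:2) {
    stl <- model$rstbs[[1]]$stls[[i]]
    stl$mha$wo$value[] <- 0; stl$mha$bo$value[] <- 0
    stl$fc2$w$value[] <- 0; stl$fc2$b$value[] <- 0
    model$rstbs[[1]]$stls[[i]] <- stl
  }
  d <- 12L
  ident <- array(0, c(3, 3, d, d))
  for (c in seq_len(d)) ident[2, 2, c, c] <- 1
  model$rstbs[[1]]$conv$w$value <- ident
  model$rstbs[[1]]$conv$b$value[] <- 0
  set.seed(8)
  g <- array(rnorm(4 * 4 * d), c(4, 4, d))
  expect_equal(rstb_forward(g, model, 1), g, tolerance = 1e-10)

  # compositional oracle: chain the two sub-steps by hand on a live model
  model2 <- generator_new(tiny_gen_config(size = 32L), seed = 9)
  f <- stl_forward(g, model2, 1, 1)
  f <- stl_forward(f, model2, 1, 2)
  conv <- model2$rstbs[[1]]$conv
  oracle <- op_conv2d(nd_const(f), conv$w, conv$b, 1L, 1L)$value
  expect_equal(rstb_forward(g, model2, 1), oracle, tolerance = 1e-5)
  expect_identical(dim(rstb_forward(g, model2, 1)), dim(g))
})

test_that("the generator maps domains with the contracted shapes and range", {
  m <- tiny_models(size = 32L, seed = 11)
  oct <- array(runif(32 * 32), c(32, 32, 1))
  out <- generator_forward(oct, m$g_oh)
  expect_identical(dim(out$output$value), c(32L, 32L, 3L))
  expect_true(all(out$output$value >= 0 & out$output$value <= 1))
  expect_length(out$pyramid, 4L)
  expect_identical(dim(out$pyramid[[4]]$value)[1:2], c(4L, 4L))

  he <- array(runif(32 * 32 * 3), c(32, 32, 3))
  back <- generator_forward(he, m$g_ho)
  expect_identical(dim(back$output$value), c(32L, 32L, 1L))
  expect_error(generator_forward(he, m$g_oh), "channel")
  expect_error(generator_forward(array(runif(30 * 30), c(30, 30, 1)), m$g_oh),
               "divisible")
})

test_that("the head's embedding path is live: bypassing it changes the output", {
  m <- tiny_models(size = 32L, seed = 12)
  oct <- array(runif(32 * 32), c(32, 32, 1))
  with_head <- translate(oct, m$g_oh, scpa_on = TRUE)
  without <- translate(oct, m$g_oh, scpa_on = FALSE)
  expect_gt(max(abs(with_head - without)), 1e-6)
})

test_that("every trainable parameter receives gradient somewhere in a step", {
  m <- tiny_models(size = 32L, seed = 13)
  cfg <- train_config(image_size = 32L, seed = 13, epochs = 4L)
  st <- trainer_state_new(m, cfg)
  ph <- make_phantoms(2, size = 32L, seed0 = 40L)
  b_o <- list(list(image = ph[[1]]$oct_image, mask = ph[[1]]$layer_mask,
                   pathology_label = ph[[1]]$pathology_label))
  b_h <- list(list(image = ph[[2]]$he_image, mask = ph[[2]]$layer_mask,
                   pathology_label = ph[[2]]$pathology_label))
  grads_seen <- new.env()
  # run one step but inspect generator grads before the optimizer consumes them
  ad_begin()
  f <- generator_forward(b_o[[1]]$image, m$g_oh)
  d <- discriminator_forward(f$output, m$d_h)
  r <- generator_forward(f$output, m$g_ho)
  wts <- sc_token_weights(b_o[[1]]$mask, 8L)
  loss <- op_wsum(list(
    op_mean_shift_sq(d, 1),
    op_mean_abs_diff(r$output, b_o[[1]]$image),
    op_mean_abs_diff(generator_embed(r$output, m$g_oh), f$embedding),
    op_ce_weighted(f$scpa$seg_logits, wts, sum(wts)),
    op_bce_logit(f$scpa$cls_logit, 1)
  ), rep(1, 5))
  ps <- collect_params(list(g = m$g_oh, d = m$d_h))
  zero_grads(ps)
  ad_backward(loss)
  ad_end()
  nonzero <- vapply(ps, function(p) !is.null(p$grad) && any(p$grad != 0), logical(1))
  expect_true(all(nonzero),
              info = paste("dead:", paste(names(ps)[!nonzero], collapse = ", ")))
})
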
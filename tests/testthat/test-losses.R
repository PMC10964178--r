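const_d <- function(v) function(img) matrix(v, 2, 2)

test_that("least-squares adversarial terms take their closed-form values", {
  real <- list(array(0.2, c(4, 4, 1)))
  fake <- list(array(0.8, c(4, 4, 1)))
  # a discriminator that is 1 on reals and 0 on fakes is perfect
  d_perfect <- function(img) if (mean(img) < 0.5) matrix(1, 2, 2) else matrix(0, 2, 2)
  al <- adversarial_loss(d_perfect, real, fake)
  expect_equal(al$discriminator, 0)
  expect_equal(al$generator, 1)

  al2 <- adversarial_loss(const_d(0.5), real, fake)
  expect_equal(al2$discriminator, 0.5)
  expect_equal(al2$generator, 0.25)

  # arithmetic oracle on a 3-image batch with random score maps
  set.seed(1)
  scores <- replicate(6, matrix(runif(4), 2, 2), simplify = FALSE)
  i <- 0
  d_rand <- function(img) { i <<- i %% 6 + 1; scores[[i]] }
  reals <- replicate(3, array(runif(16), c(4, 4, 1)), simplify = FALSE)
  fakes <- replicate(3, array(runif(16), c(4, 4, 1)), simplify = FALSE)
  al3 <- adversarial_loss(d_rand, reals, fakes)
  exp_d <- mean(vapply(scores[1:3], function(s) mean((s - 1)^2), numeric(1))) +
    mean(vapply(scores[4:6], function(s) mean(s^2), numeric(1)))
  expect_equal(al3$discriminator, exp_d, tolerance = 1e-7)
  expect_error(adversarial_loss(d_rand, list(), fakes), "empty")
})

test_that("cycle loss closed forms and random oracle", {
  ident <- function(img) img
  batch <- list(array(runif(16), c(4, 4, 1)), array(runif(16), c(4, 4, 1)))
  expect_equal(cycle_loss(ident, ident, batch, batch), 0)

  plus <- function(img) img + 0.1
  # each direction's cycle output is input + 0.1 -> L1 of 0.1 per direction
  expect_equal(cycle_loss(plus, ident, batch, batch), 0.2, tolerance = 1e-9)

  set.seed(2)
  g1 <- function(img) img * 0.5 + 0.1
  g2 <- function(img) img * 0.8
  bo <- list(array(runif(16), c(4, 4, 1)))
  bh <- list(array(runif(16), c(4, 4, 1)))
  direct <- mean(abs(g2(g1(bo[[1]])) - bo[[1]])) + mean(abs(g1(g2(bh[[1]])) - bh[[1]]))
  expect_equal(cycle_loss(g1, g2, bo, bh), direct, tolerance = 1e-6)
})

test_that("embedding loss compares input and reconstruction bottlenecks", {
  ident <- list(translate = function(img) img, embed = function(img) img)
  batch <- list(array(runif(16), c(4, 4, 1)))
  expect_equal(embedding_loss(ident, ident, batch, batch), 0)

  # cycle reconstruction shifted by a constant 0.2 in embedding space
  shift <- list(translate = function(img) img + 0.2,
                embed = function(img) img)
  keep <- list(translate = function(img) img - 0.2, embed = function(img) img)
  # forward: +0.2 then backward: -0.2 -> reconstruction equals input -> 0
  expect_equal(embedding_loss(shift, keep, batch, batch), 0, tolerance = 1e-9)
  # forward and backward both +0.2 -> reconstruction differs by 0.4
  expect_equal(embedding_loss(shift, shift, batch, batch), 0.8, tolerance = 1e-9)

  plain <- function(img) img
  expect_error(embedding_loss(plain, plain, batch, batch), "embedding")
})

test_that("segmentation loss: perfect, uniform, and hand-summed cases", {
  lab <- matrix(sample(0:2, 16, replace = TRUE), 4, 4)
  perfect <- array(0, c(4, 4, 3))
  for (k in 0:2) perfect[, , k + 1][lab == k] <- 1
  expect_equal(sc_loss(perfect, lab), 0, tolerance = 1e-6)

  unif <- array(1 / 3, c(4, 4, 3))
  expect_equal(sc_loss(unif, lab), log(3), tolerance = 1e-9)

  set.seed(3)
  raw <- array(runif(8 * 8 * 3), c(8, 8, 3))
  norm <- array(apply(raw, c(1, 2), function(v) v / sum(v)), c(3, 8, 8))
  pred <- aperm(norm, c(2, 3, 1))
  lab8 <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
  valid <- matrix(sample(c(TRUE, FALSE), 64, replace = TRUE, prob = c(0.7, 0.3)), 8, 8)
  acc <- 0; n <- 0
  for (i in 1:8) for (j in 1:8) {
    if (valid[i, j]) {
      acc <- acc - log(pred[i, j, lab8[i, j] + 1])
      n <- n + 1
    }
  }
  expect_equal(sc_loss(pred, lab8, valid), acc / n, tolerance = 1e-6)

  expect_message(v0 <- sc_loss(pred, lab8, matrix(FALSE, 8, 8)), "no valid")
  expect_identical(v0, 0)
  bad <- lab8; bad[1, 1] <- 5L
  expect_error(sc_loss(pred, bad), "labels outside")
})

test_that("classification loss closed forms", {
  expect_equal(pa_loss(1, 1), 0, tolerance = 1e-6)
  expect_equal(pa_loss(0, 0), 0, tolerance = 1e-6)
  expect_equal(pa_loss(0.5, 1), log(2), tolerance = 1e-9)
  expect_equal(pa_loss(0.5, 0), log(2), tolerance = 1e-9)
  set.seed(4)
  p <- runif(6); y <- rep(c(0, 1), 3)
  by_hand <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(pa_loss(p, y), by_hand, tolerance = 1e-7)
})

test_that("the weighted total follows the five-term identity", {
  comp <- list(adv_H = 1, adv_O = 1, cycle = 1, embedding = 1, sc = 1, pa = 1)
  bd <- total_loss(comp, loss_weights(1, 0.2, 5, 5))
  expect_equal(bd$total, 13.2, tolerance = 1e-9)
  bd0 <- total_loss(lapply(comp, function(x) 0))
  expect_identical(bd0$total, 0)
  set.seed(5)
  for (rep in 1:10) {
    c6 <- as.list(stats::setNames(runif(6), names(comp)))
    w <- loss_weights(runif(1), runif(1), runif(1), runif(1))
    bd <- total_loss(c6, w)
    dot <- sum(unlist(c6) * c(1, 1, w$alpha, w$beta, w$gamma, w$iota))
    expect_equal(bd$total, dot, tolerance = 1e-9)
  }
  comp$sc <- NaN
  expect_error(total_loss(comp), "sc")
})

test_that("the patch discriminator has a 70-pixel receptive field", {
  expect_identical(discriminator_receptive_field(discriminator_config()), 70L)
  d <- discriminator_new(discriminator_config(1, 4), seed = 1)
  sm <- discriminate(array(runif(64 * 64), c(64, 64, 1)), d)
  expect_true(is.matrix(sm) && all(is.finite(sm)))
  # 64 -> 32 -> 16 -> 8 (stride 2) -> 7 -> 6 (stride 1, kernel 4, pad 1)
  expect_identical(dim(sm), c(6L, 6L))
})
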
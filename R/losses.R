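# The five-term training objective: least-squares adversarial terms for both
# domains, cycle reconstruction, bottleneck-embedding consistency, the
# structural-constraint segmentation loss and the pathology-awareness
# classification loss, combined as
#   L = Ladv_H + Ladv_O + alpha*Lcycle + beta*Lembedding + gamma*LSC + iota*LPA.

#' Loss term weights
#' @param alpha Cycle-consistency weight (default 1).
#' @param beta Embedding-consistency weight (default 0.2).
#' @param gamma Structural-constraint (segmentation) weight (default 5).
#' @param iota Pathology-awareness (classification) weight (default 5).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 1, beta = 0.2, gamma = 5, iota = 5) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, iota >= 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, iota = iota),
            class = "loss_weights")
}

# apply a generator-like object (model, plain function, or list with
# $translate / $embed) to an image
apply_gen <- function(g, img) {
  if (inherits(g, "octstain_generator")) return(translate(img, g))
  if (is.function(g)) return(g(img))
  if (is.list(g) && is.function(g$translate)) return(g$translate(img))
  stop("not a generator: expected a model, function, or list with $translate")
}

embed_of <- function(g, img) {
  if (inherits(g, "octstain_generator")) return(generator_embed(img, g)$value)
  if (is.list(g) && is.function(g$embed)) return(g$embed(img))
  stop("embeddings unavailable: generator does not expose a bottleneck")
}

score_of <- function(d, img) {
  if (inherits(d, "octstain_discriminator")) return(discriminate(img, d))
  if (is.function(d)) return(d(img))
  stop("not a discriminator")
}

#' Least-squares adversarial loss for one domain
#'
#' Discriminator side: `E[(D(real) - 1)^2] + E[D(fake)^2]`; generator side:
#' `E[(D(fake) - 1)^2]`.
#' @param d Discriminator model or a function mapping an image to scores.
#' @param real_batch,fake_batch Lists of images from the matching domain.
#' @return List with `generator` and `discriminator` loss values.
#' @export
adversarial_loss <- function(d, real_batch, fake_batch) {
  if (!length(real_batch) || !length(fake_batch)) stop("empty batch")
  sr <- vapply(real_batch, function(im) mean((score_of(d, im) - 1)^2), numeric(1))
  sf0 <- vapply(fake_batch, function(im) mean(score_of(d, im)^2), numeric(1))
  sf1 <- vapply(fake_batch, function(im) mean((score_of(d, im) - 1)^2), numeric(1))
  list(generator = mean(sf1), discriminator = mean(sr) + mean(sf0))
}

#' Cycle-consistency loss
#'
#' Mean absolute error of `G_H->O(G_O->H(O)) - O` plus the mirrored term;
#' zero exactly when both cycles reconstruct their inputs.
#' @param g_oh,g_ho Generators (models or functions).
#' @param batch_o,batch_h Lists of images from each domain.
#' @return Non-negative scalar.
#' @export
cycle_loss <- function(g_oh, g_ho, batch_o, batch_h) {
  l1 <- function(a, b) mean(abs(a - b))
  lo <- vapply(batch_o, function(im) l1(apply_gen(g_ho, apply_gen(g_oh, im)), as_image(im)), numeric(1))
  lh <- vapply(batch_h, function(im) l1(apply_gen(g_oh, apply_gen(g_ho, im)), as_image(im)), numeric(1))
  mean(lo) + mean(lh)
}

#' Embedding-consistency loss
#'
#' Mean absolute distance between the bottleneck embedding of an input and
#' the bottleneck embedding of its cycle reconstruction, accumulated over
#' both directions. Requires generators that expose their bottleneck.
#' @param g_oh,g_ho Generators (models, or lists with `$translate`/`$embed`).
#' @param batch_o,batch_h Lists of images.
#' @return Non-negative scalar.
#' @export
embedding_loss <- function(g_oh, g_ho, batch_o, batch_h) {
  term <- function(gf, gb, im) {
    rec <- apply_gen(gb, apply_gen(gf, im))
    mean(abs(embed_of(gf, im) - embed_of(gf, rec)))
  }
  lo <- vapply(batch_o, function(im) term(g_oh, g_ho, im), numeric(1))
  lh <- vapply(batch_h, function(im) term(g_ho, g_oh, im), numeric(1))
  mean(lo) + mean(lh)
}

#' Structural-constraint (segmentation) loss
#'
#' Pixel-wise cross-entropy of the predicted three-class layer probabilities
#' against ground-truth layer labels, averaged over the valid pixels.
#' @param seg_pred H x W x 3 class-probability array.
#' @param labels H x W integer matrix with classes in `{0, 1, 2}` on valid
#'   pixels (0 intima, 1 media, 2 adventitia).
#' @param valid Optional logical H x W mask of supervised pixels (e.g. the
#'   non-background part of a phantom mask). `NULL` means all pixels.
#' @return Mean negative log-likelihood over valid pixels; 0 when no pixel is
#'   valid (the skip is reported via a message).
#' @export
sc_loss <- function(seg_pred, labels, valid = NULL) {
  dm <- dim(seg_pred)
  if (is.null(valid)) valid <- matrix(TRUE, dm[1], dm[2])
  if (!any(valid)) {
    message("sc_loss: no valid pixels; returning 0")
    return(0)
  }
  lab <- labels[valid]
  if (any(!lab %in% 0:2)) stop("labels outside {0,1,2} on valid pixels")
  pm <- matrix(seg_pred, dm[1] * dm[2], dm[3])
  p_true <- pm[cbind(which(valid), lab + 1L)]
  mean(-log(pmax(p_true, 1e-7)))
}

#' Pathology-awareness (classification) loss
#'
#' Binary cross-entropy of the predicted pathology probability against the
#' image-level label, clamped away from 0/1 for stability.
#' @param p Predicted probabilities in \[0, 1\].
#' @param y Binary labels (same length).
#' @return Mean binary cross-entropy.
#' @export
pa_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Combine the five loss terms into a weighted total
#'
#' @param components Named list or vector with `adv_H`, `adv_O`, `cycle`,
#'   `embedding`, `sc`, `pa`.
#' @param weights From [loss_weights()].
#' @return A `loss_breakdown` list: the six components plus `total =
#'   adv_H + adv_O + alpha*cycle + beta*embedding + gamma*sc + iota*pa`.
#' @export
total_loss <- function(components, weights = loss_weights()) {
  comp <- as.list(components)
  need <- c("adv_H", "adv_O", "cycle", "embedding", "sc", "pa")
  if (!all(need %in% names(comp))) {
    stop("missing loss components: ", paste(setdiff(need, names(comp)), collapse = ", "))
  }
  for (nm in need) {
    if (!is.finite(comp[[nm]])) stop("non-finite loss component: ", nm)
  }
  out <- comp[need]
  out$total <- comp$adv_H + comp$adv_O + weights$alpha * comp$cycle +
    weights$beta * comp$embedding + weights$gamma * comp$sc +
    weights$iota * comp$pa
  structure(out, class = "loss_breakdown")
}
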
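# Evaluation utilities on phantom data: pathology classification accuracy,
# layer segmentation accuracy, palette recovery of translated images, and
# supervised pre-training of the structure/pathology head.

#' Pathology probability of an image under a generator's head
#' @param image H x W x C array matching the generator's input domain.
#' @param model Generator.
#' @return Probability in \[0, 1\].
#' @export
predict_pathology <- function(image, model) {
  feats <- head_features(image, model)
  sc <- scpa_forward_node(feats, model$scpa, model$config)
  1 / (1 + exp(-sc$cls_logit$value[1]))
}

# fused multi-scale head input of an image (no gradients kept)
head_features <- function(image, model) {
  x <- if (is_node(image)) image else nd_const(as_image(image))
  pyr <- generator_encode(model, x)
  scpa_fuse_pyramid(pyr, model$config$n_scales)
}

#' Pixel-level layer segmentation of an image under a generator's head
#' @param image Input image.
#' @param model Generator.
#' @return H x W integer matrix of class codes 0/1/2 at image resolution.
#' @export
predict_segmentation <- function(image, model) {
  feats <- head_features(image, model)
  sc <- scpa_forward_node(feats, model$scpa, model$config)
  up <- model$config$scpa_patch * 2L^model$config$n_scales
  seg <- seg_probabilities(sc, upscale = up)
  seg_classes(seg)
}

#' Classification accuracy of a generator's head on phantom samples
#' @param model Generator (input domain must match `domain`).
#' @param samples List of `phantom_sample`s.
#' @param domain `"oct"` or `"he"`.
#' @return Fraction of samples whose thresholded probability matches the
#'   label.
#' @export
pathology_accuracy <- function(model, samples, domain = "oct") {
  img_of <- function(s) if (domain == "oct") s$oct_image else s$he_image
  pred <- vapply(samples, function(s) predict_pathology(img_of(s), model), numeric(1))
  lab <- vapply(samples, `[[`, integer(1), "pathology_label")
  mean((pred > 0.5) == (lab == 1L))
}

#' Segmentation pixel accuracy on labeled phantom samples
#'
#' Background pixels are excluded (the head only supervises the three wall
#' layers).
#' @param model Generator.
#' @param samples List of labeled `phantom_sample`s.
#' @param domain `"oct"` or `"he"`.
#' @return Pixel accuracy over tissue pixels.
#' @export
segmentation_accuracy <- function(model, samples, domain = "oct") {
  accs <- vapply(samples, function(s) {
    img <- if (domain == "oct") s$oct_image else s$he_image
    pred <- predict_segmentation(img, model)
    valid <- s$layer_mask != PHANTOM_CLASSES[["background"]]
    mean(pred[valid] == s$layer_mask[valid])
  }, numeric(1))
  mean(accs)
}

#' Does the translated image recover the correct per-layer palette?
#'
#' Translates held-out OCT phantoms to H&E and checks, for each wall layer,
#' whether the mean output color over that layer's true pixels is closer (in
#' RGB L2) to the layer's own palette mean than to the other layers'.
#' @param model OCT-to-H&E generator.
#' @param samples List of labeled `phantom_sample`s.
#' @param palette H&E palette the phantoms were rendered with.
#' @return Logical vector of length 3 (intima, media, adventitia matched).
#' @export
layer_color_match <- function(model, samples, palette = he_palette_default()) {
  sums <- matrix(0, 3, 3)
  npix <- numeric(3)
  for (s in samples) {
    out <- translate(s$oct_image, model)
    lesion <- phantom_inclusion_mask(s)  # lesion pixels are not layer tissue
    for (li in 1:3) {
      sel <- s$layer_mask == (li - 1L) & !lesion
      if (!any(sel)) next
      for (ch in 1:3) sums[li, ch] <- sums[li, ch] + sum(out[, , ch][sel])
      npix[li] <- npix[li] + sum(sel)
    }
  }
  meancol <- sums / npix
  vapply(1:3, function(li) {
    d <- sqrt(rowSums((palette$mean - matrix(meancol[li, ], 3, 3, byrow = TRUE))^2))
    which.min(d) == li
  }, logical(1))
}

#' Supervised pre-training of the structure/pathology head
#'
#' Freezes the generator encoder (its features are computed without
#' gradients) and trains only the head parameters on labeled phantoms with
#' the segmentation cross-entropy plus classification binary cross-entropy.
#' @param model Generator whose head to train (modified in place).
#' @param samples Labeled `phantom_sample`s of the generator's input domain.
#' @param domain `"oct"` or `"he"`.
#' @param steps Optimization steps.
#' @param lr Adam learning rate.
#' @param seed Seed for the sample order and augmentation.
#' @param flip_augment Left-right flip augmentation with probability 0.5.
#' @return Invisibly, the per-step loss values.
#' @export
pretrain_scpa <- function(model, samples, domain = "oct", steps = 400L,
                          lr = 2e-3, seed = 1L, flip_augment = TRUE) {
  head_params <- collect_params(model$scpa)
  opt <- adam_new(head_params, beta1 = 0.9)
  block <- model$config$scpa_patch * 2L^model$config$n_scales
  prep <- lapply(samples, function(s) {
    img <- if (domain == "oct") s$oct_image else s$he_image
    fimg <- flip_lr(img)
    wts <- fwts <- NULL
    if (!is.null(s$layer_mask)) {
      wts <- sc_token_weights(s$layer_mask, block)
      fwts <- sc_token_weights(s$layer_mask[, rev(seq_len(ncol(s$layer_mask)))],
                               block)
    }
    list(f = head_features(img, model)$value,
         ff = if (flip_augment) head_features(fimg, model)$value,
         w = wts, wf = fwts, y = s$pathology_label)
  })
  losses <- numeric(steps)
  local_seed(seed, {
    order_idx <- rep_len(sample(seq_along(samples)), steps)
    for (t in seq_len(steps)) {
      r <- prep[[order_idx[t]]]
      flip <- flip_augment && stats::runif(1) < 0.5
      f <- if (flip) r$ff else r$f
      w <- if (flip) r$wf else r$w
      ad_begin()
      sc <- scpa_forward_node(nd_const(f), model$scpa, model$config)
      terms <- list(op_bce_logit(sc$cls_logit, r$y))
      if (!is.null(w) && sum(w) > 0) {
        terms <- c(terms, list(op_ce_weighted(sc$seg_logits, w, sum(w))))
      }
      loss <- op_wsum(terms, rep(1, length(terms)))
      zero_grads(head_params)
      ad_backward(loss)
      ad_end()
      opt <- adam_step(opt, lr)
      losses[t] <- loss$value
    }
  })
  invisible(losses)
}
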
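# Reference-free set-similarity metrics between virtual and real histology
# image sets (Frechet inception distance and perceptual hash value), and
# reader-study (visual Turing test) statistics.

#' Gaussian feature statistics of an image set
#' @param features n x d matrix of per-image feature vectors.
#' @return List with `mu` (mean vector), `sigma` (symmetrized covariance) and
#'   `n`.
#' @export
feature_stats <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 samples for covariance")
  s <- stats::cov(features)
  s <- (s + t(s)) / 2
  list(mu = colMeans(features), sigma = s, n = nrow(features))
}

# principal square root of a symmetric PSD matrix by eigendecomposition,
# clipping small negative eigenvalues
sqrtm_psd <- function(m, tol = 1e-6) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ev <- e$values
  if (any(ev < -tol * max(abs(ev), 1))) {
    warning("matrix is not PSD beyond tolerance; clipping negative eigenvalues")
  }
  ev <- pmax(ev, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

#' Frechet distance between two Gaussian feature summaries
#'
#' `|mu_A - mu_B|^2 + Tr(S_A + S_B - 2 (S_A S_B)^{1/2})`, the standard
#' Frechet form, computed by eigendecomposition with negative-eigenvalue
#' clipping. Near-singular covariances receive a small diagonal loading.
#' @param stats_a,stats_b From [feature_stats()].
#' @return Non-negative scalar; 0 for identical statistics.
#' @export
fid <- function(stats_a, stats_b) {
  if (length(stats_a$mu) != length(stats_b$mu)) stop("feature dimension mismatch")
  sa <- stats_a$sigma; sb <- stats_b$sigma
  d <- nrow(sa)
  if (rcond_est(sa) < 1e-12 || rcond_est(sb) < 1e-12) {
    message("fid: near-singular covariance; applying diagonal loading 1e-10")
    sa <- sa + diag(1e-10, d)
    sb <- sb + diag(1e-10, d)
  }
  ah <- sqrtm_psd(sa)
  mid <- ah %*% sb %*% ah
  tr_sqrt <- sum(sqrt(pmax(eigen((mid + t(mid)) / 2, symmetric = TRUE,
                                 only.values = TRUE)$values, 0)))
  v <- sum((stats_a$mu - stats_b$mu)^2) + sum(diag(sa)) + sum(diag(sb)) - 2 * tr_sqrt
  max(v, 0)
}

rcond_est <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(abs(ev))
  if (mx == 0) return(0)
  min(abs(ev)) / mx
}

#' Deterministic convolutional feature extractor
#'
#' A small fixed-weight (seeded, never trained) three-stage convolutional
#' backbone used as the default feature source for FID and PHV at desk
#' scale: conv-ReLU-pool stages of 8, 16 and 32 channels. A deeper
#' externally trained backbone can be substituted wherever an `extractor`
#' argument is accepted.
#' @param in_channels Image channels the extractor expects.
#' @param seed Seed fixing the random weights.
#' @return An extractor object usable with [extract_features()].
#' @export
conv_feature_extractor <- function(in_channels = 3L, seed = 17L) {
  widths <- c(8L, 16L, 32L)
  layers <- local_seed(seed, {
    cin <- in_channels
    lapply(widths, function(co) {
      l <- conv_layer(3L, cin, co)
      cin <<- co
      l
    })
  })
  structure(list(layers = layers, widths = widths, in_channels = in_channels),
            class = "octstain_extractor")
}

#' Multi-level features of one image
#' @param image H x W x C array.
#' @param extractor From [conv_feature_extractor()].
#' @param level Stage (1, 2 or 3) whose feature map to return.
#' @return 3-D feature array (H' x W' x channels).
#' @export
extract_features <- function(image, extractor, level = 1L) {
  stopifnot(level %in% 1:3)
  x <- nd_const(as_image(image))
  for (i in seq_len(level)) {
    x <- op_relu(op_conv2d(x, extractor$layers[[i]]$w, extractor$layers[[i]]$b, 1L, 1L))
    if (i < level) x <- nd_const(pool2(x$value))
  }
  x$value
}

pool2 <- function(a) {
  dm <- dim(a)
  h2 <- dm[1] %/% 2L; w2 <- dm[2] %/% 2L
  a <- a[seq_len(2L * h2), seq_len(2L * w2), , drop = FALSE]
  b <- array(a, c(2L, h2, 2L, w2, dm[3]))
  o <- apply(b, c(2L, 4L, 5L), mean)
  o
}

# set-level pooled feature summary: mean over images of the global average
# pool of each channel
set_pooled_features <- function(images, extractor, level) {
  if (!length(images)) stop("empty image set")
  f <- vapply(images, function(im) {
    fm <- extract_features(im, extractor, level)
    colMeans(matrix(fm, prod(dim(fm)[1:2]), dim(fm)[3]))
  }, numeric(extractor$widths[level]))
  if (is.null(dim(f))) f <- matrix(f, nrow = 1L)
  t(f)  # n_images x channels
}

#' PHV configuration
#' @param level Extractor stage (1, 2 or 3).
#' @param threshold Channel agreement threshold T (default 0.02).
#' @param extractor Feature backbone; defaults to the seeded convolutional
#'   extractor.
#' @return Configuration list.
#' @export
phv_config <- function(level = 1L, threshold = 0.02, extractor = NULL) {
  stopifnot(threshold > 0, level %in% 1:3)
  list(level = as.integer(level), threshold = threshold, extractor = extractor)
}

#' Perceptual hash value between two image sets
#'
#' Each channel of the selected feature level is average-pooled per image and
#' averaged over each set; the PHV is the percentage of channels whose
#' set-mean activations agree within the threshold T. Higher is more
#' similar; identical sets score 100.
#' @param set_gen,set_real Lists of images (same channel count).
#' @param config From [phv_config()].
#' @return Percentage in \[0, 100\].
#' @export
phv <- function(set_gen, set_real, config = phv_config()) {
  if (!length(set_gen) || !length(set_real)) stop("empty image set")
  ex <- config$extractor
  if (is.null(ex)) ex <- conv_feature_extractor(dim(as_image(set_gen[[1]]))[3])
  a <- colMeans(set_pooled_features(set_gen, ex, config$level))
  b <- colMeans(set_pooled_features(set_real, ex, config$level))
  100 * mean(abs(a - b) <= config$threshold)
}

#' FID between two image sets through a feature extractor
#' @param set_a,set_b Lists of images.
#' @param extractor Feature backbone (defaults to the seeded extractor).
#' @param level Feature stage.
#' @return Non-negative scalar.
#' @export
fid_images <- function(set_a, set_b, extractor = NULL, level = 3L) {
  if (is.null(extractor)) extractor <- conv_feature_extractor(dim(as_image(set_a[[1]]))[3])
  fa <- feature_stats(set_pooled_features(set_a, extractor, level))
  fb <- feature_stats(set_pooled_features(set_b, extractor, level))
  fid(fa, fb)
}

# ---- reader study (visual Turing test) ----

#' Reader confusion counts for a real-versus-virtual study
#'
#' "Real" is the positive class: a real histology image called real is a true
#' positive; a virtual image called real is a false positive.
#' @param n_real_called_real,n_real_called_virtual,n_virtual_called_real,n_virtual_called_virtual
#'   Non-negative integers.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(n_real_called_real, n_real_called_virtual,
                             n_virtual_called_real, n_virtual_called_virtual) {
  v <- c(n_real_called_real, n_real_called_virtual,
         n_virtual_called_real, n_virtual_called_virtual)
  if (any(v < 0)) stop("counts must be non-negative")
  structure(list(tp = n_real_called_real, fn = n_real_called_virtual,
                 fp = n_virtual_called_real, tn = n_virtual_called_virtual),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Reader-study statistics from per-reader confusion counts
#'
#' Accuracy, precision, sensitivity and specificity per reader (with "real"
#' as the positive class), unweighted averages across readers, and the
#' two-way random-effects absolute-agreement single-rater intraclass
#' correlation when per-image ratings are supplied. Zero-denominator
#' statistics are reported as `NA` (undefined), never as 0.
#'
#' @param counts_per_reader A `confusion_counts` or list of them.
#' @param ratings Optional numeric matrix (images x readers) of per-image
#'   calls for the ICC.
#' @return List with `per_reader` (data frame), `average` (named vector),
#'   and `icc` (or `NA` when ratings are absent).
#' @export
reader_study_stats <- function(counts_per_reader, ratings = NULL) {
  if (inherits(counts_per_reader, "confusion_counts")) {
    counts_per_reader <- list(counts_per_reader)
  }
  per <- do.call(rbind, lapply(seq_along(counts_per_reader), function(i) {
    cc <- counts_per_reader[[i]]
    total <- cc$tp + cc$fn + cc$fp + cc$tn
    data.frame(
      reader = i,
      accuracy = safe_ratio(cc$tp + cc$tn, total),
      precision = safe_ratio(cc$tp, cc$tp + cc$fp),
      sensitivity = safe_ratio(cc$tp, cc$tp + cc$fn),
      specificity = safe_ratio(cc$tn, cc$tn + cc$fp)
    )
  }))
  avg <- colMeans(per[, -1, drop = FALSE])
  icc <- if (is.null(ratings)) NA_real_ else icc_two_way(ratings)
  list(per_reader = per, average = avg, icc = icc)
}

#' Intraclass correlation, two-way random effects, absolute agreement,
#' single rater (ICC(2,1))
#' @param ratings Numeric matrix, rows = subjects (images), columns = raters.
#' @return ICC estimate.
#' @export
icc_two_way <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm <- colMeans(ratings)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}
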
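# Patch discriminator: a fully convolutional stack (4x4 kernels, three
# stride-2 blocks then two stride-1 blocks) scoring overlapping receptive
# fields of 70 x 70 pixels. The output is a score map, not a single scalar,
# as in the least-squares unpaired-translation convention.

#' Discriminator configuration
#' @param in_channels Channels of the judged domain (1 OCT, 3 H&E).
#' @param base_width Channels of the first block; later blocks double it.
#' @return Configuration list.
#' @export
discriminator_config <- function(in_channels = 3L, base_width = 12L) {
  list(in_channels = as.integer(in_channels), base_width = as.integer(base_width),
       kernel = 4L, strides = c(2L, 2L, 2L, 1L, 1L))
}

#' Build a patch discriminator
#' @param config From [discriminator_config()].
#' @param seed RNG seed for initialization.
#' @return Discriminator model.
#' @export
discriminator_new <- function(config, seed = 1L) {
  w <- config$base_width
  model <- local_seed(seed, list(
    config = config,
    c1 = conv_layer(4L, config$in_channels, w),
    c2 = conv_layer(4L, w, 2L * w), n2 = in_layer(2L * w),
    c3 = conv_layer(4L, 2L * w, 4L * w), n3 = in_layer(4L * w),
    c4 = conv_layer(4L, 4L * w, 8L * w), n4 = in_layer(8L * w),
    head = conv_layer(4L, 8L * w, 1L)
  ))
  class(model) <- "octstain_discriminator"
  model
}

# node-level score map
discriminator_forward <- function(image, model) {
  x <- if (is_node(image)) image else nd_const(as_image(image))
  h <- op_lrelu(op_conv2d(x, model$c1$w, model$c1$b, 2L, 1L))
  h <- op_lrelu(op_instnorm(op_conv2d(h, model$c2$w, model$c2$b, 2L, 1L),
                            model$n2$g, model$n2$b))
  h <- op_lrelu(op_instnorm(op_conv2d(h, model$c3$w, model$c3$b, 2L, 1L),
                            model$n3$g, model$n3$b))
  h <- op_lrelu(op_instnorm(op_conv2d(h, model$c4$w, model$c4$b, 1L, 1L),
                            model$n4$g, model$n4$b))
  op_conv2d(h, model$head$w, model$head$b, 1L, 1L)
}

#' Discriminator score map for an image
#' @param image H x W x C array.
#' @param model From [discriminator_new()].
#' @return Matrix of patch scores.
#' @export
discriminate <- function(image, model) {
  out <- discriminator_forward(image, model)$value
  out[, , 1]
}

#' Analytic receptive field of the discriminator's patch scores
#'
#' Walks the layer stack backwards (`rf_in = rf_out * stride + kernel -
#' stride`); the default stack gives 70 pixels.
#' @param config From [discriminator_config()].
#' @return Receptive field side length in input pixels.
#' @export
discriminator_receptive_field <- function(config = discriminator_config()) {
  rf <- 1L
  for (s in rev(config$strides)) rf <- rf * s + config$kernel - s
  rf
}
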
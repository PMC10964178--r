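# Inference-time virtual staining of 2D images and 3D volumes, tiled
# processing of large inputs, and plain-file image/volume I/O.

#' Quantize unit-interval values to an integer bit depth
#'
#' Rounds half away from zero, the convention used for all 8/16-bit exports.
#' @param x Numeric array in \[0, 1\].
#' @param bits Target bit depth (8 or 16).
#' @return Array of the same shape with values snapped to `k / (2^bits - 1)`.
#' @export
quantize_unit <- function(x, bits = 8L) {
  m <- 2^bits - 1
  floor(clamp01(x) * m + 0.5) / m
}

#' Write an image to PNG (8-bit) or TIFF (8- or 16-bit)
#' @param img H x W or H x W x C array in \[0, 1\].
#' @param path Destination; format chosen by extension (.png/.tif/.tiff).
#' @param bits Bit depth; PNG supports 8, TIFF 8 or 16.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path, bits = 8L) {
  img <- quantize_unit(img, bits)
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) dim(img) <- dim(img)[1:2]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits != 8L) stop("PNG export is 8-bit; use TIFF for 16-bit")
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read an image into an H x W x C array in \[0, 1\]
#' @param path PNG or TIFF file.
#' @return Numeric array (alpha channel dropped if present).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image format: ", ext)
  img <- as_image(img)
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

# layer masks: 8-bit PNG with integer class codes {0,1,2,3}
write_mask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Construct a volume from a list of slices
#' @param slices List of H x W x C arrays with identical dimensions.
#' @param spacing Numeric length-3: micrometers per pixel in (row, column,
#'   slice) directions.
#' @return A `volume` object.
#' @export
as_volume <- function(slices, spacing = c(2, 2, 2)) {
  if (!length(slices)) stop("empty volume")
  slices <- lapply(slices, as_image)
  d1 <- dim(slices[[1]])
  ok <- vapply(slices, function(s) identical(dim(s), d1), logical(1))
  if (!all(ok)) stop("all slices must share dimensions and channel count")
  structure(list(slices = slices, spacing = spacing), class = "volume")
}

#' Write a volume as a multi-page TIFF
#' @param vol A `volume`.
#' @param path Destination `.tif`.
#' @param bits Bit depth (8 or 16).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, bits = 8L) {
  pages <- lapply(vol$slices, function(s) {
    s <- quantize_unit(s, bits)
    if (dim(s)[3] == 1L) dim(s) <- dim(s)[1:2]
    s
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read a multi-page TIFF as a volume
#' @param path TIFF stack.
#' @param spacing Micrometers per pixel/slice.
#' @return A `volume`.
#' @export
read_volume <- function(path, spacing = c(2, 2, 2)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  as_volume(pages, spacing)
}

# tile start offsets covering 1..size with the given tile and overlap
tile_starts <- function(size, tile, overlap) {
  if (tile > size) stop("image smaller than the tile")
  if (tile == size) return(1L)
  step <- tile - overlap
  if (step < 1L) stop("overlap must be smaller than the tile")
  st <- seq.int(1L, size - tile + 1L, by = step)
  if (st[length(st)] + tile - 1L < size) st <- c(st, size - tile + 1L)
  st
}

#' Virtually stain one OCT image
#'
#' Images larger than the model's native patch size are processed in
#' overlapping tiles blended by linear feathering; a tile covering the whole
#' image reproduces the un-tiled forward pass exactly.
#'
#' @param oct_image H x W x 1 array in \[0, 1\].
#' @param model OCT-to-H&E generator (or any function mapping a tile to an
#'   output tile, e.g. for testing).
#' @param tile Tile side; defaults to the generator's configured patch size.
#' @param overlap Pixels of overlap between neighboring tiles.
#' @return Stained H x W x 3 array in \[0, 1\].
#' @export
stain_image <- function(oct_image, model, tile = NULL, overlap = 16L) {
  img <- as_image(oct_image)
  dm <- dim(img)
  if (inherits(model, "octstain_generator")) {
    if (dm[3] != model$config$in_channels) stop("channel mismatch with model config")
    if (is.null(tile)) tile <- model$config$image_size
  } else if (is.null(tile)) tile <- min(dm[1], dm[2])
  if (tile == dm[1] && tile == dm[2]) {
    return(apply_gen(model, img))
  }
  si <- tile_starts(dm[1], tile, overlap)
  sj <- tile_starts(dm[2], tile, overlap)
  tri <- pmin(seq_len(tile), tile + 1L - seq_len(tile))  # linear feather
  wt <- outer(tri, tri)
  out <- NULL
  acc <- matrix(0, dm[1], dm[2])
  for (i0 in si) for (j0 in sj) {
    ti <- i0:(i0 + tile - 1L)
    tj <- j0:(j0 + tile - 1L)
    y <- as_image(apply_gen(model, img[ti, tj, , drop = FALSE]))
    if (is.null(out)) out <- array(0, c(dm[1], dm[2], dim(y)[3]))
    for (ch in seq_len(dim(y)[3])) {
      out[ti, tj, ch] <- out[ti, tj, ch] + y[, , ch] * wt
    }
    acc[ti, tj] <- acc[ti, tj] + wt
  }
  for (ch in seq_len(dim(out)[3])) out[, , ch] <- out[, , ch] / acc
  out
}

#' Virtually stain a 3D OCT volume slice by slice
#' @param volume A `volume` of OCT slices.
#' @param model OCT-to-H&E generator.
#' @param ... Passed to [stain_image()].
#' @return A `volume` of stained slices (same slice count and spacing).
#' @export
stain_volume <- function(volume, model, ...) {
  if (!inherits(volume, "volume")) stop("expected a volume object")
  if (!length(volume$slices)) stop("empty volume")
  as_volume(lapply(volume$slices, stain_image, model = model, ...),
            spacing = volume$spacing)
}
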
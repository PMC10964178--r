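# Synthetic coronary phantom generator. Produces unpaired OCT-like and
# H&E-like image pairs over a shared three-layer laminar geometry
# (intima / media / adventitia over a lumen background), with optional
# lipid-rich or calcified inclusions, ground-truth layer masks and
# image-level pathology labels. Geometry is planar because training patches
# of a vessel wall are locally laminar at patch scale.

PHANTOM_CLASSES <- c(intima = 0L, media = 1L, adventitia = 2L, background = 3L)

#' Default per-layer H&E color statistics
#'
#' Eosin-dominated pink intima, hematoxylin-shifted purple media, collagen
#' pink adventitia; near-white lumen background. Values are RGB means in
#' \[0, 1\] with a common per-channel noise standard deviation.
#' @return List with `mean` (3 x 3 matrix, layers in rows), `sd`, and
#'   `background` RGB.
#' @export
he_palette_default <- function() {
  list(
    mean = rbind(intima = c(0.88, 0.60, 0.70),
                 media = c(0.60, 0.40, 0.68),
                 adventitia = c(0.84, 0.52, 0.56)),
    sd = 0.025,
    background = c(0.96, 0.94, 0.95)
  )
}

# per-layer OCT mean reflectivity (intima bright, media dark, adventitia
# intermediate - the usual appearance of the arterial wall)
OCT_REFLECTIVITY <- c(intima = 0.78, media = 0.36, adventitia = 0.60)

#' Specification of one synthetic phantom
#'
#' @param height,width Image size in pixels (2 um/pixel semantics).
#' @param layer_fractions Intima, media, adventitia thicknesses as fractions
#'   of the image height; strictly positive, summing to at most 1. The
#'   remainder is lumen/background above and below the wall.
#' @param pathology_kind `"none"`, `"lipid"` or `"calcium"`.
#' @param pathology_count Number of inclusions (0 iff kind is `"none"`).
#' @param pathology_radius_range Inclusive pixel range for inclusion
#'   semi-axes; must lie within `[1, min(height, width)/2]`. The default makes
#'   lesion diameters comparable to the layer thicknesses, as real lipid
#'   pools and calcifications are; cell-sized specks would not be.
#' @param speckle_contrast OCT multiplicative speckle scale; the unit-mean
#'   gamma speckle factor has shape `1/speckle_contrast^2`.
#' @param he_palette Per-layer H&E color statistics, see
#'   [he_palette_default()].
#' @param labeled Whether the sample carries a pixel-level layer mask.
#' @param seed Non-negative integer; fixes every random draw of the sample.
#' @return A validated `phantom_spec`.
#' @export
phantom_spec <- function(height = 64L, width = 64L,
                         layer_fractions = c(0.22, 0.28, 0.30),
                         pathology_kind = c("none", "lipid", "calcium"),
                         pathology_count = 0L,
                         pathology_radius_range = c(6L, 16L),
                         speckle_contrast = 0.35,
                         he_palette = he_palette_default(),
                         labeled = TRUE, seed = 0L) {
  pathology_kind <- match.arg(pathology_kind)
  if (length(layer_fractions) != 3L || any(layer_fractions <= 0) ||
      sum(layer_fractions) > 1) {
    stop("layer_fractions must be three positive values summing to at most 1")
  }
  if ((pathology_kind == "none") != (pathology_count == 0L)) {
    stop("pathology_kind == 'none' iff pathology_count == 0")
  }
  rmax <- min(height, width) / 2
  if (pathology_radius_range[1] < 1 || pathology_radius_range[2] > rmax ||
      pathology_radius_range[1] > pathology_radius_range[2]) {
    stop("pathology_radius_range must lie within [1, min(height, width)/2]")
  }
  if (speckle_contrast <= 0) stop("speckle_contrast must be positive")
  if (seed < 0) stop("seed must be non-negative")
  structure(list(
    height = as.integer(height), width = as.integer(width),
    layer_fractions = layer_fractions, pathology_kind = pathology_kind,
    pathology_count = as.integer(pathology_count),
    pathology_radius_range = pathology_radius_range,
    speckle_contrast = speckle_contrast, he_palette = he_palette,
    labeled = isTRUE(labeled), seed = as.integer(seed)
  ), class = "phantom_spec")
}

# layer class of every pixel given per-column boundary rows
rasterize_layers <- function(geom, H, W) {
  cls <- matrix(PHANTOM_CLASSES[["background"]], H, W)
  rows <- seq_len(H)
  for (x in seq_len(W)) {
    b <- c(geom$b0[x], geom$b1[x], geom$b2[x], geom$b3[x])
    cls[rows > b[1] & rows <= b[2], x] <- PHANTOM_CLASSES[["intima"]]
    cls[rows > b[2] & rows <= b[3], x] <- PHANTOM_CLASSES[["media"]]
    cls[rows > b[3] & rows <= b[4], x] <- PHANTOM_CLASSES[["adventitia"]]
  }
  cls
}

# logical mask of pixels inside any inclusion (optionally only the rim)
inclusion_membership <- function(inc, H, W, band = c(0, 1)) {
  m <- matrix(FALSE, H, W)
  if (!length(inc)) return(m)
  ij <- expand.grid(i = seq_len(H), j = seq_len(W))
  for (e in inc) {
    di <- ij$i - e$ci
    dj <- ij$j - e$cj
    u <- (cos(e$theta) * di + sin(e$theta) * dj) / e$r1
    v <- (-sin(e$theta) * di + cos(e$theta) * dj) / e$r2
    r <- sqrt(u^2 + v^2)
    m <- m | matrix(r >= band[1] & r <= band[2], H, W)
  }
  m
}

#' Generate one synthetic phantom sample
#'
#' Deterministic for a fixed `spec$seed`. The OCT image is the per-layer
#' reflectivity with exponential depth attenuation inside the tissue,
#' multiplied by unit-mean gamma speckle; the H&E image is the per-layer
#' palette color plus Gaussian noise. Lipid inclusions appear as near-white
#' regions in H&E and smooth low-signal voids in OCT; calcifications as dark
#' purple H&E regions and sharp low-signal OCT regions with a bright rim.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_sample`: `oct_image` (H x W x 1), `he_image`
#'   (H x W x 3), `layer_mask` (H x W integers 0-3, or `NULL` when
#'   unlabeled), `pathology_label` (0/1), `seed`, and the drawn `geometry`
#'   (boundaries and inclusion parameters).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  local_seed(spec$seed, {
    fr <- spec$layer_fractions
    top <- (1 - sum(fr)) * H * stats::runif(1, 0.3, 0.7)
    amp <- stats::runif(1, 0.005, 0.02) * H
    ph <- stats::runif(1, 0, 2 * pi)
    freq <- sample(1:2, 1)
    x <- seq_len(W)
    wig <- amp * sin(2 * pi * freq * x / W + ph)
    b0 <- pmin(pmax(top + wig, 0), H - 1)
    b1 <- pmin(b0 + fr[1] * H, H)
    b2 <- pmin(b1 + fr[2] * H, H)
    b3 <- pmin(b2 + fr[3] * H, H)
    inc <- list()
    if (spec$pathology_count > 0L) {
      rr <- spec$pathology_radius_range
      for (q in seq_len(spec$pathology_count)) {
        r1 <- stats::runif(1, rr[1], rr[2])
        r2 <- stats::runif(1, rr[1], rr[2])
        ja <- min(1 + r2, W / 2); jb <- max(W - r2, W / 2)
        cx <- stats::runif(1, ja, jb)
        lo <- stats::approx(x, b0, xout = cx)$y
        hi <- stats::approx(x, b3, xout = cx)$y
        ia <- min(lo + r1, H - 1); ib <- max(min(hi, H - r1), ia)
        ci <- stats::runif(1, ia, ib)
        inc[[q]] <- list(ci = ci, cj = cx, r1 = r1, r2 = r2,
                         theta = stats::runif(1, 0, pi),
                         kind = spec$pathology_kind)
      }
    }
    geom <- list(b0 = b0, b1 = b1, b2 = b2, b3 = b3, inclusions = inc)
    cls <- rasterize_layers(geom, H, W)

    # --- OCT rendering ---
    refl <- matrix(0.02, H, W)
    for (nm in names(OCT_REFLECTIVITY)) {
      refl[cls == PHANTOM_CLASSES[[nm]]] <- OCT_REFLECTIVITY[[nm]]
    }
    depth <- sweep(matrix(seq_len(H), H, W), 2L, b0)
    atten <- exp(-pmax(depth, 0) / (0.9 * H))
    refl <- refl * atten
    if (length(inc)) {
      core <- inclusion_membership(inc, H, W, c(0, 0.85))
      shell <- inclusion_membership(inc, H, W, c(0.85, 1))
      if (spec$pathology_kind == "lipid") {
        soft <- inclusion_membership(inc, H, W, c(0, 1))
        refl[soft] <- refl[soft] * 0.30
      } else {
        refl[core] <- refl[core] * 0.15
        refl[shell] <- 0.95 * atten[shell]
      }
    }
    shape <- 1 / spec$speckle_contrast^2
    speck <- matrix(stats::rgamma(H * W, shape = shape, rate = shape), H, W)
    oct <- clamp01(refl * speck)
    dim(oct) <- c(H, W, 1L)

    # --- H&E rendering ---
    pal <- spec$he_palette
    he <- array(0, c(H, W, 3L))
    for (ch in 1:3) {
      plane <- matrix(pal$background[ch], H, W)
      for (li in 1:3) plane[cls == li - 1L] <- pal$mean[li, ch]
      he[, , ch] <- plane
    }
    if (length(inc)) {
      inside <- inclusion_membership(inc, H, W, c(0, 1))
      lesion_col <- if (spec$pathology_kind == "lipid") {
        c(0.97, 0.96, 0.95)   # lipid: near-white hole
      } else {
        c(0.32, 0.18, 0.40)   # calcium: dark purple
      }
      for (ch in 1:3) {
        plane <- he[, , ch]
        plane[inside] <- lesion_col[ch]
        he[, , ch] <- plane
      }
    }
    he <- clamp01(he + array(stats::rnorm(H * W * 3, sd = pal$sd), c(H, W, 3L)))

    structure(list(
      oct_image = oct, he_image = he,
      layer_mask = if (spec$labeled) cls else NULL,
      pathology_label = as.integer(length(inc) > 0L),
      seed = spec$seed, geometry = geom, spec = spec
    ), class = "phantom_sample")
  })
}

#' Pixels covered by any pathological inclusion of a sample
#'
#' Re-derives inclusion membership from the stored geometry alone, so a
#' blinded checker can recover the image-level pathology label from pixels.
#' @param sample A `phantom_sample`.
#' @return Logical H x W matrix.
#' @export
phantom_inclusion_mask <- function(sample) {
  d <- dim(sample$oct_image)
  inclusion_membership(sample$geometry$inclusions, d[1], d[2])
}

#' Generate an unpaired two-domain phantom dataset on disk
#'
#' Each sample is rendered from its own seed and written in one domain only
#' (domains alternate within the normal and pathological groups), emulating
#' an unpaired OCT / histology collection. Exactly
#' `round(labeled_fraction * n)` samples carry pixel masks.
#'
#' @param n_normal,n_pathological Sample counts per class.
#' @param base_spec Template [phantom_spec()]; per-sample seeds, pathology
#'   kind (alternating lipid/calcium when the template says `"none"`) and
#'   inclusion counts are derived deterministically from `seed`.
#' @param labeled_fraction Fraction of samples with pixel masks.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (also written as
#'   `manifest.csv` with columns `id,domain,path,mask_path,pathology_label,
#'   seed`; paths relative to `out_dir`).
#' @export
generate_dataset <- function(n_normal, n_pathological,
                             base_spec = phantom_spec(),
                             labeled_fraction = 0.5, seed = 1L,
                             out_dir) {
  stopifnot(n_normal >= 0, n_pathological >= 0,
            labeled_fraction >= 0, labeled_fraction <= 1)
  n <- n_normal + n_pathological
  if (n == 0L) stop("empty dataset")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("unwritable output directory: ", out_dir)
  seeds <- (as.numeric(seed) * 10007 + 17 * seq_len(n)) %% 2147483647
  pathological <- c(rep(FALSE, n_normal), rep(TRUE, n_pathological))
  domain <- character(n)
  domain[!pathological] <- rep_len(c("oct", "he"), n_normal)
  domain[pathological] <- rep_len(c("oct", "he"), n_pathological)
  kinds <- rep("none", n)
  kinds[pathological] <- rep_len(c("lipid", "calcium"), n_pathological)
  n_labeled <- round(labeled_fraction * n)
  labeled <- rep(FALSE, n)
  if (n_labeled > 0) labeled[local_seed(seed, sample.int(n, n_labeled))] <- TRUE
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$seed <- as.integer(seeds[i])
    sp$pathology_kind <- kinds[i]
    sp$pathology_count <- if (pathological[i]) 1L + as.integer(seeds[i] %% 3) else 0L
    sp$labeled <- labeled[i]
    sample_i <- generate_phantom(sp)
    id <- sprintf("s%04d", i)
    img <- if (domain[i] == "oct") sample_i$oct_image else sample_i$he_image
    ipath <- file.path("images", paste0(id, "_", domain[i], ".png"))
    write_image(img, file.path(out_dir, ipath))
    mpath <- NA_character_
    if (labeled[i]) {
      mpath <- file.path("masks", paste0(id, "_mask.png"))
      write_mask(sample_i$layer_mask, file.path(out_dir, mpath))
    }
    rows[[i]] <- data.frame(
      id = id, domain = domain[i], path = ipath, mask_path = mpath,
      pathology_label = sample_i$pathology_label, seed = sp$seed,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(manifest)
}

#' Read a dataset manifest and its images into memory
#' @param manifest_path Path to `manifest.csv`.
#' @return List of records: `image` (H x W x C in \[0, 1\]), `mask` (matrix
#'   or `NULL`), `domain`, `pathology_label`, `id`, `seed`.
#' @export
load_dataset <- function(manifest_path) {
  root <- dirname(manifest_path)
  mf <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(mf)), function(i) {
    r <- mf[i, ]
    mask <- NULL
    if (!is.na(r$mask_path) && nzchar(r$mask_path)) {
      mask <- read_mask(file.path(root, r$mask_path))
    }
    list(image = read_image(file.path(root, r$path)), mask = mask,
         domain = r$domain, pathology_label = r$pathology_label,
         id = r$id, seed = r$seed)
  })
}
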
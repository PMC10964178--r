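test_that("phantom generation is bit-identical for a fixed seed", {
  sp <- phantom_spec(seed = 7L, pathology_kind = "lipid", pathology_count = 2L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$oct_image, b$oct_image)
  expect_identical(a$he_image, b$he_image)
  expect_identical(a$layer_mask, b$layer_mask)
  expect_identical(a$pathology_label, b$pathology_label)
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(layer_fractions = c(0.5, 0.4, 0.3)), "summing")
  expect_error(phantom_spec(layer_fractions = c(-0.1, 0.2, 0.2)), "positive")
  expect_error(phantom_spec(pathology_kind = "lipid", pathology_count = 0L), "iff")
  expect_error(phantom_spec(pathology_kind = "none", pathology_count = 2L), "iff")
  expect_error(phantom_spec(pathology_radius_range = c(0.5, 8)), "radius")
  expect_error(phantom_spec(height = 32, width = 32,
                            pathology_radius_range = c(3, 20)), "radius")
})

test_that("a pathology-free phantom is labeled normal and purely layered", {
  s <- generate_phantom(phantom_spec(seed = 3L))
  expect_identical(s$pathology_label, 0L)
  expect_length(s$geometry$inclusions, 0L)
  expect_false(any(phantom_inclusion_mask(s)))
  expect_true(all(s$oct_image >= 0 & s$oct_image <= 1))
  expect_true(all(s$he_image >= 0 & s$he_image <= 1))
  expect_identical(dim(s$oct_image)[1:2], dim(s$he_image)[1:2])
})

test_that("mask class counts match an independent re-rasterization", {
  s <- generate_phantom(phantom_spec(
    height = 64L, width = 64L, layer_fractions = c(0.2, 0.3, 0.3),
    labeled = TRUE, seed = 21L
  ))
  g <- s$geometry
  # brute-force oracle: classify every pixel from the stored boundaries
  oracle <- matrix(3L, 64, 64)
  for (x in 1:64) for (i in 1:64) {
    oracle[i, x] <- if (i <= g$b0[x]) 3L
    else if (i <= g$b1[x]) 0L
    else if (i <= g$b2[x]) 1L
    else if (i <= g$b3[x]) 2L
    else 3L
  }
  expect_identical(unname(s$layer_mask), unname(oracle))
  expect_identical(as.vector(table(factor(s$layer_mask, levels = 0:3))),
                   as.vector(table(factor(oracle, levels = 0:3))))
})

test_that("unlabeled specs carry no mask and labels follow inclusions", {
  s <- generate_phantom(phantom_spec(seed = 5L, labeled = FALSE,
                                     pathology_kind = "calcium",
                                     pathology_count = 1L))
  expect_null(s$layer_mask)
  expect_identical(s$pathology_label, 1L)
})

test_that("dataset manifests count samples, labels and masks correctly", {
  d <- withr::local_tempdir()
  mf <- generate_dataset(4, 3, phantom_spec(height = 32, width = 32),
                         labeled_fraction = 0.5, seed = 2, out_dir = d)
  expect_identical(nrow(mf), 7L)
  expect_identical(sum(mf$pathology_label), 3L)
  expect_equal(sum(!is.na(mf$mask_path) & nzchar(mf$mask_path)), round(0.5 * 7))
  expect_setequal(unique(mf$domain), c("oct", "he"))
  expect_true(all(file.exists(file.path(d, mf$path))))

  d0 <- withr::local_tempdir()
  mf0 <- generate_dataset(3, 2, phantom_spec(height = 32, width = 32),
                          labeled_fraction = 0, seed = 2, out_dir = d0)
  expect_identical(length(list.files(file.path(d0, "masks"))), 0L)
})

test_that("the full-size dataset layout matches the study proportions", {
  d <- withr::local_tempdir()
  mf <- generate_dataset(112, 82,
                         phantom_spec(height = 16, width = 16,
                                      pathology_radius_range = c(2, 6)),
                         labeled_fraction = 0.25, seed = 9, out_dir = d)
  expect_identical(nrow(mf), 194L)
  expect_identical(sum(mf$pathology_label == 0L), 112L)
  expect_identical(sum(mf$pathology_label == 1L), 82L)
})

test_that("equal master seeds give byte-identical datasets", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(3, 3, phantom_spec(height = 32, width = 32),
                   labeled_fraction = 0.5, seed = 4, out_dir = d1)
  generate_dataset(3, 3, phantom_spec(height = 32, width = 32),
                   labeled_fraction = 0.5, seed = 4, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
})

test_that("a blinded rule recovers every pathology label from geometry", {
  samples <- make_phantoms(20, size = 48L, seed0 = 300L)
  recovered <- vapply(samples, function(s) {
    as.integer(sum(phantom_inclusion_mask(s)) > 0)
  }, integer(1))
  truth <- vapply(samples, `[[`, integer(1), "pathology_label")
  expect_identical(recovered, truth)
})

test_that("the two domains are separable by construction", {
  samples <- make_phantoms(10, size = 48L, seed0 = 500L)
  margin <- vapply(samples, function(s) {
    he_rgb <- apply(s$he_image, 3, mean)
    oct_rgb <- rep(mean(s$oct_image), 3)
    max(abs(he_rgb - oct_rgb))
  }, numeric(1))
  expect_true(all(margin > 0.05))
})
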
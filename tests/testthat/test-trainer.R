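records_from <- function(phantoms, domains = NULL) {
  lapply(seq_along(phantoms), function(i) {
    s <- phantoms[[i]]
    dom <- if (is.null(domains)) c("oct", "he")[1 + i %% 2] else domains[i]
    list(image = if (dom == "oct") s$oct_image else s$he_image,
         mask = s$layer_mask, pathology_label = s$pathology_label,
         domain = dom, id = i)
  })
}

test_that("the learning-rate ramp starts at lr0 and decays linearly to zero", {
  cfg <- train_config(lr0 = 1e-4, decay_every = 2L, epochs = 100L)
  expect_equal(lr_at(0, cfg), 1e-4)
  expect_equal(lr_at(1, cfg), 1e-4)             # same 2-epoch block
  n_blocks <- 50
  expect_equal(lr_at(98, cfg), 1e-4 / n_blocks) # last nonzero block
  expect_equal(lr_at(100, cfg), 0)
  mid <- lr_at(50, cfg)
  expect_lt(abs(mid - 5e-5), 1e-4 / n_blocks + 1e-12)
  # piecewise constant within a block, non-increasing across blocks
  lrs <- vapply(0:99, lr_at, numeric(1), config = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_true(all(lrs[seq(1, 99, 2)] == lrs[seq(2, 100, 2)]))
})

test_that("a training step honors the loss-breakdown identity and gating", {
  ph <- make_phantoms(4, size = 32L, seed0 = 600L)
  recs <- records_from(ph)
  m <- tiny_models(size = 32L, seed = 3)
  cfg <- train_config(image_size = 32L, seed = 3, epochs = 4L)
  st <- trainer_state_new(m, cfg)
  b_o <- Filter(function(r) r$domain == "oct", recs)[1]
  b_h <- Filter(function(r) r$domain == "he", recs)[1]
  bd <- train_step(b_o, b_h, m, st, 1e-4)
  w <- cfg$weights
  expect_equal(bd$total,
               bd$adv_H + bd$adv_O + w$alpha * bd$cycle +
                 w$beta * bd$embedding + w$gamma * bd$sc + w$iota * bd$pa,
               tolerance = 1e-9)
  expect_true(all(unlist(bd[c("adv_H", "adv_O", "cycle", "embedding", "sc", "pa")]) >= 0))

  # gamma = iota = 0 with unlabeled data reduces to the cycle + embedding GAN
  m2 <- tiny_models(size = 32L, seed = 4)
  cfg2 <- train_config(image_size = 32L, seed = 4, epochs = 4L,
                       weights = loss_weights(gamma = 0, iota = 0))
  st2 <- trainer_state_new(m2, cfg2)
  strip <- function(r) { r$mask <- NULL; r$pathology_label <- 0L; r }
  bd2 <- train_step(lapply(b_o, strip), lapply(b_h, strip), m2, st2, 1e-4,
                    scpa_on = FALSE)
  expect_identical(bd2$sc, 0)
  expect_identical(bd2$pa, 0)
  expect_gt(bd2$cycle, 0)
})

test_that("fixed seeds make training runs bit-identical", {
  ph <- make_phantoms(6, size = 32L, seed0 = 700L)
  recs <- records_from(ph)
  run <- function() {
    cfg <- train_config(image_size = 32L, seed = 9, epochs = 2L, batch_size = 2L)
    m <- models_new(tiny_gen_config(size = 32L), disc_base_width = 4L, seed = 9)
    fit(recs, cfg, out_dir = withr::local_tempdir(), models = m, steps = 4)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$losses, r2$losses)
  p1 <- param_values(r1$models$g_oh)
  p2 <- param_values(r2$models$g_oh)
  expect_identical(p1, p2)
})

test_that("epoch accounting: 6 samples at batch 2 give 3 steps per epoch", {
  ph <- make_phantoms(12, size = 32L, seed0 = 800L)
  recs <- records_from(ph)  # 6 per domain
  cfg <- train_config(image_size = 32L, seed = 1, epochs = 1L, batch_size = 2L)
  m <- models_new(tiny_gen_config(size = 32L), disc_base_width = 4L, seed = 1)
  res <- fit(recs, cfg, out_dir = withr::local_tempdir(), models = m)
  expect_identical(nrow(res$losses), 3L)
  expect_identical(res$losses$step, 1:3)
  expect_error(fit(Filter(function(r) r$domain == "oct", recs), cfg,
                   out_dir = withr::local_tempdir()), "non-empty")
})

test_that("resuming from a checkpoint matches the uninterrupted run", {
  ph <- make_phantoms(6, size = 32L, seed0 = 900L)
  recs <- records_from(ph)
  mkcfg <- function() train_config(image_size = 32L, seed = 5, epochs = 4L,
                                   checkpoint_every = 3L)
  d1 <- withr::local_tempdir()
  m1 <- models_new(tiny_gen_config(size = 32L), disc_base_width = 4L, seed = 5)
  full <- fit(recs, mkcfg(), out_dir = d1, models = m1, steps = 6)
  d2 <- withr::local_tempdir()
  m2 <- models_new(tiny_gen_config(size = 32L), disc_base_width = 4L, seed = 5)
  fit(recs, mkcfg(), out_dir = d2, models = m2, steps = 3)
  d3 <- withr::local_tempdir()
  resumed <- fit(recs, mkcfg(), out_dir = d3,
                 resume_from = file.path(d2, "ckpt_step3.bin"), steps = 3)
  pf <- param_values(full$models$g_oh)
  pr <- param_values(resumed$models$g_oh)
  expect_equal(pf, pr, tolerance = 1e-12)
  pfd <- param_values(full$models$d_h)
  prd <- param_values(resumed$models$d_h)
  expect_equal(pfd, prd, tolerance = 1e-12)
})

test_that("without flips, same-seed runs write identical loss traces", {
  ph <- make_phantoms(4, size = 32L, seed0 = 950L)
  recs <- records_from(ph)
  run <- function(dir) {
    cfg <- train_config(image_size = 32L, seed = 2, epochs = 2L,
                        flip_augment = FALSE)
    m <- models_new(tiny_gen_config(size = 32L), disc_base_width = 4L, seed = 2)
    fit(recs, cfg, out_dir = dir, models = m, steps = 4)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run(d1); run(d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "loss.csv"))),
                   unname(tools::md5sum(file.path(d2, "loss.csv"))))
})

test_that("a short smoke run reduces the generator-side objective", {
  ph <- make_phantoms(40, size = 32L, seed0 = 1100L)
  recs <- records_from(ph)
  cfg <- train_config(image_size = 32L, seed = 7, epochs = 10L)
  m <- models_new(generator_config(image_size = 32L), seed = 7)
  res <- fit(recs, cfg, out_dir = withr::local_tempdir(), models = m, steps = 200)
  qm <- quintile_medians(res$losses$total)
  expect_lt(qm["last"], qm["first"])
})

test_that("checkpoints round-trip the full model state", {
  m <- tiny_models(size = 32L, seed = 8)
  d <- withr::local_tempdir()
  p <- file.path(d, "ckpt_step0.bin")
  save_checkpoint(m, p, step = 0L)
  back <- load_checkpoint(p)
  expect_identical(param_values(back$models$g_oh), param_values(m$g_oh))
  expect_identical(param_values(back$models$d_o), param_values(m$d_o))
  img <- array(runif(32 * 32), c(32, 32, 1))
  expect_identical(translate(img, back$models$g_oh), translate(img, m$g_oh))
})
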
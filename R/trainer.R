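# Alternating minmax training of the two generators (each with its
# structure/pathology head) against the two patch discriminators on unpaired
# two-domain data.

#' Training configuration
#'
#' @param batch_size Images drawn from each domain per step (published run: 9;
#'   desk-scale default 1).
#' @param lr0 Initial learning rate (1e-4).
#' @param decay_every Epoch block length of the piecewise-constant linear
#'   learning-rate decay (2).
#' @param epochs Training horizon in epochs; the linear ramp reaches 0 here
#'   (published run: 10000; desk-scale runs use far fewer).
#' @param weights Loss term weights, see [loss_weights()].
#' @param flip_augment Random left-right flips with probability 0.5.
#' @param seed Master seed: parameter init, data order, augmentation.
#' @param checkpoint_every Steps between checkpoints (0 = only final).
#' @param image_size Training patch side in pixels.
#' @param fake_pool_size Size of the discriminator fake-image history pool;
#'   0 (default) disables it, which keeps runs step-for-step deterministic
#'   in their data order.
#' @return A `train_config`.
#' @export
train_config <- function(batch_size = 1L, lr0 = 1e-4, decay_every = 2L,
                         epochs = 100L, weights = loss_weights(),
                         flip_augment = TRUE, seed = 1L,
                         checkpoint_every = 0L, image_size = 64L,
                         fake_pool_size = 0L) {
  stopifnot(lr0 > 0, batch_size >= 1, decay_every >= 1, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs), weights = weights,
                 flip_augment = isTRUE(flip_augment), seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 image_size = as.integer(image_size),
                 fake_pool_size = as.integer(fake_pool_size)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Piecewise constant over `decay_every`-epoch blocks, decreasing linearly
#' from `lr0` at epoch 0 to 0 at the configured horizon; never negative.
#' @param epoch Zero-based epoch index.
#' @param config A [train_config()].
#' @return Learning rate.
#' @export
lr_at <- function(epoch, config) {
  stopifnot(epoch >= 0)
  n_blocks <- ceiling(config$epochs / config$decay_every)
  block <- epoch %/% config$decay_every
  config$lr0 * max(0, 1 - block / n_blocks)
}

flip_lr <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]

# per-token class pixel counts for the weighted segmentation cross-entropy:
# token t (row-major over the token grid) covers a block x block pixel block;
# background pixels (class 3) are excluded from supervision.
sc_token_weights <- function(mask, block) {
  H <- nrow(mask); W <- ncol(mask)
  nph <- H %/% block; npw <- W %/% block
  i <- (seq_len(H) - 1L) %/% block
  j <- (seq_len(W) - 1L) %/% block
  tok <- outer(i * npw, j, `+`) + 1L  # H x W token ids (row-major tokens)
  wts <- matrix(0, nph * npw, SCPA_K)
  for (k in seq_len(SCPA_K)) {
    sel <- mask == (k - 1L)
    if (any(sel)) {
      tb <- tabulate(tok[sel], nbins = nph * npw)
      wts[, k] <- tb
    }
  }
  wts
}

# one generator-side direction: returns the scalar loss nodes and the
# detached fake image for the discriminator update
gen_direction <- function(rec_in, g_fwd, g_bwd, d_fwd, scpa_on = TRUE) {
  f <- generator_forward(rec_in$image, g_fwd, scpa_on = scpa_on)
  dsc <- discriminator_forward(f$output, d_fwd)
  adv <- op_mean_shift_sq(dsc, 1)
  r <- generator_forward(f$output, g_bwd, scpa_on = scpa_on)
  cyc <- op_mean_abs_diff(r$output, as_image(rec_in$image))
  emb <- op_mean_abs_diff(generator_embed(r$output, g_fwd), f$embedding)
  sc <- NULL
  if (scpa_on && !is.null(rec_in$mask)) {
    block <- g_fwd$config$scpa_patch * 2L^g_fwd$config$n_scales
    wts <- sc_token_weights(rec_in$mask, block)
    tot <- sum(wts)
    if (tot > 0) sc <- op_ce_weighted(f$scpa$seg_logits, wts, tot)
  }
  pa <- if (scpa_on) op_bce_logit(f$scpa$cls_logit, rec_in$pathology_label)
  list(adv = adv, cycle = cyc, emb = emb, sc = sc, pa = pa,
       fake = f$output$value)
}

mean_nodes <- function(nodes) {
  nodes <- Filter(Negate(is.null), nodes)
  if (!length(nodes)) return(nd_const(0))
  op_wsum(nodes, rep(1 / length(nodes), length(nodes)))
}

#' One alternating optimization step
#'
#' Generator side: both translation directions are run through their cycles;
#' the weighted five-term objective is back-propagated and both generators
#' (with their heads) receive one Adam update. Discriminator side: each
#' discriminator is updated on its least-squares term with the fakes
#' detached. The returned breakdown satisfies the exact identity
#' `total = adv_H + adv_O + alpha*cycle + beta*embedding + gamma*sc +
#' iota*pa`.
#'
#' @param batch_o,batch_h Lists of records (`image`, optional `mask`,
#'   `pathology_label`), already augmented.
#' @param models From [models_new()].
#' @param state Trainer state from [trainer_state_new()].
#' @param lr Learning rate for this step.
#' @param scpa_on Ablation switch: `FALSE` trains the plain
#'   cycle-consistent transformer GAN without the structure/pathology head.
#' @return The `loss_breakdown` for the step.
#' @export
train_step <- function(batch_o, batch_h, models, state, lr, scpa_on = TRUE) {
  wts <- state$config$weights
  ad_begin()
  dir_o <- lapply(batch_o, gen_direction, g_fwd = models$g_oh,
                  g_bwd = models$g_ho, d_fwd = models$d_h, scpa_on = scpa_on)
  dir_h <- lapply(batch_h, gen_direction, g_fwd = models$g_ho,
                  g_bwd = models$g_oh, d_fwd = models$d_o, scpa_on = scpa_on)
  adv_h <- mean_nodes(lapply(dir_o, `[[`, "adv"))
  adv_o <- mean_nodes(lapply(dir_h, `[[`, "adv"))
  cyc <- op_add(mean_nodes(lapply(dir_o, `[[`, "cycle")),
                mean_nodes(lapply(dir_h, `[[`, "cycle")))
  emb <- op_add(mean_nodes(lapply(dir_o, `[[`, "emb")),
                mean_nodes(lapply(dir_h, `[[`, "emb")))
  sc <- op_add(mean_nodes(lapply(dir_o, `[[`, "sc")),
               mean_nodes(lapply(dir_h, `[[`, "sc")))
  pa <- op_add(mean_nodes(lapply(dir_o, `[[`, "pa")),
               mean_nodes(lapply(dir_h, `[[`, "pa")))
  comp <- list(adv_H = adv_h$value, adv_O = adv_o$value, cycle = cyc$value,
               embedding = emb$value, sc = sc$value, pa = pa$value)
  for (nm in names(comp)) {
    if (!is.finite(comp[[nm]])) stop("non-finite loss in term: ", nm)
  }
  total <- op_wsum(list(adv_h, adv_o, cyc, emb, sc, pa),
                   c(1, 1, wts$alpha, wts$beta, wts$gamma, wts$iota))
  zero_grads(state$gen_params)
  ad_backward(total)
  ad_end()
  state$opt_g <- adam_step(state$opt_g, lr)
  bd <- total_loss(comp, wts)
  if (abs(bd$total - total$value) > 1e-9) {
    stop("loss breakdown identity violated")
  }

  fakes_h <- lapply(dir_o, `[[`, "fake")
  fakes_o <- lapply(dir_h, `[[`, "fake")
  if (state$config$fake_pool_size > 0L) {
    fakes_h <- pool_swap(state, "h", fakes_h)
    fakes_o <- pool_swap(state, "o", fakes_o)
  }
  d_update <- function(d, reals, fakes, opt_name) {
    ad_begin()
    lr_r <- mean_nodes(lapply(reals, function(r) {
      op_mean_shift_sq(discriminator_forward(r$image, d), 1)
    }))
    lr_f <- mean_nodes(lapply(fakes, function(f) {
      op_mean_shift_sq(discriminator_forward(f, d), 0)
    }))
    dl <- op_add(lr_r, lr_f)
    zero_grads(state[[opt_name]]$params)
    ad_backward(dl)
    ad_end()
    state[[opt_name]] <- adam_step(state[[opt_name]], lr)
    dl$value
  }
  bd$d_H <- d_update(models$d_h, batch_h, fakes_h, "opt_dh")
  bd$d_O <- d_update(models$d_o, batch_o, fakes_o, "opt_do")
  bd
}

# history pool for discriminator fakes (optional; randomized swaps)
pool_swap <- function(state, key, fakes) {
  pool <- state$pools[[key]]
  out <- fakes
  for (i in seq_along(fakes)) {
    if (length(pool) < state$config$fake_pool_size) {
      pool[[length(pool) + 1L]] <- fakes[[i]]
    } else if (stats::runif(1) > 0.5) {
      j <- sample.int(length(pool), 1L)
      out[[i]] <- pool[[j]]
      pool[[j]] <- fakes[[i]]
    }
  }
  state$pools[[key]] <- pool
  out
}

#' Create mutable trainer state (optimizers, pools, counters)
#' @param models From [models_new()].
#' @param config A [train_config()].
#' @return An environment holding optimizer state.
#' @export
trainer_state_new <- function(models, config) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$gen_params <- collect_params(list(g_oh = models$g_oh, g_ho = models$g_ho))
  st$opt_g <- adam_new(st$gen_params)
  st$opt_dh <- adam_new(collect_params(models$d_h))
  st$opt_do <- adam_new(collect_params(models$d_o))
  st$pools <- list(h = list(), o = list())
  st$step <- 0L
  st
}

opt_state <- function(o) list(m = o$m, v = o$v, t = o$t)
opt_restore <- function(o, s) { o$m <- s$m; o$v <- s$v; o$t <- s$t; o }

#' Train on an unpaired two-domain dataset
#'
#' Epochs are defined over the larger domain; each epoch reshuffles both
#' domains (the smaller one recycles). Samples with masks contribute the
#' structural-constraint loss; every sample contributes the image-level
#' pathology loss. Left-right flip augmentation (probability 0.5) is applied
#' to images and masks together. A per-term loss trace is written as
#' `loss.csv` and checkpoints as `ckpt_step{N}.bin`.
#'
#' @param data Manifest path (see [generate_dataset()]) or a list of records
#'   with `image`, `domain`, `pathology_label`, optional `mask`.
#' @param config A [train_config()].
#' @param out_dir Output directory for checkpoints and the loss trace.
#' @param models Optional pre-built models (fresh ones by default).
#' @param resume_from Optional checkpoint path to continue from.
#' @param steps Optional hard cap on total optimization steps.
#' @param scpa_on Ablation switch passed to [train_step()].
#' @return List with `models`, `losses` (data frame), `checkpoint` (final
#'   path).
#' @export
fit <- function(data, config = train_config(), out_dir = tempfile("octstain_run"),
                models = NULL, resume_from = NULL, steps = NULL, scpa_on = TRUE) {
  records <- if (is.character(data)) load_dataset(data) else data
  recs_o <- Filter(function(r) r$domain == "oct", records)
  recs_h <- Filter(function(r) r$domain == "he", records)
  if (!length(recs_o) || !length(recs_h)) stop("both domains must be non-empty")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  start_step <- 0L
  if (!is.null(resume_from)) {
    ck <- load_checkpoint(resume_from)
    models <- ck$models
    start_step <- ck$step
  } else if (is.null(models)) {
    models <- models_new(generator_config(image_size = config$image_size),
                         seed = config$seed)
  }
  state <- trainer_state_new(models, config)
  set.seed(config$seed)
  if (!is.null(resume_from)) {
    # optimizer moments come from the checkpoint; the RNG stream is
    # reproduced by replaying the data order from the master seed below
    state$opt_g <- opt_restore(state$opt_g, ck$extra$opt_g)
    state$opt_dh <- opt_restore(state$opt_dh, ck$extra$opt_dh)
    state$opt_do <- opt_restore(state$opt_do, ck$extra$opt_do)
  }
  n_big <- max(length(recs_o), length(recs_h))
  steps_per_epoch <- ceiling(n_big / config$batch_size)
  rows <- list()
  step <- 0L
  done <- FALSE
  for (epoch in seq_len(config$epochs) - 1L) {
    if (done) break
    lr <- lr_at(epoch, config)
    perm_o <- sample(rep_len(seq_along(recs_o), steps_per_epoch * config$batch_size))
    perm_h <- sample(rep_len(seq_along(recs_h), steps_per_epoch * config$batch_size))
    for (s in seq_len(steps_per_epoch)) {
      idx <- (s - 1L) * config$batch_size + seq_len(config$batch_size)
      batch_o <- lapply(recs_o[perm_o[idx]], augment_record, config = config)
      batch_h <- lapply(recs_h[perm_h[idx]], augment_record, config = config)
      step <- step + 1L
      if (step <= start_step) next  # replay data order when resuming
      bd <- train_step(batch_o, batch_h, models, state, lr, scpa_on = scpa_on)
      rows[[length(rows) + 1L]] <- data.frame(
        step = step, adv_H = bd$adv_H, adv_O = bd$adv_O, cycle = bd$cycle,
        embedding = bd$embedding, sc = bd$sc, pa = bd$pa, total = bd$total
      )
      if (config$checkpoint_every > 0L && step %% config$checkpoint_every == 0L) {
        save_fit_checkpoint(models, state, step, out_dir)
      }
      if (!is.null(steps) && step - start_step >= steps) { done <- TRUE; break }
    }
  }
  losses <- do.call(rbind, rows)
  utils::write.csv(losses, file.path(out_dir, "loss.csv"), row.names = FALSE)
  final <- save_fit_checkpoint(models, state, step, out_dir)
  list(models = models, losses = losses, checkpoint = final)
}

augment_record <- function(r, config) {
  if (config$flip_augment && stats::runif(1) < 0.5) {
    r$image <- flip_lr(as_image(r$image))
    if (!is.null(r$mask)) r$mask <- r$mask[, rev(seq_len(ncol(r$mask)))]
  }
  r
}

save_fit_checkpoint <- function(models, state, step, out_dir) {
  path <- file.path(out_dir, sprintf("ckpt_step%d.bin", step))
  save_checkpoint(models, path, step = step, extra = list(
    opt_g = opt_state(state$opt_g), opt_dh = opt_state(state$opt_dh),
    opt_do = opt_state(state$opt_do),
    rng = get(".Random.seed", envir = globalenv())
  ))
  path
}
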
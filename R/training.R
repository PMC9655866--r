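#' Training configuration
#'
#' The full-scale protocol: 500 epochs of Adam (beta1 = 0.5, beta2 = 0.999)
#' at learning rate 0.002 held constant for the first 200 epochs then
#' decayed linearly to zero at epoch 500; batch size 4; random 96^3 crops
#' with random transverse rotations as augmentation; every epoch
#' checkpointed. Desk-scale runs shrink `width_mult`, `crop_size` and
#' `epochs` but keep the protocol.
#'
#' @param scheme Dataset scheme `"A"`, `"B"` or `"C"`.
#' @param epochs Total epochs.
#' @param lr0 Initial learning rate.
#' @param decay_start Epoch after which the linear decay begins.
#' @param beta1,beta2 Adam momentum parameters.
#' @param batch_size Samples per batch.
#' @param crop_size Augmentation crop edge (voxels).
#' @param width_mult Network width multiplier.
#' @param weights A [loss_weights()].
#' @param avd_reduction,l1_reduction `"mean"` or `"sum"`.
#' @param augment Apply random crop/rotation augmentation (default TRUE);
#'   when FALSE a deterministic centre crop with no rotation is used.
#' @param seed Master seed driving split, initialization and augmentation
#'   streams independently.
#' @param checkpoint_dir Directory for per-epoch checkpoints and the loss
#'   log; NULL disables checkpointing.
#' @return A `train_config` list.
#' @export
train_config <- function(scheme = c("A", "B", "C"), epochs = 500L,
                         lr0 = 0.002, decay_start = 200L, beta1 = 0.5,
                         beta2 = 0.999, batch_size = 4L, crop_size = 96L,
                         width_mult = 1, weights = loss_weights(),
                         avd_reduction = "mean", l1_reduction = "mean",
                         augment = TRUE, seed = 1L, checkpoint_dir = NULL) {
  scheme <- match.arg(scheme)
  if (decay_start >= epochs && epochs > 0)
    stop("decay_start must be < epochs")
  if (batch_size < 1) stop("batch size must be >= 1")
  structure(list(scheme = scheme, epochs = as.integer(epochs), lr0 = lr0,
                 decay_start = as.integer(decay_start), beta1 = beta1,
                 beta2 = beta2, batch_size = as.integer(batch_size),
                 crop_size = as.integer(crop_size), width_mult = width_mult,
                 weights = weights, avd_reduction = avd_reduction,
                 l1_reduction = l1_reduction, augment = isTRUE(augment),
                 seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Constant `lr0` through `decay_start`, then linear to zero at the final
#' epoch: 0.002 at epoch 100, 0.001 at epoch 350, 0 at epoch 500 under the
#' default protocol.
#'
#' @param epoch Epoch number (0..epochs).
#' @param config A [train_config()].
#' @return Learning rate.
#' @export
learning_rate_at <- function(epoch, config = train_config()) {
  if (epoch < 0 || epoch > config$epochs) stop("epoch out of range")
  if (epoch <= config$decay_start) return(config$lr0)
  config$lr0 * (config$epochs - epoch) / (config$epochs - config$decay_start)
}

#' Split cases into a test set and seven cross-validation folds
#'
#' Randomly holds out `n_test` cases, then cycles the remainder into
#' `n_folds` folds with a 6:1 train:validation ratio (98 remaining cases
#' give 14 validation cases per fold under the defaults).
#'
#' @param case_ids Character or integer vector of case identifiers.
#' @param n_test Number of held-out test cases (default 20).
#' @param n_folds Number of cross-validation folds (default 7).
#' @param seed Seed for the shuffle.
#' @return A `split_plan`: list with `test` and `folds` (each fold has
#'   `train` and `validation`).
#' @export
make_split <- function(case_ids, n_test = 20L, n_folds = 7L, seed = 1L) {
  if (length(case_ids) <= n_test + n_folds)
    stop("not enough cases for the requested split")
  shuffled <- with_seed(seed, sample(case_ids))
  test <- shuffled[seq_len(n_test)]
  rest <- shuffled[-seq_len(n_test)]
  fold_of <- rep_len(seq_len(n_folds), length(rest))
  folds <- lapply(seq_len(n_folds), function(f)
    list(train = rest[fold_of != f], validation = rest[fold_of == f]))
  structure(list(test = test, folds = folds, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d test cases, %d folds (validation sizes: %s)\n",
              length(x$test), length(x$folds),
              paste(vapply(x$folds, function(f) length(f$validation),
                           numeric(1)), collapse = ", ")))
  invisible(x)
}

#' @method tidy split_plan
#' @export
tidy.split_plan <- function(x, ...) {
  rows <- list(tibble::tibble(case_id = as.character(x$test), role = "test",
                              fold = NA_integer_))
  for (f in seq_along(x$folds)) {
    rows <- c(rows, list(
      tibble::tibble(case_id = as.character(x$folds[[f]]$train),
                     role = "train", fold = f),
      tibble::tibble(case_id = as.character(x$folds[[f]]$validation),
                     role = "validation", fold = f)
    ))
  }
  dplyr::bind_rows(rows)
}

# deterministic centre crop of a (x,y,z,C) stack
center_crop_stack <- function(stack, crop) {
  d <- dim(stack)
  lo <- pmax(1L, (d[1:3] - crop) %/% 2L + 1L)
  stack[lo[1]:(lo[1] + crop - 1L), lo[2]:(lo[2] + crop - 1L),
        lo[3]:(lo[3] + crop - 1L), , drop = FALSE]
}

# rotate the in-plane (row, column) axes of a (x,y,z,C) stack by kx90 degrees
rotate_transverse <- function(stack, k) {
  k <- k %% 4
  if (k == 0) return(stack)
  for (i in seq_len(k)) {
    stack <- aperm(stack, c(1, 3, 2, 4))
    stack <- stack[, , rev(seq_len(dim(stack)[3])), , drop = FALSE]
  }
  stack
}

#' Augment a training sample
#'
#' Applies one random crop of `crop^3` voxels and one random in-plane
#' rotation (90, 180 or 270 degrees in the transverse plane) identically to
#' every channel. Masks stay binary because rotation only permutes voxels.
#'
#' @param stack A `channel_stack` or 4D array (x, y, z, channels).
#' @param crop Crop edge in voxels (default 96).
#' @param seed Seed; identical seeds give identical crop offset and angle.
#' @return Cropped and rotated stack of the same type.
#' @export
augment_sample <- function(stack, crop = 96L, seed = 1L) {
  d <- dim(stack)
  if (any(d[1:3] < crop)) stop("input smaller than the crop size")
  att <- attributes(stack)
  out <- with_seed(seed, {
    lo <- vapply(d[1:3], function(n)
      if (n == crop) 1L else sample.int(n - crop + 1L, 1L), integer(1))
    k <- sample(1:3, 1L)
    cropped <- unclass(stack)[lo[1]:(lo[1] + crop - 1L),
                              lo[2]:(lo[2] + crop - 1L),
                              lo[3]:(lo[3] + crop - 1L), , drop = FALSE]
    rotate_transverse(cropped, k)
  })
  if (!is.null(att$class)) {
    attributes(out) <- c(attributes(out),
                         att[setdiff(names(att), c("dim", "dimnames"))])
  }
  out
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(as.array(p)))),
       v = lapply(params, function(p) array(0, dim(as.array(p)))),
       t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(params)) {
    g <- grads[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    upd <- lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
    if (is.null(dim(params[[key]]))) upd <- as.numeric(upd)
    params[[key]] <- params[[key]] - upd
  }
  list(state = state, params = params)
}

# ---- adversarial training --------------------------------------------------

#' Train the conditional adversarial model
#'
#' Alternates one discriminator update and one generator update per batch:
#' the discriminator sees the conditioning stack with the clinical dose
#' (label 1) and with the generated dose, detached (label 0), minimizing the
#' averaged BCE; the generator then minimizes the weighted sum of its
#' adversarial, adjacent-voxel-difference and L1 terms with gradients
#' flowing through the discriminator. Both networks are Kaiming-initialized;
#' every epoch is checkpointed when a checkpoint directory is set, and the
#' per-epoch loss means are returned as a tibble (one row per epoch).
#'
#' @param samples List of training samples, each a `channel_stack` (or 4D
#'   array) whose first channel is the normalized clinical dose.
#' @param config A [train_config()].
#' @param generator,discriminator Optional pre-built networks (for resuming
#'   or for width plans other than the config's).
#' @return An `fd_fit`: list with `generator`, `discriminator`, `loss_log`
#'   (tibble), `config`.
#' @export
train_adversarial <- function(samples, config = train_config(),
                              generator = NULL, discriminator = NULL) {
  if (!length(samples)) stop("need at least one training sample")
  nch <- dim(samples[[1]])[4]
  exp_ch <- fd_config()$discriminator$in_channels[[config$scheme]]
  if (nch != exp_ch)
    stop(sprintf("scheme %s expects %d channels (dose first), got %d",
                 config$scheme, exp_ch, nch))
  if (is.null(generator))
    generator <- build_generator(
      generator_spec(config$scheme, config$width_mult), seed = config$seed + 1L)
  if (is.null(discriminator))
    discriminator <- build_discriminator(
      discriminator_spec(config$scheme, config$width_mult),
      seed = config$seed + 2L)
  ckdir <- config$checkpoint_dir
  if (!is.null(ckdir)) dir.create(ckdir, recursive = TRUE, showWarnings = FALSE)
  save_ckpt <- function(epoch) {
    if (is.null(ckdir)) return(invisible())
    saveRDS(list(generator = network_state(generator),
                 discriminator = network_state(discriminator),
                 epoch = epoch, config = config),
            file.path(ckdir, sprintf("epoch_%04d.rds", epoch)))
  }
  save_ckpt(0L)

  opt_g <- adam_new(net_params(generator))
  opt_d <- adam_new(net_params(discriminator))
  w <- config$weights
  log_rows <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lr <- learning_rate_at(epoch, config)
    order_seed <- config$seed + 1000L * epoch
    idx <- with_seed(order_seed, sample(length(samples)))
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    ep <- c(L_D_GT = 0, L_D_Pre = 0, L_D = 0, L_G_cGAN = 0, L_G_AVD = 0,
            L_G_L1 = 0, L_G = 0)
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      stacks <- lapply(seq_along(b), function(j) {
        if (config$augment)
          unclass(augment_sample(samples[[b[j]]], crop = config$crop_size,
                                 seed = order_seed + 17L * b[j]))
        else
          center_crop_stack(unclass(samples[[b[j]]]), config$crop_size)
      })
      d <- dim(stacks[[1]])
      batch <- array(unlist(stacks, use.names = FALSE), c(d, length(b)))
      cond <- batch[, , , -1, , drop = FALSE]            # stack without dose
      gt_dose <- batch[, , , 1, , drop = FALSE]

      # --- discriminator update ------------------------------------------
      fake_dose <- generator_forward(generator, cond, tape = NULL,
                                     training = TRUE)   # detached
      tape <- new_tape()
      wd <- wrap_network(tape, discriminator)
      logit_real <- discriminator_forward(discriminator,
                                          ag_leaf(tape, batch), tape,
                                          training = TRUE, wrapped = wd)
      fake_stack <- abind_channel(fake_dose, cond)
      logit_fake <- discriminator_forward(discriminator,
                                          ag_leaf(tape, fake_stack), tape,
                                          training = TRUE, wrapped = wd)
      l_gt <- op_bce_logits(tape, logit_real, 1)
      l_pre <- op_bce_logits(tape, logit_fake, 0)
      l_d <- op_weighted_sum(tape, list(l_gt, l_pre), c(0.5, 0.5))
      check_finite(ag_val(l_d), epoch, bi, "discriminator")
      grads <- ag_backward(l_d)
      gd <- wrapped_grads(wd, grads, discriminator)
      pd <- net_params(discriminator)
      stepd <- adam_step(opt_d, pd, gd, lr, config$beta1, config$beta2)
      opt_d <- stepd$state
      set_net_params(discriminator, stepd$params)

      # --- generator update ----------------------------------------------
      tape <- new_tape()
      wg <- wrap_network(tape, generator)
      pred <- generator_forward(generator, cond, tape, training = TRUE,
                                wrapped = wg)
      fake_stack_n <- op_concat(tape, c(list(pred), split_channels(cond)))
      logit_fake <- discriminator_forward(discriminator, fake_stack_n, tape,
                                          training = TRUE)
      l_cgan <- op_bce_logits(tape, logit_fake, 1)
      l_avd <- op_avd(tape, pred, gt_dose, config$avd_reduction)
      l_l1 <- op_l1(tape, pred, gt_dose, config$l1_reduction)
      l_g <- op_weighted_sum(tape, list(l_cgan, l_avd, l_l1),
                             c(w$cgan, w$avd, w$l1))
      check_finite(ag_val(l_g), epoch, bi, "generator")
      grads <- ag_backward(l_g)
      gg <- wrapped_grads(wg, grads, generator)
      pg <- net_params(generator)
      stepg <- adam_step(opt_g, pg, gg, lr, config$beta1, config$beta2)
      opt_g <- stepg$state
      set_net_params(generator, stepg$params)

      ep <- ep + c(ag_val(l_gt), ag_val(l_pre), ag_val(l_d), ag_val(l_cgan),
                   ag_val(l_avd), ag_val(l_l1), ag_val(l_g))
    }
    ep <- unname(ep / length(batches))
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, L_D_GT = ep[1], L_D_Pre = ep[2], L_D = ep[3],
      L_G_cGAN = ep[4], L_G_AVD = ep[5], L_G_L1 = ep[6], L_G = ep[7])
    save_ckpt(epoch)
  }
  loss_log <- dplyr::bind_rows(log_rows)
  if (!is.null(ckdir))
    utils::write.csv(loss_log, file.path(ckdir, "loss_log.csv"),
                     row.names = FALSE)
  structure(list(generator = generator, discriminator = discriminator,
                 loss_log = loss_log, config = config),
            class = "fd_fit")
}

check_finite <- function(x, epoch, batch, which) {
  if (!is.finite(x))
    stop(sprintf("non-finite %s loss at epoch %d, batch %d", which, epoch, batch))
}

# concatenate (x,y,z,1,N) dose with (x,y,z,C,N) conditioning channels
abind_channel <- function(dose, cond) {
  d <- dim(cond)
  out <- array(0, c(d[1:3], d[4] + 1L, d[5]))
  out[, , , 1, ] <- dose
  out[, , , -1, ] <- cond
  out
}

split_channels <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[4]), function(c) {
    v <- x[, , , c, , drop = FALSE]
    dim(v) <- c(d[1:3], 1L, d[5])
    v
  })
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("<fd_fit> scheme %s, %d epochs\n", x$config$scheme,
              nrow(x$loss_log)))
  if (nrow(x$loss_log)) {
    last <- x$loss_log[nrow(x$loss_log), ]
    cat(sprintf("  final losses: L_D %.4f | L_G %.4f (cGAN %.4f, AVD %.4g, L1 %.4f)\n",
                last$L_D, last$L_G, last$L_G_cGAN, last$L_G_AVD, last$L_G_L1))
  }
  invisible(x)
}

#' @method tidy fd_fit
#' @export
tidy.fd_fit <- function(x, ...) {
  tidyr::pivot_longer(x$loss_log, cols = -c("epoch", "lr"),
                      names_to = "term", values_to = "loss")
}

#' @method glance fd_fit
#' @export
glance.fd_fit <- function(x, ...) {
  last <- x$loss_log[nrow(x$loss_log), ]
  tibble::tibble(epochs = nrow(x$loss_log), scheme = x$config$scheme,
                 L_D = last$L_D, L_G = last$L_G, L_G_L1 = last$L_G_L1)
}

#' Predict a dose distribution
#'
#' Runs the generator on a conditioning stack (no dose channel), maps the
#' tanh output back to cGy through the inverse dose normalization
#' (\[0, 1.2 x prescription\]) and clips at zero.
#'
#' @param generator A trained (or freshly initialized) generator.
#' @param stack Conditioning `channel_stack` / 4D array without the dose
#'   channel.
#' @param prescription Prescription in cGy (defaults to the stack's
#'   attribute).
#' @param spacing Voxel spacing (defaults to the stack's attribute).
#' @return A [dose_distribution].
#' @export
predict_dose <- function(generator, stack, prescription = NULL,
                         spacing = NULL) {
  if (is.null(prescription)) prescription <- attr(stack, "prescription")
  if (is.null(spacing)) spacing <- attr(stack, "spacing")
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (is.null(prescription)) stop("prescription required")
  x <- unclass(stack)
  y <- generator_forward(generator, x, tape = NULL, training = FALSE)
  dose <- denormalize_affine(y[, , , 1, 1], dose_range(prescription))
  dose <- pmax(dose, 0)
  dim(dose) <- dim(x)[1:3]
  dose_distribution(volume_grid(dose, spacing = spacing), prescription)
}

#' Save / load a network checkpoint
#'
#' @param fit_or_net An `fd_fit` or `fd_network`.
#' @param file Path to an `.rds` checkpoint.
#' @export
save_checkpoint <- function(fit_or_net, file) {
  obj <- if (inherits(fit_or_net, "fd_fit"))
    list(generator = network_state(fit_or_net$generator),
         discriminator = network_state(fit_or_net$discriminator),
         config = fit_or_net$config)
  else list(generator = network_state(fit_or_net))
  saveRDS(obj, file)
  invisible(file)
}

#' @rdname save_checkpoint
#' @param net Network whose architecture matches the checkpoint.
#' @export
load_checkpoint <- function(net, file) {
  st <- readRDS(file)
  key <- if (net$kind == "generator") "generator" else "discriminator"
  restore_network_state(net, st[[key]])
  net
}
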
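test_that("the learning-rate schedule has the plateau and linear decay", {
  cfg <- train_config()
  expect_equal(learning_rate_at(0, cfg), 0.002)
  expect_equal(learning_rate_at(100, cfg), 0.002)
  expect_equal(learning_rate_at(200, cfg), 0.002)
  expect_equal(learning_rate_at(350, cfg), 0.001)
  expect_equal(learning_rate_at(500, cfg), 0)
  expect_error(learning_rate_at(501, cfg), "range")
  lrs <- vapply(200:500, learning_rate_at, numeric(1), config = cfg)
  expect_true(all(diff(lrs) < 0))      # strictly decreasing past the plateau
})

test_that("case splitting yields a disjoint test set and balanced folds", {
  ids <- sprintf("case%03d", 1:118)
  sp <- make_split(ids, n_test = 20, n_folds = 7, seed = 4)
  expect_length(sp$test, 20)
  rest <- setdiff(ids, sp$test)
  expect_length(rest, 98)
  for (f in sp$folds) {
    expect_length(f$validation, 14)                  # 98 / 7
    expect_length(f$train, 84)                       # 6:1 ratio
    expect_length(intersect(f$validation, sp$test), 0)
    expect_setequal(c(f$train, f$validation), rest)
  }
  # validation sets partition the train-validation pool
  vals <- unlist(lapply(sp$folds, `[[`, "validation"))
  expect_setequal(vals, rest)
  expect_equal(anyDuplicated(vals), 0L)
  expect_identical(make_split(ids, seed = 4), sp)    # deterministic
  expect_false(identical(make_split(ids, seed = 5)$test, sp$test))
  long <- tidy(sp)
  expect_equal(sum(long$role == "test"), 20)
})

test_that("augmentation crops to the requested cube and rotates in-plane only", {
  set.seed(21)
  big <- array(rnorm(100 * 100 * 100 * 2), c(100, 100, 100, 2))
  out <- augment_sample(big, crop = 96, seed = 8)
  expect_equal(dim(out), c(96L, 96L, 96L, 2L))
  expect_identical(augment_sample(big, crop = 96, seed = 8), out)
  expect_false(identical(augment_sample(big, crop = 96, seed = 9), out))
  # rotation acts within transverse planes: a volume whose value equals its
  # slice index stays constant per slice
  ramp <- array(rep(1:32, times = 32 * 32), c(32, 32, 32, 1))
  aug <- augment_sample(ramp, crop = 32, seed = 3)
  for (s in c(1, 16, 32))
    expect_equal(length(unique(as.numeric(aug[s, , , 1]))), 1L)
  # masks stay binary
  m <- array(rbinom(32^3, 1, 0.3), c(32, 32, 32, 1))
  expect_true(all(augment_sample(m, crop = 32, seed = 2) %in% c(0, 1)))
  # 180-degree rotation applied twice is the identity
  r2 <- fusedose:::rotate_transverse(fusedose:::rotate_transverse(ramp, 2), 2)
  expect_identical(r2, ramp)
  expect_error(augment_sample(m, crop = 64), "smaller")
})

test_that("a discriminator step reduces its loss on the same batch", {
  set.seed(22)
  cs <- tiny_case()
  stk <- assemble_channel_stack(cs$ct, cs$structures, cs$dose, scheme = "B")
  cfg <- train_config("B", epochs = 1, decay_start = 0, batch_size = 1,
                      crop_size = 32, width_mult = 1 / 16, augment = FALSE,
                      seed = 31)
  gen <- build_generator(generator_spec("B", 1 / 16), seed = 32)
  disc <- build_discriminator(discriminator_spec("B", 1 / 16), seed = 33)
  batch <- array(unclass(stk), c(dim(stk), 1L))
  cond <- batch[, , , -1, , drop = FALSE]
  fake <- generator_forward(gen, cond, training = TRUE)
  ld_of <- function(d) {
    lr <- discriminator_forward(d, batch, training = FALSE)
    lf <- discriminator_forward(d, fusedose:::abind_channel(fake, cond),
                                training = FALSE)
    discriminator_loss(lr, lf)$L_D
  }
  before <- ld_of(disc)
  g_before <- fusedose:::net_params(gen)
  fit <- train_adversarial(list(stk), cfg, generator = gen,
                           discriminator = disc)
  expect_lt(ld_of(fit$discriminator), before)
  # the discriminator step never touches generator weights within the same
  # batch until the generator's own update runs; across the full epoch the
  # generator changed, but a zero-lr run leaves both untouched
  cfg0 <- cfg; cfg0$lr0 <- 0; cfg0$decay_start <- 1; cfg0$epochs <- 1L
  gen0 <- build_generator(generator_spec("B", 1 / 16), seed = 32)
  disc0 <- build_discriminator(discriminator_spec("B", 1 / 16), seed = 33)
  p_g <- fusedose:::net_params(gen0); p_d <- fusedose:::net_params(disc0)
  fit0 <- train_adversarial(list(stk), cfg0, generator = gen0,
                            discriminator = disc0)
  expect_equal(fusedose:::net_params(fit0$generator), p_g, tolerance = 1e-12)
  expect_equal(fusedose:::net_params(fit0$discriminator), p_d, tolerance = 1e-12)
})

test_that("pure L1+AVD regression overfits a single fixed batch monotonically", {
  cs <- tiny_case(seed = 19)
  stk <- assemble_channel_stack(cs$ct, cs$structures, cs$dose, scheme = "B")
  cfg <- train_config("B", epochs = 10, decay_start = 9, batch_size = 1,
                      crop_size = 32, width_mult = 1 / 16,
                      weights = loss_weights(cgan = 0, avd = 10, l1 = 100),
                      augment = FALSE, seed = 41)
  fit <- train_adversarial(list(stk), cfg)
  l1 <- fit$loss_log$L_G_L1
  expect_length(l1, 10)
  expect_true(all(diff(l1) < 0))
  # with no adversarial weight the cGAN term never enters the total
  expect_equal(fit$loss_log$L_G,
               10 * fit$loss_log$L_G_AVD + 100 * fit$loss_log$L_G_L1,
               tolerance = 1e-10)
})

test_that("training logs one row per epoch and checkpoints every epoch", {
  cs <- tiny_case()
  stk <- assemble_channel_stack(cs$ct, cs$structures, cs$dose, scheme = "C")
  ckdir <- tempfile()
  cfg <- train_config("C", epochs = 2, decay_start = 1, batch_size = 1,
                      crop_size = 32, width_mult = 1 / 16, seed = 51,
                      checkpoint_dir = ckdir)
  fit <- train_adversarial(list(stk), cfg)
  expect_equal(nrow(fit$loss_log), 2L)
  expect_named(fit$loss_log, c("epoch", "lr", "L_D_GT", "L_D_Pre", "L_D",
                               "L_G_cGAN", "L_G_AVD", "L_G_L1", "L_G"))
  expect_true(all(is.finite(as.matrix(fit$loss_log))))
  expect_equal(fit$loss_log$L_D, (fit$loss_log$L_D_GT + fit$loss_log$L_D_Pre) / 2,
               tolerance = 1e-12)
  expect_true(all(file.exists(file.path(ckdir, sprintf("epoch_%04d.rds", 0:2)))))
  expect_true(file.exists(file.path(ckdir, "loss_log.csv")))
  # checkpoint 0 is the initialization
  ck0 <- readRDS(file.path(ckdir, "epoch_0000.rds"))
  init <- build_generator(generator_spec("C", 1 / 16), seed = cfg$seed + 1L)
  expect_equal(ck0$generator$stem_1$W, init$layers$stem_1$W, tolerance = 1e-12)
  # a reloaded checkpoint reproduces the trained network's predictions
  gen2 <- build_generator(generator_spec("C", 1 / 16))
  gen2 <- load_checkpoint(gen2, file.path(ckdir, "epoch_0002.rds"))
  inf <- assemble_channel_stack(cs$ct, cs$structures, dose = NULL,
                                scheme = "C", prescription = 5400)
  expect_equal(predict_dose(gen2, inf)$grid$values,
               predict_dose(fit$generator, inf)$grid$values, tolerance = 1e-12)
})

test_that("dose prediction denormalizes onto [0, 1.2 Rx] deterministically", {
  cs <- tiny_case()
  gen <- build_generator(generator_spec("B", 1 / 16), seed = 61)
  inf <- assemble_channel_stack(cs$ct, cs$structures, dose = NULL,
                                scheme = "B", prescription = 5400)
  p1 <- predict_dose(gen, inf)
  p2 <- predict_dose(gen, inf)
  expect_identical(p1$grid$values, p2$grid$values)
  expect_equal(dim(p1$grid$values), dim(cs$ct$values))
  expect_true(all(p1$grid$values >= 0 & p1$grid$values <= 1.2 * 5400))
  expect_equal(p1$prescription, 5400)
  expect_equal(p1$grid$spacing, cs$ct$spacing)
})
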
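test_that("rigid draws respect the rotation and shift ranges", {
  cfg <- training_config(seed = 3)
  draws <- fissureseg:::with_seed(99, {
    lapply(1:1000, function(i) random_rigid_params(cfg))
  })
  ang <- do.call(rbind, lapply(draws, `[[`, "angles"))
  sh <- do.call(rbind, lapply(draws, `[[`, "shift"))
  expect_true(all(ang >= -10 & ang <= 10))
  expect_true(all(sh >= -10 & sh <= 10))
  # shifts touch a nonempty axis subset; untouched axes are exactly zero
  for (d in draws[1:50]) {
    expect_gte(length(d$axes), 1)
    expect_true(all(d$shift[-d$axes] == 0) || length(d$axes) == 3)
  }
  expect_identical(random_rigid_params(cfg, seed = 7),
                   random_rigid_params(cfg, seed = 7))
  zero <- training_config(rotation_range = c(0, 0), shift_range = c(0, 0))
  z <- random_rigid_params(zero, seed = 1)
  expect_identical(z$angles, rep(0, 3))
  expect_identical(z$shift, rep(0, 3))
})

test_that("augmentation emits the configured number of invariant-preserving pairs", {
  s <- make_training_samples(1, grid = 16, seed0 = 40L)[[1]]
  cfg <- training_config(augment_per_image = 40)
  aug <- augment_image(s$volume, s$labels, cfg, seed = 5)
  expect_length(aug, 40)
  for (pair in aug[c(1, 13, 40)]) {
    expect_triplet_invariants(pair$labels)
    expect_identical(dim(pair$volume), dim(s$volume$data))
  }
  # identity transform reproduces the input exactly
  id_cfg <- training_config(augment_per_image = 2,
                            rotation_range = c(0, 0),
                            shift_range = c(0, 0))
  ide <- augment_image(s$volume, s$labels, id_cfg, seed = 5)
  expect_equal(ide[[1]]$volume, s$volume$data, tolerance = 1e-9)
  expect_identical(ide[[1]]$labels$fissures$data, s$labels$fissures$data)
})

test_that("soft Dice loss matches hand-evaluated values", {
  g <- array(0L, dim = c(2, 2, 2))
  g[1:2, 1:2, 1] <- 1L  # half full
  expect_equal(soft_dice_loss(array(as.numeric(g), dim = dim(g)), g), 0)
  expect_equal(soft_dice_loss(array(1 - as.numeric(g), dim = dim(g)), g), 1)
  # uniform 0.5: num = 2*(0.5*4) = 4, den = 8*0.25 + 4 = 6, loss = 1 - 4/6
  expect_equal(soft_dice_loss(array(0.5, dim = c(2, 2, 2)), g), 1 / 3)
  expect_error(soft_dice_loss(array(0.5, dim = c(4, 4, 4)), g), "shapes")
})

test_that("training runs, records history, and is seed-deterministic", {
  samples <- make_training_samples(3, grid = 16, seed0 = 60L)
  cfg <- training_config(epochs = 1, target = "whole",
                         augment_per_image = 0, seed = 11)
  spec <- arch_spec(encoder_filters = c(2, 2, 4, 4, 8),
                    decoder_filters = c(8, 4, 4, 2, 2))
  fit <- train_model(spec, list(train = samples[1:2], val = samples[3]), cfg)
  expect_identical(nrow(fit$history), 1L)
  expect_true(all(is.finite(unlist(fit$history))))
  fit2 <- train_model(spec, list(train = samples[1:2], val = samples[3]), cfg)
  expect_identical(fit$history$train_loss, fit2$history$train_loss)
  expect_identical(fit$model$params$out.w, fit2$model$params$out.w)
  expect_error(train_model(spec, list(train = list(), val = samples[3]), cfg),
               "nonempty")
})

test_that("training loss trends downward on noiseless phantoms", {
  samples <- make_training_samples(4, grid = 16, seed0 = 70L)
  cfg <- training_config(epochs = 8, target = "whole",
                         augment_per_image = 0, seed = 2)
  fit <- train_model(arch_spec(encoder_filters = c(2, 2, 4, 8, 16),
                               decoder_filters = c(16, 8, 4, 2, 2)),
                     list(train = samples[1:3], val = samples[4]), cfg)
  h <- fit$history$train_loss
  expect_lt(median(tail(h, 3)), median(head(h, 3)))
})
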
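# Losses, splitting, metrics, and the training loop.

test_that("mse_loss matches its definition", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, 1)), 1)
  set.seed(41)
  y <- rnorm(50); yh <- rnorm(50)
  expect_equal(mse_loss(y, yh), sum((y - yh)^2) / 50, tolerance = 1e-12)
  expect_error(mse_loss(1:3, 1:2), "length mismatch")
})

test_that("mask similarity loss is negative cosine (and the literal printed
           form is available)", {
  v <- c(0.2, 0.5, 0.3)
  expect_equal(mask_similarity_loss(v, v), -1)
  expect_equal(mask_similarity_loss(c(1, 0), c(0, 1)), 0)
  set.seed(42)
  I <- matrix(runif(5 * 20), 5); O <- matrix(runif(5 * 20), 5)
  direct <- -mean(vapply(1:5, function(i)
    sum(I[i, ] * O[i, ]) / sqrt(sum(I[i, ]^2) * sum(O[i, ]^2)), numeric(1)))
  expect_equal(mask_similarity_loss(I, O), direct, tolerance = 1e-10)
  # the literal absolute-sum normalization does not reach -1 on identity
  expect_gt(mask_similarity_loss(v, v, literal = TRUE), -1)
  expect_warning(mask_similarity_loss(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("total_loss combines components with the default mask weight", {
  b <- total_loss(1, -1)
  expect_equal(b$alpha_mask, 0.05)
  expect_equal(b$total, 0.95)
  expect_equal(total_loss(2, -0.5, alpha_mask = 0)$total, 2)
})

test_that("split_dataset partitions reproducibly with 80/10/10 sizes", {
  ds <- generate_dataset(100, tiny_synth_config(), seed = 43)
  sp <- split_dataset(ds, seed = 7)
  expect_equal(length(sp$train), 80)
  expect_equal(length(sp$val), 10)
  expect_equal(length(sp$test), 10)
  ids <- c(sp$train$sample_id, sp$val$sample_id, sp$test$sample_id)
  expect_setequal(ids, ds$sample_id)
  expect_equal(anyDuplicated(ids), 0L)
  sp2 <- split_dataset(ds, seed = 7)
  expect_identical(sp$train$sample_id, sp2$train$sample_id)
  expect_error(split_dataset(ds[1:5], seed = 1), "at least 10")
})

test_that("compute_metrics matches the closed forms", {
  y <- c(10, 20, 30); expect_warning(compute_metrics(c(5, 5), c(5, 5)), "constant")
  m0 <- compute_metrics(y, y)
  expect_equal(c(m0$r2, m0$rmse, m0$mape), c(1, 0, 0))
  mbar <- compute_metrics(y, rep(mean(y), 3))
  expect_equal(mbar$r2, 0)
  set.seed(44)
  yy <- runif(30, 50, 150); yh <- yy + rnorm(30, sd = 10)
  m <- compute_metrics(yy, yh)
  expect_equal(m$r2, 1 - sum((yy - yh)^2) / sum((yy - mean(yy))^2),
               tolerance = 1e-10)
  expect_equal(m$rmse, sqrt(mean((yy - yh)^2)), tolerance = 1e-10)
  expect_equal(m$mape, 100 * mean(abs((yh - yy) / yy)), tolerance = 1e-10)
  expect_warning(compute_metrics(c(0, 1, 2), c(1, 1, 1)), "zero-valued")
})

test_that("cyclic schedule starts at the peak and decays per cycle", {
  lr <- vapply(1:100, specindexnet:::cyclic_lr, numeric(1),
               base = 1e-4, mx = 1e-3, cycle = 50, mode = "triangular")
  expect_equal(lr[1], 1e-3, tolerance = 1e-9)       # initial rate = peak
  expect_equal(max(lr), 1e-3, tolerance = 1e-9)
  expect_equal(min(lr), 1e-4, tolerance = 5e-5)
  expect_equal(lr[1:50], lr[51:100], tolerance = 1e-12)  # periodic
  lr2 <- vapply(1:100, specindexnet:::cyclic_lr, numeric(1),
                base = 1e-4, mx = 1e-3, cycle = 50, mode = "triangular2")
  # peak amplitude halves every cycle
  expect_equal(max(lr2[51:100]) - 1e-4, (max(lr2[1:50]) - 1e-4) / 2,
               tolerance = 1e-6)
})

test_that("rectified Adam minimizes a quadratic", {
  # the variance rectifier deliberately damps early updates, so convergence
  # takes more steps than plain Adam
  p <- specindexnet:::ad_param(c(5, -3))
  for (t in 1:1200) {
    g <- 2 * (p$val - c(1, 2))
    specindexnet:::radam_step(list(p), list(g), lr = 0.1, t = t)
  }
  expect_equal(p$val, c(1, 2), tolerance = 1e-2)
})

test_that("a small model overfits a tiny training set and returns the best
           checkpoint", {
  set.seed(45)
  ds <- generate_dataset(44, tiny_synth_config(), seed = 45)
  tr <- ds[1:32]; va <- ds[33:44]
  m <- indexfindnet(model_config(n_bands = 32L, profile = "reduced",
                                 gconv_channels = 16L, attn_channels = 8L,
                                 recurrent_hidden = 8L, head_hidden = 16L,
                                 dropout_rate = 0),
                    wavelengths = ds$wavelengths, seed = 45)
  cfg <- train_config(batch_size = 8L, max_epochs = 300L, eval_every = 50L,
                      patience = 300L, lr_mode = "triangular", seed = 45,
                      weight_decay = 0)
  fit <- train_model(m, tr, va, "vcmax", cfg)
  h <- fit$history
  first_mse <- h$mse[1]
  last_mse <- mean(utils::tail(h$mse, 5))
  expect_lt(last_mse, 0.2 * first_mse)    # large reduction on train loss
  # best-checkpoint contract
  expect_equal(fit$best$val_r2, max(h$val_r2, na.rm = TRUE), tolerance = 1e-9)
  expect_true(fit$model$trained)
})

test_that("training stalls stop at the patience boundary", {
  set.seed(46)
  ds <- generate_dataset(24, tiny_synth_config(), seed = 46)
  tr <- ds[1:16]
  va <- ds[17:24]
  va$vcmax <- rep(80, 8)    # constant validation target: R2 is never finite
  m <- indexfindnet(tiny_model_config(), wavelengths = ds$wavelengths,
                    seed = 46)
  cfg <- train_config(batch_size = 8L, max_epochs = 200L, eval_every = 5L,
                      patience = 20L, seed = 46)
  fit <- suppressWarnings(train_model(m, tr, va, "vcmax", cfg))
  expect_equal(max(fit$history$epoch), 20L)
})

test_that("training with the mask loss preserves spectral shape better than
           without", {
  set.seed(47)
  ds <- generate_dataset(40, tiny_synth_config(), seed = 47)
  tr <- ds[1:32]; va <- ds[33:40]
  cos_after <- function(alpha) {
    m <- indexfindnet(tiny_model_config(), wavelengths = ds$wavelengths,
                      seed = 48)
    cfg <- train_config(batch_size = 8L, max_epochs = 20L, eval_every = 10L,
                        patience = 20L, seed = 48, alpha_mask = alpha)
    fit <- train_model(m, tr, va, "vcmax", cfg)
    mk <- mask_forward(fit$model, t(va$reflectance))
    -mask_similarity_loss(va$reflectance, t(mk$output))
  }
  expect_gt(cos_after(0.05), cos_after(0))
})
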
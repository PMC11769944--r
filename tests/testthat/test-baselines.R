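# Baseline regressors and the benchmark harness.

test_that("SVR honors its behavioural contracts", {
  set.seed(71)
  X <- matrix(runif(40 * 5), 40, 5)
  # constant response -> constant predictions (inside the tube)
  m <- svr_fit(X, rep(7, 40))
  expect_equal(predict(m, X), rep(7, 40), tolerance = 0.2)
  # separable toy data: training-point predictions near their labels
  y <- 3 * X[, 1] - 2 * X[, 2]
  m2 <- svr_fit(X, y, C = 10, epsilon = 0.01)
  expect_lt(sqrt(mean((predict(m2, X) - y)^2)), 0.15 * stats::sd(y))
  # unfitted predict is an error
  broken <- m2; broken$fitted <- FALSE
  expect_error(predict(broken, X), "unfitted")
})

test_that("SVR beats a linear fit on quadratic toy data", {
  set.seed(72)
  x <- seq(-1, 1, length.out = 80)
  y <- 2 * x^2 + rnorm(80, sd = 0.05)
  tr <- seq(1, 80, by = 2); te <- seq(2, 80, by = 2)
  X <- matrix(x, ncol = 1)
  pred_svr <- {
    m <- svr_fit(X[tr, , drop = FALSE], y[tr], C = 10, epsilon = 0.05,
                 gamma = 2)
    predict(m, X[te, , drop = FALSE])
  }
  lin <- stats::lm(yy ~ xx, data = data.frame(xx = x[tr], yy = y[tr]))
  pred_lin <- stats::predict(lin, newdata = data.frame(xx = x[te]))
  expect_lt(sqrt(mean((pred_svr - y[te])^2)),
            sqrt(mean((pred_lin - y[te])^2)))
})

test_that("PLS1 recovers a rank-1 latent structure exactly", {
  set.seed(73)
  n <- 30; p <- 10
  u <- rnorm(n)
  X <- outer(u, runif(p)) + 0  # rank-1 design
  y <- 2 * u + 5
  tr <- 1:20; te <- 21:30
  dtr <- spectral_dataset(seq(400, 900, length.out = p),
                          (X[tr, ] - min(X)) / diff(range(X)),
                          vcmax = y[tr], jmax = rep(NA_real_, 20))
  dte <- spectral_dataset(seq(400, 900, length.out = p),
                          (X[te, ] - min(X)) / diff(range(X)),
                          vcmax = y[te], jmax = rep(NA_real_, 10))
  out <- plsr_fit_predict(dtr, dte, "vcmax", component_grid = 1L)
  expect_equal(out$predictions, y[te], tolerance = 1e-6)
})

test_that("PLS1 matches the independent Krylov-subspace oracle and the grid
           stays within 10..15", {
  set.seed(74)
  ds <- generate_dataset(80, tiny_synth_config(), seed = 74)
  sp <- split_dataset(ds, seed = 74)
  X <- sp$train$reflectance; y <- sp$train$vcmax
  for (nc in c(3, 7, 12)) {
    fit <- specindexnet:::pls1_nipals(X, y, nc)
    mine <- specindexnet:::pls1_predict(fit, sp$test$reflectance)
    orc <- oracle_pls1(X, y, nc, sp$test$reflectance)
    expect_equal(mine, orc, tolerance = 1e-6)
  }
  out <- plsr_fit_predict(sp$train, sp$test, "vcmax", component_grid = 10:15)
  expect_true(out$ncomp >= 10 && out$ncomp <= 15)
  expect_error(plsr_fit_predict(ds[1:12], sp$test, "vcmax", 10:15),
               "too small")
})

test_that("PLSR with full components reproduces least squares on full-rank
           toy data", {
  set.seed(75)
  n <- 40; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% runif(p) + rnorm(n, sd = 0.01) + 3
  fit <- specindexnet:::pls1_nipals(X, y, p)
  ols <- stats::lm.fit(cbind(1, X), y)
  pred_pls <- specindexnet:::pls1_predict(fit, X)
  pred_ols <- cbind(1, X) %*% ols$coefficients
  expect_equal(pred_pls, as.vector(pred_ols), tolerance = 1e-6)
})

test_that("the 1-D CNN has the published shape arithmetic", {
  m <- onedcnn(204)
  expect_equal(m$config$pooled, 20)
  expect_equal(m$config$l1, 16)
  expect_equal(m$config$l2, 8)
  expect_equal(m$config$flat, 400)
  expect_error(onedcnn(204, fc1_units = 300), "400")
  expect_error(onedcnn(204, fc1_units = 1200), "400")
  out <- onedcnn_forward(m, runif(204))
  expect_true(is.finite(out))
  expect_error(onedcnn_forward(m, runif(100)), "length")
})

test_that("the vegetation-index CNN equals its stagewise manual composition", {
  set.seed(76)
  m <- indicecnn(n_bands = 40, channels = 8, pool_kernel = 12, seed = 76)
  expect_equal(m$config$pool_out, 3)
  x <- runif(40, 0.1, 0.8)
  got <- indicecnn_forward(m, x)
  # manual composition: conv(k5, pad2) -> sigmoid -> avgpool(12, 12) per role
  conv1 <- function(W, b) {
    xp <- c(0, 0, x, 0, 0)
    sapply(1:40, function(l) as.vector(W[, 1, ] %*% xp[l:(l + 4)]) + b)
  }
  R <- lapply(1:4, function(i) {
    z <- 1 / (1 + exp(-conv1(m$params[[paste0("rW", i)]]$val,
                             m$params[[paste0("rb", i)]]$val)))
    sapply(c(1, 13, 25), function(s) rowMeans(z[, s:(s + 11)]))
  })
  expect_true(all(R[[1]] > 0 & R[[1]] < 1))   # sigmoid features in (0,1)
  core <- (R[[1]] + R[[2]]) / (R[[3]] * R[[4]] + m$config$eps)
  manual <- as.vector(m$params$out_W$val %*% as.vector(core)) +
    m$params$out_b$val
  expect_equal(got, manual, tolerance = 1e-6)
})

test_that("the index-combination core reproduces the worked arithmetic", {
  # (0.5 + 0.25) / (0.8 * 0.4) = 2.34375 before the linear map
  expect_equal((0.5 + 0.25) / (0.8 * 0.4 + 1e-6), 2.34375, tolerance = 1e-4)
})

test_that("run_benchmark produces one row per model x variant and is
           reproducible", {
  ds <- generate_dataset(60, tiny_synth_config(), seed = 77)
  tc <- train_config(batch_size = 16L, max_epochs = 3L, eval_every = 1L,
                     patience = 3L)
  rep1 <- run_benchmark(ds, "vcmax", models = c("svr", "plsr", "indicecnn"),
                        variants = c("SG", "SG-POC"), n_runs = 2L, seed = 9L,
                        train_cfg = tc, component_grid = 10:12)
  expect_equal(nrow(rep1$summary), 6)
  expect_true(all(rep1$summary$n_ok == 2))
  rep2 <- run_benchmark(ds, "vcmax", models = c("svr", "plsr", "indicecnn"),
                        variants = c("SG", "SG-POC"), n_runs = 2L, seed = 9L,
                        train_cfg = tc, component_grid = 10:12)
  expect_equal(rep1$summary, rep2$summary)
  # per-cell failures are recorded, not fatal: a model that cannot run
  ds_small <- ds[1:30]
  rep3 <- run_benchmark(ds_small, "vcmax", models = "plsr",
                        variants = "SG", n_runs = 1L, seed = 9L,
                        train_cfg = tc, component_grid = 30:35)
  expect_equal(rep3$summary$n_ok, 0)
})
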
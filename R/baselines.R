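# Baseline regressors: epsilon-insensitive RBF support vector regression,
# PLS1 partial least squares, and the two CNN baselines (plain 1-D CNN and
# the vegetation-index CNN), plus the benchmark harness.

# ---- support vector regression --------------------------------------------

rbf_kernel <- function(X, Z, gamma) {
  # ||x - z||^2 = |x|^2 + |z|^2 - 2 x.z
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  exp(-gamma * pmax(d2, 0))
}

#' Fit epsilon-insensitive kernel support vector regression
#'
#' RBF-kernel SVR solved in the primal with an L-BFGS quasi-Newton method on
#' the squared epsilon-insensitive loss (residuals inside the epsilon tube
#' carry no loss). Targets are standardized internally.
#'
#' @param X numeric matrix (samples x features).
#' @param y numeric response.
#' @param C box/regularization constant (loss weight).
#' @param epsilon tube half-width on the standardized response scale.
#' @param gamma RBF width; default `1/(p * mean(var(X)))` ("scale").
#' @return an `svr_model` with a `predict` method.
#' @export
svr_fit <- function(X, y, C = 1, epsilon = 0.1, gamma = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1L) stop("empty training set")
  if (is.null(gamma)) {
    v <- mean(apply(X, 2L, stats::var))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  }
  yc <- mean(y)
  ys <- stats::sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
  yy <- (y - yc) / ys
  K <- rbf_kernel(X, X, gamma)
  lambda <- 1 / C
  obj <- function(theta) {
    a <- theta[1:n]; b <- theta[n + 1L]
    r <- yy - as.vector(K %*% a) - b
    s <- pmax(0, abs(r) - epsilon)
    0.5 * lambda * sum(a * (K %*% a)) + sum(s^2)
  }
  grad <- function(theta) {
    a <- theta[1:n]; b <- theta[n + 1L]
    Ka <- as.vector(K %*% a)
    r <- yy - Ka - b
    u <- 2 * pmax(0, abs(r) - epsilon) * sign(r)
    c(lambda * Ka - as.vector(K %*% u), -sum(u))
  }
  fit <- stats::optim(rep(0, n + 1L), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 500))
  structure(list(X = X, alpha = fit$par[1:n], b = fit$par[n + 1L],
                 gamma = gamma, epsilon = epsilon, C = C,
                 y_center = yc, y_scale = ys, fitted = TRUE),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  if (!isTRUE(object$fitted)) stop("predict on unfitted SVR model")
  K <- rbf_kernel(as.matrix(newdata), object$X, object$gamma)
  (as.vector(K %*% object$alpha) + object$b) * object$y_scale + object$y_center
}

#' Fit SVR on a train set and predict a test set
#'
#' @param train,test labeled [spectral_dataset()]s (or matrices with `y`
#'   supplied through `trait`).
#' @param trait `"vcmax"` or `"jmax"`.
#' @param C,epsilon,gamma kernel configuration, see [svr_fit()].
#' @return numeric predictions for `test`.
#' @export
svr_fit_predict <- function(train, test, trait = c("vcmax", "jmax"),
                            C = 1, epsilon = 0.1, gamma = NULL) {
  trait <- match.arg(trait)
  m <- svr_fit(reflectance_matrix(train), train[[trait]], C, epsilon, gamma)
  predict(m, reflectance_matrix(test))
}

# ---- partial least squares ------------------------------------------------

# PLS1 via NIPALS with deflation; returns regression vector and intercept
pls1_nipals <- function(X, y, ncomp) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  mx <- attr(Xc, "scaled:center")
  yc <- mean(y)
  u <- y - yc
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  Xd <- Xc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, u)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    tt <- Xd %*% w
    tsq <- sum(tt^2)
    pp <- crossprod(Xd, tt) / tsq
    qq <- sum(u * tt) / tsq
    Xd <- Xd - tcrossprod(tt, pp)
    u <- u - qq * tt
    W[, a] <- w; P[, a] <- pp; q[a] <- qq
  }
  if (ncomp < 1L) stop("PLS: degenerate response")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P, W), q)
  list(coef = as.vector(B), x_center = mx, y_center = yc, ncomp = ncomp)
}

pls1_predict <- function(fit, X) {
  as.vector(sweep(as.matrix(X), 2L, fit$x_center) %*% fit$coef) + fit$y_center
}

#' PLSR fit/predict with component grid search
#'
#' Selects the number of latent components by validation R^2 over
#' `component_grid` (an internal seeded 80/20 split of the training set),
#' refits on the full training set, and predicts the test set.
#'
#' @param train,test labeled [spectral_dataset()]s.
#' @param trait `"vcmax"` or `"jmax"`.
#' @param component_grid candidate component counts (default 10:15).
#' @param seed seed for the internal selection split.
#' @return list with `predictions` and `ncomp` (chosen component count).
#' @export
plsr_fit_predict <- function(train, test, trait = c("vcmax", "jmax"),
                             component_grid = 10:15, seed = 1L) {
  trait <- match.arg(trait)
  X <- reflectance_matrix(train)
  y <- train[[trait]]
  n <- nrow(X)
  if (n < max(component_grid) + 2L)
    stop("training set too small for component grid up to ",
         max(component_grid))
  if (length(component_grid) > 1L) {
    set.seed(seed)
    idx <- sample.int(n)
    nv <- max(2L, floor(0.2 * n))
    vi <- idx[seq_len(nv)]; ti <- idx[-seq_len(nv)]
    r2s <- vapply(component_grid, function(a) {
      f <- pls1_nipals(X[ti, , drop = FALSE], y[ti], a)
      pv <- pls1_predict(f, X[vi, , drop = FALSE])
      1 - sum((y[vi] - pv)^2) / sum((y[vi] - mean(y[vi]))^2)
    }, numeric(1))
    ncomp <- component_grid[which.max(r2s)]
  } else ncomp <- component_grid
  fit <- pls1_nipals(X, y, ncomp)
  list(predictions = pls1_predict(fit, reflectance_matrix(test)),
       ncomp = fit$ncomp)
}

# ---- 1-D CNN baseline ------------------------------------------------------

#' One-dimensional CNN baseline
#'
#' Average pooling (kernel 10, stride 10, padding 2), two convolutions
#' (1->50 k5 d1, then 50->50 k5 d2, no padding), and two fully connected
#' layers. For a 204-band input the flattened width is 50 x 8 = 400.
#'
#' @param n_bands input band count (default 204).
#' @param fc1_units width of the first fully connected layer, in
#'   `[400, 1000]`.
#' @param channels convolution channels (default 50).
#' @param seed weight-initialization seed.
#' @return an `onedcnn` model usable with [train_model()].
#' @export
onedcnn <- function(n_bands = 204L, fc1_units = 400L, channels = 50L,
                    seed = NULL) {
  if (fc1_units < 400L || fc1_units > 1000L)
    stop("fc1_units must be within [400, 1000]")
  if (!is.null(seed)) set.seed(seed)
  Lp <- (n_bands + 4L - 10L) %/% 10L + 1L
  L1 <- Lp - 4L            # conv k5 d1, no padding
  L2 <- L1 - 8L            # conv k5 d2, no padding
  if (L2 < 1L) stop("n_bands too small for the fixed architecture")
  flat <- channels * L2
  p <- list(
    conv1_W = ad_param(.init_u(c(channels, 1L, 5L), 5L), "conv1_W"),
    conv1_b = ad_param(rep(0, channels), "conv1_b"),
    conv2_W = ad_param(.init_u(c(channels, channels, 5L), channels * 5L), "conv2_W"),
    conv2_b = ad_param(rep(0, channels), "conv2_b"),
    fc1_W = ad_param(.init_u(c(fc1_units, flat), flat), "fc1_W"),
    fc1_b = ad_param(rep(0, fc1_units), "fc1_b"),
    fc2_W = ad_param(.init_u(c(1L, fc1_units), fc1_units), "fc2_W"),
    fc2_b = ad_param(rep(0, 1L), "fc2_b"))
  structure(list(config = list(n_bands = as.integer(n_bands),
                               fc1_units = as.integer(fc1_units),
                               channels = as.integer(channels),
                               flat = flat, pooled = Lp, l1 = L1, l2 = L2),
                 params = p, bn = list(), y_center = 0, y_scale = 1,
                 trained = FALSE),
            class = "onedcnn")
}

onedcnn_graph <- function(ctx, m, refl) {
  B <- ncol(refl)
  x3 <- ad_const(ctx, array(refl, c(1L, nrow(refl), B)))
  h <- op_avgpool(ctx, x3, 10L, 10L, 2L)
  h <- op_relu(ctx, op_conv1d(ctx, h, ad_leaf(ctx, m$params$conv1_W),
                              ad_leaf(ctx, m$params$conv1_b), 1L, 0L))
  h <- op_relu(ctx, op_conv1d(ctx, h, ad_leaf(ctx, m$params$conv2_W),
                              ad_leaf(ctx, m$params$conv2_b), 2L, 0L))
  h <- op_flatten(ctx, h)
  h <- op_relu(ctx, op_linear(ctx, h, ad_leaf(ctx, m$params$fc1_W),
                              ad_leaf(ctx, m$params$fc1_b)))
  op_linear(ctx, h, ad_leaf(ctx, m$params$fc2_W), ad_leaf(ctx, m$params$fc2_b))
}

#' Forward pass of the 1-D CNN baseline
#' @param model an [onedcnn()] model.
#' @param reflectance vector of length `n_bands` or bands x B matrix.
#' @return numeric predictions (standardized scale until trained).
#' @export
onedcnn_forward <- function(model, reflectance) {
  refl <- as.matrix(reflectance)
  if (nrow(refl) != model$config$n_bands) refl <- t(refl)
  if (nrow(refl) != model$config$n_bands)
    stop("input length does not match n_bands")
  ctx <- ad_ctx(training = FALSE)
  as.vector(onedcnn_graph(ctx, model, refl)$val) * model$y_scale + model$y_center
}

#' @export
forward_std.onedcnn <- function(model, refl) {
  ctx <- ad_ctx(training = FALSE)
  as.vector(onedcnn_graph(ctx, model, refl)$val)
}

#' @export
build_loss_graph.onedcnn <- function(model, ctx, refl, ystd, alpha_mask) {
  pred <- onedcnn_graph(ctx, model, refl)
  mse <- op_mse(ctx, pred, ystd)
  list(loss = mse, pred = pred, mse = mse$val, mask_loss = NULL)
}

# ---- vegetation-index CNN baseline ----------------------------------------

#' Vegetation-index CNN baseline
#'
#' Reconstruction of the index-computing CNN: four parallel convolutional
#' feature extractors with sigmoid activations and average pooling produce
#' per-region role features R1..R4, combined elementwise as
#' `(R1+R2)/(R3*R4)` (epsilon guarded) and mapped by a linear layer. The
#' exact conv/pooling stack of the original is defined in prior work; this
#' parallel-extractor form keeps the published equations (a fully global
#' band average would collapse the features to near-constants, so pooling
#' keeps `pool_out` spectral regions per channel).
#'
#' @param n_bands input band count.
#' @param channels feature channels per role extractor (default 16).
#' @param pool_kernel average-pooling kernel and stride (default 12).
#' @param eps denominator guard.
#' @param seed weight-initialization seed.
#' @return an `indicecnn` model usable with [train_model()].
#' @export
indicecnn <- function(n_bands = 204L, channels = 16L, pool_kernel = 12L,
                      eps = 1e-6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Lp <- (n_bands - pool_kernel) %/% pool_kernel + 1L
  if (Lp < 1L) stop("n_bands too small for the pooling kernel")
  flat <- channels * Lp
  p <- list()
  for (i in 1:4) {
    p[[paste0("rW", i)]] <- ad_param(.init_u(c(channels, 1L, 5L), 5L), paste0("rW", i))
    p[[paste0("rb", i)]] <- ad_param(rep(0, channels), paste0("rb", i))
  }
  p$out_W <- ad_param(.init_u(c(1L, flat), flat), "out_W")
  p$out_b <- ad_param(rep(0, 1L), "out_b")
  structure(list(config = list(n_bands = as.integer(n_bands),
                               channels = as.integer(channels),
                               pool_kernel = as.integer(pool_kernel),
                               pool_out = Lp, eps = eps),
                 params = p, bn = list(), y_center = 0, y_scale = 1,
                 trained = FALSE),
            class = "indicecnn")
}

indicecnn_graph <- function(ctx, m, refl) {
  B <- ncol(refl)
  k <- m$config$pool_kernel
  x3 <- ad_const(ctx, array(refl, c(1L, nrow(refl), B)))
  R <- lapply(1:4, function(i) {
    h <- op_conv1d(ctx, x3, ad_leaf(ctx, m$params[[paste0("rW", i)]]),
                   ad_leaf(ctx, m$params[[paste0("rb", i)]]), 1L, 2L)
    op_avgpool(ctx, op_sigmoid(ctx, h), k, k, 0L)
  })
  core <- op_div_guard(ctx, op_add(ctx, R[[1]], R[[2]]),
                       op_mul(ctx, R[[3]], R[[4]]), m$config$eps)
  list(pred = op_linear(ctx, op_flatten(ctx, core),
                        ad_leaf(ctx, m$params$out_W),
                        ad_leaf(ctx, m$params$out_b)),
       roles = R, core = core)
}

#' Forward pass of the vegetation-index CNN
#' @param model an [indicecnn()] model.
#' @param reflectance vector or bands x B matrix.
#' @return numeric predictions.
#' @export
indicecnn_forward <- function(model, reflectance) {
  refl <- as.matrix(reflectance)
  if (nrow(refl) != model$config$n_bands) refl <- t(refl)
  ctx <- ad_ctx(training = FALSE)
  as.vector(indicecnn_graph(ctx, model, refl)$pred$val) * model$y_scale +
    model$y_center
}

#' @export
forward_std.indicecnn <- function(model, refl) {
  ctx <- ad_ctx(training = FALSE)
  as.vector(indicecnn_graph(ctx, model, refl)$pred$val)
}

#' @export
build_loss_graph.indicecnn <- function(model, ctx, refl, ystd, alpha_mask) {
  pred <- indicecnn_graph(ctx, model, refl)$pred
  mse <- op_mse(ctx, pred, ystd)
  list(loss = mse, pred = pred, mse = mse$val, mask_loss = NULL)
}

# ---- benchmark harness -----------------------------------------------------

#' Benchmark all models on one dataset
#'
#' For each run (seed + run index) the dataset is split 80/10/10 once, the
#' requested preprocessing variants are applied, and every model is trained
#' on identical splits and evaluated on the held-out test set. Results are
#' aggregated as mean +/- sd across runs. Per-cell failures are recorded and
#' the run continues.
#'
#' @param dataset a labeled [spectral_dataset()].
#' @param trait `"vcmax"` or `"jmax"`.
#' @param models subset of `c("svr", "plsr", "onedcnn", "indicecnn",
#'   "indexfindnet")`.
#' @param variants preprocessing variants: `"SG"` and/or `"SG-POC"`.
#' @param poc_beta compression exponent of the SG-POC variant.
#' @param n_runs number of repeated runs.
#' @param seed base seed; run r uses `seed + r - 1`.
#' @param train_cfg a [train_config()] for the deep models (scaled-down
#'   epochs recommended on CPU).
#' @param model_cfg a [model_config()] for the band-selecting network.
#' @param component_grid PLSR component grid.
#' @return a `benchmark_report`: list with `cells` (per-run results) and
#'   `summary` (data.frame model x variant with mean/sd metrics and
#'   parameter counts).
#' @export
run_benchmark <- function(dataset, trait = c("vcmax", "jmax"),
                          models = c("svr", "plsr", "onedcnn", "indicecnn",
                                     "indexfindnet"),
                          variants = c("SG", "SG-POC"), poc_beta = 0.6,
                          n_runs = 3L, seed = 1L,
                          train_cfg = train_config(max_epochs = 60L,
                                                   eval_every = 10L,
                                                   patience = 60L,
                                                   batch_size = 32L),
                          model_cfg = model_config(profile = "reduced"),
                          component_grid = 10:15) {
  trait <- match.arg(trait)
  models <- match.arg(models, several.ok = TRUE)
  variants <- match.arg(variants, c("SG", "SG-POC"), several.ok = TRUE)
  cells <- list()
  param_counts <- list()
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r - 1L
    sp <- split_dataset(dataset, seed = run_seed)
    for (v in variants) {
      beta <- if (v == "SG-POC") poc_beta else 1
      pc <- preprocess_config(poc_beta = beta)
      tr <- preprocess_dataset(sp$train, pc)
      va <- preprocess_dataset(sp$val, pc)
      te <- preprocess_dataset(sp$test, pc)
      nb <- length(tr$wavelengths)
      for (mod in models) {
        key <- paste(mod, v, r, sep = "|")
        res <- tryCatch({
          pred <- switch(mod,
            svr = svr_fit_predict(tr, te, trait),
            plsr = plsr_fit_predict(tr, te, trait, component_grid,
                                    seed = run_seed)$predictions,
            onedcnn = {
              m <- onedcnn(nb, seed = run_seed)
              cfgr <- train_cfg; cfgr$seed <- run_seed
              fit <- train_model(m, tr, va, trait, cfgr)
              param_counts[[mod]] <- count_parameters(fit$model)
              evaluate_model(fit$model, te, trait)$predictions
            },
            indicecnn = {
              m <- indicecnn(nb, seed = run_seed)
              cfgr <- train_cfg; cfgr$seed <- run_seed
              fit <- train_model(m, tr, va, trait, cfgr)
              param_counts[[mod]] <- count_parameters(fit$model)
              evaluate_model(fit$model, te, trait)$predictions
            },
            indexfindnet = {
              cfgm <- model_cfg
              if (cfgm$n_bands != nb) cfgm$n_bands <- nb
              m <- indexfindnet(cfgm, wavelengths = tr$wavelengths,
                                seed = run_seed)
              cfgr <- train_cfg; cfgr$seed <- run_seed
              fit <- train_model(m, tr, va, trait, cfgr)
              param_counts[[mod]] <- count_parameters(fit$model)
              evaluate_model(fit$model, te, trait)$predictions
            })
          mets <- compute_metrics(te[[trait]], pred)
          list(ok = TRUE, r2 = mets$r2, rmse = mets$rmse, mape = mets$mape)
        }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
        cells[[key]] <- c(list(model = mod, variant = v, run = r), res)
      }
    }
  }
  summary <- do.call(rbind, lapply(models, function(mod) {
    do.call(rbind, lapply(variants, function(v) {
      ok <- Filter(function(cl) cl$model == mod && cl$variant == v &&
                     isTRUE(cl$ok), cells)
      if (length(ok) == 0L) {
        data.frame(model = mod, variant = v, n_ok = 0L,
                   r2_mean = NA, r2_sd = NA, rmse_mean = NA, rmse_sd = NA,
                   mape_mean = NA, mape_sd = NA, params = NA)
      } else {
        g <- function(f) vapply(ok, `[[`, numeric(1), f)
        data.frame(model = mod, variant = v, n_ok = length(ok),
                   r2_mean = mean(g("r2")), r2_sd = stats::sd(g("r2")),
                   rmse_mean = mean(g("rmse")), rmse_sd = stats::sd(g("rmse")),
                   mape_mean = mean(g("mape")), mape_sd = stats::sd(g("mape")),
                   params = if (is.null(param_counts[[mod]])) NA_real_
                            else param_counts[[mod]])
      }
    }))
  }))
  structure(list(cells = cells, summary = summary, trait = trait,
                 n_runs = n_runs, seed = seed),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark (", x$trait, ", ", x$n_runs, " runs)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
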
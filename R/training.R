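# Losses, dataset splitting, the training loop (rectified Adam + cyclic
# triangular learning rate, early stopping on validation R^2), and metrics.

#' Training configuration
#'
#' Defaults follow the reference protocol: batch size 8, initial learning
#' rate 1e-3 with a cyclic triangular schedule, rectified Adam with L2 weight
#' decay 1e-3, up to 1000 epochs with validation every 50 epochs and
#' patience 500 epochs, 80/10/10 split, results averaged over 3 runs.
#' Cyclic bounds (base 1e-4, max = `lr`, 50-epoch cycle) are package choices.
#'
#' @param batch_size mini-batch size.
#' @param lr maximum (initial) learning rate.
#' @param lr_base lower bound of the cyclic schedule.
#' @param lr_cycle cycle length in epochs (triangular).
#' @param lr_mode `"triangular2"` (peak halves every cycle; the decaying
#'   cyclic strategy) or `"triangular"` (constant amplitude).
#' @param weight_decay L2 penalty added to gradients.
#' @param max_epochs training epoch cap.
#' @param eval_every validation cadence in epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param split train/validation/test fractions (sum to 1).
#' @param seed integer RNG seed.
#' @param n_runs number of repeated runs for mean +/- sd reporting.
#' @param alpha_mask weight of the mask-similarity loss.
#' @param tau_end final Gumbel-softmax temperature of the annealing schedule
#'   (training uses the soft relaxation with the temperature decaying
#'   geometrically from the model's `gumbel_temperature` to `tau_end`, so
#'   the soft alignment converges to the hard one-hot used at evaluation).
#' @param clip_grad global gradient-norm clip (numerical guard for the
#'   epsilon-guarded index divisions); `Inf` disables.
#' @param time_budget wall-clock training cap in seconds; training stops at
#'   the end of the first epoch that exceeds it (with a final validation),
#'   returning the best state so far. `Inf` disables. Lets a fixed protocol
#'   degrade gracefully on slower hardware instead of overrunning.
#' @param fp32 run the convolution matrix products in single precision
#'   during training (about twice the throughput; the ~1e-7 relative error
#'   is far below the gradient noise floor). Evaluation always uses double
#'   precision.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 8L, lr = 1e-3, lr_base = 1e-4,
                         lr_cycle = 50L, lr_mode = "triangular2",
                         weight_decay = 1e-3,
                         max_epochs = 1000L, eval_every = 50L,
                         patience = 500L, split = c(0.8, 0.1, 0.1),
                         seed = 1L, n_runs = 3L, alpha_mask = 0.05,
                         clip_grad = 5, tau_end = 0.05, time_budget = Inf,
                         fp32 = FALSE) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (patience > max_epochs) stop("patience must be <= max_epochs")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 lr_base = lr_base, lr_cycle = as.integer(lr_cycle),
                 lr_mode = lr_mode,
                 weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience), split = split,
                 seed = as.integer(seed), n_runs = as.integer(n_runs),
                 alpha_mask = alpha_mask, clip_grad = clip_grad,
                 tau_end = tau_end, time_budget = time_budget, fp32 = fp32),
            class = "train_config")
}

#' Mean squared error
#' @param y,yhat numeric vectors of equal length.
#' @return scalar mean squared difference.
#' @export
mse_loss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch in mse_loss")
  if (length(y) < 1L) stop("empty vectors in mse_loss")
  mean((y - yhat)^2)
}

#' Mask-similarity loss
#'
#' Negative mean cosine similarity between each input spectrum (row) and its
#' masked output; in `[-1, 1]`, lower = more similar. The literal printed
#' normalization (sums of absolute values instead of L2 norms) is available
#' via `literal = TRUE` for comparison; it does not reach -1 for identical
#' vectors.
#'
#' @param input,output numeric matrices (samples x bands) or vectors.
#' @param literal use the absolute-sum normalization.
#' @return scalar loss.
#' @export
mask_similarity_loss <- function(input, output, literal = FALSE) {
  I <- if (is.null(dim(input))) matrix(input, nrow = 1L) else as.matrix(input)
  O <- if (is.null(dim(output))) matrix(output, nrow = 1L) else as.matrix(output)
  if (!all(dim(I) == dim(O))) stop("input/output shape mismatch")
  per <- vapply(seq_len(nrow(I)), function(i) {
    a <- I[i, ]; b <- O[i, ]
    if (literal) {
      den <- sum(abs(a)) * sum(abs(b))
      if (den == 0) { warning("zero-norm vector contributes 0"); return(0) }
      sum(a * b) / den
    } else {
      den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
      if (den == 0) { warning("zero-norm vector contributes 0"); return(0) }
      sum(a * b) / den
    }
  }, numeric(1))
  -mean(per)
}

#' Total training loss bundle
#'
#' @param mse regression mean squared error.
#' @param mask_loss mask-similarity loss.
#' @param alpha_mask weight of the mask term (default 0.05).
#' @return a `loss_bundle` list with `mse`, `mask_loss`, `alpha_mask`,
#'   `total = mse + alpha_mask * mask_loss`.
#' @export
total_loss <- function(mse, mask_loss, alpha_mask = 0.05) {
  structure(list(mse = mse, mask_loss = mask_loss, alpha_mask = alpha_mask,
                 total = mse + alpha_mask * mask_loss),
            class = "loss_bundle")
}

#' Random train/validation/test split
#'
#' @param dataset a [spectral_dataset()].
#' @param fractions length-3 fractions summing to 1.
#' @param seed integer seed (reproducible assignment).
#' @return list of three `spectral_dataset`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(dataset)
  if (n < 10L) stop("need at least 10 samples to split")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  set.seed(seed)
  idx <- sample.int(n)
  n_val <- floor(n * fractions[2L])
  n_test <- floor(n * fractions[3L])
  n_train <- n - n_val - n_test
  list(train = dataset[idx[seq_len(n_train)]],
       val = dataset[idx[n_train + seq_len(n_val)]],
       test = dataset[idx[n_train + n_val + seq_len(n_test)]])
}

#' Regression evaluation metrics
#'
#' `r2 = 1 - sum((y - yhat)^2)/sum((y - mean(y))^2)`,
#' `rmse = sqrt(mean((y - yhat)^2))`,
#' `mape = (100/n) * sum(|yhat - y| / |y|)` (percent; zero-valued targets are
#' skipped with a warning).
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return a `metrics` list with `r2`, `rmse`, `mape`, `n`.
#' @export
compute_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch in compute_metrics")
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations")
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) { warning("constant y: r2 undefined"); NaN }
        else 1 - ss_res / ss_tot
  rmse <- sqrt(ss_res / n)
  nz <- y != 0
  if (any(!nz)) warning("zero-valued targets skipped in MAPE")
  mape <- if (any(nz)) 100 * mean(abs((yhat[nz] - y[nz]) / y[nz])) else NaN
  structure(list(r2 = r2, rmse = rmse, mape = mape, n = n),
            class = "metrics")
}

# ---- generic loss graphs and prediction ------------------------------------

# Builds the per-batch loss graph. refl: bands x B matrix (preprocessed),
# ystd: standardized targets. Dispatches on model class.
build_loss_graph <- function(model, ctx, refl, ystd, alpha_mask) {
  UseMethod("build_loss_graph")
}

#' @export
build_loss_graph.indexfindnet <- function(model, ctx, refl, ystd, alpha_mask) {
  # soft relaxation during training (annealed temperature); the training
  # loop switches to hard straight-through for the consolidation phase
  g <- model_graph(ctx, model, refl, hard = FALSE, noise = ctx$training)
  mse <- op_mse(ctx, g$pred, ystd)
  ml <- op_neg_cosine(ctx, refl, g$masked)
  list(loss = op_axpy(ctx, mse, ml, alpha_mask), pred = g$pred,
       mse = mse$val, mask_loss = ml$val)
}

# numeric forward -> standardized predictions (vector)
forward_std <- function(model, refl) UseMethod("forward_std")

#' @export
forward_std.indexfindnet <- function(model, refl) {
  ctx <- ad_ctx(training = FALSE)
  g <- model_graph(ctx, model, refl, hard = TRUE, noise = FALSE)
  as.vector(g$pred$val)
}

# Re-estimate batch-norm running statistics under deterministic hard-mode
# forwards (training relaxes the band selection; evaluation uses hard
# argmax, whose feature statistics differ)
recalibrate_bn <- function(model, X, n_max = 256L) {
  if (!inherits(model, "indexfindnet")) return(invisible(model))
  idx <- seq_len(min(ncol(X), n_max))
  ctx <- ad_ctx(training = TRUE)
  ctx$bn_momentum <- 1
  invisible(model_graph(ctx, model, X[, idx, drop = FALSE], hard = TRUE,
                        noise = FALSE))
  invisible(model)
}

# deep-copy the trainable state (weights + batchnorm running stats)
snapshot_state <- function(model) {
  list(weights = lapply(model$params, function(p) p$val),
       bn = lapply(model$bn, function(e) list(mean = e$mean, var = e$var)))
}

restore_state <- function(model, snap) {
  for (nm in names(snap$weights)) model$params[[nm]]$val <- snap$weights[[nm]]
  for (nm in names(snap$bn)) {
    model$bn[[nm]]$mean <- snap$bn[[nm]]$mean
    model$bn[[nm]]$var <- snap$bn[[nm]]$var
  }
  model
}

# cyclic learning rate, cycle length in epochs; "triangular2" (default)
# halves the peak amplitude every cycle (the decaying cyclic strategy),
# "triangular" keeps it constant
cyclic_lr <- function(epoch, base, mx, cycle, mode = "triangular2") {
  step <- cycle / 2
  # phase-shifted so training starts at the peak (the stated initial rate)
  pos <- (epoch - 1 + step) %% cycle
  x <- abs(pos - step) / step
  amp <- mx - base
  if (identical(mode, "triangular2")) {
    amp <- amp / 2^((epoch - 1 + step) %/% cycle)
  }
  base + amp * (1 - x)
}

# one rectified-Adam update over all params; grads is a parallel list.
# Weight decay is decoupled (applied to the weights directly, not through
# the adaptive moments), which keeps it effective under Adam-style scaling.
radam_step <- function(params, grads, lr, t, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  rho_inf <- 2 / (1 - beta2) - 1
  rho_t <- rho_inf - 2 * t * beta2^t / (1 - beta2^t)
  rect <- rho_t > 4
  r_t <- if (rect)
    sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
           ((rho_inf - 4) * (rho_inf - 2) * rho_t)) else NA_real_
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- grads[[i]]
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^t)
    if (rect) {
      vhat <- sqrt(p$v / (1 - beta2^t))
      p$val <- p$val - lr * r_t * mhat / (vhat + eps)
    } else {
      p$val <- p$val - lr * mhat
    }
    if (weight_decay > 0) p$val <- p$val * (1 - lr * weight_decay)
  }
  invisible(NULL)
}

clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  tot <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (tot > max_norm) grads <- lapply(grads, function(g) g * max_norm / tot)
  grads
}

#' Train a model
#'
#' Mini-batch training with rectified Adam, L2 weight decay, a triangular
#' cyclic learning rate, and early stopping on the validation R^2 (evaluated
#' every `eval_every` epochs; the state with the best validation R^2 is
#' returned). Targets are standardized internally with train-set statistics.
#' Works for the band-selecting network and both CNN baselines.
#'
#' @param model an untrained model ([indexfindnet()], [onedcnn()],
#'   [indicecnn()]).
#' @param train,val labeled [spectral_dataset()]s.
#' @param trait `"vcmax"` or `"jmax"`.
#' @param config a [train_config()].
#' @param verbose print progress every validation.
#' @return list with `model` (best state), `history` (per-epoch data.frame:
#'   epoch, train_loss, mse, mask_loss, lr, val_r2, val_rmse, val_mape) and
#'   `best` (epoch and validation R^2 of the returned state).
#' @export
train_model <- function(model, train, val, trait = c("vcmax", "jmax"),
                        config = train_config(), verbose = FALSE) {
  trait <- match.arg(trait)
  if (length(train) == 0L || length(val) == 0L) stop("empty train or val set")
  ytr <- train[[trait]]
  yva <- val[[trait]]
  if (any(is.na(ytr)) || any(is.na(yva))) stop("unlabeled samples in train/val")
  set.seed(config$seed)
  model$y_center <- mean(ytr)
  model$y_scale <- stats::sd(ytr)
  if (model$y_scale == 0) model$y_scale <- 1
  ystd <- (ytr - model$y_center) / model$y_scale
  Xtr <- t(train$reflectance)            # bands x samples
  Xva <- t(val$reflectance)
  if (inherits(model, "indexfindnet"))
    model$probe <- rowMeans(Xtr)         # probe spectrum for interpretation
  n <- length(ystd)
  hist_rows <- vector("list", config$max_epochs)
  best_r2 <- -Inf
  best_epoch <- 0L
  best_snap <- snapshot_state(model)
  t_step <- 0L
  tau0 <- if (!is.null(model$config$gumbel_temperature))
    model$config$gumbel_temperature else 1
  t_start <- Sys.time()
  budget <- if (is.null(config$time_budget)) Inf else config$time_budget
  for (epoch in seq_len(config$max_epochs)) {
    lr <- cyclic_lr(epoch, config$lr_base, config$lr, config$lr_cycle,
                    config$lr_mode)
    if (inherits(model, "indexfindnet") && config$tau_end < tau0) {
      # reach the temperature floor early, then consolidate there
      frac <- min(1, epoch / (0.4 * config$max_epochs))
      model$config$gumbel_temperature <- tau0 * (config$tau_end / tau0)^frac
    }
    ord <- sample.int(n)
    ep_loss <- ep_mse <- ep_ml <- 0
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, n)]
      ctx <- ad_ctx(training = TRUE)
      ctx$fp32 <- isTRUE(config$fp32)
      gl <- build_loss_graph(model, ctx, Xtr[, bi, drop = FALSE], ystd[bi],
                             config$alpha_mask)
      if (!is.finite(gl$loss$val))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      ad_backward(ctx, gl$loss)
      grads <- ad_param_grads(ctx, model$params)
      grads <- clip_global_norm(grads, config$clip_grad)
      t_step <- t_step + 1L
      radam_step(model$params, grads, lr, t_step,
                 weight_decay = config$weight_decay)
      ep_loss <- ep_loss + gl$loss$val
      ep_mse <- ep_mse + gl$mse
      ep_ml <- ep_ml + if (is.null(gl$mask_loss)) 0 else gl$mask_loss
      nb <- nb + 1L
    }
    row <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                      mse = ep_mse / nb, mask_loss = ep_ml / nb, lr = lr,
                      val_r2 = NA_real_, val_rmse = NA_real_,
                      val_mape = NA_real_)
    timed_out <- as.numeric(difftime(Sys.time(), t_start, units = "secs")) >
      budget
    if (epoch %% config$eval_every == 0L || epoch == config$max_epochs ||
        timed_out) {
      recalibrate_bn(model, Xtr)
      pv <- forward_std(model, Xva) * model$y_scale + model$y_center
      mets <- suppressWarnings(compute_metrics(yva, pv))
      row$val_r2 <- mets$r2; row$val_rmse <- mets$rmse; row$val_mape <- mets$mape
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val R2 %.3f", epoch,
                        row$train_loss, mets$r2))
      if (is.finite(mets$r2) && mets$r2 > best_r2) {
        best_r2 <- mets$r2
        best_epoch <- epoch
        best_snap <- snapshot_state(model)
      }
      if (epoch - best_epoch >= config$patience || timed_out) {
        hist_rows[[epoch]] <- row
        break
      }
    }
    hist_rows[[epoch]] <- row
  }
  model <- restore_state(model, best_snap)
  model$trained <- TRUE
  list(model = model,
       history = do.call(rbind, hist_rows[!vapply(hist_rows, is.null, logical(1))]),
       best = list(epoch = best_epoch, val_r2 = best_r2))
}

#' Evaluate a trained model on a labeled dataset
#'
#' @param model a trained model.
#' @param dataset labeled [spectral_dataset()].
#' @param trait `"vcmax"` or `"jmax"`.
#' @return a `metrics` list (see [compute_metrics()]) plus `predictions`.
#' @export
evaluate_model <- function(model, dataset, trait = c("vcmax", "jmax")) {
  trait <- match.arg(trait)
  y <- dataset[[trait]]
  pred <- forward_std(model, t(dataset$reflectance)) * model$y_scale +
    model$y_center
  m <- compute_metrics(y, pred)
  m$predictions <- pred
  m
}
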
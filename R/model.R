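# The band-selecting network ("Indexfindnet"): a gated-convolution +
# encoder/decoder Mask module, ten non-local band-attention heads that pick
# one wavelength per channel through a uniform-Gumbel softmax, three
# vegetation-index branches, and a softmax-gated fusion head.

#' Model configuration for the band-selecting network
#'
#' Collects every architectural hyperparameter. The `"reference"` profile is
#' the published configuration for a 1 x 204 input (64 attention channels,
#' 128 gated-convolution channels); the `"reduced"` profile halves the
#' channel widths for CPU-scale training while keeping the same
#' architecture. Any width can be overridden individually (the acceptance
#' suite runs attention channels 16 / gated channels 32).
#'
#' @param n_bands number of spectral bands of the input (>= 16; the encoder
#'   halves the band axis four times).
#' @param gconv_channels output channels of the gated convolution before the
#'   feature/gate split (must be even).
#' @param attn_channels channels per attention head (also the width of the
#'   index branches).
#' @param recurrent_hidden hidden size of the LSTM bottleneck.
#' @param head_hidden width of the first fusion linear layer.
#' @param ucrn_kernel,ucrn_dilation kernel size and dilation of the two
#'   pre-mapping convolutions of the encoder-decoder module.
#' @param attn_kernel,attn_dilation kernel size and dilation of the attention
#'   convolutions (padding is chosen to preserve the band axis).
#' @param attn_scale which "feature dimension" divides the alignment logits:
#'   `"adacos"` (no extra division; the adaptive cosine scale alone
#'   calibrates the softmax, as in the adaptive-scale literature; default),
#'   `"channels"` (divide by the channel dimension, as in standard scaled
#'   attention), or `"bands"` (the literal band-count reading, under which
#'   the selection gradient is so small that the uniform noise dominates and
#'   the selector does not train — kept for comparison).
#' @param gumbel_temperature softmax temperature tau of the band selector.
#' @param gumbel_shrink shrinking factor dividing the uniform noise.
#' @param dropout_rate dropout before the final linear layer.
#' @param index_eps epsilon guarding the index-branch denominators.
#' @param branch_clamp bound on the index-branch features (the guarded
#'   divisions are finite but can reach ~1/eps when a denominator difference
#'   vanishes; features are clamped to `[-branch_clamp, branch_clamp]` for
#'   training stability; `Inf` disables).
#' @param profile `"reference"` or `"reduced"`; sets channel-width defaults.
#' @return an object of class `model_config` (a list).
#' @export
model_config <- function(n_bands = 204L,
                         profile = c("reference", "reduced"),
                         gconv_channels = NULL,
                         attn_channels = NULL,
                         recurrent_hidden = NULL,
                         head_hidden = NULL,
                         ucrn_kernel = 5L, ucrn_dilation = 2L,
                         attn_kernel = 5L, attn_dilation = 2L,
                         attn_scale = c("adacos", "channels", "bands"),
                         gumbel_temperature = 1.0,
                         gumbel_shrink = 10,
                         dropout_rate = 0.2,
                         index_eps = 1e-6,
                         branch_clamp = 50) {
  profile <- match.arg(profile)
  attn_scale <- match.arg(attn_scale)
  base <- if (profile == "reference") 64L else 32L
  if (is.null(gconv_channels)) gconv_channels <- 2L * base
  if (is.null(attn_channels)) attn_channels <- base
  if (is.null(recurrent_hidden)) recurrent_hidden <- base
  if (is.null(head_hidden)) head_hidden <- 2L * base
  if (gconv_channels %% 2L != 0L) stop("gconv_channels must be even")
  if (n_bands < 16L) stop("n_bands must be >= 16 (four pooling halvings)")
  stopifnot(gumbel_temperature > 0, gumbel_shrink > 0,
            dropout_rate >= 0, dropout_rate < 1, index_eps > 0)
  ch <- gconv_channels %/% 2L
  structure(list(
    n_bands = as.integer(n_bands),
    profile = profile,
    gconv_channels = as.integer(gconv_channels),
    channels = ch,                       # feature half; also UCRN stage width
    ucrn_stage_channels = rep(ch, 4L),
    ucrn_kernel = as.integer(ucrn_kernel),
    ucrn_dilation = as.integer(ucrn_dilation),
    pool_kernel = 2L,
    recurrent_hidden = as.integer(recurrent_hidden),
    attn_channels = as.integer(attn_channels),
    attn_kernel = as.integer(attn_kernel),
    attn_dilation = as.integer(attn_dilation),
    attn_scale = attn_scale,
    gumbel_temperature = gumbel_temperature,
    gumbel_shrink = gumbel_shrink,
    dropout_rate = dropout_rate,
    head_hidden = as.integer(head_hidden),
    index_eps = index_eps,
    branch_clamp = branch_clamp,
    n_heads = 10L
  ), class = "model_config")
}

# branch layout: head index -> (branch, role). Fixed by the three index forms.
index_branch_layout <- function() {
  data.frame(
    head = 1:10,
    branch = c(rep("double_diff", 4), rep("add_mul", 4), rep("ratio", 2)),
    role = c("R1", "R2", "R3", "R4", "R1", "R2", "R3", "R4", "R1", "R2"),
    stringsAsFactors = FALSE
  )
}

.init_u <- function(dims, fan_in) {
  s <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -s, s), dims)
}

new_bn <- function(C) {
  e <- new.env(parent = emptyenv())
  e$mean <- rep(0, C); e$var <- rep(1, C)
  e
}

#' Construct an untrained band-selecting network
#'
#' @param config a [model_config()].
#' @param wavelengths optional numeric grid (nm) of length `config$n_bands`,
#'   used to map selected band indices to wavelengths.
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `indexfindnet`.
#' @export
indexfindnet <- function(config = model_config(), wavelengths = NULL,
                         seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(wavelengths) && length(wavelengths) != config$n_bands)
    stop("wavelengths must have length n_bands")
  C <- config$channels
  A <- config$attn_channels
  k <- config$ucrn_kernel
  ka <- config$attn_kernel
  H <- config$recurrent_hidden
  Ccomp <- max(4L, C %/% 2L)
  p <- list()
  # gated convolution: two independent kernels (feature and gate halves)
  p$gconv_Wf <- ad_param(.init_u(c(C, 1L, k), k), "gconv_Wf")
  p$gconv_bf <- ad_param(rep(0, C), "gconv_bf")
  p$gconv_Wg <- ad_param(.init_u(c(C, 1L, k), k), "gconv_Wg")
  p$gconv_bg <- ad_param(rep(0, C), "gconv_bg")
  # UCRN pre-mapping (two dilated convs)
  for (i in 1:2) {
    p[[paste0("pre_W", i)]] <- ad_param(.init_u(c(C, C, k), C * k), paste0("pre_W", i))
    p[[paste0("pre_b", i)]] <- ad_param(rep(0, C), paste0("pre_b", i))
  }
  # encoder stages: conv + batchnorm
  for (i in 1:4) {
    p[[paste0("enc_W", i)]] <- ad_param(.init_u(c(C, C, k), C * k), paste0("enc_W", i))
    p[[paste0("enc_b", i)]] <- ad_param(rep(0, C), paste0("enc_b", i))
    p[[paste0("enc_g", i)]] <- ad_param(rep(1, C), paste0("enc_g", i))
    p[[paste0("enc_be", i)]] <- ad_param(rep(0, C), paste0("enc_be", i))
  }
  # bottleneck: linear compress -> LSTM -> linear expand
  p$bott_Wc <- ad_param(.init_u(c(Ccomp, C), C), "bott_Wc")
  p$bott_bc <- ad_param(rep(0, Ccomp), "bott_bc")
  p$lstm_Wx <- ad_param(.init_u(c(4L * H, Ccomp), Ccomp), "lstm_Wx")
  p$lstm_Wh <- ad_param(.init_u(c(4L * H, H), H), "lstm_Wh")
  p$lstm_b <- ad_param(rep(0, 4L * H), "lstm_b")
  p$bott_We <- ad_param(.init_u(c(C, H), H), "bott_We")
  p$bott_be <- ad_param(rep(0, C), "bott_be")
  # decoder stages
  for (i in 1:4) {
    p[[paste0("dec_W", i)]] <- ad_param(.init_u(c(C, C, k), C * k), paste0("dec_W", i))
    p[[paste0("dec_b", i)]] <- ad_param(rep(0, C), paste0("dec_b", i))
  }
  p$mask_W <- ad_param(.init_u(c(1L, C, 1L), C), "mask_W")
  # bias 1 starts the mask near the identity (alive ReLU; the mask loss
  # pulls masked output toward the input anyway)
  p$mask_b <- ad_param(rep(1, 1L), "mask_b")
  # attention heads
  for (h in 1:10) {
    p[[paste0("attn_Wq", h)]] <- ad_param(.init_u(c(A, 1L, ka), ka), paste0("attn_Wq", h))
    p[[paste0("attn_bq", h)]] <- ad_param(rep(0, A), paste0("attn_bq", h))
    p[[paste0("attn_Wv", h)]] <- ad_param(.init_u(c(A, A, ka), A * ka), paste0("attn_Wv", h))
    p[[paste0("attn_bv", h)]] <- ad_param(rep(0, A), paste0("attn_bv", h))
    p[[paste0("attn_Wl", h)]] <- ad_param(matrix(stats::rnorm(A * A, sd = 1 / sqrt(A)), A, A),
                                          paste0("attn_Wl", h))
  }
  # fusion head; batch-norm on the fused features (the index ratios have a
  # large constant component, which otherwise ill-conditions the head)
  p$fuse_Wf <- ad_param(.init_u(c(3L, 3L), 3L), "fuse_Wf")
  p$fuse_bf <- ad_param(rep(0, 3L), "fuse_bf")
  p$fuse_g <- ad_param(rep(1, A), "fuse_g")
  p$fuse_be <- ad_param(rep(0, A), "fuse_be")
  p$head_W1 <- ad_param(.init_u(c(config$head_hidden, A), A), "head_W1")
  p$head_b1 <- ad_param(rep(0, config$head_hidden), "head_b1")
  # zero-initialized output layer: predictions start at 0 on the
  # standardized trait scale, so the first epochs are well-conditioned
  p$head_W2 <- ad_param(array(0, c(1L, config$head_hidden)), "head_W2")
  p$head_b2 <- ad_param(rep(0, 1L), "head_b2")

  bn <- lapply(1:4, function(i) new_bn(C))
  names(bn) <- paste0("enc", 1:4)
  bn$fuse <- new_bn(A)
  structure(list(
    config = config,
    params = p,
    bn = bn,
    comp_channels = Ccomp,
    wavelengths = wavelengths,
    y_center = 0, y_scale = 1,
    trained = FALSE
  ), class = "indexfindnet")
}

#' Count trainable parameters
#'
#' Sums the number of elements of every trainable weight of a model built on
#' the internal autodiff engine (the band-selecting network or either CNN
#' baseline). Batch-normalization running statistics are not trainable and are
#' not counted.
#'
#' @param model a model object with a `params` list.
#' @return integer number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$val), numeric(1)))
}

#' Adaptive cosine scale factor
#'
#' Computes the adaptive scale applied to the cosine-similarity activations of
#' one attention channel: `S = 2*ln(bandnum)`, `B_i = exp(S*x_i - max(S*x))`,
#' `alpha = max(S*x) + ln(mean(B))/cos(pi/4)`.
#'
#' @param x numeric activation vector (one channel across bands).
#' @param bandnum number of bands (>= 2).
#' @return scalar scale factor.
#' @export
adacos_scale <- function(x, bandnum) {
  if (length(x) == 0L) stop("adacos_scale: empty activation vector")
  if (bandnum < 2L) stop("adacos_scale: bandnum must be >= 2")
  S <- 2 * log(bandnum)
  sx <- S * x
  mx <- max(sx)
  Bavg <- mean(exp(sx - mx))
  mx + log(Bavg) / cos(pi / 4)
}

#' Uniform-Gumbel softmax
#'
#' Differentiable discrete selection where the standard Gumbel noise is
#' replaced by uniform noise on `[0, 1)` divided by a shrinking factor:
#' `p'_i = softmax((g_i + logits)/tau)`. In hard mode the one-hot vector at
#' the argmax is returned (training uses straight-through gradients through
#' the soft probabilities; this numeric front-end returns the selection only).
#'
#' @param logits numeric vector.
#' @param tau temperature (> 0).
#' @param shrink noise shrinking factor (> 0).
#' @param hard if `TRUE` return an exact one-hot vector.
#' @param noise if `FALSE`, skip the noise draw (deterministic evaluation).
#' @return numeric vector on the simplex (one-hot in hard mode).
#' @export
uniform_gumbel_softmax <- function(logits, tau = 1, shrink = 10, hard = FALSE,
                                   noise = TRUE) {
  if (tau <= 0) stop("uniform_gumbel_softmax: tau must be > 0")
  if (shrink <= 0) stop("uniform_gumbel_softmax: shrink must be > 0")
  z <- logits
  if (noise) z <- z + stats::runif(length(logits)) / shrink
  z <- z / tau
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  if (hard) {
    h <- numeric(length(p))
    h[which.max(p)] <- 1
    h
  } else p
}

# ---- forward graph ---------------------------------------------------------

# Mask module sub-graph. x3 is a (1, L, B) node; returns list of nodes.
.graph_mask <- function(ctx, m, x3) {
  cfg <- m$config
  p <- m$params
  k <- cfg$ucrn_kernel
  pad_same <- (k - 1L) %/% 2L
  f <- op_conv1d(ctx, x3, ad_leaf(ctx, p$gconv_Wf), ad_leaf(ctx, p$gconv_bf),
                 dilation = 1L, pad = pad_same, pad_mode = "replicate")
  g <- op_conv1d(ctx, x3, ad_leaf(ctx, p$gconv_Wg), ad_leaf(ctx, p$gconv_bg),
                 dilation = 1L, pad = pad_same, pad_mode = "replicate")
  gout <- op_relu(ctx, op_mul(ctx, f, op_sigmoid(ctx, g)))
  u <- .ucrn_subgraph(ctx, m, gout)
  masked <- op_mul(ctx, u$mask, x3)
  list(mask = u$mask, masked = masked, gconv = gout, pre = u$pre,
       encs = u$encs)
}

# One attention head. masked: (1, L, B) node; refl: (L, B) constant matrix.
.graph_attention <- function(ctx, m, head, masked, refl, hard, noise) {
  cfg <- m$config
  p <- m$params
  pad_a <- (cfg$attn_kernel - 1L) * cfg$attn_dilation %/% 2L
  # replicate padding: zero padding makes the edge bands look structurally
  # distinct and the selector then favours the grid edges
  Q <- op_relu(ctx, op_conv1d(ctx, masked,
                              ad_leaf(ctx, p[[paste0("attn_Wq", head)]]),
                              ad_leaf(ctx, p[[paste0("attn_bq", head)]]),
                              dilation = cfg$attn_dilation, pad = pad_a,
                              pad_mode = "replicate"))
  V <- op_relu(ctx, op_conv1d(ctx, Q,
                              ad_leaf(ctx, p[[paste0("attn_Wv", head)]]),
                              ad_leaf(ctx, p[[paste0("attn_bv", head)]]),
                              dilation = cfg$attn_dilation, pad = pad_a,
                              pad_mode = "replicate"))
  Vn <- op_l2norm_cols(ctx, V)
  Wn <- op_rownorm(ctx, ad_leaf(ctx, p[[paste0("attn_Wl", head)]]))
  cosm <- op_matmul_shared(ctx, Wn, Vn)
  if (any(!is.finite(cosm$val)))
    stop("band attention head ", head, ": non-finite activations")
  D <- switch(cfg$attn_scale, bands = cfg$n_bands,
              channels = cfg$attn_channels, adacos = 1)
  Aw <- op_attention_select(ctx, cosm, cfg$n_bands, D,
                            cfg$gumbel_temperature, cfg$gumbel_shrink,
                            hard = hard, noise = noise)
  Oa <- op_sigmoid(ctx, op_contract_bands(ctx, Aw, refl))
  list(Oa = Oa, A = Aw, cosm = cosm, alpha = Aw$alpha, sel = Aw$argmax)
}

.graph_branches <- function(ctx, m, Oas) {
  eps <- m$config$index_eps
  cl <- m$config$branch_clamp
  dd <- op_div_guard(ctx, op_sub(ctx, Oas[[1]], Oas[[2]]),
                     op_sub(ctx, Oas[[3]], Oas[[4]]), eps)
  am <- op_div_guard(ctx, op_add(ctx, Oas[[5]], Oas[[6]]),
                     op_mul(ctx, Oas[[7]], Oas[[8]]), eps)
  rt <- op_div_guard(ctx, Oas[[9]], Oas[[10]], eps)
  # bounded features: the epsilon-guarded divisions are finite but heavy
  # tailed (ratios of near-equal sigmoids); clamp the extreme tail, then
  # squash with asinh (near-linear in the typical range) so the feature
  # statistics entering the fusion head stay well conditioned
  if (is.finite(cl)) {
    dd <- op_clamp(ctx, dd, -cl, cl)
    am <- op_clamp(ctx, am, -cl, cl)
    rt <- op_clamp(ctx, rt, -cl, cl)
  }
  dd <- op_asinh(ctx, dd)
  am <- op_asinh(ctx, am)
  rt <- op_asinh(ctx, rt)
  list(double_diff = dd, add_mul = am, ratio = rt)
}

.graph_fusion <- function(ctx, m, branches) {
  p <- m$params
  st <- op_stack_first(ctx, branches)               # (3, A, B)
  pre <- op_add_bias(ctx, op_matmul_shared(ctx, ad_leaf(ctx, p$fuse_Wf), st),
                     ad_leaf(ctx, p$fuse_bf))
  S <- op_softmax_first(ctx, pre)
  fused <- op_sum_first(ctx, op_mul(ctx, S, st))    # (A, B)
  fused <- op_batchnorm(ctx, fused, ad_leaf(ctx, p$fuse_g),
                        ad_leaf(ctx, p$fuse_be), m$bn$fuse)
  h1 <- op_relu(ctx, op_linear(ctx, fused, ad_leaf(ctx, p$head_W1),
                               ad_leaf(ctx, p$head_b1)))
  h1 <- op_dropout(ctx, h1, m$config$dropout_rate)
  out <- op_linear(ctx, h1, ad_leaf(ctx, p$head_W2), ad_leaf(ctx, p$head_b2))
  list(out = out, S = S)
}

# Full forward graph. refl: (L, B) numeric matrix of (preprocessed)
# reflectance. Returns nodes plus band selections.
model_graph <- function(ctx, m, refl, hard = TRUE, noise = ctx$training) {
  cfg <- m$config
  if (nrow(refl) != cfg$n_bands)
    stop("input has ", nrow(refl), " bands; model expects ", cfg$n_bands)
  if (any(!is.finite(refl))) stop("non-finite reflectance input")
  B <- ncol(refl)
  x3 <- ad_const(ctx, array(refl, c(1L, cfg$n_bands, B)))
  mk <- .graph_mask(ctx, m, x3)
  heads <- lapply(1:10, function(h)
    .graph_attention(ctx, m, h, mk$masked, refl, hard, noise))
  Oas <- lapply(heads, `[[`, "Oa")
  br <- .graph_branches(ctx, m, Oas)
  fu <- .graph_fusion(ctx, m, list(br$double_diff, br$add_mul, br$ratio))
  list(pred = fu$out, S = fu$S, mask = mk$mask, masked = mk$masked,
       heads = heads, branches = br, x3 = x3)
}

#' Run the band-selecting network forward
#'
#' Composes the Mask module, the ten attention heads, the three index
#' branches and the fusion head on one or more spectra. With `hard = TRUE`
#' and `noise = FALSE` (the defaults) the pass is deterministic.
#'
#' @param model an [indexfindnet()] model.
#' @param reflectance numeric vector of length `n_bands` or matrix
#'   (`n_bands` x samples).
#' @param hard emit exact one-hot band selections.
#' @param noise add uniform selection noise (training behaviour).
#' @return a list: `prediction` (numeric, original trait units), `selections`
#'   (data.frame with head, branch, role, channel, band_index, wavelength),
#'   `form_scores` (named 3-vector over the index forms, summing to 1),
#'   `mask` and `masked` (band-axis matrices).
#' @export
model_forward <- function(model, reflectance, hard = TRUE, noise = FALSE) {
  refl <- as.matrix(reflectance)
  if (ncol(refl) == 1L && nrow(refl) != model$config$n_bands) refl <- t(refl)
  ctx <- ad_ctx(training = FALSE)
  g <- model_graph(ctx, model, refl, hard = hard, noise = noise)
  pred <- as.vector(g$pred$val) * model$y_scale + model$y_center
  layout <- index_branch_layout()
  sels <- do.call(rbind, lapply(1:10, function(h) {
    sel <- g$heads[[h]]$sel[, 1L]
    data.frame(head = h, branch = layout$branch[h], role = layout$role[h],
               channel = seq_along(sel), band_index = sel,
               wavelength = if (is.null(model$wavelengths)) NA_real_
                            else model$wavelengths[sel],
               stringsAsFactors = FALSE)
  }))
  scores <- rowMeans(matrix(g$S$val, nrow = 3L))
  names(scores) <- c("double_diff", "add_mul", "ratio")
  list(prediction = pred, selections = sels, form_scores = scores,
       mask = matrix(g$mask$val, model$config$n_bands, ncol(refl)),
       masked = matrix(g$masked$val, model$config$n_bands, ncol(refl)))
}

#' @export
predict.indexfindnet <- function(object, newdata, ...) {
  refl <- t(reflectance_matrix(newdata))
  model_forward(object, refl)$prediction
}

# ---- stage-level front-ends (single spectrum / small batch) ---------------

run_eval_ctx <- function() ad_ctx(training = FALSE)

#' Gated convolution stage
#'
#' Convolves the input spectrum into feature and gate halves and combines
#' them as `ReLU(feature * sigmoid(gate))`.
#'
#' @param model an [indexfindnet()] model.
#' @param input numeric vector of length `n_bands`, or `n_bands` x B matrix.
#' @return a `channels x n_bands` matrix (one sample) or a
#'   `channels x n_bands x B` array.
#' @export
gated_conv_forward <- function(model, input) {
  x <- as.matrix(input)
  if (nrow(x) != model$config$n_bands) x <- t(x)
  if (nrow(x) != model$config$n_bands)
    stop("input band length ", nrow(x), " does not match config n_bands ",
         model$config$n_bands)
  ctx <- run_eval_ctx()
  x3 <- ad_const(ctx, array(x, c(1L, nrow(x), ncol(x))))
  p <- model$params
  k <- model$config$ucrn_kernel
  pad_same <- (k - 1L) %/% 2L
  f <- op_conv1d(ctx, x3, ad_leaf(ctx, p$gconv_Wf), ad_leaf(ctx, p$gconv_bf),
                 dilation = 1L, pad = pad_same, pad_mode = "replicate")
  g <- op_conv1d(ctx, x3, ad_leaf(ctx, p$gconv_Wg), ad_leaf(ctx, p$gconv_bg),
                 dilation = 1L, pad = pad_same, pad_mode = "replicate")
  out <- op_relu(ctx, op_mul(ctx, f, op_sigmoid(ctx, g)))
  drop_b1(out$val)
}

drop_b1 <- function(a) if (dim(a)[3L] == 1L) matrix(a, dim(a)[1L], dim(a)[2L]) else a

#' Encoder-decoder (UCRN) stage
#'
#' Runs the dilated pre-mapping, four pooling encoder stages, the LSTM
#' bottleneck and the upsampling decoder with skip additions, returning the
#' one-channel mask map.
#'
#' @param model an [indexfindnet()] model.
#' @param features `channels x n_bands` matrix (output of
#'   [gated_conv_forward()]) or a 3-d array with a trailing batch dim.
#' @return numeric vector of length `n_bands` (or matrix for a batch).
#' @export
ucrn_forward <- function(model, features) {
  C <- model$config$channels
  a <- if (length(dim(features)) == 3L) features
       else array(features, c(dim(features), 1L))
  if (dim(a)[1L] != C) stop("feature channel count mismatch")
  ctx <- run_eval_ctx()
  # reuse the mask graph from the pre-map stage onward by faking the gconv out
  m <- model
  g <- .ucrn_subgraph(ctx, m, ad_const(ctx, a))
  out <- matrix(g$mask$val, dim(a)[2L], dim(a)[3L])
  if (ncol(out) == 1L) as.vector(out) else out
}

.ucrn_subgraph <- function(ctx, m, gout) {
  cfg <- m$config
  p <- m$params
  k <- cfg$ucrn_kernel
  pad_same <- (k - 1L) %/% 2L
  pad_dil <- (k - 1L) * cfg$ucrn_dilation %/% 2L
  h <- gout
  for (i in 1:2) {
    h <- op_relu(ctx, op_conv1d(ctx, h,
                                ad_leaf(ctx, p[[paste0("pre_W", i)]]),
                                ad_leaf(ctx, p[[paste0("pre_b", i)]]),
                                dilation = cfg$ucrn_dilation, pad = pad_dil,
                                pad_mode = "replicate"))
  }
  pre <- h
  encs <- vector("list", 4L)
  for (i in 1:4) {
    h <- op_maxpool2(ctx, h)
    h <- op_conv1d(ctx, h, ad_leaf(ctx, p[[paste0("enc_W", i)]]),
                   ad_leaf(ctx, p[[paste0("enc_b", i)]]),
                   dilation = 1L, pad = pad_same, pad_mode = "replicate")
    h <- op_batchnorm(ctx, h, ad_leaf(ctx, p[[paste0("enc_g", i)]]),
                      ad_leaf(ctx, p[[paste0("enc_be", i)]]), m$bn[[i]])
    h <- op_relu(ctx, h)
    encs[[i]] <- h
  }
  comp <- op_add_bias(ctx, op_matmul_shared(ctx, ad_leaf(ctx, p$bott_Wc), h),
                      ad_leaf(ctx, p$bott_bc))
  seq3 <- op_lstm(ctx, comp, ad_leaf(ctx, p$lstm_Wx),
                  ad_leaf(ctx, p$lstm_Wh), ad_leaf(ctx, p$lstm_b))
  h <- op_add_bias(ctx, op_matmul_shared(ctx, ad_leaf(ctx, p$bott_We), seq3),
                   ad_leaf(ctx, p$bott_be))
  skips <- list(encs[[3]], encs[[2]], encs[[1]], pre)
  for (i in 1:4) {
    target <- dim(skips[[i]]$val)[2L]
    h <- op_upsample2(ctx, h, target)
    h <- op_conv1d(ctx, h, ad_leaf(ctx, p[[paste0("dec_W", i)]]),
                   ad_leaf(ctx, p[[paste0("dec_b", i)]]),
                   dilation = 1L, pad = pad_same, pad_mode = "replicate")
    h <- op_relu(ctx, h)
    h <- op_add(ctx, h, skips[[i]])
  }
  mask <- op_relu(ctx, op_conv1d(ctx, h, ad_leaf(ctx, p$mask_W),
                                 ad_leaf(ctx, p$mask_b), dilation = 1L, pad = 0L))
  list(mask = mask, pre = pre, encs = encs)
}

#' Mask module: multiply the input by its learned spectral mask
#'
#' @param model an [indexfindnet()] model.
#' @param input numeric vector (length `n_bands`) or matrix (`n_bands` x B).
#' @return list with `output` (masked spectrum) and `mask` (mask map), each
#'   shaped like the input.
#' @export
mask_forward <- function(model, input) {
  x <- as.matrix(input)
  if (nrow(x) != model$config$n_bands) x <- t(x)
  ctx <- run_eval_ctx()
  x3 <- ad_const(ctx, array(x, c(1L, nrow(x), ncol(x))))
  mk <- .graph_mask(ctx, model, x3)
  out <- matrix(mk$masked$val, nrow(x), ncol(x))
  msk <- matrix(mk$mask$val, nrow(x), ncol(x))
  if (ncol(x) == 1L) list(output = as.vector(out), mask = as.vector(msk))
  else list(output = out, mask = msk)
}

#' Non-local band attention head
#'
#' Runs one attention head on a masked spectrum: dilated Q/V convolutions,
#' cosine similarity against row-normalized weights, adaptive cosine scaling,
#' uniform-Gumbel one-hot band selection, and the sigmoid-activated gather of
#' the reflectance at the selected bands.
#'
#' @param model an [indexfindnet()] model.
#' @param features masked spectrum (vector of length `n_bands`).
#' @param reflectance raw reflectance on the same grid (defaults to
#'   `features`).
#' @param head head index in 1..10.
#' @param hard emit exact one-hots.
#' @param noise add uniform selection noise.
#' @return list with `output` (`attn_channels` vector in (0,1)),
#'   `selections` (data.frame of per-channel band choices) and `A` (the
#'   alignment matrix, `attn_channels` x `n_bands`).
#' @export
band_attention_forward <- function(model, features, reflectance = features,
                                   head = 1L, hard = TRUE, noise = FALSE) {
  x <- as.matrix(features)
  if (nrow(x) != model$config$n_bands) x <- t(x)
  r <- as.matrix(reflectance)
  if (nrow(r) != model$config$n_bands) r <- t(r)
  ctx <- run_eval_ctx()
  x3 <- ad_const(ctx, array(x, c(1L, nrow(x), ncol(x))))
  ha <- .graph_attention(ctx, model, head, x3, r, hard, noise)
  layout <- index_branch_layout()
  sel <- ha$sel[, 1L]
  list(output = ha$Oa$val[, 1L],
       selections = data.frame(
         head = head, branch = layout$branch[head], role = layout$role[head],
         channel = seq_along(sel), band_index = sel,
         wavelength = if (is.null(model$wavelengths)) NA_real_
                      else model$wavelengths[sel],
         stringsAsFactors = FALSE),
       A = matrix(ha$A$val[, , 1L],
                  model$config$attn_channels, model$config$n_bands))
}

#' Vegetation-index branch arithmetic
#'
#' Combines per-role selected activations elementwise:
#' `double_diff = (R1-R2)/(R3-R4+eps)`, `add_mul = (R1+R2)/(R3*R4+eps)`,
#' `ratio = R1/(R2+eps)`.
#'
#' @param selected named list of numeric vectors (`R1`..`R4` as required).
#' @param branch `"double_diff"`, `"add_mul"`, or `"ratio"`.
#' @param eps denominator guard.
#' @return numeric vector of branch features.
#' @export
index_branch_forward <- function(selected, branch = c("double_diff", "add_mul", "ratio"),
                                 eps = 1e-6) {
  branch <- match.arg(branch)
  need <- if (branch == "ratio") c("R1", "R2") else c("R1", "R2", "R3", "R4")
  if (!all(need %in% names(selected)))
    stop("branch '", branch, "' needs roles: ", paste(need, collapse = ", "))
  with(selected, switch(branch,
    double_diff = (R1 - R2) / (R3 - R4 + eps),
    add_mul = (R1 + R2) / (R3 * R4 + eps),
    ratio = R1 / (R2 + eps)))
}

#' Fusion head
#'
#' Scores the three index forms with a 1x1 convolution and softmax across
#' forms at every feature position, sums the score-weighted features, and
#' maps them through the two final linear layers.
#'
#' @param model an [indexfindnet()] model.
#' @param branch_features 3 x `attn_channels` matrix (rows: double_diff,
#'   add_mul, ratio).
#' @param force_form optionally an index 1..3; puts all softmax weight on one
#'   form (used for the masked-forward oracle).
#' @return list with `prediction` (scalar, standardized scale) and `scores`
#'   (3 x `attn_channels` matrix of form scores, columns sum to 1).
#' @export
fusion_head_forward <- function(model, branch_features, force_form = NULL) {
  bf <- as.matrix(branch_features)
  if (nrow(bf) != 3L) stop("branch_features must have exactly 3 rows")
  ctx <- run_eval_ctx()
  nodes <- lapply(1:3, function(i) ad_const(ctx, matrix(bf[i, ], ncol = 1L)))
  st <- op_stack_first(ctx, nodes)
  p <- model$params
  pre <- op_add_bias(ctx, op_matmul_shared(ctx, ad_leaf(ctx, p$fuse_Wf), st),
                     ad_leaf(ctx, p$fuse_bf))
  S <- op_softmax_first(ctx, pre)
  Sv <- S$val
  if (!is.null(force_form)) {
    Sv <- array(0, dim(Sv)); Sv[force_form, , ] <- 1
    S <- ad_const(ctx, Sv)
  }
  fused <- op_sum_first(ctx, op_mul(ctx, S, st))
  fused <- op_batchnorm(ctx, fused, ad_leaf(ctx, p$fuse_g),
                        ad_leaf(ctx, p$fuse_be), model$bn$fuse)
  h1 <- op_relu(ctx, op_linear(ctx, fused, ad_leaf(ctx, p$head_W1),
                               ad_leaf(ctx, p$head_b1)))
  out <- op_linear(ctx, h1, ad_leaf(ctx, p$head_W2), ad_leaf(ctx, p$head_b2))
  list(prediction = as.vector(out$val),
       scores = matrix(Sv, 3L, ncol(bf)))
}

# ---- serialization ---------------------------------------------------------

#' Save / load a trained model
#'
#' The checkpoint is a binary RDS of the weights plus a JSON sidecar holding
#' the full configuration and the wavelength grid, so selected band indices
#' can always be mapped back to nm after a round-trip.
#'
#' @param model an [indexfindnet()] model (or CNN baseline).
#' @param path checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  weights <- lapply(model$params, function(p) p$val)
  bn <- lapply(model$bn, function(e) list(mean = e$mean, var = e$var))
  saveRDS(list(class = class(model)[1L], weights = weights, bn = bn,
               y_center = model$y_center, y_scale = model$y_scale,
               trained = model$trained, comp_channels = model$comp_channels,
               probe = model$probe),
          path)
  sidecar <- list(config = unclass(model$config),
                  wavelengths = model$wavelengths)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  blob <- readRDS(path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- sc$config
  config <- do.call(model_config, cfg[c("n_bands", "profile", "gconv_channels",
                                        "attn_channels", "recurrent_hidden",
                                        "head_hidden", "ucrn_kernel",
                                        "ucrn_dilation", "attn_kernel",
                                        "attn_dilation", "attn_scale",
                                        "gumbel_temperature",
                                        "gumbel_shrink", "dropout_rate",
                                        "index_eps", "branch_clamp")])
  m <- indexfindnet(config, wavelengths = sc$wavelengths)
  for (nm in names(blob$weights)) m$params[[nm]]$val <- blob$weights[[nm]]
  for (nm in names(blob$bn)) {
    m$bn[[nm]]$mean <- blob$bn[[nm]]$mean
    m$bn[[nm]]$var <- blob$bn[[nm]]$var
  }
  m$y_center <- blob$y_center; m$y_scale <- blob$y_scale
  m$trained <- blob$trained
  m$probe <- blob$probe
  m
}
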
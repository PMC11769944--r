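# Engine-level checks: op correctness against plain-R references and a
# finite-difference gradient check through the full model graph.

test_that("conv1d matches a plain-R tap-loop reference (values and grads)", {
  set.seed(31)
  Cin <- 3L; Cout <- 4L; L <- 17L; B <- 2L; k <- 5L; dil <- 2L; pad <- 4L
  x <- array(rnorm(Cin * L * B), c(Cin, L, B))
  W <- array(rnorm(Cout * Cin * k, sd = 0.3), c(Cout, Cin, k))
  b <- rnorm(Cout)
  ref_conv <- function(x, W, b, dil, pad) {
    Lout <- L + 2 * pad - ((k - 1) * dil + 1) + 1
    xp <- array(0, c(Cin, L + 2 * pad, B))
    xp[, pad + (1:L), ] <- x
    y <- array(0, c(Cout, Lout, B))
    for (bb in 1:B) for (l in 1:Lout) {
      acc <- b
      for (t in 1:k) acc <- acc + W[, , t] %*% xp[, l + (t - 1) * dil, bb]
      y[, l, bb] <- acc
    }
    y
  }
  ctx <- specindexnet:::ad_ctx()
  xn <- specindexnet:::ad_const(ctx, x)
  Wn <- specindexnet:::ad_leaf(ctx, specindexnet:::ad_param(W))
  bn <- specindexnet:::ad_leaf(ctx, specindexnet:::ad_param(b))
  y <- specindexnet:::op_conv1d(ctx, xn, Wn, bn, dil, pad)
  expect_equal(y$val, ref_conv(x, W, b, dil, pad), tolerance = 1e-12)

  # gradient of sum(y * G) via backward vs. finite differences on W
  G <- array(rnorm(length(y$val)), dim(y$val))
  loss <- specindexnet:::ad_node(ctx, sum(y$val * G), list(y),
                                 function(g, nd) list(g * G))
  specindexnet:::ad_backward(ctx, loss)
  h <- 1e-6
  for (i in sample(length(W), 5)) {
    Wp <- W; Wp[i] <- Wp[i] + h
    Wm <- W; Wm[i] <- Wm[i] - h
    num <- (sum(ref_conv(x, Wp, b, dil, pad) * G) -
              sum(ref_conv(x, Wm, b, dil, pad) * G)) / (2 * h)
    expect_equal(Wn$grad[i], num, tolerance = 1e-5)
  }
  # gradient w.r.t. the input
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    num <- (sum(ref_conv(xp, W, b, dil, pad) * G) -
              sum(ref_conv(xm, W, b, dil, pad) * G)) / (2 * h)
    expect_equal(xn$grad[i], num, tolerance = 1e-5)
  }
})

test_that("pooling and upsampling shapes and gradients behave", {
  set.seed(32)
  ctx <- specindexnet:::ad_ctx()
  x <- array(rnorm(2 * 9 * 2), c(2, 9, 2))
  xn <- specindexnet:::ad_const(ctx, x)
  p <- specindexnet:::op_maxpool2(ctx, xn)
  expect_equal(dim(p$val), c(2, 4, 2))       # floor(9/2)
  expect_equal(p$val[1, 1, 1], max(x[1, 1:2, 1]))
  u <- specindexnet:::op_upsample2(ctx, p, 9L)
  expect_equal(dim(u$val), c(2, 9, 2))
  expect_equal(u$val[1, 1, 1], p$val[1, 1, 1])
  expect_equal(u$val[1, 9, 1], p$val[1, 4, 1])  # padded with last
})

test_that("mask-module gradients agree with finite differences", {
  # the mask-similarity objective exercises the gated convolution, the full
  # encoder-decoder (incl. LSTM bottleneck, batchnorm, pooling, upsampling,
  # skips) without the detached adaptive scale of the attention path
  set.seed(33)
  cfg <- tiny_model_config()
  m <- indexfindnet(cfg, seed = 34)
  refl <- matrix(runif(32 * 4, 0.1, 0.6), 32, 4)
  lossfun <- function() {
    ctx <- specindexnet:::ad_ctx(training = TRUE)
    x3 <- specindexnet:::ad_const(ctx, array(refl, c(1L, 32L, 4L)))
    mk <- specindexnet:::.graph_mask(ctx, m, x3)
    list(ctx = ctx, loss = specindexnet:::op_neg_cosine(ctx, refl, mk$masked))
  }
  gl <- lossfun()
  specindexnet:::ad_backward(gl$ctx, gl$loss)
  grads <- specindexnet:::ad_param_grads(gl$ctx, m$params)
  names(grads) <- names(m$params)
  mask_params <- grep("^(gconv|pre|enc|dec|bott|lstm|mask)", names(m$params),
                      value = TRUE)
  h <- 1e-5
  errs <- c()
  set.seed(35)
  for (nm in mask_params) {
    p <- m$params[[nm]]
    for (i in sample(length(p$val), min(2, length(p$val)))) {
      v0 <- p$val[i]
      p$val[i] <- v0 + h; lp <- lossfun()$loss$val
      p$val[i] <- v0 - h; lm <- lossfun()$loss$val
      p$val[i] <- v0
      num <- (lp - lm) / (2 * h)
      errs <- c(errs, abs(num - grads[[nm]][i]) /
                  max(1e-4, abs(num) + abs(grads[[nm]][i])))
    }
  }
  # ReLU kinks can make isolated coordinates non-smooth; the bulk matches
  expect_lt(stats::median(errs), 1e-6)
  expect_gte(mean(errs < 1e-3), 0.9)
})

test_that("the fused attention selector matches an alpha-frozen reference", {
  set.seed(37)
  C <- 4L; L <- 12L; B <- 3L
  cosm <- array(runif(C * L * B, -1, 1), c(C, L, B))
  D <- L; tau <- 0.7
  fw <- specindexnet:::cpp_attention_select(cosm, 2 * log(L), D, tau, 10,
                                            FALSE, FALSE)
  # reference: per (c, b), alpha via adacos_scale then softmax of
  # alpha*cos/(D*tau)
  for (b in 1:B) for (c in 1:C) {
    al <- adacos_scale(cosm[c, , b], L)
    z <- al * cosm[c, , b] / D / tau
    p <- exp(z - max(z)); p <- p / sum(p)
    expect_equal(fw$soft[c, , b], p, tolerance = 1e-12)
    expect_equal(fw$alpha[c, b], al, tolerance = 1e-12)
  }
  # backward against finite differences of the alpha-frozen map
  G <- array(rnorm(C * L * B), c(C, L, B))
  ga <- specindexnet:::cpp_attention_select_bwd(fw$soft, G, fw$alpha, D, tau)
  h <- 1e-7
  ref_loss <- function(cs) {
    tot <- 0
    for (b in 1:B) for (c in 1:C) {
      z <- fw$alpha[c, b] * cs[c, , b] / D / tau   # alpha held fixed
      p <- exp(z - max(z)); p <- p / sum(p)
      tot <- tot + sum(p * G[c, , b])
    }
    tot
  }
  set.seed(38)
  for (i in sample(length(cosm), 8)) {
    cp <- cosm; cp[i] <- cp[i] + h
    cm <- cosm; cm[i] <- cm[i] - h
    num <- (ref_loss(cp) - ref_loss(cm)) / (2 * h)
    expect_equal(ga[i], num, tolerance = 1e-5)
  }
})

test_that("fusion head gradients agree with finite differences", {
  set.seed(39)
  cfg <- tiny_model_config()
  m <- indexfindnet(cfg, seed = 40)
  A <- cfg$attn_channels
  feats <- lapply(1:3, function(i) matrix(runif(A * 3), A, 3))
  y <- rnorm(3)
  lossfun <- function() {
    ctx <- specindexnet:::ad_ctx(training = FALSE)
    nodes <- lapply(feats, function(f) specindexnet:::ad_const(ctx, f))
    fu <- specindexnet:::.graph_fusion(ctx, m, nodes)
    list(ctx = ctx, loss = specindexnet:::op_mse(ctx, fu$out, y))
  }
  gl <- lossfun()
  specindexnet:::ad_backward(gl$ctx, gl$loss)
  grads <- specindexnet:::ad_param_grads(gl$ctx, m$params)
  names(grads) <- names(m$params)
  h <- 1e-6
  for (nm in c("fuse_Wf", "fuse_bf", "head_W1", "head_b1", "head_W2",
               "head_b2")) {
    p <- m$params[[nm]]
    for (i in sample(length(p$val), min(3, length(p$val)))) {
      v0 <- p$val[i]
      p$val[i] <- v0 + h; lp <- lossfun()$loss$val
      p$val[i] <- v0 - h; lm <- lossfun()$loss$val
      p$val[i] <- v0
      expect_equal(grads[[nm]][i], (lp - lm) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("batchnorm normalizes in training mode and uses running stats in
           eval mode", {
  set.seed(36)
  x <- array(rnorm(3 * 50 * 4, mean = 2, sd = 3), c(3, 50, 4))
  gamma <- specindexnet:::ad_param(rep(1, 3))
  beta <- specindexnet:::ad_param(rep(0, 3))
  bn <- specindexnet:::new_bn(3)
  ctx <- specindexnet:::ad_ctx(training = TRUE)
  y <- specindexnet:::op_batchnorm(ctx, specindexnet:::ad_const(ctx, x),
                                   specindexnet:::ad_leaf(ctx, gamma),
                                   specindexnet:::ad_leaf(ctx, beta), bn)
  m <- rowMeans(matrix(y$val, 3))
  v <- apply(matrix(y$val, 3), 1, stats::var)
  expect_equal(m, rep(0, 3), tolerance = 1e-10)
  expect_equal(v, rep(1, 3), tolerance = 1e-2)
  # eval mode is deterministic given the running stats
  ctx2 <- specindexnet:::ad_ctx(training = FALSE)
  y2 <- specindexnet:::op_batchnorm(ctx2, specindexnet:::ad_const(ctx2, x),
                                    specindexnet:::ad_leaf(ctx2, gamma),
                                    specindexnet:::ad_leaf(ctx2, beta), bn)
  expect_true(all(is.finite(y2$val)))
})
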
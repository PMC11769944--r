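# Core network: stage shapes, stage oracles, discrete selection, parameter
# count.

ref_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- indexfindnet(model_config(), seed = 50,
                                       wavelengths = seq(400, 1000,
                                                         length.out = 204))
    m
  }
})

test_that("gated convolution has the published shape and matches a direct
           evaluation", {
  m <- ref_model()
  x <- runif(204, 0.05, 0.7)
  out <- gated_conv_forward(m, x)
  expect_equal(dim(out), c(64, 204))
  # zero input with zero biases stays zero: ReLU(0 * sigmoid(0)) = 0
  expect_equal(gated_conv_forward(m, rep(0, 204)),
               matrix(0, 64, 204), ignore_attr = TRUE)
  # independent direct evaluation: two convolutions (replicate padding),
  # sigmoid gate, ReLU
  Wf <- m$params$gconv_Wf$val; Wg <- m$params$gconv_Wg$val
  xp <- c(x[1], x[1], x, x[204], x[204])
  direct <- matrix(0, 64, 204)
  for (l in 1:204) {
    win <- xp[l:(l + 4)]
    f <- as.vector(Wf[, 1, ] %*% win) + m$params$gconv_bf$val
    g <- as.vector(Wg[, 1, ] %*% win) + m$params$gconv_bg$val
    direct[, l] <- pmax(0, f * (1 / (1 + exp(-g))))
  }
  expect_lt(max(abs(out - direct)), 1e-6)
})

test_that("encoder-decoder module preserves the published shapes", {
  m <- ref_model()
  x <- runif(204, 0.05, 0.7)
  feats <- gated_conv_forward(m, x)
  out <- ucrn_forward(m, feats)
  expect_length(out, 204)
  expect_true(all(is.finite(out)))
  # pooled band lengths along the encoder: floor halvings of 204
  ctx <- specindexnet:::ad_ctx()
  g <- specindexnet:::.ucrn_subgraph(ctx, m,
         specindexnet:::ad_const(ctx, array(feats, c(64, 204, 1))))
  lens <- vapply(g$encs, function(e) dim(e$val)[2], numeric(1))
  expect_equal(lens, c(102, 51, 25, 12))
})

test_that("mask output has the input shape and zero input maps to zero", {
  m <- ref_model()
  x <- runif(204, 0.05, 0.7)
  mk <- mask_forward(m, x)
  expect_length(mk$output, 204)
  expect_equal(mask_forward(m, rep(0, 204))$output, rep(0, 204))
})

test_that("adacos scale follows the closed form", {
  expect_equal(2 * log(204), 10.6360, tolerance = 1e-4)
  # constant input: all B_i = 1, alpha = S * c
  S <- 2 * log(204)
  expect_equal(adacos_scale(rep(0.3, 204), 204), S * 0.3, tolerance = 1e-12)
  set.seed(51)
  x <- runif(50, -1, 1)
  S50 <- 2 * log(50)
  direct <- max(S50 * x) +
    log(mean(exp(S50 * x - max(S50 * x)))) / cos(pi / 4)
  expect_equal(adacos_scale(x, 50), direct, tolerance = 1e-10)
  expect_error(adacos_scale(numeric(0), 10), "empty")
})

test_that("uniform-Gumbel softmax satisfies its contracts", {
  set.seed(52)
  for (i in 1:20) {
    p <- uniform_gumbel_softmax(rnorm(30), tau = runif(1, 0.1, 2))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
  # dominant logit at low temperature
  p <- uniform_gumbel_softmax(c(10, 0, 0), tau = 0.01)
  expect_gt(p[1], 0.999)
  h <- uniform_gumbel_softmax(c(0.3, 0.1, 0.2), hard = TRUE)
  expect_equal(sort(h), c(0, 0, 1))
  expect_error(uniform_gumbel_softmax(1:3, tau = 0), "tau")
  expect_error(uniform_gumbel_softmax(1:3, shrink = -1), "shrink")
})

test_that("hard selection frequencies match an independent sampler", {
  logits <- c(0.02, 0.05, 0.00, 0.04)
  n <- 1e5
  set.seed(53)
  counts <- integer(4)
  for (i in seq_len(n)) {
    h <- uniform_gumbel_softmax(logits, tau = 1, shrink = 10, hard = TRUE)
    counts[which.max(h)] <- counts[which.max(h)] + 1L
  }
  freq <- counts / n
  set.seed(54)
  ref <- oracle_gumbel_freq(logits, tau = 1, shrink = 10, n = n)
  se <- sqrt(ref * (1 - ref) / n) + sqrt(freq * (1 - freq) / n)
  expect_true(all(abs(freq - ref) <= 3 * pmax(se, 1e-4)))
})

test_that("band attention emits one-hot selections gathering the reflectance", {
  m <- ref_model()
  set.seed(55)
  x <- runif(204, 0.05, 0.7)
  masked <- mask_forward(m, x)$output
  at <- band_attention_forward(m, masked, x, head = 3, hard = TRUE,
                               noise = FALSE)
  expect_length(at$output, 64)
  expect_true(all(at$output > 0 & at$output < 1))
  # exact one-hot rows
  expect_true(all(rowSums(at$A) == 1))
  expect_true(all(at$A %in% c(0, 1)))
  # explicit gather oracle: output = sigmoid(reflectance at argmax band)
  sel <- apply(at$A, 1, which.max)
  expect_equal(at$selections$band_index, unname(sel))
  expect_lt(max(abs(at$output - 1 / (1 + exp(-x[sel])))), 1e-7)
})

test_that("index branch arithmetic follows the three formulas", {
  sel <- list(R1 = 0.5, R2 = 0.25, R3 = 0.8, R4 = 0.4)
  expect_equal(index_branch_forward(sel, "add_mul"), 0.75 / 0.32,
               tolerance = 1e-5)
  expect_equal(index_branch_forward(list(R1 = 0.6, R2 = 0.6), "ratio"), 1,
               tolerance = 1e-5)
  dd <- index_branch_forward(list(R1 = 0.5, R2 = 0.2, R3 = 0.3, R4 = 0.3),
                             "double_diff")
  expect_true(is.finite(dd))
  expect_error(index_branch_forward(list(R1 = 1), "add_mul"), "needs roles")
  # vectorized over channels
  v <- index_branch_forward(list(R1 = c(0.5, 0.6), R2 = c(0.25, 0.3),
                                 R3 = c(0.8, 0.5), R4 = c(0.4, 0.5)),
                            "add_mul")
  expect_length(v, 2)
})

test_that("fusion head scores are a softmax over forms and forcing one form
           isolates that branch", {
  m <- ref_model()
  set.seed(56)
  bf <- matrix(runif(3 * 64), 3, 64)
  fu <- fusion_head_forward(m, bf)
  expect_length(fu$prediction, 1)
  expect_equal(colSums(fu$scores), rep(1, 64), tolerance = 1e-9)
  # forcing all the weight on form 2 equals running the head on that branch
  forced <- fusion_head_forward(m, bf, force_form = 2)
  alone <- fusion_head_forward(m, rbind(bf[2, ], bf[2, ], bf[2, ]))
  expect_equal(forced$prediction, alone$prediction, tolerance = 1e-7)
})

test_that("model_forward is deterministic and equals the stage-by-stage
           composition", {
  cfg <- tiny_model_config()
  m <- indexfindnet(cfg, seed = 57,
                    wavelengths = seq(400, 1000, length.out = 32))
  x <- runif(32, 0.05, 0.7)
  f1 <- model_forward(m, x, hard = TRUE, noise = FALSE)
  f2 <- model_forward(m, x, hard = TRUE, noise = FALSE)
  expect_identical(f1$prediction, f2$prediction)
  expect_true(is.finite(f1$prediction))
  expect_equal(sum(f1$form_scores), 1, tolerance = 1e-9)
  expect_equal(nrow(f1$selections), 10 * cfg$attn_channels)

  # manual composition of the exported stage operations
  masked <- mask_forward(m, x)$output
  Oas <- lapply(1:10, function(h)
    band_attention_forward(m, masked, x, head = h, hard = TRUE,
                           noise = FALSE)$output)
  br <- rbind(
    index_branch_forward(list(R1 = Oas[[1]], R2 = Oas[[2]], R3 = Oas[[3]],
                              R4 = Oas[[4]]), "double_diff"),
    index_branch_forward(list(R1 = Oas[[5]], R2 = Oas[[6]], R3 = Oas[[7]],
                              R4 = Oas[[8]]), "add_mul"),
    index_branch_forward(list(R1 = Oas[[9]], R2 = Oas[[10]]), "ratio"))
  br <- asinh(pmin(pmax(br, -cfg$branch_clamp), cfg$branch_clamp))
  manual <- fusion_head_forward(m, br)$prediction
  expect_equal(f1$prediction, manual * m$y_scale + m$y_center,
               tolerance = 1e-6)
})

test_that("hard and soft alignment rows satisfy the simplex contracts and
           all stages stay finite on random spectra", {
  cfg <- tiny_model_config()
  m <- indexfindnet(cfg, seed = 58)
  set.seed(59)
  X <- matrix(runif(32 * 100, 0, 1), 32, 100)
  fw <- model_forward(m, X, hard = TRUE, noise = FALSE)
  expect_true(all(is.finite(fw$prediction)))
  expect_true(all(is.finite(fw$mask)))
  at <- band_attention_forward(m, X[, 1], X[, 1], head = 1, hard = FALSE,
                               noise = TRUE)
  expect_equal(rowSums(at$A), rep(1, cfg$attn_channels), tolerance = 1e-9)
  expect_true(all(at$A >= 0))
})

test_that("permuting cosine-weight rows permutes channels but not the set of
           selected bands", {
  cfg <- tiny_model_config()
  m <- indexfindnet(cfg, seed = 60)
  x <- runif(32, 0.1, 0.8)
  masked <- mask_forward(m, x)$output
  a1 <- band_attention_forward(m, masked, x, head = 1, hard = TRUE,
                               noise = FALSE)
  perm <- sample(cfg$attn_channels)
  m$params$attn_Wl1$val <- m$params$attn_Wl1$val[perm, ]
  a2 <- band_attention_forward(m, masked, x, head = 1, hard = TRUE,
                               noise = FALSE)
  expect_equal(a2$selections$band_index, a1$selections$band_index[perm])
})

test_that("parameter counts: closed form, shape walk, and the published
           bound", {
  fake <- list(params = list(W = specindexnet:::ad_param(matrix(0, 128, 64)),
                             b = specindexnet:::ad_param(rep(0, 128))))
  expect_equal(count_parameters(fake), 64 * 128 + 128)  # 8320

  m <- ref_model()
  # independent shape walk over the reference architecture
  C <- 64; A <- 64; k <- 5; H <- 64; Cc <- 32; hh <- 128
  expected <- 2 * (C * 1 * k + C) +            # gated conv, two kernels
    2 * (C * C * k + C) +                      # pre-mapping convs
    4 * (C * C * k + C + 2 * C) +              # encoder convs + batchnorm
    (Cc * C + Cc) +                            # bottleneck compression
    (4 * H * Cc + 4 * H * H + 4 * H) +         # LSTM
    (C * H + C) +                              # bottleneck expansion
    4 * (C * C * k + C) +                      # decoder convs
    (C + 1) +                                  # mask 1x1 conv
    10 * ((A * 1 * k + A) + (A * A * k + A) + A * A) +  # attention heads
    (3 * 3 + 3) + 2 * A +                      # form-score conv + fused BN
    (hh * A + hh) + (hh + 1)                   # fusion linears
  expect_equal(count_parameters(m), expected)
  expect_lte(count_parameters(m), 1e6)         # the published bound
})

test_that("model checkpoints round-trip through save/load", {
  cfg <- tiny_model_config()
  m <- indexfindnet(cfg, seed = 61,
                    wavelengths = seq(400, 1000, length.out = 32))
  m$y_center <- 85; m$y_scale <- 25; m$trained <- TRUE
  m$probe <- runif(32, 0.1, 0.6)
  x <- runif(32, 0.1, 0.7)
  before <- model_forward(m, x, hard = TRUE, noise = FALSE)
  ck <- tempfile(fileext = ".rds")
  save_model(m, ck)
  m2 <- load_model(ck)
  after <- model_forward(m2, x, hard = TRUE, noise = FALSE)
  expect_equal(after$prediction, before$prediction, tolerance = 1e-12)
  expect_equal(m2$wavelengths, m$wavelengths)
  expect_equal(m2$probe, m$probe)
})
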
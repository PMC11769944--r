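# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Values are plain R arrays. Convolutional activations use dim (C, L, B)
# (channels, band positions, batch); per-sample feature vectors use (C, B).
# All matrix products fold the trailing dims column-major, so BLAS does the
# heavy lifting. Nodes are environments; the tape is replayed in reverse by
# ad_backward(). Parameters are persistent environments re-attached to each
# forward pass through ad_leaf(), which also carries optimizer state.

.param_counter <- new.env(parent = emptyenv())
.param_counter$n <- 0L

#' @keywords internal
ad_param <- function(val, name = "") {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$name <- name
  .param_counter$n <- .param_counter$n + 1L
  p$id <- sprintf("p%07d", .param_counter$n)
  p$m <- NULL   # optimizer first moment
  p$v <- NULL   # optimizer second moment
  p
}

#' @keywords internal
ad_ctx <- function(training = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- vector("list", 1024L)
  ctx$n <- 0L
  ctx$training <- training
  ctx$leaves <- new.env(parent = emptyenv())
  ctx
}

ad_node <- function(ctx, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  n <- ctx$n + 1L
  if (n > length(ctx$tape)) ctx$tape <- c(ctx$tape, vector("list", length(ctx$tape)))
  ctx$tape[[n]] <- nd
  ctx$n <- n
  nd
}

# One leaf per parameter per tape, so repeated use accumulates gradients.
ad_leaf <- function(ctx, p) {
  nd <- ctx$leaves[[p$id]]
  if (is.null(nd)) {
    nd <- ad_node(ctx, p$val)
    nd$param <- p
    ctx$leaves[[p$id]] <- nd
  }
  nd
}

ad_const <- function(ctx, x) ad_node(ctx, x)

.acc <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

#' @keywords internal
ad_backward <- function(ctx, loss) {
  stopifnot(length(loss$val) == 1L)
  loss$grad <- 1
  for (i in seq.int(ctx$n, 1L)) {
    nd <- ctx$tape[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad, nd)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      if (!is.null(gs[[j]])) .acc(ps[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

# Collect parameter gradients from a finished tape (NULL grad -> zeros).
ad_param_grads <- function(ctx, params) {
  lapply(params, function(p) {
    nd <- ctx$leaves[[p$id]]
    if (is.null(nd) || is.null(nd$grad)) array(0, dim = dim1(p$val)) else nd$grad
  })
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- elementwise -----------------------------------------------------------

op_add <- function(ctx, a, b) {
  ad_node(ctx, a$val + b$val, list(a, b), function(g, nd) list(g, g))
}

op_sub <- function(ctx, a, b) {
  ad_node(ctx, a$val - b$val, list(a, b), function(g, nd) list(g, -g))
}

op_mul <- function(ctx, a, b) {
  ad_node(ctx, a$val * b$val, list(a, b),
          function(g, nd) list(g * nd$parents[[2]]$val, g * nd$parents[[1]]$val))
}

# y = a / (b + eps), the epsilon-guarded division of the index branches
op_div_guard <- function(ctx, a, b, eps) {
  den <- b$val + eps
  nd <- ad_node(ctx, a$val / den, list(a, b), NULL)
  nd$den <- den
  nd$backfn <- function(g, nd) {
    list(g / nd$den, -g * nd$val / nd$den)
  }
  nd
}

op_relu <- function(ctx, a) {
  v <- a$val
  v[v < 0] <- 0
  ad_node(ctx, v, list(a), function(g, nd) list(g * (nd$val > 0)))
}

op_sigmoid <- function(ctx, a) {
  v <- 1 / (1 + exp(-a$val))
  ad_node(ctx, v, list(a), function(g, nd) list(g * nd$val * (1 - nd$val)))
}

op_tanh <- function(ctx, a) {
  v <- tanh(a$val)
  ad_node(ctx, v, list(a), function(g, nd) list(g * (1 - nd$val^2)))
}

# ---- shaped ops ------------------------------------------------------------

fold2 <- function(x) matrix(x, nrow = dim(x)[1L])

# bias broadcast over the leading (channel) axis
op_add_bias <- function(ctx, x, b) {
  C <- dim1(x$val)[1L]
  ad_node(ctx, x$val + as.vector(b$val), list(x, b), function(g, nd) {
    list(g, rowSums(matrix(g, nrow = C)))
  })
}

# y = W %*% x for x (In, B) matrices
op_linear <- function(ctx, x, W, b = NULL) {
  y <- W$val %*% x$val
  if (!is.null(b)) y <- y + as.vector(b$val)
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ad_node(ctx, y, parents, function(g, nd) {
    x <- nd$parents[[1]]; W <- nd$parents[[2]]
    out <- list(crossprod(W$val, g), tcrossprod(g, x$val))
    if (length(nd$parents) == 3L) out[[3]] <- rowSums(g)
    out
  })
}

# shared (P, C) matrix applied across folded trailing dims of x (C, L, B)
op_matmul_shared <- function(ctx, W, x) {
  d <- dim(x$val)
  ym <- W$val %*% fold2(x$val)
  nd <- ad_node(ctx, array(ym, c(nrow(W$val), d[2L], d[3L])), list(W, x), NULL)
  nd$backfn <- function(g, nd) {
    W <- nd$parents[[1]]; x <- nd$parents[[2]]
    gm <- fold2(g)
    list(tcrossprod(gm, fold2(x$val)),
         array(crossprod(W$val, gm), dim(x$val)))
  }
  nd
}

pad_bands <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L], d[2L] + 2L * p, d[3L]))
  xp[, (p + 1L):(p + d[2L]), ] <- x
  xp
}

# 1-D convolution over the band axis; x (Cin, L, B), W (Cout, Cin, k),
# b (Cout). Heavy lifting (im2col + gemm) in C++; the im2col matrix is
# cached on the node for the backward pass.
op_conv1d <- function(ctx, x, W, b, dilation = 1L, pad = 0L,
                      pad_mode = c("zero", "replicate")) {
  pad_mode <- match.arg(pad_mode)
  pm <- if (pad_mode == "replicate") 1L else 0L
  single <- isTRUE(ctx$fp32)
  d <- dim(x$val)
  k <- dim(W$val)[3L]
  ext <- (k - 1L) * dilation + 1L
  Lout <- d[2L] + 2L * pad - ext + 1L
  if (Lout < 1L) stop("conv1d: band length ", d[2L], " too short for kernel ",
                      k, " with dilation ", dilation, " and padding ", pad)
  fw <- cpp_conv1d_fwd(x$val, W$val, as.numeric(b$val), dilation, pad, pm,
                       single)
  nd <- ad_node(ctx, fw$y, list(x, W, b), NULL)
  nd$col <- fw$col; nd$dilation <- dilation; nd$pad <- pad
  nd$pm <- pm; nd$single <- single
  nd$backfn <- function(g, nd) {
    x <- nd$parents[[1]]; W <- nd$parents[[2]]
    d <- dim(x$val)
    bw <- cpp_conv1d_bwd(nd$col, W$val, g, nd$dilation, nd$pad, d[1L], d[2L],
                         nd$pm, nd$single)
    list(bw$gx, bw$gW, as.vector(bw$gb))
  }
  nd
}

# fused attention band selector (adaptive cosine scale -> logits -> uniform
# noise -> softmax over bands -> optional hard one-hot); straight-through
# gradients to the cosine map, alpha detached
op_attention_select <- function(ctx, cosm, bandnum, D, tau, shrink, hard,
                                noise) {
  fw <- cpp_attention_select(cosm$val, 2 * log(bandnum), D, tau, shrink,
                             hard, noise)
  nd <- ad_node(ctx, fw$A, list(cosm), NULL)
  nd$soft <- fw$soft; nd$alpha <- fw$alpha; nd$argmax <- fw$argmax
  nd$D <- D; nd$tau <- tau
  nd$backfn <- function(g, nd) {
    list(cpp_attention_select_bwd(nd$soft, g, nd$alpha, nd$D, nd$tau))
  }
  nd
}

# max pooling, kernel 2 stride 2; odd tail band dropped (floor semantics)
op_maxpool2 <- function(ctx, x) {
  d <- dim(x$val)
  Lh <- d[2L] %/% 2L
  ia <- seq.int(1L, 2L * Lh, by = 2L)
  a <- x$val[, ia, , drop = FALSE]
  b <- x$val[, ia + 1L, , drop = FALSE]
  take_a <- a >= b
  y <- ifelse(take_a, a, b)
  dim(y) <- c(d[1L], Lh, d[3L])
  nd <- ad_node(ctx, y, list(x), NULL)
  nd$take_a <- take_a; nd$ia <- ia
  nd$backfn <- function(g, nd) {
    x <- nd$parents[[1]]
    gx <- array(0, dim(x$val))
    gx[, nd$ia, ] <- g * nd$take_a
    gx[, nd$ia + 1L, ] <- gx[, nd$ia + 1L, , drop = FALSE] + g * !nd$take_a
    list(gx)
  }
  nd
}

# nearest-neighbour x2 upsampling, then pad-with-last / truncate to target_len
op_upsample2 <- function(ctx, x, target_len) {
  d <- dim(x$val)
  idx <- rep(seq_len(d[2L]), each = 2L)
  if (length(idx) < target_len) idx <- c(idx, rep(d[2L], target_len - length(idx)))
  idx <- idx[seq_len(target_len)]
  nd <- ad_node(ctx, x$val[, idx, , drop = FALSE], list(x), NULL)
  nd$idx <- idx
  nd$backfn <- function(g, nd) {
    x <- nd$parents[[1]]
    L <- dim(x$val)[2L]
    # idx is rep(1:L, each=2) possibly truncated/padded with L at the tail:
    # accumulate the (at most three) positions mapping to each source band
    gx <- array(0, dim(x$val))
    pos <- split(seq_along(nd$idx), nd$idx)
    for (l in seq_len(L)) {
      w <- pos[[as.character(l)]]
      if (is.null(w)) next
      gl <- g[, w[1L], ]
      for (t in w[-1L]) gl <- gl + g[, t, ]
      gx[, l, ] <- gl
    }
    list(gx)
  }
  nd
}

# batch normalization over all positions/samples per channel; a context can
# override the running-stat momentum (used for post-training recalibration)
op_batchnorm <- function(ctx, x, gamma, beta, bn, eps = 1e-5, momentum = 0.1) {
  if (!is.null(ctx$bn_momentum)) momentum <- ctx$bn_momentum
  d <- dim1(x$val)
  C <- d[1L]
  xm <- matrix(x$val, nrow = C)
  m <- ncol(xm)
  if (ctx$training) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm^2) - mu^2
    bn$mean <- (1 - momentum) * bn$mean + momentum * mu
    bn$var  <- (1 - momentum) * bn$var + momentum * va * m / max(1, m - 1)
  } else {
    mu <- bn$mean
    va <- bn$var
  }
  s <- sqrt(va + eps)
  xhat <- (xm - mu) / s
  y <- array(gamma$val * xhat + beta$val, dim = dim(x$val))
  nd <- ad_node(ctx, y, list(x, gamma, beta), NULL)
  nd$xhat <- xhat; nd$s <- s; nd$train_stats <- ctx$training
  nd$backfn <- function(g, nd) {
    x <- nd$parents[[1]]; gamma <- nd$parents[[2]]
    C <- dim1(x$val)[1L]
    gm <- matrix(g, nrow = C)
    m <- ncol(gm)
    dgamma <- rowSums(gm * nd$xhat)
    dbeta <- rowSums(gm)
    dxhat <- gm * gamma$val
    if (nd$train_stats) {
      gx <- (dxhat - rowMeans(dxhat) - nd$xhat * rowMeans(dxhat * nd$xhat)) / nd$s
    } else {
      gx <- dxhat / nd$s
    }
    list(array(gx, dim(x$val)), dgamma, dbeta)
  }
  nd
}

# L2-normalize each channel-vector (per band position and sample)
op_l2norm_cols <- function(ctx, x, eps = 1e-12) {
  fw <- cpp_l2norm_cols(x$val, eps)
  nd <- ad_node(ctx, fw$y, list(x), NULL)
  nd$n <- fw$n
  nd$backfn <- function(g, nd) {
    list(cpp_l2norm_cols_bwd(nd$val, g, nd$n))
  }
  nd
}

# normalize the rows of a weight matrix (cosine-similarity weights)
op_rownorm <- function(ctx, W, eps = 1e-12) {
  n <- sqrt(rowSums(W$val^2)) + eps
  Y <- W$val / n
  nd <- ad_node(ctx, Y, list(W), NULL)
  nd$n <- n
  nd$backfn <- function(g, nd) {
    Y <- nd$val
    proj <- rowSums(g * Y)
    list((g - Y * proj) / nd$n)
  }
  nd
}

# softmax over the first axis of the folded matrix (used for 3-form scores)
op_softmax_first <- function(ctx, x) {
  d <- dim(x$val)
  xm <- fold2(x$val)
  xm <- sweep(xm, 2L, apply(xm, 2L, max), "-")
  e <- exp(xm)
  ym <- sweep(e, 2L, colSums(e), "/")
  nd <- ad_node(ctx, array(ym, d), list(x), NULL)
  nd$ym <- ym
  nd$backfn <- function(g, nd) {
    gm <- fold2(g)
    dot <- colSums(gm * nd$ym)
    list(array(nd$ym * sweep(gm, 2L, dot, "-"), dim1(nd$parents[[1]]$val)))
  }
  nd
}

op_stack_first <- function(ctx, nodes) {
  k <- length(nodes)
  d <- dim1(nodes[[1L]]$val)
  y <- array(0, c(k, d))
  for (i in seq_len(k)) y[i, , ] <- nodes[[i]]$val
  nd <- ad_node(ctx, y, nodes, NULL)
  nd$backfn <- function(g, nd) {
    lapply(seq_along(nd$parents), function(i) {
      gi <- g[i, , , drop = FALSE]
      array(gi, dim1(nd$parents[[i]]$val))
    })
  }
  nd
}

op_sum_first <- function(ctx, x) {
  d <- dim(x$val)
  ym <- colSums(matrix(x$val, nrow = d[1L]))
  nd <- ad_node(ctx, array(ym, d[-1L]), list(x), NULL)
  nd$backfn <- function(g, nd) {
    d <- dim(nd$parents[[1]]$val)
    list(array(rep(as.vector(g), each = d[1L]), d))
  }
  nd
}

op_dropout <- function(ctx, x, rate) {
  if (!ctx$training || rate <= 0) return(x)
  keep <- 1 - rate
  mask <- (array(stats::runif(length(x$val)), dim1(x$val)) < keep) / keep
  nd <- ad_node(ctx, x$val * mask, list(x), NULL)
  nd$mask <- mask
  nd$backfn <- function(g, nd) list(g * nd$mask)
  nd
}

# flatten (C, L, B) -> (C*L, B)
op_flatten <- function(ctx, x) {
  d <- dim(x$val)
  nd <- ad_node(ctx, matrix(x$val, d[1L] * d[2L], d[3L]), list(x), NULL)
  nd$backfn <- function(g, nd) list(array(g, dim(nd$parents[[1L]]$val)))
  nd
}

# ---- attention-specific ----------------------------------------------------

# O[c, b] = sum_l A[c, l, b] * r[l, b]   (r constant reflectance, (L, B))
op_contract_bands <- function(ctx, A, r) {
  nd <- ad_node(ctx, cpp_contract_fwd(A$val, r), list(A), NULL)
  nd$r <- r
  nd$backfn <- function(g, nd) list(cpp_contract_bwd(g, nd$r))
  nd
}

# inverse hyperbolic sine: monotone log-like squash for heavy-tailed inputs
op_asinh <- function(ctx, x) {
  nd <- ad_node(ctx, asinh(x$val), list(x), NULL)
  nd$backfn <- function(g, nd) list(g / sqrt(nd$parents[[1]]$val^2 + 1))
  nd
}

# clamp with pass-through gradient inside the bounds
op_clamp <- function(ctx, x, lo, hi) {
  v <- pmin(pmax(x$val, lo), hi)
  if (!is.null(dim(x$val))) dim(v) <- dim(x$val)
  nd <- ad_node(ctx, v, list(x), NULL)
  nd$inside <- (x$val > lo) & (x$val < hi)
  nd$backfn <- function(g, nd) list(g * nd$inside)
  nd
}

# ---- losses ----------------------------------------------------------------

op_mse <- function(ctx, pred, y) {
  r <- as.vector(pred$val) - y
  n <- length(y)
  nd <- ad_node(ctx, sum(r^2) / n, list(pred), NULL)
  nd$r <- r; nd$n <- n
  nd$backfn <- function(g, nd) {
    list(array(g * 2 * nd$r / nd$n, dim1(nd$parents[[1]]$val)))
  }
  nd
}

# full LSTM over the band axis as one fused node (C++ BPTT)
op_lstm <- function(ctx, x, Wx, Wh, b) {
  fw <- cpp_lstm_fwd(x$val, Wx$val, Wh$val, as.numeric(b$val))
  nd <- ad_node(ctx, fw$h, list(x, Wx, Wh, b), NULL)
  nd$cache <- fw
  nd$backfn <- function(g, nd) {
    x <- nd$parents[[1]]; Wx <- nd$parents[[2]]; Wh <- nd$parents[[3]]
    bw <- cpp_lstm_bwd(x$val, Wx$val, Wh$val, nd$cache, g)
    list(bw$gx, bw$gWx, bw$gWh, as.vector(bw$gb))
  }
  nd
}

# average pooling over the band axis with kernel/stride/padding
op_avgpool <- function(ctx, x, k, stride, pad = 0L) {
  d <- dim(x$val)
  L <- d[2L]
  Lout <- (L + 2L * pad - k) %/% stride + 1L
  xp <- pad_bands(x$val, pad)
  y <- array(0, c(d[1L], Lout, d[3L]))
  starts <- (seq_len(Lout) - 1L) * stride
  for (t in seq_len(k)) {
    y <- y + xp[, starts + t, , drop = FALSE] / k
  }
  nd <- ad_node(ctx, y, list(x), NULL)
  nd$k <- k; nd$stride <- stride; nd$pad <- pad; nd$starts <- starts
  nd$backfn <- function(g, nd) {
    d <- dim(nd$parents[[1L]]$val)
    gxp <- array(0, c(d[1L], d[2L] + 2L * nd$pad, d[3L]))
    for (t in seq_len(nd$k)) {
      idx <- nd$starts + t
      gxp[, idx, ] <- gxp[, idx, , drop = FALSE] + g / nd$k
    }
    if (nd$pad > 0L) gxp <- gxp[, (nd$pad + 1L):(nd$pad + d[2L]), , drop = FALSE]
    list(gxp)
  }
  nd
}

# negative mean cosine similarity between constant input columns (I, an L x B
# matrix) and output columns (node with L*B elements); zero-norm columns
# contribute 0
op_neg_cosine <- function(ctx, I, O) {
  Im <- I; Om <- matrix(O$val, nrow(I), ncol(I))
  ni <- sqrt(colSums(Im^2))
  no <- sqrt(colSums(Om^2))
  ok <- ni > 0 & no > 0
  B <- ncol(Im)
  cosv <- rep(0, B)
  cosv[ok] <- colSums(Im[, ok, drop = FALSE] * Om[, ok, drop = FALSE]) /
    (ni[ok] * no[ok])
  nd <- ad_node(ctx, -mean(cosv), list(O), NULL)
  nd$Im <- Im; nd$ni <- ni; nd$no <- no; nd$ok <- ok; nd$cosv <- cosv
  nd$backfn <- function(g, nd) {
    Om <- matrix(nd$parents[[1]]$val, nrow(nd$Im), ncol(nd$Im))
    B <- ncol(Om)
    gO <- matrix(0, nrow(Om), B)
    w <- which(nd$ok)
    for (b in w) {
      gO[, b] <- -(g / B) * (nd$Im[, b] / (nd$ni[b] * nd$no[b]) -
                               Om[, b] * nd$cosv[b] / nd$no[b]^2)
    }
    list(array(gO, dim1(nd$parents[[1]]$val)))
  }
  nd
}

op_axpy <- function(ctx, a, b, alpha) {
  ad_node(ctx, a$val + alpha * b$val, list(a, b),
          function(g, nd) list(g, alpha * g))
}
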
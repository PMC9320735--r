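#' @title Minimal CPU neural-network engine
#'
#' @description
#' The segmentation network runs on a small self-contained layer engine.
#' Feature maps are `(H*W) x C` matrices (pixels column-major, `p = h + H*w`),
#' convolutions use "same" zero padding with output size `ceil(in/stride)`,
#' and every layer implements an explicit backward pass so the cascade can be
#' trained with stochastic gradient descent on a plain CPU. Batch
#' normalization is computed per forward call over the pixels of the sample
#' being processed (running statistics are kept for evaluation mode) and is
#' non-affine under the package's frozen architecture flags.
#'
#' @name nn_core
#' @keywords internal
NULL

BN_EPS <- 1e-5

nn_module <- function(kind, name = kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$name <- name
  e$children <- list()
  class(e) <- "nn_module"
  e
}

# ---- convolution (+ optional batch norm + activation), fused ---------------

nn_conv <- function(cin, cout, k = 1, stride = 1, dilation = 1, groups = 1,
                    bias = FALSE, bn = TRUE, bn_affine = FALSE,
                    act = c("none", "relu", "relu6"), name = "conv") {
  act <- match.arg(act)
  if (cin %% groups != 0 || cout %% groups != 0) {
    tomseg_stop(sprintf("groups %d must divide channels %d -> %d", groups, cin, cout),
                "tomseg_spec_error")
  }
  m <- nn_module("conv", name)
  m$cin <- cin; m$cout <- cout; m$k <- k; m$stride <- stride
  m$dil <- dilation; m$groups <- groups
  m$use_bias <- bias; m$use_bn <- bn; m$affine <- bn_affine; m$act <- act
  fan_in <- k * k * cin / groups
  m$W <- matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  m$b <- if (bias) numeric(cout) else NULL
  if (bn && bn_affine) { m$gamma <- rep(1, cout); m$beta <- numeric(cout) }
  m
}

conv_fwd <- function(m, x, h, w, train) {
  r <- cpp_conv2d_fwd(x, h, w, m$W, m$k, m$stride, m$dil, m$groups)
  z <- r$y
  if (m$use_bias) z <- z + rep(m$b, each = nrow(z))
  cache <- list(x = x, h = h, w = w)
  if (m$use_bn) {
    mu <- colMeans(z)
    va <- colMeans(z * z) - mu^2
    sd <- sqrt(va + BN_EPS)
    np <- nrow(z)
    z <- (z - rep(mu, each = np)) / rep(sd, each = np)
    cache$sd <- sd; cache$yhat <- z
    if (m$affine) {
      z <- z * rep(m$gamma, each = np) + rep(m$beta, each = np)
    }
  }
  if (m$act == "relu") {
    cache$mask <- z > 0
    z <- z * cache$mask
  } else if (m$act == "relu6") {
    cache$mask <- (z > 0) & (z < 6)
    z <- pmin(pmax(z, 0), 6)
  }
  m$cache <- cache
  list(y = z, h = r$oh, w = r$ow)
}

conv_bwd <- function(m, gy) {
  cc <- m$cache
  if (m$act != "none") gy <- gy * cc$mask
  if (m$use_bn) {
    np <- nrow(gy)
    if (m$affine) {
      m$g_gamma <- m$g_gamma + colSums(gy * cc$yhat)
      m$g_beta <- m$g_beta + colSums(gy)
      gy <- gy * rep(m$gamma, each = np)
    }
    # backward through the per-call normalization
    mg <- colMeans(gy)
    mgy <- colMeans(gy * cc$yhat)
    gy <- (gy - rep(mg, each = np) - cc$yhat * rep(mgy, each = np)) /
      rep(cc$sd, each = np)
  }
  if (m$use_bias) m$gb <- m$gb + colSums(gy)
  r <- cpp_conv2d_bwd(cc$x, cc$h, cc$w, m$W, m$k, m$stride, m$dil, m$groups, gy,
                      !isTRUE(m$input_layer))
  m$gW <- m$gW + r$gw
  r$gx
}

# ---- parameter-free layers --------------------------------------------------

nn_upsample <- function(factor, name = sprintf("upsample_x%d", factor)) {
  m <- nn_module("upsample", name)
  m$factor <- factor
  m
}

bilinear_matrix <- function(n_out, n_in) {
  if (n_in == 1) return(matrix(1, n_out, 1))
  src <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
  i0 <- floor(src); frac <- src - i0
  i0c <- pmin(pmax(i0, 0), n_in - 1)
  i1c <- pmin(pmax(i0 + 1, 0), n_in - 1)
  M <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  M[cbind(idx, i0c + 1)] <- M[cbind(idx, i0c + 1)] + (1 - frac)
  M[cbind(idx, i1c + 1)] <- M[cbind(idx, i1c + 1)] + frac
  M
}

# y[oH,oW,c] = Mh %*% x[,,c] %*% t(Mw), applied to (H*W) x C storage
resample_hw <- function(x, h, w, Mh, Mw) {
  ch <- ncol(x)
  oh <- nrow(Mh); ow <- nrow(Mw)
  tMw <- t(Mw)
  out <- matrix(0, oh * ow, ch)
  for (c in seq_len(ch)) {
    out[, c] <- Mh %*% matrix(x[, c], h, w) %*% tMw
  }
  out
}

rowmax <- function(z) {
  m <- z[, 1]
  for (j in seq_len(ncol(z))[-1]) m <- pmax(m, z[, j])
  m
}

upsample_fwd <- function(m, x, h, w) {
  oh <- h * m$factor; ow <- w * m$factor
  key <- paste(h, w, sep = "x")
  if (is.null(m$key) || m$key != key) {
    m$Mh <- bilinear_matrix(oh, h); m$Mw <- bilinear_matrix(ow, w); m$key <- key
  }
  m$cache <- list(h = h, w = w)
  list(y = resample_hw(x, h, w, m$Mh, m$Mw), h = oh, w = ow)
}

upsample_bwd <- function(m, gy) {
  cc <- m$cache
  resample_hw(gy, cc$h * m$factor, cc$w * m$factor, t(m$Mh), t(m$Mw))
}

nn_dropout <- function(rate, name = sprintf("dropout_%g", rate)) {
  m <- nn_module("dropout", name)
  m$rate <- rate
  m
}

dropout_fwd <- function(m, x, h, w, train) {
  if (train && m$rate > 0) {
    keep <- 1 - m$rate
    m$cache <- (matrix(stats::runif(length(x)), nrow(x), ncol(x)) < keep) / keep
    x <- x * m$cache
  } else {
    m$cache <- NULL
  }
  list(y = x, h = h, w = w)
}

# ---- composites -------------------------------------------------------------

nn_seq <- function(children, name = "seq") {
  m <- nn_module("seq", name)
  m$children <- children
  m
}

# inverted residual bottleneck: 1x1 expand, depthwise 3x3, 1x1 project;
# identity skip iff stride 1 and cin == cout
nn_bottleneck_mod <- function(body, residual, name) {
  m <- nn_module("bottleneck", name)
  m$children <- list(body = body)
  m$residual <- residual
  m
}

# three grouped branches added together, then a 1x1 mixing conv
nn_feature_mod <- function(branches, mix, name) {
  m <- nn_module("feature", name)
  m$children <- c(branches, list(mix = mix))
  m
}

# pyramid pooling: pool at bins, 1x1-project each level, upsample, concatenate
# the levels, add the trunk, reduce 1x1
nn_ppm_mod <- function(projs, reduce, bins, name) {
  m <- nn_module("ppm", name)
  m$children <- c(projs, list(reduce = reduce))
  m$bins <- bins
  m
}

adaptive_pool_fwd <- function(x, h, w, bin) {
  # region (i,j): rows floor((i-1)h/b)+1 .. ceil(ih/b)
  rh <- lapply(seq_len(bin), function(i) (floor((i - 1) * h / bin) + 1):ceiling(i * h / bin))
  rw <- lapply(seq_len(bin), function(j) (floor((j - 1) * w / bin) + 1):ceiling(j * w / bin))
  out <- matrix(0, bin * bin, ncol(x))
  for (j in seq_len(bin)) for (i in seq_len(bin)) {
    px <- as.vector(outer(rh[[i]], (rw[[j]] - 1) * h, "+"))
    out[i + bin * (j - 1), ] <- colMeans(x[px, , drop = FALSE])
  }
  list(y = out, rh = rh, rw = rw)
}

adaptive_pool_bwd <- function(gp, h, w, bin, rh, rw, nc) {
  gx <- matrix(0, h * w, nc)
  for (j in seq_len(bin)) for (i in seq_len(bin)) {
    px <- as.vector(outer(rh[[i]], (rw[[j]] - 1) * h, "+"))
    gx[px, ] <- gx[px, ] + matrix(gp[i + bin * (j - 1), ] / length(px),
                                  length(px), nc, byrow = TRUE)
  }
  gx
}

# ---- dispatch ---------------------------------------------------------------

nn_forward <- function(m, x, h, w, train = FALSE) {
  switch(m$kind,
    conv = conv_fwd(m, x, h, w, train),
    upsample = upsample_fwd(m, x, h, w),
    dropout = dropout_fwd(m, x, h, w, train),
    seq = {
      for (ch in m$children) {
        r <- nn_forward(ch, x, h, w, train)
        x <- r$y; h <- r$h; w <- r$w
      }
      list(y = x, h = h, w = w)
    },
    bottleneck = {
      r <- nn_forward(m$children$body, x, h, w, train)
      if (m$residual) r$y <- r$y + x
      r
    },
    feature = {
      nb <- length(m$children) - 1
      acc <- NULL
      for (i in seq_len(nb)) {
        r <- nn_forward(m$children[[i]], x, h, w, train)
        acc <- if (is.null(acc)) r$y else acc + r$y
      }
      nn_forward(m$children$mix, acc, r$h, r$w, train)
    },
    ppm = {
      np <- length(m$bins)
      if (h < max(m$bins) || w < max(m$bins)) {
        tomseg_stop(sprintf(
          "pyramid pooling needs input of at least %d x %d pixels, got %d x %d",
          max(m$bins), max(m$bins), h, w), "tomseg_runtime_error")
      }
      ups <- vector("list", np)
      m$pp_cache <- vector("list", np)
      for (i in seq_len(np)) {
        b <- m$bins[i]
        p <- adaptive_pool_fwd(x, h, w, b)
        pr <- nn_forward(m$children[[i]], p$y, b, b, train)
        Mh <- bilinear_matrix(h, b); Mw <- bilinear_matrix(w, b)
        ups[[i]] <- resample_hw(pr$y, b, b, Mh, Mw)
        m$pp_cache[[i]] <- list(rh = p$rh, rw = p$rw, Mh = Mh, Mw = Mw)
      }
      s <- do.call(cbind, ups) + x     # concat levels (sum of widths = cin), add trunk
      m$hw <- c(h, w)
      nn_forward(m$children$reduce, s, h, w, train)
    },
    tomseg_stop(paste("unknown module kind:", m$kind), "tomseg_internal_error"))
}

nn_backward <- function(m, gy) {
  switch(m$kind,
    conv = conv_bwd(m, gy),
    upsample = upsample_bwd(m, gy),
    dropout = if (is.null(m$cache)) gy else gy * m$cache,
    seq = {
      for (ch in rev(m$children)) gy <- nn_backward(ch, gy)
      gy
    },
    bottleneck = {
      gx <- nn_backward(m$children$body, gy)
      if (m$residual) gx <- gx + gy
      gx
    },
    feature = {
      g <- nn_backward(m$children$mix, gy)
      nb <- length(m$children) - 1
      gx <- NULL
      for (i in seq_len(nb)) {
        gb <- nn_backward(m$children[[i]], g)
        gx <- if (is.null(gx)) gb else gx + gb
      }
      gx
    },
    ppm = {
      gs <- nn_backward(m$children$reduce, gy)
      h <- m$hw[1]; w <- m$hw[2]
      gx <- gs                       # trunk path
      off <- 0
      for (i in seq_along(m$bins)) {
        b <- m$bins[i]
        pc <- m$pp_cache[[i]]
        wch <- m$children[[i]]$cout
        gu <- gs[, off + seq_len(wch), drop = FALSE]
        gp <- resample_hw(gu, h, w, t(pc$Mh), t(pc$Mw))
        gpr <- nn_backward(m$children[[i]], gp)
        gx <- gx + adaptive_pool_bwd(gpr, h, w, b, pc$rh, pc$rw, ncol(gx))
        off <- off + wch
      }
      gx
    },
    tomseg_stop(paste("unknown module kind:", m$kind), "tomseg_internal_error"))
}

# ---- parameter bookkeeping --------------------------------------------------

collect_leaves <- function(m, out = list()) {
  if (m$kind == "conv") {
    out[[length(out) + 1]] <- m
  }
  for (ch in m$children) out <- collect_leaves(ch, out)
  out
}

zero_grads <- function(net) {
  for (m in collect_leaves(net)) {
    m$gW <- matrix(0, nrow(m$W), ncol(m$W))
    if (m$use_bias) m$gb <- numeric(m$cout)
    if (isTRUE(m$affine)) { m$g_gamma <- numeric(m$cout); m$g_beta <- numeric(m$cout) }
  }
  invisible(net)
}

sgd_step <- function(net, lr, momentum = 0.9) {
  for (m in collect_leaves(net)) {
    if (is.null(m$vW)) m$vW <- m$gW * 0
    m$vW <- momentum * m$vW - lr * m$gW
    m$W <- m$W + m$vW
    if (m$use_bias) {
      if (is.null(m$vb)) m$vb <- m$gb * 0
      m$vb <- momentum * m$vb - lr * m$gb
      m$b <- m$b + m$vb
    }
    if (isTRUE(m$affine)) {
      if (is.null(m$vgam)) { m$vgam <- numeric(m$cout); m$vbet <- numeric(m$cout) }
      m$vgam <- momentum * m$vgam - lr * m$g_gamma
      m$gamma <- m$gamma + m$vgam
      m$vbet <- momentum * m$vbet - lr * m$g_beta
      m$beta <- m$beta + m$vbet
    }
  }
  invisible(net)
}

# Nested snapshot of every trainable tensor for checkpoints.
get_weights <- function(net) {
  lapply(collect_leaves(net), function(m) {
    list(W = m$W, b = m$b, gamma = m$gamma, beta = m$beta)
  })
}

set_weights <- function(net, weights) {
  leaves <- collect_leaves(net)
  stopifnot(length(leaves) == length(weights))
  for (i in seq_along(leaves)) {
    m <- leaves[[i]]; wt <- weights[[i]]
    stopifnot(identical(dim(m$W), dim(wt$W)))
    m$W <- wt$W
    if (!is.null(wt$b)) m$b <- wt$b
    if (!is.null(wt$gamma)) { m$gamma <- wt$gamma; m$beta <- wt$beta }
  }
  invisible(net)
}

softmax_rows <- function(z) {
  e <- exp(z - rowmax(z))
  e / rowSums(e)
}
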
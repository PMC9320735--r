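#' @title Two-stage hard-pixel cascade network
#'
#' @description
#' Stage 1 is a small depthwise-separable network whose per-pixel softmax
#' confidence (the maximum class probability, "Premax") gates the cascade:
#' pixels with confidence at or below the threshold `t1` are "hard" and keep
#' their values in the stage-2 side inputs, all other ("easy") pixels are
#' zeroed there. Stage 2 consumes the full RGB image, the hard-pixel-masked
#' RGB image and the hard-pixel-masked mean-centered depth map through three
#' input convolutions concatenated at a 12:16:4 channel ratio, and produces
#' the final full-resolution four-class probability map.
#'
#' @name cascade_net
NULL

#' Cascade gating configuration
#'
#' @param t1 stage-1 confidence threshold in (0, 1); pixels with confidence
#'   `<= t1` are routed to stage 2 as hard pixels. 0.7 gave the best
#'   published results.
#' @param fusion_ratio channel widths of the three stage-2 input branches
#'   (RGB, masked RGB, masked depth).
#' @param resolution default input resolution `c(height, width)`.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(t1 = 0.7, fusion_ratio = c(12, 16, 4),
                           resolution = c(480, 640)) {
  if (!(t1 > 0 && t1 < 1)) {
    tomseg_stop("t1 must lie strictly inside (0, 1)", "tomseg_argument_error")
  }
  structure(list(t1 = t1, fusion_ratio = fusion_ratio, resolution = resolution),
            class = "cascade_config")
}

#' Per-pixel confidence of a probability map
#'
#' The maximum of the four class probabilities at each pixel; lies in
#' `[0.25, 1]` for any valid probability map.
#'
#' @param p `H x W x 4` probability array (class scores summing to 1).
#' @return `H x W` confidence matrix.
#' @export
premax <- function(p) {
  stopifnot(length(dim(p)) == 3)
  out <- matrix(p[, , 1], dim(p)[1], dim(p)[2])
  for (k in seq_len(dim(p)[3])[-1]) out <- pmax(out, matrix(p[, , k], dim(p)[1], dim(p)[2]))
  out
}

#' Hard-pixel mask from a confidence grid
#'
#' A pixel is hard when its confidence is at or below `t1` (borderline
#' pixels are routed to stage 2, which can only add information).
#'
#' @param conf `H x W` confidence matrix with values in `[0, 1]`.
#' @param t1 threshold in (0, 1).
#' @return Logical `H x W` matrix, `TRUE` = hard.
#' @export
hard_mask <- function(conf, t1 = 0.7) {
  if (!(t1 > 0 && t1 < 1)) {
    tomseg_stop("t1 must lie strictly inside (0, 1)", "tomseg_argument_error")
  }
  conf <= t1
}

#' Zero out easy pixels
#'
#' Sets every channel of the pixels marked easy (mask `FALSE`) to zero and
#' passes hard pixels through unchanged.
#'
#' @param image `H x W` matrix or `H x W x C` array.
#' @param mask logical `H x W` hard-pixel mask.
#' @return Same shape as `image`.
#' @export
mask_easy <- function(image, mask) {
  d <- dim(image)
  if (!identical(d[1:2], dim(mask))) {
    tomseg_stop("image and mask dimensions differ", "tomseg_argument_error")
  }
  if (length(d) == 2) return(image * mask)
  out <- image
  for (k in seq_len(d[3])) out[, , k] <- out[, , k] * mask
  out
}

# ---- stage builders ---------------------------------------------------------

#' Build the stage-1 network
#'
#' DSConv chain 3 -> 32 (stride 2) -> 64 (stride 2) -> 96 -> 32, a 1 x 1
#' convolution to 4 class channels, and a bilinear x4 upsample back to input
#' resolution. The caller applies the softmax.
#'
#' @param flags an [arch_variant_flags()] list.
#' @return An `nn_module`.
#' @export
build_stage1 <- function(flags = arch_variant_flags()) {
  ds1 <- make_dsconv(3, 32, k = 3, stride = 2, flags = flags, name = "s1_ds1")
  ds1$children[[1]]$input_layer <- TRUE
  nn_seq(list(
    ds1,
    make_dsconv(32, 64, k = 3, stride = 2, flags = flags, name = "s1_ds2"),
    make_dsconv(64, 96, k = 3, flags = flags, name = "s1_ds3"),
    make_dsconv(96, 32, k = 3, flags = flags, name = "s1_ds4"),
    nn_conv(32, 4, k = 1, bias = TRUE, bn = FALSE, act = "none", name = "s1_head"),
    nn_upsample(4)),
    name = "stage1")
}

#' Build the stage-2 network
#'
#' Three 3 x 3 input convolutions (RGB -> 12, masked RGB -> 16, masked
#' centered depth -> 4) concatenated to 32 channels, three stride-2
#' convolutions taking the trunk to eighth resolution (tapping C1 at quarter
#' resolution, 64 channels), the bottleneck chain, the three feature blocks,
#' pyramid pooling to 96 channels, skip fusion with C1, and the
#' classification head back to full resolution.
#'
#' @param flags an [arch_variant_flags()] list.
#' @param depth_channels 1 for the depth branch of the proposed network,
#'   3 when the third branch is fed RGB (Versions 1 and 2).
#' @return An `nn_module` of kind `stage2`; run it with the internal
#'   `stage2_forward()`.
#' @export
build_stage2 <- function(flags = arch_variant_flags(), depth_channels = 1) {
  bias <- flag_bias(flags); aff <- flag_affine(flags)
  ch <- list(
    i1 = nn_conv(3, 12, k = 3, bias = bias, bn = TRUE, bn_affine = aff,
                 act = "relu", name = "i1"),
    i2 = nn_conv(3, 16, k = 3, bias = bias, bn = TRUE, bn_affine = aff,
                 act = "relu", name = "i2"),
    i3 = nn_conv(depth_channels, 4, k = 3, bias = bias, bn = TRUE, bn_affine = aff,
                 act = "relu", name = "i3"),
    down0 = nn_conv(32, 32, k = 3, stride = 2, bias = bias, bn = TRUE,
                    bn_affine = aff, act = "relu", name = "down0"),
    c1 = nn_conv(32, 64, k = 3, stride = 2, bias = bias, bn = TRUE,
                 bn_affine = aff, act = "relu", name = "c1"),
    down1 = nn_conv(64, 64, k = 3, stride = 2, bias = bias, bn = TRUE,
                    bn_affine = aff, act = "relu", name = "down1"),
    bottlenecks = if (flags$bottleneck_chain == "collapsed") {
      nn_seq(list(make_bottleneck(6, 64, 64, flags = flags, name = "bneck1"),
                  make_bottleneck(5, 64, 64, flags = flags, name = "bneck2"),
                  make_bottleneck(4, 64, 64, flags = flags, name = "bneck3")),
             name = "bottlenecks")
    } else {
      nn_seq(list(make_bottleneck(6, 64, 64, flags = flags, name = "bneck1"),
                  make_bottleneck(5, 64, 96, flags = flags, name = "bneck2"),
                  make_bottleneck(4, 96, 96, flags = flags, name = "bneck3"),
                  nn_conv(96, 64, k = 1, bias = bias, bn = TRUE, bn_affine = aff,
                          act = "relu", name = "bneck_exit")),
             name = "bottlenecks")
    },
    features = nn_seq(list(make_feature_block("s1", flags),
                           make_feature_block("s2", flags),
                           make_feature_block("d", flags)),
                      name = "features"),
    ppm = make_ppm(96, 96, flags),
    up2 = nn_upsample(2))
  if (flags$skip_fusion == "project-and-add") {
    ch$fuse_proj <- nn_conv(64, 96, k = 1, bias = bias, bn = TRUE, bn_affine = aff,
                            act = "none", name = "fuse_proj")
  }
  ch$classify <- make_classify(flags)
  for (nm in c("i1", "i2", "i3")) ch[[nm]]$input_layer <- TRUE
  m <- nn_module("stage2")
  m$children <- ch
  m$fusion <- flags$skip_fusion
  m
}

stage2_forward <- function(s2, xrgb, mrgb, mdep, h, w, train = FALSE) {
  ch <- s2$children
  r1 <- nn_forward(ch$i1, xrgb, h, w, train)
  r2 <- nn_forward(ch$i2, mrgb, h, w, train)
  r3 <- nn_forward(ch$i3, mdep, h, w, train)
  x <- cbind(r1$y, r2$y, r3$y)
  d0 <- nn_forward(ch$down0, x, h, w, train)
  c1 <- nn_forward(ch$c1, d0$y, d0$h, d0$w, train)
  d1 <- nn_forward(ch$down1, c1$y, c1$h, c1$w, train)
  b <- nn_forward(ch$bottlenecks, d1$y, d1$h, d1$w, train)
  f <- nn_forward(ch$features, b$y, b$h, b$w, train)
  p <- nn_forward(ch$ppm, f$y, f$h, f$w, train)
  u <- nn_forward(ch$up2, p$y, p$h, p$w, train)
  if (s2$fusion == "concatenate") {
    fx <- cbind(c1$y, u$y)
  } else {
    pj <- nn_forward(ch$fuse_proj, c1$y, c1$h, c1$w, train)
    fx <- pj$y + u$y
  }
  s2$split <- c(ncol(r1$y), ncol(r2$y), ncol(r3$y))
  nn_forward(ch$classify, fx, c1$h, c1$w, train)
}

stage2_backward <- function(s2, gy) {
  ch <- s2$children
  g <- nn_backward(ch$classify, gy)
  if (s2$fusion == "concatenate") {
    gc1a <- g[, 1:64, drop = FALSE]
    gu <- g[, -(1:64), drop = FALSE]
  } else {
    gc1a <- nn_backward(ch$fuse_proj, g)
    gu <- g
  }
  gp <- nn_backward(ch$up2, gu)
  gf <- nn_backward(ch$ppm, gp)
  gb <- nn_backward(ch$features, gf)
  gd1 <- nn_backward(ch$bottlenecks, gb)
  gc1 <- nn_backward(ch$down1, gd1) + gc1a
  gd0 <- nn_backward(ch$c1, gc1)
  gx <- nn_backward(ch$down0, gd0)
  sp <- s2$split
  nn_backward(ch$i1, gx[, seq_len(sp[1]), drop = FALSE])
  nn_backward(ch$i2, gx[, sp[1] + seq_len(sp[2]), drop = FALSE])
  nn_backward(ch$i3, gx[, sp[1] + sp[2] + seq_len(sp[3]), drop = FALSE])
  invisible(NULL)
}

# ---- model assembly ---------------------------------------------------------

#' Build a network variant
#'
#' `"proposed"` is the full two-stage cascade with the depth branch, `"v2"`
#' replaces the masked-depth input with the masked RGB image (two stages, no
#' depth), and `"v1"` is the stage-2 structure alone run on RGB only (no
#' gating, single forward pass).
#'
#' @param which `"proposed"`, `"v1"` or `"v2"`.
#' @param flags an [arch_variant_flags()] list.
#' @param seed integer seed for weight initialization.
#' @param config a [cascade_config()].
#' @return A list of class `tomseg_model` with elements `variant`, `flags`,
#'   `config`, `stage1` (absent for v1) and `stage2`.
#' @export
build_variant <- function(which = c("proposed", "v1", "v2"),
                          flags = arch_variant_flags(), seed = 1,
                          config = cascade_config()) {
  which <- match.arg(which)
  with_seed(seed, {
    stage1 <- if (which != "v1") build_stage1(flags) else NULL
    stage2 <- build_stage2(flags, depth_channels = if (which == "proposed") 1 else 3)
    structure(list(variant = which, flags = flags, config = config,
                   stage1 = stage1, stage2 = stage2),
              class = "tomseg_model")
  })
}

#' @export
print.tomseg_model <- function(x, ...) {
  pc <- count_params(x)
  cat(sprintf("<tomseg_model '%s'> %s trainable parameters, t1 = %g\n",
              x$variant, format(pc$total, big.mark = ","), x$config$t1))
  invisible(x)
}

model_modules <- function(model) {
  mods <- model$stage2$children
  if (!is.null(model$stage1)) mods <- c(list(stage1 = model$stage1), mods)
  m <- nn_module("model")
  m$children <- mods
  m
}

# count_params() support for an assembled model
#' @rdname count_params
#' @export
count_params.tomseg_model <- function(block) count_params.default(model_modules(block))

# helpers between H x W x C arrays and (H*W) x C storage
flat_to_map <- function(x, h, w) array(x, c(h, w, ncol(x)))
map_to_flat <- function(a) matrix(a, nrow = dim(a)[1] * dim(a)[2], ncol = dim(a)[3])

pad_to_multiple <- function(mat_or_arr, m = 8) {
  d <- dim(mat_or_arr)
  h <- d[1]; w <- d[2]
  ph <- ceiling(h / m) * m; pw <- ceiling(w / m) * m
  if (ph == h && pw == w) return(mat_or_arr)
  if (length(d) == 2) {
    out <- matrix(0, ph, pw)
    out[1:h, 1:w] <- mat_or_arr
  } else {
    out <- array(0, c(ph, pw, d[3]))
    out[1:h, 1:w, ] <- mat_or_arr
  }
  out
}

# normalized network inputs for one sample: RGB in [0,1], centered depth in m
prepare_inputs <- function(sample) {
  rgb <- pad_to_multiple(sample$rgb / 255)
  dep <- pad_to_multiple(center_depth(sample$depth) / 1000)
  list(rgb = rgb, depth = dep, h = dim(rgb)[1], w = dim(rgb)[2],
       orig = dim(sample$depth))
}

stage1_probs <- function(model, xflat, h, w, train = FALSE) {
  r <- nn_forward(model$stage1, xflat, h, w, train)
  list(logits = r$y, probs = softmax_rows(r$y), h = r$h, w = r$w)
}

# full cascade forward for one prepared sample; returns stage-2 logits and
# the gating artifacts
cascade_forward <- function(model, prep, t1 = model$config$t1, train = FALSE) {
  xrgb <- map_to_flat(prep$rgb)
  h <- prep$h; w <- prep$w
  if (model$variant == "v1") {
    logits <- stage2_forward(model$stage2, xrgb, xrgb, xrgb, h, w, train)
    return(list(logits = logits$y, p1 = NULL, hard = NULL))
  }
  s1 <- stage1_probs(model, xrgb, h, w, train = FALSE)
  conf <- matrix(rowmax(s1$probs), h, w)
  hard <- if (t1 <= 0) matrix(FALSE, h, w) else hard_mask(conf, t1)
  mrgb <- map_to_flat(mask_easy(prep$rgb, hard))
  third <- if (model$variant == "proposed") {
    matrix(mask_easy(prep$depth, hard), ncol = 1)
  } else {
    mrgb
  }
  logits <- stage2_forward(model$stage2, xrgb, mrgb, third, h, w, train)
  list(logits = logits$y, p1 = s1$probs, hard = hard, conf = conf,
       mrgb = mrgb, third = third, xrgb = xrgb)
}

#' Segment one RGB-D sample with the cascade
#'
#' Runs stage 1, derives the hard-pixel mask at threshold `t1`, masks the
#' stage-2 side inputs, runs stage 2 and returns the per-pixel argmax label
#' map together with the cascade diagnostics (stage-1 probability map,
#' confidence grid and hard-pixel mask).
#'
#' @param model a [build_variant()] model (weights trained or initialized).
#' @param sample an [rgbd_sample()]; the label component is not used.
#' @param t1 gating threshold; defaults to the model's configuration. `0`
#'   disables the cascade inputs (all pixels easy).
#' @return A list with `label` (`H x W` integer map over `{0,1,2,3}`),
#'   `probs` (`H x W x 4` array) and `diagnostics` (list with `stage1_probs`,
#'   `confidence`, `hard_mask`, `n_hard`).
#' @export
predict_sample <- function(model, sample, t1 = model$config$t1) {
  stopifnot(inherits(model, "tomseg_model"), inherits(sample, "rgbd_sample"))
  prep <- prepare_inputs(sample)
  r <- cascade_forward(model, prep, t1 = t1, train = FALSE)
  probs <- softmax_rows(r$logits)
  h <- prep$h; w <- prep$w
  oh <- prep$orig[1]; ow <- prep$orig[2]
  parr <- flat_to_map(probs, h, w)[seq_len(oh), seq_len(ow), , drop = FALSE]
  lab <- matrix(max.col(probs, ties.method = "first") - 1L, h, w)[seq_len(oh), seq_len(ow)]
  diag <- if (is.null(r$p1)) NULL else list(
    stage1_probs = flat_to_map(r$p1, h, w)[seq_len(oh), seq_len(ow), , drop = FALSE],
    confidence = r$conf[seq_len(oh), seq_len(ow)],
    hard_mask = r$hard[seq_len(oh), seq_len(ow)],
    n_hard = sum(r$hard))
  list(label = lab, probs = parr, diagnostics = diag)
}
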
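#' @title Network building blocks and exact parameter accounting
#'
#' @description
#' Constructors for every block of the two-stage cascade: depthwise-separable
#' convolutions (DSConv), inverted bottleneck residual blocks, the three
#' multi-kernel grouped "feature" blocks, the pyramid pooling module and the
#' classification head. The printed architecture tables leave several details
#' ambiguous (bias placement, normalization affinity, the feature-branch
#' convolution style, one non-dividing group count, the bottleneck channel
#' chain, and the skip-fusion form); [arch_variant_flags()] enumerates those
#' resolutions and [resolve_variant()] arbitrates them against the published
#' trainable-parameter totals.
#'
#' @name net_blocks
NULL

#' Architecture ambiguity flags
#'
#' Each field resolves one ambiguity in the printed block tables. The
#' defaults are the combination frozen by [resolve_variant()] against the
#' published parameter counts (680,760 proposed / 680,832 for the
#' depth-free Version 2).
#'
#' @param conv_bias `"off-before-norm"` (convolutions feeding a
#'   normalization layer carry no bias; bare output heads keep theirs) or
#'   `"on"` (every convolution has a bias).
#' @param norm_affine whether batch-normalization layers carry trainable
#'   scale/shift pairs (`"on"`) or are pure normalizations (`"off"`).
#' @param dsconv_style_in_feature_blocks `"grouped-plus-pointwise"` (each
#'   feature branch is a grouped k x k convolution followed by a 1 x 1
#'   channel mixer, the depthwise-separable reading) or
#'   `"grouped-conv-only"`.
#' @param s1_third_branch_groups group count of the third (7 x 7) branch of
#'   Feature_s1; the printed 26 does not divide 64, so 16 (the w/4 pattern of
#'   the sibling tables) or 32 stand in.
#' @param bottleneck_chain `"collapsed"` (three bottlenecks 64 -> 64,
#'   matching the 64-channel input of Feature_s1) or `"as-printed"`
#'   (64 -> 96 -> 96 with a 1 x 1 entry projection back to 64).
#' @param skip_fusion how the quarter-resolution trunk tap C1 (64 ch) meets
#'   the pyramid output C2 (96 ch at eighth resolution, upsampled x2):
#'   `"concatenate"` (160 channels into the classifier) or
#'   `"project-and-add"` (project C1 to 96 and add).
#' @param final_upsample `"x4-from-quarter"` (classifier upsamples x4 from
#'   quarter resolution) or `"x8-from-eighth"`.
#' @param dilation_mapping reading of the Feature_d dilation column 0/1/2:
#'   `"offset-by-one"` (rates 1/2/3) or `"literal-with-0-as-1"` (rates
#'   1/1/2). Does not change parameter counts.
#' @return A named list of class `arch_variant_flags`.
#' @export
arch_variant_flags <- function(conv_bias = c("off-before-norm", "on"),
                               norm_affine = c("off", "on"),
                               dsconv_style_in_feature_blocks =
                                 c("grouped-plus-pointwise", "grouped-conv-only"),
                               s1_third_branch_groups = 16,
                               bottleneck_chain = c("collapsed", "as-printed"),
                               skip_fusion = c("concatenate", "project-and-add"),
                               final_upsample = c("x4-from-quarter", "x8-from-eighth"),
                               dilation_mapping = c("offset-by-one", "literal-with-0-as-1")) {
  flags <- list(conv_bias = match.arg(conv_bias),
                norm_affine = match.arg(norm_affine),
                dsconv_style_in_feature_blocks = match.arg(dsconv_style_in_feature_blocks),
                s1_third_branch_groups = s1_third_branch_groups,
                bottleneck_chain = match.arg(bottleneck_chain),
                skip_fusion = match.arg(skip_fusion),
                final_upsample = match.arg(final_upsample),
                dilation_mapping = match.arg(dilation_mapping))
  if (!flags$s1_third_branch_groups %in% c(16, 32)) {
    tomseg_stop("s1_third_branch_groups must be 16 or 32 (printed 26 does not divide 64)",
                "tomseg_spec_error")
  }
  structure(flags, class = "arch_variant_flags")
}

flag_bias <- function(flags) flags$conv_bias == "on"
flag_affine <- function(flags) flags$norm_affine == "on"

#' Depthwise-separable convolution block
#'
#' A grouped k x k spatial convolution (depthwise when `groups = cin`)
#' followed by a 1 x 1 pointwise mixer, each with batch normalization and
#' rectification. Output spatial size is `ceil(input / stride)`.
#'
#' @param cin,cout input/output channel counts.
#' @param k kernel size (odd).
#' @param stride 1 or 2.
#' @param flags an [arch_variant_flags()] list.
#' @param groups group count of the spatial convolution (default depthwise).
#' @param dilation dilation rate of the spatial convolution.
#' @param name block name used in parameter breakdowns.
#' @return An `nn_module`.
#' @export
make_dsconv <- function(cin, cout, k = 3, stride = 1, flags = arch_variant_flags(),
                        groups = cin, dilation = 1, name = "dsconv") {
  nn_seq(list(
    nn_conv(cin, cin, k = k, stride = stride, dilation = dilation, groups = groups,
            bias = flag_bias(flags), bn = TRUE, bn_affine = flag_affine(flags),
            act = "relu", name = paste0(name, "_dw")),
    nn_conv(cin, cout, k = 1, bias = flag_bias(flags), bn = TRUE,
            bn_affine = flag_affine(flags), act = "relu",
            name = paste0(name, "_pw"))), name = name)
}

#' Inverted bottleneck residual block
#'
#' 1 x 1 expansion to `t * cin` channels, depthwise 3 x 3 (stride `s`),
#' 1 x 1 projection to `cout`. The clipped rectifier (relu6) follows the
#' expansion and depthwise stages; the projection is linear. An identity
#' skip is added iff `s = 1` and `cin = cout`.
#'
#' @param t expansion factor (>= 1).
#' @param cin,cout channel counts.
#' @param s stride of the depthwise stage.
#' @param flags an [arch_variant_flags()] list.
#' @param name block name.
#' @return An `nn_module`.
#' @export
make_bottleneck <- function(t, cin, cout, s = 1, flags = arch_variant_flags(),
                            name = "bottleneck") {
  if (t < 1) tomseg_stop("expansion factor t must be >= 1", "tomseg_spec_error")
  e <- t * cin
  body <- nn_seq(list(
    nn_conv(cin, e, k = 1, bias = flag_bias(flags), bn = TRUE,
            bn_affine = flag_affine(flags), act = "relu6", name = paste0(name, "_expand")),
    nn_conv(e, e, k = 3, stride = s, groups = e, bias = flag_bias(flags), bn = TRUE,
            bn_affine = flag_affine(flags), act = "relu6", name = paste0(name, "_dw")),
    nn_conv(e, cout, k = 1, bias = flag_bias(flags), bn = TRUE,
            bn_affine = flag_affine(flags), act = "none", name = paste0(name, "_project"))),
    name = paste0(name, "_body"))
  nn_bottleneck_mod(body, residual = (s == 1 && cin == cout), name = name)
}

feature_spec <- function(which, flags) {
  switch(which,
    s1 = list(width = 64, groups = c(64, 32, flags$s1_third_branch_groups),
              out = 128, dil = c(1, 1, 1)),
    s2 = list(width = 128, groups = c(128, 64, 32), out = 256, dil = c(1, 1, 1)),
    d  = list(width = 256, groups = c(256, 128, 64), out = 96,
              dil = if (flags$dilation_mapping == "offset-by-one") c(1, 2, 3)
                    else c(1, 1, 2)),
    tomseg_stop("feature block must be one of s1, s2, d", "tomseg_spec_error"))
}

#' Multi-kernel grouped feature block
#'
#' Three parallel grouped convolutions with kernels 3/5/7 and decreasing
#' group counts are summed elementwise, then a 1 x 1 convolution mixes the
#' result to the block's output width. `Feature_d` additionally dilates its
#' branches. Instead of widening the network, the blocks vary kernel, group
#' and dilation size to diversify features at constant width.
#'
#' @param which `"s1"` (64 ch), `"s2"` (128 ch) or `"d"` (256 ch, dilated).
#' @param flags an [arch_variant_flags()] list.
#' @return An `nn_module`.
#' @export
make_feature_block <- function(which = c("s1", "s2", "d"), flags = arch_variant_flags()) {
  which <- match.arg(which)
  sp <- feature_spec(which, flags)
  name <- paste0("feature_", which)
  branches <- lapply(1:3, function(i) {
    k <- c(3, 5, 7)[i]
    bname <- sprintf("%s_x%d", name, i)
    if (flags$dsconv_style_in_feature_blocks == "grouped-plus-pointwise") {
      make_dsconv(sp$width, sp$width, k = k, flags = flags, groups = sp$groups[i],
                  dilation = sp$dil[i], name = bname)
    } else {
      nn_seq(list(nn_conv(sp$width, sp$width, k = k, groups = sp$groups[i],
                          dilation = sp$dil[i], bias = flag_bias(flags), bn = TRUE,
                          bn_affine = flag_affine(flags), act = "relu", name = bname)),
             name = bname)
    }
  })
  mix <- nn_conv(sp$width, sp$out, k = 1, bias = flag_bias(flags), bn = TRUE,
                 bn_affine = flag_affine(flags), act = "relu",
                 name = paste0(name, "_mix"))
  nn_feature_mod(branches, mix, name = name)
}

#' Pyramid pooling module
#'
#' Pools the trunk at bin sizes 1, 2, 3 and 6, projects each pooled level
#' with a 1 x 1 convolution to `cin / 4` channels, upsamples bilinearly to
#' the trunk size, concatenates the levels (restoring `cin` channels), adds
#' the trunk, and reduces with a 1 x 1 convolution to `cout`. Captures the
#' global context that separates visually similar plant parts.
#'
#' @param cin trunk channel count (divisible by 4).
#' @param cout output channel count.
#' @param flags an [arch_variant_flags()] list.
#' @param bins pooling grid sizes.
#' @return An `nn_module`.
#' @export
make_ppm <- function(cin = 96, cout = 96, flags = arch_variant_flags(),
                     bins = c(1, 2, 3, 6)) {
  if (cin %% length(bins) != 0) {
    tomseg_stop("trunk channels must be divisible by the number of pyramid bins",
                "tomseg_spec_error")
  }
  proj_w <- cin / length(bins)
  projs <- lapply(seq_along(bins), function(i)
    nn_conv(cin, proj_w, k = 1, bias = flag_bias(flags), bn = TRUE,
            bn_affine = flag_affine(flags), act = "relu",
            name = sprintf("ppm_proj%d", bins[i])))
  reduce <- nn_conv(cin, cout, k = 1, bias = flag_bias(flags), bn = TRUE,
                    bn_affine = flag_affine(flags), act = "relu", name = "ppm_reduce")
  nn_ppm_mod(projs, reduce, bins, name = "ppm")
}

#' Classification head
#'
#' Two depthwise-separable 3 x 3 convolutions (to 64 then 32 channels), a
#' bilinear x4 upsample, dropout at rate 0.1 (training mode only) and a
#' 1 x 1 convolution to the 4 class channels.
#'
#' @param flags an [arch_variant_flags()] list.
#' @param cin input channel count; defaults to the fusion output implied by
#'   `flags$skip_fusion` (160 for concatenation, 96 for project-and-add).
#' @return An `nn_module`.
#' @export
make_classify <- function(flags = arch_variant_flags(),
                          cin = if (flags$skip_fusion == "concatenate") 160 else 96) {
  nn_seq(list(
    make_dsconv(cin, 64, k = 3, flags = flags, name = "classify_ds1"),
    make_dsconv(64, 32, k = 3, flags = flags, name = "classify_ds2"),
    nn_upsample(4),
    nn_dropout(0.1),
    nn_conv(32, 4, k = 1, bias = TRUE, bn = FALSE, act = "none",
            name = "classify_head")),
    name = "classify")
}

# ---- parameter counting -----------------------------------------------------

#' Count trainable parameters of a block or network
#'
#' Counts every trainable entry: convolution kernels, enabled biases and
#' normalization affine pairs. Running statistics of normalization layers
#' are not trainable and are excluded.
#'
#' @param block an `nn_module` (any block or assembled network).
#' @return A list of class `param_count` with `total` and a named
#'   `breakdown` vector (one entry per top-level block).
#' @export
count_params <- function(block) UseMethod("count_params")

#' @rdname count_params
#' @export
count_params.default <- function(block) {
  leaf_count <- function(m) {
    n <- length(m$W) + length(m$b)
    if (isTRUE(m$affine)) n <- n + length(m$gamma) + length(m$beta)
    n
  }
  per_block <- vapply(
    if (length(block$children)) block$children else list(block),
    function(ch) sum(vapply(collect_leaves(ch), leaf_count, numeric(1))),
    numeric(1))
  names(per_block) <- vapply(
    if (length(block$children)) block$children else list(block),
    function(ch) ch$name, character(1))
  structure(list(total = sum(per_block), breakdown = per_block),
            class = "param_count")
}

#' @export
print.param_count <- function(x, ...) {
  cat(sprintf("total trainable parameters: %s\n", format(x$total, big.mark = ",")))
  for (i in seq_along(x$breakdown)) {
    cat(sprintf("  %-18s %10s\n", names(x$breakdown)[i],
                format(x$breakdown[i], big.mark = ",")))
  }
  invisible(x)
}

# Closed-form per-block parameter counts; must agree with count_params() on
# instantiated networks (property-tested).
conv_n <- function(k, cin, cout, g, bias, affine, bn = TRUE) {
  n <- k * k * (cin / g) * cout
  if (bias) n <- n + cout
  if (bn && affine) n <- n + 2 * cout
  n
}

variant_param_formula <- function(which = c("proposed", "v1", "v2"),
                                  flags = arch_variant_flags()) {
  which <- match.arg(which)
  bias <- flag_bias(flags); aff <- flag_affine(flags)
  ds <- function(k, cin, cout, g = cin) {
    conv_n(k, cin, cin, g, bias, aff) + conv_n(1, cin, cout, 1, bias, aff)
  }
  bott <- function(t, cin, cout) {
    e <- t * cin
    conv_n(1, cin, e, 1, bias, aff) + conv_n(3, e, e, e, bias, aff) +
      conv_n(1, e, cout, 1, bias, aff)
  }
  feat <- function(which_f) {
    sp <- feature_spec(which_f, flags)
    br <- sum(vapply(1:3, function(i) {
      k <- c(3, 5, 7)[i]
      if (flags$dsconv_style_in_feature_blocks == "grouped-plus-pointwise") {
        ds(k, sp$width, sp$width, sp$groups[i])
      } else {
        conv_n(k, sp$width, sp$width, sp$groups[i], bias, aff)
      }
    }, numeric(1)))
    br + conv_n(1, sp$width, sp$out, 1, bias, aff)
  }
  stage1 <- ds(3, 3, 32) + ds(3, 32, 64) + ds(3, 64, 96) + ds(3, 96, 32) +
    conv_n(1, 32, 4, 1, bias = TRUE, affine = FALSE, bn = FALSE)
  depth_in <- if (which == "proposed") 1 else 3
  inputs <- conv_n(3, 3, 12, 1, bias, aff) + conv_n(3, 3, 16, 1, bias, aff) +
    conv_n(3, depth_in, 4, 1, bias, aff)
  trunk <- conv_n(3, 32, 32, 1, bias, aff) + conv_n(3, 32, 64, 1, bias, aff) +
    conv_n(3, 64, 64, 1, bias, aff)
  bneck <- if (flags$bottleneck_chain == "collapsed") {
    bott(6, 64, 64) + bott(5, 64, 64) + bott(4, 64, 64)
  } else {
    bott(6, 64, 64) + bott(5, 64, 96) + bott(4, 96, 96) + conv_n(1, 96, 64, 1, bias, aff)
  }
  features <- c(feature_s1 = feat("s1"), feature_s2 = feat("s2"), feature_d = feat("d"))
  ppm <- 4 * conv_n(1, 96, 24, 1, bias, aff) + conv_n(1, 96, 96, 1, bias, aff)
  if (flags$skip_fusion == "concatenate") {
    fusion <- 0; cls_in <- 160
  } else {
    fusion <- conv_n(1, 64, 96, 1, bias, aff); cls_in <- 96
  }
  classify <- ds(3, cls_in, 64) + ds(3, 64, 32) +
    conv_n(1, 32, 4, 1, bias = TRUE, affine = FALSE, bn = FALSE)
  out <- c(stage1 = stage1, stage2_inputs = inputs, stage2_trunk = trunk,
           bottlenecks = bneck, features, ppm = ppm, fusion = fusion,
           classify = classify)
  if (which == "v1") out <- out[names(out) != "stage1"]
  out
}

#' Enumerate architecture flags and arbitrate against published totals
#'
#' Builds the closed-form parameter count of every combination of
#' [arch_variant_flags()] and compares it with target totals (by default the
#' published 680,760 for the proposed network and 680,832 for Version 2).
#' If one or more combinations match every target exactly they are returned;
#' otherwise the combinations nearest in maximum relative deviation are
#' returned together with a per-block delta report, so a typo in the printed
#' tables degrades the match transparently instead of silently.
#'
#' @param targets named numeric vector of target totals; names from
#'   `"proposed"`, `"v1"`, `"v2"`.
#' @return A list of class `variant_resolution`: `exact` (logical), `flags`
#'   (best flag set), `candidates` (data frame of all combinations with
#'   totals and deviations), and `report` (character lines with per-block
#'   deltas of the best candidate).
#' @export
resolve_variant <- function(targets = c(proposed = 680760, v2 = 680832)) {
  if (!length(targets)) tomseg_stop("targets must be non-empty", "tomseg_argument_error")
  grid <- expand.grid(conv_bias = c("off-before-norm", "on"),
                      norm_affine = c("off", "on"),
                      dsconv_style_in_feature_blocks =
                        c("grouped-plus-pointwise", "grouped-conv-only"),
                      s1_third_branch_groups = c(16, 32),
                      bottleneck_chain = c("collapsed", "as-printed"),
                      skip_fusion = c("concatenate", "project-and-add"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fl <- do.call(arch_variant_flags, as.list(grid[i, ]))
    tot <- vapply(names(targets), function(v)
      sum(variant_param_formula(v, fl)), numeric(1))
    list(flags = fl, totals = tot,
         maxrel = max(abs(tot - targets) / targets))
  })
  totals <- t(vapply(res, `[[`, numeric(length(targets)), "totals"))
  colnames(totals) <- names(targets)
  cand <- cbind(grid, totals,
                maxrel = vapply(res, `[[`, numeric(1), "maxrel"))
  cand <- cand[order(cand$maxrel), ]
  best <- res[[as.integer(rownames(cand)[1])]]
  exact <- best$maxrel == 0
  report <- c(
    sprintf("variant arbitration against targets: %s",
            paste(sprintf("%s=%d", names(targets), targets), collapse = ", ")),
    sprintf("exact match found: %s", exact),
    sprintf("best flags: %s",
            paste(sprintf("%s=%s", names(best$flags), unlist(best$flags)),
                  collapse = "; ")),
    unname(vapply(names(targets), function(v) {
      sprintf("  %s: counted %d, target %d, delta %+d", v,
              as.integer(best$totals[v]), as.integer(targets[v]),
              as.integer(best$totals[v] - targets[v]))
    }, character(1))),
    "per-block breakdown of best candidate (proposed reading):")
  bd <- variant_param_formula(if ("proposed" %in% names(targets)) "proposed"
                              else names(targets)[1], best$flags)
  report <- c(report, sprintf("  %-18s %8d", names(bd), as.integer(bd)))
  structure(list(exact = exact, flags = best$flags, candidates = cand,
                 report = report),
            class = "variant_resolution")
}

#' @export
print.variant_resolution <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}
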
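ns <- asNamespace("tomseg")

test_that("DSConv halves spatial size at stride 2 and counts 193 parameters", {
  flags_affine <- arch_variant_flags(norm_affine = "on")
  blk <- tomseg:::with_seed(1, make_dsconv(3, 32, k = 3, stride = 2, flags = flags_affine))
  # depthwise 27 + pointwise 96 + two non-affine-free norms (2*3 + 2*32)
  expect_equal(count_params(blk)$total, 27 + 96 + 2 * 3 + 2 * 32)
  x <- matrix(rnorm(120 * 160 * 3), 120 * 160, 3)
  r <- ns$nn_forward(blk, x, 120, 160, train = TRUE)
  expect_equal(c(r$h, r$w, ncol(r$y)), c(60, 80, 32))
  blk1 <- tomseg:::with_seed(1, make_dsconv(8, 8, k = 3, stride = 1))
  r1 <- ns$nn_forward(blk1, matrix(rnorm(30 * 40 * 8), 1200, 8), 30, 40, TRUE)
  expect_equal(c(r1$h, r1$w), c(30, 40))
})

test_that("stride-2 blocks take the ceiling of odd input sizes", {
  blk <- tomseg:::with_seed(2, make_dsconv(4, 4, k = 3, stride = 2))
  r <- ns$nn_forward(blk, matrix(rnorm(15 * 21 * 4), 315, 4), 15, 21, TRUE)
  expect_equal(c(r$h, r$w), c(8, 11))
})

test_that("bottleneck residual connection follows the shape rule", {
  b1 <- make_bottleneck(6, 64, 64, s = 1)
  expect_true(b1$residual)
  b2 <- make_bottleneck(5, 64, 96, s = 1)
  expect_false(b2$residual)
  b3 <- make_bottleneck(4, 16, 16, s = 2)
  expect_false(b3$residual)
  # parameter count equals exhaustive entry enumeration of the layers:
  # expand 96*384 + dw 9*384 + project 384*96 (biases off, norms non-affine)
  expect_equal(count_params(make_bottleneck(4, 96, 96))$total, 77184)
  tot <- sum(vapply(ns$collect_leaves(make_bottleneck(4, 96, 96)),
                    function(m) length(m$W) + length(m$b), numeric(1)))
  expect_equal(tot, 77184)
})

test_that("feature blocks mix three grouped branches to the table widths", {
  fs2 <- tomseg:::with_seed(3, make_feature_block("s2"))
  x <- matrix(rnorm(12 * 16 * 128), 192, 128)
  r <- ns$nn_forward(fs2, x, 12, 16, TRUE)
  expect_equal(ncol(r$y), 256)
  expect_equal(c(r$h, r$w), c(12, 16))
  # zeroed branches leave only the (bias-free, normalized) mixer response: 0
  fz <- tomseg:::with_seed(4, make_feature_block("s1"))
  for (i in 1:3) {
    for (m in ns$collect_leaves(fz$children[[i]])) m$W[] <- 0
  }
  rz <- ns$nn_forward(fz, matrix(rnorm(64 * 64), 64, 64), 8, 8, TRUE)
  expect_true(all(rz$y == 0))
  # dilation reading does not change the parameter count
  f_a <- make_feature_block("d", arch_variant_flags(dilation_mapping = "offset-by-one"))
  f_b <- make_feature_block("d", arch_variant_flags(dilation_mapping = "literal-with-0-as-1"))
  expect_equal(count_params(f_a)$total, count_params(f_b)$total)
  expect_error(make_feature_block("s1", arch_variant_flags(s1_third_branch_groups = 26)),
               class = "tomseg_spec_error")
})

test_that("pyramid pooling keeps spatial size and the stage-2 output width", {
  ppm <- tomseg:::with_seed(5, make_ppm(96, 96))
  x <- matrix(rnorm(8 * 10 * 96), 80, 96)
  r <- ns$nn_forward(ppm, x, 8, 10, TRUE)
  expect_equal(c(r$h, r$w, ncol(r$y)), c(8, 10, 96))
  expect_error(ns$nn_forward(ppm, matrix(rnorm(4 * 4 * 96), 16, 96), 4, 4, TRUE),
               "at least", class = "tomseg_runtime_error")
  # constant input pools to the same constant at every pyramid level
  pool <- ns$adaptive_pool_fwd(matrix(5, 36, 2), 6, 6, 3)
  expect_true(all(pool$y == 5))
})

test_that("the classification head is deterministic in evaluation mode only", {
  cls <- tomseg:::with_seed(6, make_classify(cin = 96))
  x <- matrix(rnorm(8 * 10 * 96), 80, 96)
  e1 <- ns$nn_forward(cls, x, 8, 10, FALSE)
  e2 <- ns$nn_forward(cls, x, 8, 10, FALSE)
  expect_identical(e1$y, e2$y)
  expect_equal(ncol(e1$y), 4)
  expect_equal(c(e1$h, e1$w), c(32, 40))
  set.seed(1)
  t1 <- ns$nn_forward(cls, x, 8, 10, TRUE)
  t2 <- ns$nn_forward(cls, x, 8, 10, TRUE)
  expect_false(identical(t1$y, t2$y))   # dropout active
})

test_that("parameter counting matches the closed-form accounting", {
  single <- ns$nn_conv(1, 4, k = 1, bias = TRUE, bn = FALSE)
  expect_equal(count_params(single)$total, 8)
  for (fl in list(arch_variant_flags(),
                  arch_variant_flags(conv_bias = "on", norm_affine = "on"),
                  arch_variant_flags(bottleneck_chain = "as-printed",
                                     skip_fusion = "project-and-add",
                                     s1_third_branch_groups = 32),
                  arch_variant_flags(dsconv_style_in_feature_blocks =
                                       "grouped-conv-only"))) {
    for (v in c("proposed", "v2", "v1")) {
      built <- count_params(build_variant(v, fl, seed = 0))$total
      expect_equal(built, sum(ns$variant_param_formula(v, fl)),
                   info = paste(v, fl$conv_bias, fl$bottleneck_chain))
    }
  }
})

test_that("variant arbitration lands within half a percent of both printed totals", {
  res <- resolve_variant()
  expect_s3_class(res, "variant_resolution")
  expect_true(nrow(res$candidates) > 10)
  expect_lt(res$candidates$maxrel[1], 0.005)
  tot_p <- sum(ns$variant_param_formula("proposed", res$flags))
  tot_v2 <- sum(ns$variant_param_formula("v2", res$flags))
  expect_equal(tot_v2 - tot_p, 72)
  # the frozen package defaults are the arbitrated flags
  expect_equal(unclass(res$flags), unclass(arch_variant_flags()),
               ignore_attr = TRUE)
  expect_true(any(grepl("per-block", res$report)))
})

test_that("all blocks map bounded random inputs to finite outputs", {
  blocks <- list(
    list(tomseg:::with_seed(7, make_dsconv(8, 16)), 8),
    list(tomseg:::with_seed(7, make_bottleneck(4, 8, 8)), 8),
    list(tomseg:::with_seed(7, make_feature_block("s1")), 64),
    list(tomseg:::with_seed(7, make_ppm(8, 8)), 8),
    list(tomseg:::with_seed(7, make_classify(cin = 8)), 8))
  for (bc in blocks) {
    x <- matrix(runif(12 * 12 * bc[[2]], -10, 10), 144, bc[[2]])
    for (train in c(TRUE, FALSE)) {
      r <- ns$nn_forward(bc[[1]], x, 12, 12, train)
      expect_true(all(is.finite(r$y)))
    }
  }
})
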
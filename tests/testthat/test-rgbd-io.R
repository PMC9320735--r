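test_that("depth encoding matches base-256 decomposition and is exact", {
  expect_equal(as.vector(encode_depth(matrix(0, 1, 1))), c(0, 0, 0))
  expect_equal(as.vector(encode_depth(matrix(300, 1, 1))), c(44, 1, 0))
  expect_equal(as.vector(encode_depth(matrix(70000, 1, 1))), c(112, 17, 1))
  set.seed(11)
  vals <- floor(runif(500) * 2^24)
  for (v in vals[1:20]) {
    expect_equal(as.vector(encode_depth(matrix(v, 1, 1))), oracle_base256(v))
  }
  d <- matrix(vals, 25, 20)
  expect_identical(decode_depth(encode_depth(d)), matrix(as.integer(vals), 25, 20))
})

test_that("out-of-range depth values are rejected with the offending pixel", {
  d <- matrix(0, 3, 3); d[2, 3] <- 2^24
  expect_error(encode_depth(d), "row 2, col 3", class = "tomseg_range_error")
  expect_error(decode_depth(array(300, c(2, 2, 3))), class = "tomseg_format_error")
  expect_error(decode_depth(array(1, c(2, 2, 2))), class = "tomseg_format_error")
})

test_that("decoding inverts encoding on hand-worked triples", {
  img <- array(0, c(1, 2, 3))
  img[1, 1, ] <- c(0, 0, 0)
  img[1, 2, ] <- c(112, 17, 1)
  expect_equal(as.vector(decode_depth(img)), c(0, 70000))
})

test_that("depth centering has zero mean and translation invariance", {
  expect_equal(center_depth(matrix(500, 4, 5)), matrix(0, 4, 5))
  expect_equal(as.vector(center_depth(matrix(c(400, 600), 1, 2))), c(-100, 100))
  set.seed(2)
  d <- matrix(runif(35, 0, 3000), 5, 7)
  cd <- center_depth(d)
  expect_lt(abs(mean(cd)), 1e-6 * max(abs(cd)))
  expect_equal(center_depth(d + 250), cd)
  expect_error(center_depth(matrix(numeric(0), 0, 0)), class = "tomseg_argument_error")
})

test_that("label palette is injective and invertible", {
  lab <- matrix(0L, 3, 4)
  expect_true(all(label_to_color(lab) == 0))
  lab[1, 1:4] <- 0:3
  img <- label_to_color(lab)
  expect_equal(nrow(unique(matrix(img, ncol = 3))), 4)
  expect_identical(color_to_label(img), lab)
  set.seed(3)
  l2 <- matrix(sample(0:3, 60, TRUE), 6, 10)
  expect_identical(color_to_label(label_to_color(l2)), l2)
})

test_that("dataset save/load round trip is pixel-identical in both depth dialects", {
  s <- tiny_scene(seed = 4, h = 48, w = 48)
  for (fmt in c("encoded", "raw16")) {
    root <- withr::local_tempdir()
    save_sample(s, root, depth_format = fmt)
    s2 <- load_sample(root, s$id)
    expect_identical(s2$rgb, s$rgb)
    expect_identical(s2$depth, s$depth)
    expect_identical(s2$label, s$label)
  }
})

test_that("encoded-depth file decodes through the same codec", {
  s <- tiny_scene(seed = 5, h = 48, w = 48)
  root <- withr::local_tempdir()
  save_sample(s, root)
  img <- round(png::readPNG(file.path(root, "depth", paste0(s$id, ".png"))) * 255)
  expect_identical(decode_depth(img), s$depth)
})

test_that("loading rejects missing files and invalid label values", {
  s <- tiny_scene(seed = 6, h = 48, w = 48)
  root <- withr::local_tempdir()
  save_sample(s, root)
  expect_error(load_sample(root, "nope"), class = "tomseg_not_found_error")
  bad <- matrix(7L, 48, 48)
  png::writePNG(bad / 255, file.path(root, "labels", paste0(s$id, ".png")))
  expect_error(load_sample(root, s$id), class = "tomseg_validation_error")
})

test_that("the 16-bit PNG writer produces files readPNG recovers exactly", {
  v <- matrix(sample(0:65535, 300), 15, 20)
  f <- withr::local_tempfile(fileext = ".png")
  tomseg:::write_png16(v, f)
  back <- round(png::readPNG(f) * 65535)
  expect_equal(back, v, ignore_attr = TRUE)
})

test_that("the 80/10/10 split partitions deterministically", {
  ids <- sprintf("s%03d", 1:100)
  sp <- split_dataset(ids, seed = 9)
  expect_equal(lengths(sp), c(train = 80, val = 10, test = 10))
  expect_setequal(unlist(sp), ids)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_identical(sp, split_dataset(ids, seed = 9))
  expect_false(identical(sp, split_dataset(ids, seed = 10)))
  # ragged sizes stay within one sample of the exact ratio
  sp2 <- split_dataset(ids[1:13], seed = 1)
  expect_equal(lengths(sp2), c(train = 11, val = 1, test = 1))
  expect_error(split_dataset(ids[1:9], seed = 1), class = "tomseg_argument_error")
})
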
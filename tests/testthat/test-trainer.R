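ns <- asNamespace("tomseg")

test_that("the learning-rate schedule follows the closed-form decay", {
  cfg <- train_config()
  expect_equal(learning_rate(cfg, 0), 0.025)
  expect_equal(learning_rate(cfg, 1), 0.025 * 0.997)
  expect_equal(learning_rate(cfg, 100), 0.025 * 0.997^100)
  expect_equal(learning_rate(cfg, 100), 0.01852, tolerance = 1e-3)
})

test_that("augmentation preserves shapes and the label value set", {
  s <- tiny_scene(seed = 71, h = 64, w = 80)
  for (sd in 1:6) {
    a <- augment(s, seed = sd)
    expect_equal(dim(a$rgb), dim(s$rgb))
    expect_equal(dim(a$depth), dim(s$depth))
    expect_true(all(a$label %in% 0:3))
  }
  expect_identical(augment(s, seed = 3)$rgb, augment(s, seed = 3)$rgb)
})

test_that("two horizontal flips restore the sample exactly", {
  s <- tiny_scene(seed = 72, h = 48, w = 64)
  ff <- ns$flip_sample(ns$flip_sample(s))
  expect_identical(ff$rgb, s$rgb)
  expect_identical(ff$depth, s$depth)
  expect_identical(ff$label, s$label)
})

test_that("scaling at rate one with a degenerate crop is the identity", {
  s <- tiny_scene(seed = 73, h = 48, w = 64)
  sc <- ns$scale_crop_sample(s, 1, 1, 1)
  expect_identical(sc$depth, s$depth)
  expect_identical(sc$label, s$label)
  expect_identical(sc$rgb, s$rgb)
})

test_that("scaling preserves the sucker-adjacency structure", {
  s <- generate_scene(scene_params(height = 120, width = 160, seed = 74,
                                   sucker_probability = 1))
  sc <- ns$scale_crop_sample(s, 1.5, 10, 12)
  lab <- sc$label
  comp <- label_components(lab == 3L, 8)
  if (max(comp) > 0) {
    for (k in seq_len(max(comp))) {
      idx <- which(comp == k, arr.ind = TRUE)
      grown <- unique(do.call(rbind, lapply(-2:2, function(dr)
        do.call(rbind, lapply(-2:2, function(dc)
          cbind(pmin(pmax(idx[, 1] + dr, 1), nrow(lab)),
                pmin(pmax(idx[, 2] + dc, 1), ncol(lab))))))))
      near <- lab[grown]
      expect_true(1L %in% near)   # a stem within 2 px
    }
  }
})

test_that("pixel loss is zero iff one-hot correct and ln 4 for uniform maps", {
  target <- matrix(sample(0:3, 24, TRUE), 4, 6)
  onehot <- array(0, c(4, 6, 4))
  for (i in 1:4) for (j in 1:6) onehot[i, j, target[i, j] + 1] <- 1
  expect_equal(pixel_loss(onehot, target), 0)
  uniform <- array(0.25, c(4, 6, 4))
  expect_equal(pixel_loss(uniform, target), log(4))
  # raising the correct-class probability lowers the loss
  better <- array(0.2 / 3, c(4, 6, 4))
  for (i in 1:4) for (j in 1:6) better[i, j, target[i, j] + 1] <- 0.8
  expect_lt(pixel_loss(better, target), pixel_loss(uniform, target))
  expect_error(pixel_loss(uniform, matrix(5L, 4, 6)), class = "tomseg_validation_error")
})

test_that("phase two refuses to run without a completed stage-1 phase", {
  m <- build_variant("proposed", seed = 11)
  s <- list(tiny_scene(seed = 75, h = 48, w = 48))
  cfg2 <- train_config(batch_size = 1, iterations = 1, augment = FALSE,
                       phase = "stage2")
  expect_error(train_phase(m, s, cfg2), class = "tomseg_configuration_error")
})

test_that("training descends and phase two leaves stage 1 bit-identical", {
  scenes <- lapply(1:2, function(i) tiny_scene(seed = 80 + i, h = 48, w = 48))
  m <- build_variant("proposed", seed = 12)
  cfg1 <- train_config(batch_size = 1, iterations = 12, augment = FALSE,
                       seed = 2, phase = "stage1")
  m <- train_phase(m, scenes, cfg1)
  h1 <- attr(m, "history")
  expect_equal(nrow(h1), 12)
  expect_lt(mean(tail(h1$loss, 4)), mean(head(h1$loss, 4)))
  expect_equal(h1$lr, 0.025 * 0.997^(h1$iteration - 1))
  w1_before <- ns$get_weights(m$stage1)
  cfg2 <- train_config(batch_size = 1, iterations = 8, augment = FALSE,
                       seed = 2, phase = "stage2")
  m <- train_phase(m, scenes, cfg2)
  expect_identical(ns$get_weights(m$stage1), w1_before)
  h2 <- attr(m, "history")
  expect_true(all(is.finite(h2$loss)))
})

test_that("training is deterministic under a fixed seed", {
  scenes <- list(tiny_scene(seed = 91, h = 48, w = 48))
  run <- function() {
    m <- build_variant("proposed", seed = 13)
    cfg <- train_config(batch_size = 1, iterations = 4, augment = FALSE,
                        seed = 9, phase = "stage1")
    m <- train_phase(m, scenes, cfg)
    list(h = attr(m, "history"), w = ns$get_weights(m$stage1))
  }
  a <- run(); b <- run()
  expect_identical(a$h, b$h)
  expect_identical(a$w, b$w)
})

test_that("the full protocol records its configuration and reloads exactly", {
  scenes <- lapply(1:10, function(i) tiny_scene(seed = 100 + i, h = 48, w = 48))
  cfg <- train_config(batch_size = 12, epochs = 2, iterations = 4,
                      augment = FALSE, seed = 3)
  ck <- fit(scenes, cfg)
  expect_s3_class(ck, "tomseg_checkpoint")
  expect_equal(ck$train_config$epochs, 2)
  expect_equal(ck$train_config$batch_size, 12)
  expect_equal(lengths(ck$split_ids), c(train = 8, val = 1, test = 1))
  val <- scenes[vapply(scenes, `[[`, "", "id") %in% ck$split_ids$val]
  rep1 <- evaluate_dataset(ck, val)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  ck2 <- load_checkpoint(f)
  rep2 <- evaluate_dataset(ck2, val)
  expect_identical(rep1$mean_iou, rep2$mean_iou)
  expect_identical(rep1$per_class_iou, rep2$per_class_iou)
})
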
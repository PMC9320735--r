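test_that("class IOU matches the explicit pixel-set oracle", {
  a <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  expect_equal(class_iou(a, a)$mean, 1)
  b <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  expect_equal(class_iou(a, b)$per_class[["stem"]], 0)
  set.seed(31)
  for (i in 1:100) {
    p <- random_label_map(16, 16)
    t <- random_label_map(16, 16)
    got <- class_iou(p, t)
    want <- oracle_iou(p, t)
    expect_equal(unname(got$per_class), want$per_class)
    expect_equal(got$mean, want$mean)
  }
  expect_error(class_iou(a, matrix(0L, 3, 2)), class = "tomseg_argument_error")
})

test_that("classes absent from both maps are excluded from the mean", {
  p <- matrix(c(0L, 1L), 1, 2)
  t <- matrix(c(0L, 1L), 1, 2)
  ci <- class_iou(p, t)
  expect_true(all(is.na(ci$per_class[c("branch", "sucker")])))
  expect_equal(ci$mean, 1)
})

test_that("sucker binarization counts exactly the class-3 pixels", {
  lab <- random_label_map(10, 10)
  m <- sucker_binary(lab)
  expect_equal(sum(m), sum(lab == 3))
  expect_true(all(sucker_binary(matrix(0L, 4, 4)) == 0))
  expect_true(all(sucker_binary(matrix(3L, 4, 4)) == 1))
})

test_that("component labeling agrees with flood fill and EBImage", {
  set.seed(32)
  for (conn in c(4, 8)) {
    for (i in 1:20) {
      mask <- matrix(rbinom(18 * 15, 1, 0.35), 18, 15)
      lab <- label_components(mask, conn)
      want <- oracle_components(mask, conn)
      expect_equal(max(lab), max(want))
      # same partition: components correspond one to one
      for (k in seq_len(max(lab))) {
        expect_equal(length(unique(want[lab == k])), 1)
      }
    }
  }
  mask <- matrix(rbinom(30 * 30, 1, 0.3), 30, 30)
  eb <- EBImage::bwlabel(mask)           # EBImage labels 4-connected
  expect_equal(max(label_components(mask, 4)), max(eb))
})

test_that("the noise filter applies a strict-below-threshold rule", {
  m <- matrix(0L, 30, 30)
  m[1:10, 1:16] <- 1L                  # area 160: survives at t = 160
  expect_equal(filter_noise_regions(m, eval_config(160)), m)
  m2 <- matrix(0L, 30, 30)
  m2[1:10, 1:16] <- 1L; m2[1, 16] <- 0L  # area 159: removed
  expect_true(all(filter_noise_regions(m2, eval_config(160)) == 0))
  m3 <- matrix(0L, 40, 40)
  m3[1:10, 1:20] <- 1L                 # area 200
  m3[30:34, 30:39] <- 1L               # area 50
  f <- filter_noise_regions(m3, eval_config(160))
  expect_equal(sum(f), 200)
  expect_true(all(f[30:34, 30:39] == 0))
})

test_that("the noise filter is idempotent on random masks", {
  set.seed(33)
  for (i in 1:20) {
    m <- matrix(rbinom(40 * 40, 1, 0.4), 40, 40)
    cfg <- eval_config(noise_area_threshold = sample(c(5, 20, 160), 1))
    f1 <- filter_noise_regions(m, cfg)
    expect_identical(filter_noise_regions(f1, cfg), f1)
  }
})

test_that("sucker counting reproduces the worked example and the oracle", {
  fx <- generate_counting_fixture()
  res <- count_correct_suckers(fx$prediction, fx$ground_truth)
  expect_equal(res$n_ground_truth_suckers, 2)
  expect_equal(res$n_correct, 1)
  expect_equal(res$n_prediction_regions_after_filter, 2)  # sub-160 region removed
  empty <- matrix(0L, 480, 640)
  expect_equal(count_correct_suckers(empty, fx$ground_truth)$n_correct, 0)
  set.seed(34)
  for (i in 1:30) {
    p <- matrix(sample(c(0L, 3L), 400, TRUE, prob = c(0.6, 0.4)), 20, 20)
    t <- matrix(sample(c(0L, 3L), 400, TRUE, prob = c(0.7, 0.3)), 20, 20)
    cfg <- eval_config(noise_area_threshold = 10)
    got <- count_correct_suckers(p, t, cfg)
    want <- oracle_count_correct(p, t, t = 10)
    expect_equal(got$n_ground_truth_suckers, want$n_gt)
    expect_equal(got$n_correct, want$n_correct)
  }
})

test_that("sub-threshold noise regions never change the count", {
  fx <- generate_counting_fixture()
  base <- count_correct_suckers(fx$prediction, fx$ground_truth)
  noisy <- fx$prediction
  noisy[470:475, 10:15] <- 3L          # 36 px of extra noise
  noisy[200:205, 600:604] <- 3L
  res <- count_correct_suckers(noisy, fx$ground_truth)
  expect_equal(res$n_correct, base$n_correct)
  expect_equal(res$n_prediction_regions_after_filter,
               base$n_prediction_regions_after_filter)
})

test_that("dataset evaluation aggregates consistently and flags undefined detection", {
  m <- build_variant("proposed", seed = 3)
  scenes <- lapply(c(61, 62), function(sd) tiny_scene(seed = sd, h = 48, w = 48))
  rep <- evaluate_dataset(m, scenes)
  expect_true(rep$mean_iou >= 0 && rep$mean_iou <= 1)
  expect_equal(nrow(rep$per_image), 2)
  expect_equal(sum(rep$per_image$n_suckers) > 0,
               !is.na(rep$sucker_detection_pct))
  no_suck <- lapply(c(63, 64), function(sd)
    tiny_scene(seed = sd, h = 48, w = 48, sucker_probability = 0))
  rep2 <- evaluate_dataset(m, no_suck)
  expect_true(is.na(rep2$sucker_detection_pct))
})

test_that("throughput measurement returns a positive rate", {
  m <- build_variant("v1", seed = 4)
  s <- tiny_scene(seed = 65, h = 48, w = 48)
  fps <- measure_throughput(m, n_frames = 2, sample = s, warmup = 1)
  expect_true(is.finite(fps) && fps > 0)
})
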
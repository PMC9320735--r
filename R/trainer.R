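#' @title Augmentation and the two-phase training protocol
#'
#' @description
#' The cascade is trained in two phases. Phase one sets the stage-1 output
#' as the final output and optimizes only stage-1 parameters. Phase two
#' freezes stage 1 (it only supplies the hard-pixel gating, recomputed on
#' the fly per batch) and optimizes only stage-2 parameters against the
#' final output. Optimization is stochastic gradient descent with momentum
#' 0.9; the learning rate starts at 0.025 and is multiplied by 0.997 at
#' every optimizer step.
#'
#' @name trainer
NULL

#' Training configuration
#'
#' Defaults are the published hyperparameters: batch size 12, 40 epochs,
#' initial learning rate 0.025 decaying by a factor 0.997 per iteration
#' (one optimizer step), gating threshold 0.7.
#'
#' @param batch_size samples per optimizer step.
#' @param epochs passes over the training set.
#' @param initial_lr initial learning rate.
#' @param lr_decay_per_iteration multiplicative decay applied each step, so
#'   the rate after `k` steps is `initial_lr * lr_decay_per_iteration^k`.
#' @param t1 cascade gating threshold.
#' @param seed master seed for batching, augmentation and initialization.
#' @param phase `"stage1"` or `"stage2"`.
#' @param momentum SGD momentum.
#' @param augment whether to apply the augmentation pipeline during
#'   training.
#' @param iterations optional hard cap on optimizer steps for the phase
#'   (overrides `epochs`); useful for small-sample studies.
#' @param class_weights optional length-4 vector of per-class loss weights.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 12, epochs = 40, initial_lr = 0.025,
                         lr_decay_per_iteration = 0.997, t1 = 0.7, seed = 1,
                         phase = c("stage1", "stage2"), momentum = 0.9,
                         augment = TRUE, iterations = NULL,
                         class_weights = NULL) {
  structure(list(batch_size = batch_size, epochs = epochs,
                 initial_lr = initial_lr,
                 lr_decay_per_iteration = lr_decay_per_iteration, t1 = t1,
                 seed = seed, phase = match.arg(phase), momentum = momentum,
                 augment = augment, iterations = iterations,
                 class_weights = class_weights),
            class = "train_config")
}

#' Learning rate after k optimizer steps
#'
#' @param config a [train_config()].
#' @param k number of completed steps.
#' @return `initial_lr * lr_decay_per_iteration^k`.
#' @export
learning_rate <- function(config, k) {
  config$initial_lr * config$lr_decay_per_iteration^k
}

# ---- augmentation -----------------------------------------------------------

flip_sample <- function(sample) {
  w <- ncol(sample$depth)
  rgbd_sample(sample$rgb[, w:1, , drop = FALSE], sample$depth[, w:1],
              if (!is.null(sample$label)) sample$label[, w:1], sample$id)
}

nearest_index <- function(n_out, n_in) {
  pmin(pmax(round((seq_len(n_out) - 0.5) * n_in / n_out + 0.5), 1), n_in)
}

# scale up by `rate` then crop back to the original size at (oy, ox)
scale_crop_sample <- function(sample, rate, oy, ox) {
  h <- nrow(sample$depth); w <- ncol(sample$depth)
  nh <- round(h * rate); nw <- round(w * rate)
  ri <- nearest_index(nh, h)[oy + seq_len(h) - 1]
  ci <- nearest_index(nw, w)[ox + seq_len(w) - 1]
  Mh <- bilinear_matrix(nh, h)[oy + seq_len(h) - 1, , drop = FALSE]
  Mw <- bilinear_matrix(nw, w)[ox + seq_len(w) - 1, , drop = FALSE]
  rgb <- array(0L, c(h, w, 3))
  for (k in 1:3) {
    rgb[, , k] <- as.integer(round(pmin(pmax(Mh %*% sample$rgb[, , k] %*% t(Mw), 0), 255)))
  }
  rgbd_sample(rgb, sample$depth[ri, ci],
              if (!is.null(sample$label)) sample$label[ri, ci], sample$id)
}

blur_channel <- function(m, sigma) {
  r <- max(1, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  acc <- m * 0
  for (i in seq_along(k)) {          # vertical pass, replicated edges
    acc <- acc + k[i] * m[pmin(pmax(seq_len(h) + i - r - 1, 1), h), ]
  }
  out <- acc * 0
  for (i in seq_along(k)) {          # horizontal pass
    out <- out + k[i] * acc[, pmin(pmax(seq_len(w) + i - r - 1, 1), w)]
  }
  out
}

#' Augment an RGB-D sample
#'
#' Spatial operations (horizontal flip; scale-up by a random rate in
#' `[1, 2]` followed by a random crop back to the original size) are applied
#' identically to RGB, depth and label, with nearest-neighbor resampling for
#' depth and label so class indices and millimeter values stay exact.
#' Photometric operations (Gaussian blur, additive channel noise,
#' brightness) touch the RGB image only — they do not move objects, so the
#' depth map stays valid. Each operation fires independently with
#' probability 1/2.
#'
#' @param sample a labeled [rgbd_sample()].
#' @param seed optional seed; by default draws from the current RNG stream.
#' @return An augmented [rgbd_sample()] of identical shape.
#' @export
augment <- function(sample, seed = NULL) {
  run <- function() {
    if (runif(1) < 0.5) sample <- flip_sample(sample)
    if (runif(1) < 0.5) {
      rate <- runif(1, 1, 2)
      h <- nrow(sample$depth); w <- ncol(sample$depth)
      nh <- round(h * rate); nw <- round(w * rate)
      oy <- sample.int(nh - h + 1, 1)
      ox <- sample.int(nw - w + 1, 1)
      sample <- scale_crop_sample(sample, rate, oy, ox)
    }
    rgb <- sample$rgb * 1.0
    if (runif(1) < 0.5) {
      sigma <- runif(1, 0.5, 1.5)
      for (k in 1:3) rgb[, , k] <- blur_channel(rgb[, , k], sigma)
    }
    if (runif(1) < 0.5) {
      rgb <- rgb + array(runif(length(rgb), -10, 10), dim(rgb))
    }
    if (runif(1) < 0.5) {
      rgb <- rgb * runif(1, 0.8, 1.2)
    }
    rgb <- array(as.integer(round(pmin(pmax(rgb, 0), 255))), dim(rgb))
    rgbd_sample(rgb, sample$depth, sample$label, sample$id)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# ---- loss -------------------------------------------------------------------

#' Mean per-pixel negative log-likelihood
#'
#' `-mean(log p[target])` over all pixels; non-negative, and zero exactly
#' when the prediction is one-hot correct everywhere.
#'
#' @param pred `H x W x 4` probability array.
#' @param target integer label matrix over `{0,1,2,3}`.
#' @return Scalar loss.
#' @export
pixel_loss <- function(pred, target) {
  target <- validate_label(target)
  stopifnot(identical(dim(pred)[1:2], dim(target)))
  h <- dim(pred)[1]; w <- dim(pred)[2]
  idx <- cbind(rep(seq_len(h), w), rep(seq_len(w), each = h),
               as.vector(target) + 1L)
  -mean(log(pmax(pred[idx], 1e-12)))
}

# softmax cross-entropy loss and gradient wrt logits, with an optional
# validity mask (padding pixels excluded) and per-class weights
ce_loss_grad <- function(logits, target_vec, valid, class_weights = NULL) {
  p <- softmax_rows(logits)
  n <- max(sum(valid), 1)
  wt <- valid / n
  if (!is.null(class_weights)) {
    cw <- class_weights[target_vec + 1L]
    wt <- wt * cw / mean(class_weights)
  }
  ii <- cbind(seq_along(target_vec), target_vec + 1L)
  loss <- -sum(log(pmax(p[ii], 1e-12)) * wt)
  g <- p
  g[ii] <- g[ii] - 1
  list(loss = loss, grad = g * wt)
}

# ---- phase training ---------------------------------------------------------

padded_target <- function(sample) {
  h <- nrow(sample$label); w <- ncol(sample$label)
  lab <- pad_to_multiple(sample$label)
  valid <- pad_to_multiple(matrix(1, h, w))
  list(target = as.vector(lab), valid = as.vector(valid))
}

#' Run one training phase
#'
#' `phase = "stage1"` optimizes only stage-1 parameters against the stage-1
#' output; `phase = "stage2"` requires a completed stage-1 phase, keeps
#' stage 1 frozen (its weights and running statistics are never touched —
#' gating masks are recomputed per batch in evaluation mode) and optimizes
#' only stage-2 parameters against the final output. The learning rate is
#' multiplied by the decay factor at every optimizer step. Fully
#' deterministic for a fixed seed.
#'
#' @param model a [build_variant()] model.
#' @param samples list of labeled training samples.
#' @param config a [train_config()] with `phase` set.
#' @param start_iteration number of steps already taken in this phase's
#'   schedule (continues the learning-rate decay across calls).
#' @return The model, with a `history` data frame (iteration, lr, loss)
#'   attached as attribute `history`.
#' @export
train_phase <- function(model, samples, config, start_iteration = 0) {
  stopifnot(inherits(model, "tomseg_model"))
  phase <- config$phase
  if (phase == "stage1" && is.null(model$stage1)) {
    tomseg_stop("variant v1 has no stage 1 to train", "tomseg_configuration_error")
  }
  if (phase == "stage2" && !is.null(model$stage1) && !isTRUE(model$stage1_trained)) {
    tomseg_stop("phase stage2 requires a completed stage-1 checkpoint; run phase stage1 first",
                "tomseg_configuration_error")
  }
  n <- length(samples)
  if (!n) tomseg_stop("no training samples", "tomseg_argument_error")
  bs <- min(config$batch_size, n)
  iters <- if (!is.null(config$iterations)) config$iterations
           else config$epochs * ceiling(n / bs)
  net <- if (phase == "stage1") model$stage1 else model$stage2
  hist <- data.frame(iteration = integer(iters), lr = numeric(iters),
                     loss = numeric(iters))
  with_seed(derive_seed(config$seed, if (phase == "stage1") 11 else 22) +
              start_iteration, {
    for (k in seq_len(iters)) {
      kk <- start_iteration + k
      lr <- config$initial_lr * config$lr_decay_per_iteration^(kk - 1)
      idx <- if (bs == n) seq_len(n) else sample.int(n, bs)
      zero_grads(net)
      loss_acc <- 0
      for (i in idx) {
        s <- samples[[i]]
        if (isTRUE(config$augment)) s <- augment(s)
        prep <- prepare_inputs(s)
        tg <- padded_target(s)
        if (phase == "stage1") {
          r <- stage1_probs(model, map_to_flat(prep$rgb), prep$h, prep$w, train = TRUE)
          lg <- ce_loss_grad(r$logits, tg$target, tg$valid, config$class_weights)
          nn_backward(model$stage1, lg$grad / bs)
        } else {
          r <- cascade_forward(model, prep, t1 = config$t1, train = TRUE)
          lg <- ce_loss_grad(r$logits, tg$target, tg$valid, config$class_weights)
          stage2_backward(model$stage2, lg$grad / bs)
        }
        loss_acc <- loss_acc + lg$loss / bs
      }
      sgd_step(net, lr, config$momentum)
      hist[k, ] <- list(kk, lr, loss_acc)
    }
  })
  if (phase == "stage1") model$stage1_trained <- TRUE
  attr(model, "history") <- hist
  model
}

# ---- full protocol ----------------------------------------------------------

#' Train the cascade end to end
#'
#' Random initialization (no pretrained weights), an 80/10/10
#' train/validation/test split, phase one on stage 1, then phase two on
#' stage 2 with the best epoch selected by validation mean IOU.
#'
#' @param data a dataset root directory in the standard layout, or a list
#'   of labeled [rgbd_sample()] objects.
#' @param config a [train_config()]; the `phase` field is managed
#'   internally.
#' @param variant network variant passed to [build_variant()].
#' @param flags an [arch_variant_flags()] list.
#' @return A list of class `tomseg_checkpoint`: `model`, `flags`,
#'   `train_config`, `split_ids`, `history` (both phases), `val_iou`,
#'   `best_epoch`.
#' @export
fit <- function(data, config = train_config(), variant = "proposed",
                flags = arch_variant_flags()) {
  samples <- if (is.character(data)) {
    ids <- list_samples(data)
    lapply(ids, function(id) load_sample(data, id))
  } else data
  if (!length(samples)) tomseg_stop("empty dataset", "tomseg_argument_error")
  sp <- split_dataset(samples, config$seed)
  model <- build_variant(variant, flags, seed = derive_seed(config$seed, 7),
                         config = cascade_config(t1 = config$t1))
  cfg1 <- config; cfg1$phase <- "stage1"
  cfg2 <- config; cfg2$phase <- "stage2"
  h1 <- NULL
  if (variant != "v1") {
    model <- train_phase(model, sp$train, cfg1)
    h1 <- attr(model, "history")
  } else {
    model$stage1_trained <- TRUE
  }
  spe <- if (!is.null(config$iterations)) {
    max(1, config$iterations %/% max(1, config$epochs))
  } else ceiling(length(sp$train) / min(config$batch_size, length(sp$train)))
  best <- list(iou = -Inf, weights = NULL, epoch = 0)
  h2 <- NULL
  for (e in seq_len(config$epochs)) {
    cfg2e <- cfg2; cfg2e$iterations <- spe
    model <- train_phase(model, sp$train, cfg2e, start_iteration = (e - 1) * spe)
    h2 <- rbind(h2, attr(model, "history"))
    rep <- evaluate_dataset(model, sp$val)
    if (rep$mean_iou > best$iou) {
      best <- list(iou = rep$mean_iou, weights = get_weights(model$stage2), epoch = e)
    }
  }
  if (!is.null(best$weights)) set_weights(model$stage2, best$weights)
  structure(list(model = model, flags = flags, train_config = config,
                 split_ids = lapply(sp, function(g) vapply(g, `[[`, "", "id")),
                 history = list(stage1 = h1, stage2 = h2),
                 val_iou = best$iou, best_epoch = best$epoch),
            class = "tomseg_checkpoint")
}

clear_caches <- function(model) {
  nets <- Filter(Negate(is.null), list(model$stage1, model$stage2))
  for (net in nets) {
    mods <- c(list(net), collect_leaves(net))
    walk <- function(m) {
      m$cache <- NULL; m$pp_cache <- NULL; m$split <- NULL
      for (ch in m$children) walk(ch)
    }
    walk(net)
  }
  invisible(model)
}

#' Save a trained checkpoint
#'
#' Stores the variant name, frozen architecture flags, configurations and
#' every weight tensor, so [load_checkpoint()] reproduces evaluation
#' results exactly.
#'
#' @param checkpoint a `tomseg_checkpoint` or bare `tomseg_model`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  model <- as_tomseg_model(checkpoint)
  payload <- list(
    variant = model$variant, flags = model$flags, config = model$config,
    stage1_trained = isTRUE(model$stage1_trained),
    w1 = if (!is.null(model$stage1)) get_weights(model$stage1),
    w2 = get_weights(model$stage2),
    train_config = if (inherits(checkpoint, "tomseg_checkpoint")) checkpoint$train_config,
    history = if (inherits(checkpoint, "tomseg_checkpoint")) checkpoint$history,
    val_iou = if (inherits(checkpoint, "tomseg_checkpoint")) checkpoint$val_iou)
  saveRDS(payload, path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return A `tomseg_checkpoint` whose model reproduces the saved weights
#'   bit for bit.
#' @export
load_checkpoint <- function(path) {
  p <- readRDS(path)
  model <- build_variant(p$variant, p$flags, seed = 0, config = p$config)
  if (!is.null(p$w1)) set_weights(model$stage1, p$w1)
  set_weights(model$stage2, p$w2)
  model$stage1_trained <- p$stage1_trained
  structure(list(model = model, flags = p$flags, train_config = p$train_config,
                 history = p$history, val_iou = p$val_iou),
            class = "tomseg_checkpoint")
}
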
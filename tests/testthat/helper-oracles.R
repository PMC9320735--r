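# Independent brute-force oracles and small fixtures used across the suite.

# base-256 decomposition, digit by digit (independent of encode_depth)
oracle_base256 <- function(d) {
  c(d %% 256, (d %/% 256) %% 256, (d %/% 256 %/% 256) %% 256)
}

# per-class IOU by explicit pixel-set intersection/union
oracle_iou <- function(pred, truth) {
  per <- sapply(0:3, function(cl) {
    a <- which(pred == cl)
    b <- which(truth == cl)
    u <- union(a, b)
    if (!length(u)) NA_real_ else length(intersect(a, b)) / length(u)
  })
  list(per_class = per, mean = mean(per, na.rm = TRUE))
}

# connected components by breadth-first flood fill (independent of the
# union-find implementation)
oracle_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] != 0 && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (q in seq_len(nrow(nb))) {
          r <- p[1] + nb[q, 1]; c <- p[2] + nb[q, 2]
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              mask[r, c] != 0 && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# all-pairs overlap counting: a ground-truth component is detected iff any
# of its pixels is set in the filtered prediction mask
oracle_count_correct <- function(pred, truth, t = 160, connectivity = 8) {
  pm <- matrix(as.integer(pred == 3), nrow(pred))
  plab <- oracle_components(pm, connectivity)
  if (max(plab) > 0) {
    for (i in seq_len(max(plab))) {
      if (sum(plab == i) < t) pm[plab == i] <- 0L
    }
  }
  tlab <- oracle_components(matrix(as.integer(truth == 3), nrow(truth)), connectivity)
  n <- 0
  for (i in seq_len(max(tlab))) {
    hit <- FALSE
    for (px in which(tlab == i)) if (pm[px] == 1L) { hit <- TRUE; break }
    if (hit) n <- n + 1
  }
  list(n_gt = max(tlab), n_correct = n)
}

# random four-class label map
random_label_map <- function(h, w) {
  matrix(sample(0:3, h * w, replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.2)), h, w)
}

tiny_scene <- function(seed = 1, h = 64, w = 80, ...) {
  generate_scene(scene_params(height = h, width = w, seed = seed, ...))
}

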
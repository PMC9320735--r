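#' @title Synthetic tomato RGB-D scene generator
#'
#' @description
#' Seeded generator of synthetic RGB-D tomato scenes that mirror the
#' statistical structure of greenhouse imagery: thin, elongated stems with
#' branches leaving at nodes, suckers rising inside the stem-branch axil
#' (always between a stem and a branch), heavy class imbalance in favor of
#' background, and two depth layers — an optional far plant drawn behind the
#' near plant so that a far stem can cross behind a near stem-branch
#' junction, the classic source of sucker/stem confusion in 2-D images.
#' Rendering is deliberately non-photorealistic: flat class-dependent
#' greens/browns plus additive Gaussian noise, with hard (anti-aliasing-free)
#' class boundaries so labels are unambiguous.
#'
#' @name synth_scene
NULL

#' Scene generation parameters
#'
#' @param height,width canvas size in pixels (camera default 480 x 640;
#'   tests typically use 120 x 160).
#' @param n_stems number of near-plant stems (>= 1).
#' @param sucker_probability probability that a stem node carrying a branch
#'   also carries a sucker.
#' @param include_far_plant draw a second plant behind the near one,
#'   creating the crossing-stem depth ambiguity.
#' @param near_depth_mm,far_depth_mm,background_depth_mm layer distances in
#'   integer millimeters; must be strictly increasing. The defaults place
#'   the near plant at the typical 0.5 m camera working distance.
#' @param noise_sd standard deviation (mm) of the Gaussian depth noise.
#' @param seed master seed; every draw in the generator flows from it.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(height = 480, width = 640, n_stems = 2,
                         sucker_probability = 0.7, include_far_plant = TRUE,
                         near_depth_mm = 500, far_depth_mm = 900,
                         background_depth_mm = 2000, noise_sd = 4, seed = 1) {
  if (!(near_depth_mm < far_depth_mm && far_depth_mm < background_depth_mm)) {
    tomseg_stop("depth layers must satisfy near < far < background",
                "tomseg_argument_error")
  }
  if (n_stems < 1) tomseg_stop("n_stems must be >= 1", "tomseg_argument_error")
  structure(list(height = height, width = width, n_stems = n_stems,
                 sucker_probability = sucker_probability,
                 include_far_plant = include_far_plant,
                 near_depth_mm = near_depth_mm, far_depth_mm = far_depth_mm,
                 background_depth_mm = background_depth_mm,
                 noise_sd = noise_sd, seed = seed),
            class = "scene_params")
}

# pixel (row, col) pairs of a thick line segment; x = col, y = row
stroke_pixels <- function(h, w, x0, y0, x1, y1, width) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2, ceiling(len * 2))
  ts <- seq(0, 1, length.out = n)
  px <- round(x0 + ts * (x1 - x0))
  py <- round(y0 + ts * (y1 - y0))
  r <- width / 2
  rr <- ceiling(r)
  off <- expand.grid(dx = -rr:rr, dy = -rr:rr)
  off <- off[off$dx^2 + off$dy^2 <= r^2 + 0.5, , drop = FALSE]
  k <- nrow(off)
  cols <- rep(px, each = k) + rep(off$dx, times = n)
  rows <- rep(py, each = k) + rep(off$dy, times = n)
  keep <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  unique(cbind(row = rows[keep], col = cols[keep]))
}

# draw one plant onto the label/plant-id canvases (modified in place via
# return); returns updated state
draw_plant <- function(state, params, plant_id, base_x, with_suckers) {
  h <- params$height; w <- params$width
  put <- function(state, pix, class) {
    idx <- pix[, 1] + (pix[, 2] - 1) * h
    state$label[idx] <- class
    state$pid[idx] <- plant_id
    state
  }
  stem_w <- runif(1, 8, 14)
  drift <- runif(1, -0.25, 0.25)
  top_y <- runif(1, 0.02, 0.1) * h
  # stem as short near-vertical segments with drift
  ys <- seq(h, top_y, length.out = 8)
  xs <- base_x + cumsum(c(0, runif(7, -1, 1) * 6)) + (h - ys) * drift
  xs <- pmin(pmax(xs, 2), w - 1)
  for (i in 1:7) {
    state <- put(state, stroke_pixels(h, w, xs[i], ys[i], xs[i + 1], ys[i + 1], stem_w), 1L)
  }
  # nodes along the upper stem carry branches; suckers sit in the axil
  node_t <- seq(0.35, 0.85, length.out = max(2, round(h / 60)))
  for (t in node_t) {
    iy <- 1 + floor(t * 6.999)
    ny <- ys[iy] + (ys[iy + 1] - ys[iy]) * (t * 7 - (iy - 1))
    nx <- xs[iy] + (xs[iy + 1] - xs[iy]) * (t * 7 - (iy - 1))
    if (runif(1) > 0.9) next
    side <- sample(c(-1, 1), 1)
    ang <- runif(1, 40, 70) * pi / 180          # from vertical
    blen <- runif(1, 20, 60)
    bx <- nx + side * sin(ang) * blen
    by <- ny - cos(ang) * blen
    state <- put(state, stroke_pixels(h, w, nx, ny, bx, by, runif(1, 5, 10)), 2L)
    if (with_suckers && runif(1) < params$sucker_probability) {
      # sucker along the axil bisector, between stem (up) and branch
      sang <- ang / 2
      slen <- runif(1, 20, 60)
      sx <- nx + side * sin(sang) * slen
      sy <- ny - cos(sang) * slen
      state <- put(state, stroke_pixels(h, w, nx, ny, sx, sy, runif(1, 4, 8)), 3L)
    }
  }
  state
}

#' Generate one synthetic RGB-D scene
#'
#' Draws the far plant first (when enabled) and the near plant over it, so
#' near structures occlude far ones. Depth is the layer distance plus
#' Gaussian noise; suckers inherit their stem's layer, so sucker and stem
#' depth agree to within the noise. The returned sample carries the
#' plant-id matrix (0 background, 1 far, 2 near) as attribute `plant_map`.
#'
#' @param params a [scene_params()] list.
#' @return An [rgbd_sample()] with label classes
#'   `{0 other, 1 stem, 2 branch, 3 sucker}`.
#' @export
generate_scene <- function(params = scene_params()) {
  h <- params$height; w <- params$width
  if (h < 48 || w < 48) {
    tomseg_stop("canvas too small to place a stem (need at least 48 x 48)",
                "tomseg_argument_error")
  }
  with_seed(params$seed, {
    state <- list(label = matrix(0L, h, w), pid = matrix(0L, h, w))
    near_x <- (seq_len(params$n_stems) - 0.5) / params$n_stems * w * 0.8 + 0.1 * w
    if (params$include_far_plant) {
      # behind and leaning, so it crosses the near stem-branch junctions
      state <- draw_plant(state, params, plant_id = 1L,
                          base_x = near_x[1] + runif(1, 20, 40),
                          with_suckers = FALSE)
    }
    for (bx in near_x) {
      state <- draw_plant(state, params, plant_id = 2L,
                          base_x = bx + runif(1, -10, 10), with_suckers = TRUE)
    }
    depth <- matrix(params$background_depth_mm, h, w)
    depth[state$pid == 1L] <- params$far_depth_mm
    depth[state$pid == 2L] <- params$near_depth_mm
    depth <- depth + round(matrix(rnorm(h * w, sd = params$noise_sd), h, w))
    depth[depth < 0] <- 0L
    storage.mode(depth) <- "integer"
    base_cols <- rbind(c(58, 66, 48),     # background
                       c(112, 92, 62),    # stem
                       c(72, 128, 58),    # branch
                       c(96, 148, 70))    # sucker
    shade <- ifelse(state$pid == 1L, 0.75, 1)   # far plant darker
    rgb <- array(0, c(h, w, 3))
    for (k in 1:3) {
      rgb[, , k] <- base_cols[state$label + 1L, k] * shade +
        rnorm(h * w, sd = 8)
    }
    rgb <- round(pmin(pmax(rgb, 0), 255))
    storage.mode(rgb) <- "integer"
    s <- rgbd_sample(rgb, depth, state$label,
                     id = sprintf("scene_s%d", params$seed))
    attr(s, "plant_map") <- state$pid
    s
  })
}

#' Generate a set of synthetic scenes
#'
#' Scene `i` uses a sub-seed derived from the master seed, so the whole set
#' regenerates identically from `params$seed` and identifiers are unique.
#'
#' @param n number of scenes (>= 1).
#' @param params a [scene_params()] list; its `seed` is the master seed.
#' @return A list of [rgbd_sample()] objects.
#' @export
generate_dataset <- function(n, params = scene_params()) {
  if (n < 1) tomseg_stop("n must be >= 1", "tomseg_argument_error")
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- derive_seed(params$seed, i)
    s <- generate_scene(p)
    s$id <- sprintf("scene_%04d", i)
    s
  })
}

#' Worked sucker-counting fixture
#'
#' A deterministic 480 x 640 prediction/ground-truth pair reproducing the
#' published counting example: the ground truth holds two sucker regions;
#' the prediction holds three — one overlapping the first true sucker, one
#' spurious region large enough to survive the area filter, and one small
#' noise region (under 160 px) that the filter removes. The four-step
#' counting procedure therefore finds exactly one correct sucker.
#'
#' @return A list with integer label matrices `prediction` and
#'   `ground_truth`.
#' @export
generate_counting_fixture <- function() {
  h <- 480; w <- 640
  truth <- matrix(0L, h, w)
  pred <- matrix(0L, h, w)
  truth[100:119, 100:109] <- 3L   # sucker A, 200 px
  truth[300:319, 400:409] <- 3L   # sucker B, 200 px
  pred[105:124, 103:112] <- 3L    # overlaps sucker A, 200 px
  pred[50:69, 500:509] <- 3L      # spurious but large, 200 px
  pred[400:409, 200:214] <- 3L    # noise, 150 px < 160
  list(prediction = pred, ground_truth = truth)
}
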
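#' @title RGB-D input/output: depth codec, centering, dataset layout
#'
#' @description
#' Depth maps are integer matrices of camera distance in millimeters. A depth
#' value `d` is stored losslessly in an ordinary 8-bit RGB PNG through the
#' base-256 decomposition `d = R + 256*G + 65536*B`, so any distance below
#' 2^24 mm survives a PNG round trip exactly. Label maps are integer matrices
#' over `{0,1,2,3}` = other/stem/branch/sucker.
#'
#' @name rgbd_io
NULL

tomseg_stop <- function(msg, class) {
  stop(structure(class = c(class, "tomseg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Encode a depth map into three 8-bit channels
#'
#' Splits each distance (integer millimeters) into red, green and blue bytes
#' so that `d = R + 256*G + 65536*B`. The encoding is a bijection on
#' `[0, 2^24)`; [decode_depth()] inverts it exactly.
#'
#' @param depth integer matrix of non-negative distances in `[0, 2^24)`.
#' @return An `H x W x 3` integer array with values in `[0, 255]`,
#'   channels ordered R, G, B.
#' @seealso [decode_depth()]
#' @examples
#' e <- encode_depth(matrix(c(0, 300, 70000, 123456), 2, 2))
#' e[1, 2, ]  # 70000 -> (112, 17, 1)
#' @export
encode_depth <- function(depth) {
  depth <- as.matrix(depth)
  if (any(is.na(depth)) || any(depth < 0)) {
    tomseg_stop("depth values must be non-negative integers", "tomseg_range_error")
  }
  bad <- which(depth >= 2^24)
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(depth))
    tomseg_stop(sprintf(
      "depth value %d at pixel (row %d, col %d) is >= 2^24 and cannot be encoded",
      depth[bad[1]], ij[1], ij[2]), "tomseg_range_error")
  }
  d <- round(depth)
  r <- d %% 256
  g <- (d %/% 256) %% 256
  b <- d %/% 65536
  out <- array(0L, c(nrow(d), ncol(d), 3))
  out[, , 1] <- as.integer(r); out[, , 2] <- as.integer(g); out[, , 3] <- as.integer(b)
  out
}

#' Decode three 8-bit channels back to a depth map
#'
#' Exact inverse of [encode_depth()]: `d = R + 256*G + 65536*B`.
#'
#' @param img `H x W x 3` array of integer channel values in `[0, 255]`.
#' @return Integer matrix of distances in millimeters.
#' @export
decode_depth <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    tomseg_stop("encoded depth image must have exactly three channels of equal size",
                "tomseg_format_error")
  }
  ch <- round(img)
  if (any(ch < 0) || any(ch > 255)) {
    tomseg_stop("channel values must lie in [0, 255]", "tomseg_format_error")
  }
  matrix(as.integer(ch[, , 1] + 256 * ch[, , 2] + 65536 * ch[, , 3]),
         nrow = dim(img)[1], ncol = dim(img)[2])
}

#' Subtract the image-mean distance from a depth map
#'
#' Returns `D = d - mean(d)`, the per-pixel distance relative to the scene
#' average. The result has zero mean and is invariant to a constant shift of
#' the whole map, so it does not depend on how far the camera stood from the
#' plants — only relative depth structure remains.
#'
#' @param depth numeric matrix of distances (millimeters).
#' @return Numeric matrix with zero mean.
#' @export
center_depth <- function(depth) {
  depth <- as.matrix(depth)
  if (length(depth) == 0) {
    tomseg_stop("cannot center an empty depth map", "tomseg_argument_error")
  }
  n <- length(depth)
  if (all(depth == round(depth))) {
    # exact integer path: splitting the mean into quotient and remainder
    # makes centering bit-for-bit invariant to adding any integer constant
    s <- sum(as.numeric(depth))
    (depth - s %/% n) - (s %% n) / n
  } else {
    depth - mean(depth)
  }
}

#' Visualization palette for the four-class label map
#'
#' Colors follow the field convention: stems violet, branches pink, suckers
#' green, everything else black.
#'
#' @return A 4 x 3 integer matrix of RGB values, rows ordered by class
#'   index 0..3.
#' @export
label_palette <- function() {
  rbind(other  = c(0L, 0L, 0L),
        stem   = c(138L, 43L, 226L),
        branch = c(255L, 105L, 180L),
        sucker = c(0L, 255L, 0L))
}

#' Render a label map with the class palette
#'
#' @param label integer matrix over `{0,1,2,3}`.
#' @return `H x W x 3` integer RGB array. [color_to_label()] inverts it.
#' @export
label_to_color <- function(label) {
  label <- validate_label(label)
  pal <- label_palette()
  out <- array(0L, c(nrow(label), ncol(label), 3))
  for (k in 1:3) out[, , k] <- pal[label + 1L, k]
  out
}

#' Recover a label map from a palette rendering
#'
#' @param img `H x W x 3` RGB array produced by [label_to_color()].
#' @return Integer label matrix.
#' @export
color_to_label <- function(img) {
  pal <- label_palette()
  key <- img[, , 1] * 65536 + img[, , 2] * 256 + img[, , 3]
  palkey <- pal[, 1] * 65536 + pal[, 2] * 256 + pal[, 3]
  idx <- match(key, palkey)
  if (any(is.na(idx))) {
    tomseg_stop("image contains colors outside the label palette", "tomseg_validation_error")
  }
  matrix(as.integer(idx - 1L), nrow(key), ncol(key))
}

validate_label <- function(label) {
  label <- as.matrix(label)
  vals <- unique(as.vector(label))
  if (!all(vals %in% 0:3)) {
    tomseg_stop(sprintf("label values outside {0,1,2,3}: %s",
                        paste(setdiff(vals, 0:3), collapse = ", ")),
                "tomseg_validation_error")
  }
  storage.mode(label) <- "integer"
  label
}

#' Construct and validate an RGB-D sample
#'
#' @param rgb `H x W x 3` integer array, values 0..255.
#' @param depth integer matrix of millimeter distances, same `H x W`.
#' @param label optional integer label matrix over `{0,1,2,3}`, same `H x W`.
#' @param id sample identifier (file stem in the dataset layout).
#' @return An object of class `rgbd_sample`.
#' @export
rgbd_sample <- function(rgb, depth, label = NULL, id = "sample") {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    tomseg_stop("rgb must be an H x W x 3 array", "tomseg_validation_error")
  }
  depth <- as.matrix(depth)
  if (!identical(dim(rgb)[1:2], dim(depth))) {
    tomseg_stop("rgb and depth dimensions differ", "tomseg_validation_error")
  }
  if (!is.null(label)) {
    label <- validate_label(label)
    if (!identical(dim(depth), dim(label))) {
      tomseg_stop("depth and label dimensions differ", "tomseg_validation_error")
    }
  }
  storage.mode(depth) <- "integer"
  structure(list(rgb = rgb, depth = depth, label = label, id = as.character(id)),
            class = "rgbd_sample")
}

#' @export
print.rgbd_sample <- function(x, ...) {
  cat(sprintf("<rgbd_sample '%s'> %d x %d, depth %d..%d mm, %s\n",
              x$id, nrow(x$depth), ncol(x$depth), min(x$depth), max(x$depth),
              if (is.null(x$label)) "unlabeled"
              else paste0("classes {", paste(sort(unique(as.vector(x$label))),
                                             collapse = ","), "}")))
  invisible(x)
}

# ---- PNG plumbing -----------------------------------------------------------

int_be <- function(x, nbytes = 4) {
  as.raw(sapply(seq(nbytes - 1, 0), function(i) (x %/% 256^i) %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- cpp_crc32(body, 0)
  c(int_be(length(data)), body, int_be(crc))
}

# Deflate "stored" blocks wrapped in a zlib stream (header 78 01, adler32).
zlib_stored <- function(data) {
  n <- length(data)
  out <- list(as.raw(c(0x78, 0x01)))
  pos <- 0
  repeat {
    len <- min(65535, n - pos)
    final <- if (pos + len >= n) 1L else 0L
    hdr <- as.raw(c(final, len %% 256, len %/% 256, (65535 - len) %% 256, (65535 - len) %/% 256))
    out[[length(out) + 1]] <- c(hdr, data[seq_len(len) + pos])
    pos <- pos + len
    if (final == 1L) break
  }
  ad <- cpp_adler32(data)
  out[[length(out) + 1]] <- int_be(ad)
  do.call(c, out)
}

# Write a 16-bit grayscale PNG (big-endian samples, filter 0 on every row).
write_png16 <- function(values, path) {
  values <- as.matrix(values)
  if (any(values < 0 | values > 65535)) {
    tomseg_stop("16-bit PNG values must lie in [0, 65535]", "tomseg_range_error")
  }
  h <- nrow(values); w <- ncol(values)
  v <- round(t(values))                      # column j = image row j
  bytes <- matrix(0L, 2 * w, h)
  bytes[seq(1, 2 * w, 2), ] <- v %/% 256     # big-endian sample pairs
  bytes[seq(2, 2 * w, 2), ] <- v %% 256
  raw_stream <- as.raw(rbind(0L, bytes))     # filter byte 0 per scanline
  ihdr <- c(int_be(w), int_be(h), as.raw(c(16, 0, 0, 0, 0)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", zlib_stored(raw_stream)), con)
  writeBin(png_chunk("IEND", raw()), con)
  invisible(path)
}

read_png_int <- function(path, scale) {
  x <- png::readPNG(path)
  round(x * scale)
}

# ---- dataset layout ---------------------------------------------------------

#' Write an RGB-D sample into the dataset directory layout
#'
#' Creates `rgb/<id>.png` (8-bit RGB), `depth/<id>.png` and
#' `labels/<id>.png` (8-bit single channel holding the raw class indices).
#' Depth is written as a 24-bit encoded RGB PNG by default (the canonical
#' interchange form) or as a raw 16-bit grayscale PNG.
#'
#' @param sample an [rgbd_sample()].
#' @param root dataset root directory (created if absent).
#' @param depth_format `"encoded"` (24-bit RGB) or `"raw16"` (16-bit gray).
#' @return `root`, invisibly.
#' @export
save_sample <- function(sample, root, depth_format = c("encoded", "raw16")) {
  depth_format <- match.arg(depth_format)
  stopifnot(inherits(sample, "rgbd_sample"))
  for (d in c("rgb", "depth", "labels")) {
    dir.create(file.path(root, d), recursive = TRUE, showWarnings = FALSE)
  }
  png::writePNG(sample$rgb / 255, file.path(root, "rgb", paste0(sample$id, ".png")))
  if (depth_format == "encoded") {
    png::writePNG(encode_depth(sample$depth) / 255,
                  file.path(root, "depth", paste0(sample$id, ".png")))
  } else {
    if (any(sample$depth > 65535)) {
      tomseg_stop("depth exceeds 16-bit range; use the encoded format", "tomseg_range_error")
    }
    write_png16(sample$depth, file.path(root, "depth", paste0(sample$id, ".png")))
  }
  if (!is.null(sample$label)) {
    png::writePNG(sample$label / 255, file.path(root, "labels", paste0(sample$id, ".png")))
  }
  invisible(root)
}

#' Load an RGB-D sample from the dataset directory layout
#'
#' Reads `rgb/<id>.png`, `depth/<id>.png`, `labels/<id>.png`. Both depth
#' dialects are accepted and auto-detected by channel count: a single-channel
#' PNG is raw 16-bit millimeters, a three-channel PNG is the 24-bit base-256
#' encoding.
#'
#' @param root dataset root directory.
#' @param id sample identifier (file stem).
#' @param require_label error when the label file is missing (default TRUE).
#' @return An [rgbd_sample()].
#' @export
load_sample <- function(root, id, require_label = TRUE) {
  paths <- file.path(root, c("rgb", "depth", "labels"), paste0(id, ".png"))
  for (p in paths[1:2]) {
    if (!file.exists(p)) {
      tomseg_stop(paste0("missing file: ", p), "tomseg_not_found_error")
    }
  }
  rgb <- read_png_int(paths[1], 255)
  if (length(dim(rgb)) == 3 && dim(rgb)[3] == 4) rgb <- rgb[, , 1:3]  # drop alpha
  storage.mode(rgb) <- "integer"
  draw <- png::readPNG(paths[2])
  if (length(dim(draw)) == 2) {
    depth <- matrix(as.integer(round(draw * 65535)), nrow(draw), ncol(draw))
  } else if (dim(draw)[3] >= 3) {
    depth <- decode_depth(round(draw[, , 1:3] * 255))
  } else {
    tomseg_stop("unrecognized depth PNG layout", "tomseg_format_error")
  }
  label <- NULL
  if (file.exists(paths[3])) {
    lraw <- png::readPNG(paths[3])
    if (length(dim(lraw)) == 3) lraw <- lraw[, , 1]
    label <- validate_label(matrix(as.integer(round(lraw * 255)), nrow(lraw), ncol(lraw)))
  } else if (require_label) {
    tomseg_stop(paste0("missing file: ", paths[3]), "tomseg_not_found_error")
  }
  rgbd_sample(rgb, depth, label, id)
}

#' List sample identifiers present in a dataset directory
#'
#' @param root dataset root directory.
#' @return Character vector of file stems found under `rgb/`.
#' @export
list_samples <- function(root) {
  sort(tools::file_path_sans_ext(basename(
    list.files(file.path(root, "rgb"), pattern = "\\.png$"))))
}

#' Split samples 80/10/10 into train, validation and test sets
#'
#' A seeded uniform shuffle followed by a deterministic 80/10/10 cut:
#' validation and test each receive `floor(n/10)` samples, training the rest,
#' so every set size is within one sample of the exact ratio.
#'
#' @param samples a list of samples or a character vector of identifiers.
#' @param seed integer seed making the shuffle reproducible.
#' @return A list with elements `train`, `val`, `test` (same type as input).
#' @export
split_dataset <- function(samples, seed = 1) {
  n <- length(samples)
  if (n < 10) {
    tomseg_stop("need at least 10 samples for an 80/10/10 split", "tomseg_argument_error")
  }
  ord <- with_seed(seed, sample.int(n))
  n_val <- n %/% 10; n_test <- n %/% 10
  list(train = samples[ord[seq_len(n - n_val - n_test)]],
       val   = samples[ord[seq_len(n_val) + (n - n_val - n_test)]],
       test  = samples[ord[seq_len(n_test) + (n - n_test)]])
}
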
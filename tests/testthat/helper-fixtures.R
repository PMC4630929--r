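# Shared fixtures: all generated in code at test time.

# blank matrix with a filled disc
disc_mask <- function(r, pad = 30) {
  n <- 2 * (r + pad)
  m <- matrix(FALSE, n, n)
  c0 <- n / 2
  m[(row(m) - c0)^2 + (col(m) - c0)^2 <= r^2] <- TRUE
  m
}

# draw a constant-width stroke (stadium) into a logical matrix
draw_stroke <- function(m, p0, p1, width) {
  rootcrown:::rasterize_stadium(m, p0, p1, width / 2)
}

# brute-force 8-connectivity flood-fill labeling (the oracle)
flood_label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j]) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni < 1 || nj < 1 || ni > nrow(mask) || nj > ncol(mask)) next
        if (mask[ni, nj] && !lab[ni, nj]) {
          lab[ni, nj] <- nxt; queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# brute-force exact Euclidean distance transform: all fg-bg pixel
# pairs considered (vectorized O(n^2) oracle)
brute_edt <- function(mask) {
  fgi <- which(mask, arr.ind = TRUE)
  bgi <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  if (nrow(bgi) == 0) return(out + Inf)
  d2 <- outer(fgi[, 1], bgi[, 1], "-")^2 + outer(fgi[, 2], bgi[, 2], "-")^2
  out[fgi] <- sqrt(matrixStats::rowMins(d2))
  out
}

# random blob mask from thresholded smoothed noise, deterministic
random_blob <- function(n = 48, seed = 1, density = 0.55) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  sm <- EBImage::gblur(m, sigma = 2.5)
  sm > quantile(sm, density)
}

# a small, fast, protocol-compliant fan spec (for batch-scale tests)
small_fan_spec <- function(seed, ...) {
  args <- list(
    preset = "monocot_fan",
    image_size = c(320, 320),
    marker_center = c(280, 48), marker_diameter_px = 40,
    marker_diameter_mm = 20,
    tag_bbox = c(8, 34, 120, 220),
    collar = c(48, 170),
    n_strokes = 7, opening_angle = 50, stroke_length = 200,
    stroke_width = 5, stem_width = 10,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synthetic_root_spec, args)
}

# full synthetic scene written as a PNG file; returns the path
write_scene_png <- function(spec, dir, name = NULL) {
  sc <- render_scene(spec)
  name <- name %||% paste0(sc$image$source_id, ".png")
  path <- file.path(dir, name)
  write_image(sc$image$pixels, path)
  path
}

`%||%` <- rlang::`%||%`
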
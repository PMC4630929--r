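# Shared numerical helpers.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Absolute angle from horizontal of the major axis of a 2-D point cloud
#'
#' Fits a total-least-squares line (first principal axis) to a set of
#' (row, col) points and returns its absolute angle from the horizontal
#' in degrees, in \[0, 90\]. Row increases downward (image convention),
#' so a vertical structure scores 90.
#'
#' @param points two-column matrix or data frame of (row, col) coordinates.
#' @return angle in degrees, in \[0, 90\]; `NA` for fewer than 2 points.
#' @export
tls_angle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) return(NA_real_)
  cc <- sweep(points, 2, colMeans(points))
  cv <- crossprod(cc) / nrow(points)
  if (all(abs(cv) < 1e-12)) return(NA_real_)
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  atan2(abs(v[1]), abs(v[2])) * 180 / pi
}

# Per-point tangent angle of a pixel polyline, from the secant over a
# centered window of `w` points (clipped at the ends). Returns degrees
# from horizontal in [0, 90] plus the signed horizontal direction.
secant_angles <- function(coords, w = 9) {
  n <- nrow(coords)
  h <- max(1L, (as.integer(w) - 1L) %/% 2L)
  i1 <- pmax(1L, seq_len(n) - h)
  i2 <- pmin(n, seq_len(n) + h)
  dr <- coords[i2, 1] - coords[i1, 1]
  dc <- coords[i2, 2] - coords[i1, 2]
  ang <- atan2(abs(dr), abs(dc)) * 180 / pi
  list(angle_deg = ang, dcol = dc)
}

# Diameter estimate from a medial (EDT) radius. The distance transform
# measures pixel-center to pixel-center distance, which exceeds the true
# half-width by half a pixel on average (exactly +1 px on 2r for odd drawn
# widths, +0 for even); subtracting 0.5 px bounds the error at 0.5 px for
# axis-aligned bars of any width.
diameter_px <- function(radius) {
  pmax(2 * radius - 0.5, 0)
}

# Arclength of a pixel polyline with unit/diagonal steps.
polyline_length <- function(coords) {
  if (nrow(coords) < 2) return(0)
  d <- diff(coords)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# Cumulative arclength along a polyline (first point 0).
polyline_cumlen <- function(coords) {
  if (nrow(coords) < 2) return(0)
  d <- diff(coords)
  c(0, cumsum(sqrt(d[, 1]^2 + d[, 2]^2)))
}

stop_input <- function(msg, class = "rootcrown_invalid_input") {
  abort(msg, class = class)
}
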
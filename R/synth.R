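# Synthetic protocol-compliant scenes with analytically known ground
# truth: dark noisy background, one bright circular scale marker, one
# rectangular tag above the root, and a root rendered from constant-width
# strokes ("stadium" = all points within width/2 of a centre segment).
# The same closed-form stroke geometry produces both the raster and the
# ground-truth values, so no pipeline code touches the truth.

# ---- stadium geometry -------------------------------------------------

# Analytic horizontal cross-section [left, right] of a stadium (segment
# p0 -> p1 dilated by rho) at continuous rows r. Returns a 2-col matrix
# with NA rows where the stadium does not intersect the row.
stadium_extent <- function(p0, p1, rho, r) {
  ar <- p0[1]; ac <- p0[2]; br <- p1[1]; bc <- p1[2]
  dr <- br - ar; dc <- bc - ac
  n <- length(r)
  left <- rep(NA_real_, n); right <- rep(NA_real_, n)

  cap <- function(er, ec, r) {
    h2 <- rho^2 - (r - er)^2
    ifelse(h2 >= 0, sqrt(pmax(h2, 0)), NA_real_)
  }
  c1 <- cap(ar, ac, r); c2 <- cap(br, bc, r)
  right <- pmax(ifelse(is.na(c1), -Inf, ac + c1),
                ifelse(is.na(c2), -Inf, bc + c2))
  left <- pmin(ifelse(is.na(c1), Inf, ac - c1),
               ifelse(is.na(c2), Inf, bc - c2))

  if (dr == 0) {
    # horizontal segment: straight sides between the caps
    hit <- abs(r - ar) <= rho
    h <- sqrt(pmax(rho^2 - (r - ar)^2, 0))
    right <- ifelse(hit, pmax(right, pmax(ac, bc) + h), right)
    left <- ifelse(hit, pmin(left, pmin(ac, bc) - h), left)
  } else {
    m <- dc / dr                       # col change per row
    off <- rho * sqrt(1 + m^2)
    # interior tangency rows: perpendicular foot within the segment
    sr_hi <- r + m * rho / sqrt(1 + m^2)   # foot row for the right side
    sr_lo <- r - m * rho / sqrt(1 + m^2)   # foot row for the left side
    lo <- min(ar, br); hi <- max(ar, br)
    cline <- function(s) ac + (s - ar) * m
    ok_hi <- sr_hi >= lo & sr_hi <= hi
    ok_lo <- sr_lo >= lo & sr_lo <= hi
    right <- ifelse(ok_hi, pmax(right, cline(r) + off, na.rm = TRUE), right)
    left <- ifelse(ok_lo, pmin(left, cline(r) - off, na.rm = TRUE), left)
  }
  out <- cbind(left, right)
  out[!is.finite(out[, 1]) | !is.finite(out[, 2]), ] <- NA_real_
  out
}

# Rasterize a stadium into a logical matrix (pixel centre within rho of
# the segment).
rasterize_stadium <- function(mask, p0, p1, rho) {
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- max(1L, floor(min(p0[1], p1[1]) - rho)); r1 <- min(nr, ceiling(max(p0[1], p1[1]) + rho))
  c0 <- max(1L, floor(min(p0[2], p1[2]) - rho)); c1 <- min(nc, ceiling(max(p0[2], p1[2]) + rho))
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  rg <- matrix(rows, length(rows), length(cols))
  cg <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  dr <- p1[1] - p0[1]; dc <- p1[2] - p0[2]
  len2 <- dr^2 + dc^2
  t <- if (len2 == 0) 0 else clamp(((rg - p0[1]) * dr + (cg - p0[2]) * dc) / len2, 0, 1)
  d2 <- (rg - (p0[1] + t * dr))^2 + (cg - (p0[2] + t * dc))^2
  mask[rows, cols] <- mask[rows, cols] | (d2 <= rho^2)
  mask
}

# ---- specs ------------------------------------------------------------

#' Specify a synthetic root scene
#'
#' Defines a protocol-compliant scene: dark noisy background, a bright
#' circular scale marker of known physical diameter, a rectangular tag
#' above the root, and a root drawn from constant-width strokes in one
#' of three presets: `monocot_fan` (stem plus a fan of straight strokes
#' from the stem foot), `dicot_taproot` (vertical taproot with laterals)
#' or `excised_segments` (disconnected segments).
#'
#' @param preset one of `"monocot_fan"`, `"dicot_taproot"`,
#'   `"excised_segments"`.
#' @param image_size c(rows, cols) of the scene.
#' @param background,noise_sd background intensity and Gaussian noise sd.
#' @param marker_center,marker_diameter_px,marker_diameter_mm,marker_intensity
#'   circular scale marker placement and physical size.
#' @param tag_bbox,tag_intensity tag rectangle (r0, r1, c0, c1) above
#'   the root.
#' @param collar (row, col) of the collar for crown presets.
#' @param root_intensity stroke intensity (>= 0.8).
#' @param stem_width,stem_frac stem stroke width (px) and the stem's
#'   intended fraction of the total root depth (monocot).
#' @param n_strokes,opening_angle,stroke_length,stroke_width fan
#'   geometry: stroke count, full opening angle (degrees), per-stroke
#'   length and width (px).
#' @param taproot_length,taproot_width,lateral_z,lateral_angle,lateral_length,lateral_width,lateral_side
#'   dicot geometry; `lateral_z` are junction depth fractions of the
#'   taproot length, `lateral_angle` degrees from the taproot,
#'   `lateral_side` +1 (right) or -1 (left), recycled.
#' @param segment_lengths,segment_width excised geometry (centreline
#'   lengths in px).
#' @param seed RNG seed controlling the noise field.
#' @return a `synthetic_root_spec` list.
#' @export
synthetic_root_spec <- function(
    preset = c("monocot_fan", "dicot_taproot", "excised_segments"),
    image_size = c(640, 640),
    background = 0.1, noise_sd = 0.03,
    marker_center = c(560, 90), marker_diameter_px = 80,
    marker_diameter_mm = 20, marker_intensity = 0.95,
    tag_bbox = c(15, 70, 240, 440), tag_intensity = 0.95,
    collar = c(95, 330), root_intensity = 0.9,
    stem_width = 16, stem_frac = 0.12,
    n_strokes = 11, opening_angle = 50, stroke_length = 420,
    stroke_width = 7,
    taproot_length = 430, taproot_width = 18,
    lateral_z = c(0.25, 0.35, 0.5, 0.65), lateral_angle = 55,
    lateral_length = 110, lateral_width = 7, lateral_side = c(1, -1),
    segment_lengths = c(180, 240, 300), segment_width = 9,
    seed = 1) {
  preset <- match.arg(preset)
  if (stroke_width < 3 || stem_width < 3 || taproot_width < 3 ||
      lateral_width < 3 || segment_width < 3) {
    stop_input("stroke widths must be at least 3 px")
  }
  spec <- list(
    preset = preset, image_size = image_size,
    background = background, noise_sd = noise_sd,
    marker_center = marker_center, marker_diameter_px = marker_diameter_px,
    marker_diameter_mm = marker_diameter_mm,
    marker_intensity = marker_intensity,
    tag_bbox = tag_bbox, tag_intensity = tag_intensity,
    collar = collar, root_intensity = root_intensity,
    stem_width = stem_width, stem_frac = stem_frac,
    n_strokes = n_strokes, opening_angle = opening_angle,
    stroke_length = stroke_length, stroke_width = stroke_width,
    taproot_length = taproot_length, taproot_width = taproot_width,
    lateral_z = lateral_z, lateral_angle = lateral_angle,
    lateral_length = lateral_length, lateral_width = lateral_width,
    lateral_side = lateral_side,
    segment_lengths = segment_lengths, segment_width = segment_width,
    seed = seed
  )
  class(spec) <- "synthetic_root_spec"
  spec
}

# Stroke set of a spec: list of list(p0, p1, rho) in row/col px, plus the
# stem rectangle for the fan preset.
spec_strokes <- function(spec) {
  cl <- spec$collar
  if (spec$preset == "monocot_fan") {
    n <- spec$n_strokes
    half <- spec$opening_angle / 2 * pi / 180
    theta <- if (n == 1) 0 else seq(-half, half, length.out = n)
    # stem length: its intended fraction of total depth
    depth_fan <- spec$stroke_length * max(cos(theta))
    L_stem <- round(spec$stem_frac / (1 - spec$stem_frac) * depth_fan)
    foot <- c(cl[1] + L_stem, cl[2])
    strokes <- lapply(theta, function(th) {
      list(p0 = foot,
           p1 = c(foot[1] + spec$stroke_length * cos(th),
                  foot[2] + spec$stroke_length * sin(th)),
           rho = spec$stroke_width / 2)
    })
    list(strokes = strokes,
         stem = list(r0 = cl[1], r1 = foot[1],
                     c0 = cl[2] - floor(spec$stem_width / 2),
                     c1 = cl[2] + floor(spec$stem_width / 2)),
         theta = theta, foot = foot, L_stem = L_stem)
  } else if (spec$preset == "dicot_taproot") {
    tap <- list(p0 = cl, p1 = c(cl[1] + spec$taproot_length, cl[2]),
                rho = spec$taproot_width / 2)
    k <- length(spec$lateral_z)
    side <- rep_len(spec$lateral_side, k)
    ang <- rep_len(spec$lateral_angle, k)
    len <- rep_len(spec$lateral_length, k)
    lats <- lapply(seq_len(k), function(i) {
      start <- c(cl[1] + spec$lateral_z[i] * spec$taproot_length, cl[2])
      phi <- ang[i] * pi / 180
      list(p0 = start,
           p1 = c(start[1] + len[i] * cos(phi),
                  start[2] + side[i] * len[i] * sin(phi)),
           rho = spec$lateral_width / 2)
    })
    list(strokes = c(list(tap), lats), taproot = tap, laterals = lats)
  } else {
    rows <- seq(150, 150 + 90 * (length(spec$segment_lengths) - 1), by = 90)
    strokes <- lapply(seq_along(spec$segment_lengths), function(i) {
      list(p0 = c(rows[i], 150),
           p1 = c(rows[i], 150 + spec$segment_lengths[i]),
           rho = spec$segment_width / 2)
    })
    list(strokes = strokes)
  }
}

# Integer per-row [left, right, extent] of the union of the spec's root
# elements, evaluated at pixel-centre rows -- the analytic counterpart
# of the rasterized width profile.
analytic_profile <- function(spec) {
  geo <- spec_strokes(spec)
  nr <- spec$image_size[1]
  rows <- 1:nr
  left <- rep(Inf, nr); right <- rep(-Inf, nr)
  for (st in geo$strokes) {
    ex <- stadium_extent(st$p0, st$p1, st$rho, rows)
    ok <- !is.na(ex[, 1])
    left[ok] <- pmin(left[ok], ex[ok, 1])
    right[ok] <- pmax(right[ok], ex[ok, 2])
  }
  if (!is.null(geo$stem)) {
    in_stem <- rows >= geo$stem$r0 & rows <= geo$stem$r1
    left[in_stem] <- pmin(left[in_stem], geo$stem$c0)
    right[in_stem] <- pmax(right[in_stem], geo$stem$c1)
  }
  li <- ceiling(left); ri <- floor(right)
  ext <- ifelse(is.finite(left) & ri >= li, ri - li + 1, 0)
  tibble(row = rows, left_c = ifelse(ext > 0, li, NA_real_),
         right_c = ifelse(ext > 0, ri, NA_real_), extent_px = ext)
}

# TLS boundary angle over a depth-fraction band of the analytic profile,
# mirroring the measurement definition but fed by closed-form geometry.
analytic_band_angle <- function(prof, band = c(0, 0.3)) {
  nz <- which(prof$extent_px > 0)
  r_top <- min(nz); r_bot <- max(nz)
  H <- r_bot - r_top + 1
  df <- (prof$row - r_top + 1) / H
  p <- prof[prof$extent_px > 0 & df >= band[1] & df <= band[2], ]
  mean(c(tls_angle(cbind(p$row, p$left_c)),
         tls_angle(cbind(p$row, p$right_c))))
}

# ---- rendering --------------------------------------------------------

#' Render a synthetic scene and its ground truth
#'
#' Deterministic given the spec's seed. Returns the image and a
#' ground-truth table of analytically known trait values with per-trait
#' tolerances.
#'
#' @param spec a [synthetic_root_spec()].
#' @return list with elements `image` (a `root_image`), `truth` (tibble
#'   `trait`, `value`, `tolerance`), `pixels_per_mm`, and `spec`.
#' @export
render_scene <- function(spec) {
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  geo <- spec_strokes(spec)

  root <- matrix(FALSE, nr, nc)
  for (st in geo$strokes) root <- rasterize_stadium(root, st$p0, st$p1, st$rho)
  if (!is.null(geo$stem)) {
    root[geo$stem$r0:geo$stem$r1, geo$stem$c0:geo$stem$c1] <- TRUE
  }
  if (spec$preset == "dicot_taproot" && spec$collar[1] > 1) {
    # the stem is cut flat at the collar, as in the imaging protocol;
    # without this the taproot's rounded cap extends above the collar
    # and shifts every depth fraction
    root[1:(spec$collar[1] - 1), ] <- FALSE
  }

  marker <- matrix(FALSE, nr, nc)
  if (spec$marker_diameter_px > 0) {
    R <- spec$marker_diameter_px / 2
    mr0 <- max(1, floor(spec$marker_center[1] - R)); mr1 <- min(nr, ceiling(spec$marker_center[1] + R))
    mc0 <- max(1, floor(spec$marker_center[2] - R)); mc1 <- min(nc, ceiling(spec$marker_center[2] + R))
    rg <- matrix(mr0:mr1, mr1 - mr0 + 1, mc1 - mc0 + 1)
    cg <- matrix(mc0:mc1, mr1 - mr0 + 1, mc1 - mc0 + 1, byrow = TRUE)
    marker[mr0:mr1, mc0:mc1] <-
      (rg - spec$marker_center[1])^2 + (cg - spec$marker_center[2])^2 <= R^2
  }

  tag <- matrix(FALSE, nr, nc)
  tb <- spec$tag_bbox
  tag[tb[1]:tb[2], tb[3]:tb[4]] <- TRUE

  if (any(root & marker) || any(root & tag) || any(marker & tag)) {
    stop_input("spec error: root, marker and tag regions overlap")
  }

  seed_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  img <- matrix(rnorm(nr * nc, spec$background, spec$noise_sd), nr, nc)
  img <- img + (spec$root_intensity - spec$background) * root +
    (spec$marker_intensity - spec$background) * marker +
    (spec$tag_intensity - spec$background) * tag
  img <- clamp(img, 0, 1)
  if (!is.null(seed_state)) assign(".Random.seed", seed_state, envir = globalenv())

  has_marker <- spec$marker_diameter_px > 0
  s <- if (has_marker) spec$marker_diameter_px / spec$marker_diameter_mm else 1
  truth <- ground_truth(spec, geo, s)
  if (!has_marker) truth <- truth[truth$trait != "PIXELS_PER_MM", ]
  list(image = as_root_image(img, source_id = sprintf("synth_%s_%d", spec$preset, spec$seed)),
       truth = truth, pixels_per_mm = s, spec = spec)
}

ground_truth <- function(spec, geo, s) {
  rows <- list(tibble(trait = "PIXELS_PER_MM", value = s, tolerance = 0.02 * s))
  if (spec$preset == "monocot_fan") {
    prof <- analytic_profile(spec)
    nzext <- prof$extent_px[prof$extent_px > 0]
    w_stem_raster <- 2 * floor(spec$stem_width / 2) + 1
    # the path count equals the stroke count only when adjacent stroke
    # ends are guaranteed to separate (non-overlapping fan contract)
    sep_end <- if (spec$n_strokes < 2) Inf else
      2 * spec$stroke_length *
      sin(spec$opening_angle / (spec$n_strokes - 1) / 2 * pi / 180)
    rtp_known <- sep_end >= spec$stroke_width + 4
    rows <- c(rows, list(tibble(
      trait = c(if (rtp_known) "RTP_COUNT", "DIA_STM", "WIDTH_MED",
                "WIDTH_MAX", "ANG_TOP", "ANG_BTM"),
      value = c(if (rtp_known) spec$n_strokes,
                w_stem_raster / s,
                median(nzext) / s,
                max(nzext) / s,
                analytic_band_angle(prof, c(0, 0.3)),
                analytic_band_angle(prof, c(0.7, 1))),
      tolerance = c(if (rtp_known) 0.5,
                    0.1 * w_stem_raster / s,
                    2 / s, 2 / s, 3, 3)
    )))
  } else if (spec$preset == "dicot_taproot") {
    k <- length(spec$lateral_z)
    ang <- rep_len(spec$lateral_angle, k)
    cls <- ifelse(spec$lateral_z <= 0.05, "ADVT",
                  ifelse(spec$lateral_z <= 0.15, "BASAL", "LT"))
    lt <- which(cls == "LT")
    tap_mm <- spec$taproot_length / s
    rows <- c(rows, list(tibble(
      trait = c("ADVT_COUNT", "BASAL_COUNT", "LT_BRA_FRQ", "LT_AVG_ANG",
                "LT_DIST_FIRST", "TAP_DIA"),
      value = c(sum(cls == "ADVT"), sum(cls == "BASAL"),
                length(lt) / tap_mm,
                if (length(lt) > 0) mean(ang[lt]) else NA_real_,
                if (length(lt) > 0) min(spec$lateral_z[lt]) * spec$taproot_length / s
                else NA_real_,
                (2 * floor(spec$taproot_width / 2) + 1) / s),
      tolerance = c(0.5, 0.5, 0.1 * max(length(lt) / tap_mm, 0.01), 4,
                    0.1 * max(spec$lateral_z) * spec$taproot_length / s,
                    0.1 * spec$taproot_width / s)
    )))
  } else {
    l <- spec$segment_lengths
    w <- spec$segment_width
    rows <- c(rows, list(tibble(
      trait = c("EXC_SEG_COUNT", "EXC_TOT_LEN", "EXC_MAX_LEN",
                "EXC_AVG_DIA", "EXC_TIP_COUNT", "EXC_BRA_FRQ"),
      value = c(length(l), sum(l) / s, max(l) / s,
                (2 * floor(w / 2) + 1) / s, 2 * length(l), 0),
      tolerance = c(0.5, length(l) * (w + 3) / s, (w + 3) / s,
                    1.5 / s, 0.5, 0.01)
    )))
  }
  dplyr::bind_rows(rows)
}

#' Generate a reproducible suite of synthetic scenes
#'
#' Samples `n` specs uniformly from parameter ranges with per-item
#' derived seeds (`seed + i`), so the suite is reproducible end to end.
#'
#' @param n number of scenes (>= 1).
#' @param preset passed to [synthetic_root_spec()].
#' @param ranges named list of `c(min, max)` numeric ranges for spec
#'   parameters (e.g. `opening_angle`, `stem_width`, `n_strokes`,
#'   `stroke_length`, `noise_sd`); integer-valued parameters
#'   (`n_strokes`) are rounded.
#' @param seed base seed.
#' @param render if `FALSE`, only the sampled specs are returned.
#' @param ... fixed spec parameters passed to [synthetic_root_spec()]
#'   (e.g. a smaller `image_size` for quick sweeps).
#' @return a tibble with columns `item`, `seed`, `spec` and (when
#'   rendered) `image`, `truth`, `pixels_per_mm`.
#' @export
make_suite <- function(n, preset = "monocot_fan",
                       ranges = list(opening_angle = c(20, 80),
                                     stem_width = c(8, 40),
                                     n_strokes = c(5, 25)),
                       seed = 1, render = TRUE, ...) {
  if (n < 1) stop_input("n must be at least 1")
  if (length(ranges) == 0) stop_input("parameter ranges must be non-empty")
  bad <- vapply(ranges, function(r) length(r) != 2 || any(!is.finite(r)) || r[2] < r[1],
                logical(1))
  if (any(bad)) stop_input("each range must be a finite c(min, max)")
  int_params <- c("n_strokes")
  rows <- lapply(seq_len(n), function(i) {
    item_seed <- seed + i
    seed_state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(item_seed)
    vals <- lapply(names(ranges), function(nm) {
      v <- runif(1, ranges[[nm]][1], ranges[[nm]][2])
      if (nm %in% int_params) round(v) else v
    })
    names(vals) <- names(ranges)
    if (!is.null(seed_state)) assign(".Random.seed", seed_state, envir = globalenv())
    fixed <- list(...)
    fixed <- fixed[setdiff(names(fixed), names(vals))]
    spec <- do.call(synthetic_root_spec,
                    c(list(preset = preset, seed = item_seed), vals, fixed))
    tibble(item = i, seed = item_seed, spec = list(spec))
  })
  out <- dplyr::bind_rows(rows)
  if (render) {
    rendered <- lapply(out$spec, render_scene)
    out$image <- lapply(rendered, `[[`, "image")
    out$truth <- lapply(rendered, `[[`, "truth")
    out$pixels_per_mm <- vapply(rendered, `[[`, numeric(1), "pixels_per_mm")
  }
  out
}

#' Write a rendered suite to disk for offline inspection
#'
#' @param suite result of [make_suite()] with `render = TRUE`.
#' @param dir output directory; PNG per scene plus a `ground_truth.csv`.
#' @return `dir`, invisibly.
#' @export
write_suite <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truths <- lapply(seq_len(nrow(suite)), function(i) {
    img <- suite$image[[i]]
    write_image(img$pixels, file.path(dir, paste0(img$source_id, ".png")))
    dplyr::mutate(suite$truth[[i]], image_id = img$source_id)
  })
  readr::write_csv(dplyr::bind_rows(truths),
                   file.path(dir, "ground_truth.csv"), progress = FALSE)
  invisible(dir)
}
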
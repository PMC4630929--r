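# Width profile and the common shape traits.

#' Per-row width profile of the root component
#'
#' For each row of the root bounding box, the horizontal extent
#' (rightmost - leftmost + 1 over root pixels of that row; 0 for rows
#' with no root pixels), the foreground pixel count, and the depth axis
#' in rows and as a fraction of the total root depth.
#'
#' @param scene a `root_scene`.
#' @return a tibble (class `width_profile`) with columns `row`,
#'   `depth_frac`, `extent_px`, `count_px`, `left_c`, `right_c`.
#' @export
width_profile <- function(scene) {
  rm <- root_mask_of(scene)
  comp <- scene_component(scene, "root")
  r_top <- comp$r0 + 1L
  r_bot <- comp$r1
  H <- r_bot - r_top + 1L
  rows <- r_top:r_bot
  idx <- which(rm, arr.ind = TRUE)
  idx <- idx[idx[, 1] >= r_top & idx[, 1] <= r_bot, , drop = FALSE]
  f <- factor(idx[, 1], levels = rows)
  left <- tapply(idx[, 2], f, min)
  right <- tapply(idx[, 2], f, max)
  count <- tapply(idx[, 2], f, length)
  left <- as.numeric(left); right <- as.numeric(right)
  count <- as.numeric(count); count[is.na(count)] <- 0
  extent <- ifelse(is.na(left), 0, right - left + 1)
  out <- tibble(
    row = rows,
    depth_frac = (rows - r_top + 1) / H,
    extent_px = extent,
    count_px = count,
    left_c = left,
    right_c = right
  )
  attr(out, "r_top") <- r_top
  attr(out, "H") <- H
  attr(out, "root_area") <- comp$area
  class(out) <- c("width_profile", class(out))
  out
}

# Cumulative-width depth landmarks: depth fraction at which the
# cumulative sum of extents first reaches x% of its total, plus the
# central-difference slope of the normalized cumulative curve there.
depth_landmarks <- function(profile, fracs = seq(0.1, 0.9, 0.1)) {
  ext <- profile$extent_px
  tot <- sum(ext)
  if (tot <= 0) {
    return(list(D = rep(NA_real_, length(fracs)),
                DS = rep(NA_real_, length(fracs))))
  }
  y <- cumsum(ext) / tot
  x <- profile$depth_frac
  n <- length(x)
  D <- DS <- numeric(length(fracs))
  for (k in seq_along(fracs)) {
    i <- which(y >= fracs[k])[1]
    D[k] <- x[i]
    i0 <- max(1L, i - 1L); i1 <- min(n, i + 1L)
    DS[k] <- (y[i1] - y[i0]) / (x[i1] - x[i0])
  }
  list(D = D, DS = DS)
}

#' Common shape traits
#'
#' Computes the projected-area, width, density, centroid-distribution,
#' skeleton-extent and depth-landmark traits from the width profile and
#' skeleton. Lengths are in mm when a scale is supplied (else px), areas
#' in mm^2 (else px^2).
#'
#' @param profile a [width_profile()].
#' @param scene the `root_scene`.
#' @param skeleton the root's `root_skeleton`.
#' @param scale a `scale_info`, or `NULL` for pixel units.
#' @return a partial trait record (tibble `trait`, `value`, `status`).
#' @export
compute_shape_traits <- function(profile, scene, skeleton, scale = NULL) {
  s <- if (!is.null(scale)) scale$pixels_per_mm else 1
  comp <- scene_component(scene, "root")
  nz <- profile$extent_px > 0
  if (!any(nz)) {
    return(empty_record(c("AREA", "AVG_DENSITY", "WIDTH_MED", "WIDTH_MAX",
                          "SKL_DEPTH", "SKL_WIDTH", "RDISTR_X", "RDISTR_Y",
                          paste0("D", seq(10, 90, 10)),
                          paste0("DS", seq(10, 90, 10)))))
  }
  bbox_h <- comp$r1 - comp$r0
  bbox_w <- comp$c1 - comp$c0
  skl_idx <- which(skeleton$mask, arr.ind = TRUE)
  lm <- depth_landmarks(profile)
  out <- dplyr::bind_rows(
    ok_trait("AREA", comp$area / s^2),
    ok_trait("AVG_DENSITY", comp$area / (bbox_h * bbox_w)),
    ok_trait("WIDTH_MED", median(profile$extent_px[nz]) / s),
    ok_trait("WIDTH_MAX", max(profile$extent_px) / s),
    ok_trait("RDISTR_X", (comp$centroid_c - comp$c0 - 0.5) / bbox_w),
    ok_trait("RDISTR_Y", (comp$centroid_r - comp$r0 - 0.5) / bbox_h),
    ok_trait("SKL_DEPTH", (max(skl_idx[, 1]) - min(skl_idx[, 1]) + 1) / s),
    ok_trait("SKL_WIDTH", (max(skl_idx[, 2]) - min(skl_idx[, 2]) + 1) / s),
    ok_trait(paste0("D", seq(10, 90, 10)), lm$D),
    ok_trait(paste0("DS", seq(10, 90, 10)), lm$DS)
  )
  out
}

#' Stem diameter traits
#'
#' `DIA_STM` is twice the largest medial radius (less the half-pixel
#' distance-transform offset) over central-path points whose depth lies
#' in the top `f_stem` fraction of the root depth. The maximum is used
#' rather than a band average because radii near the root's top edge are
#' truncated by the distance to the background above the collar, which
#' biases averages low for stems wider than the band is deep; and the
#' maximum is taken over all skeleton pixels in the band (not only the
#' central path), because on wide stems the topmost skeleton tip sits on
#' a corner bisector that may only join the stem's centre line below the
#' band. The band itself lies above any branching, so all skeleton
#' material in it is stem. `DIA_STM_SIMPLE` is
#' the median per-row extent over those top rows. When the band holds no
#' skeleton pixels it is widened to the top 10 rows.
#'
#' @param paths an `rtp_set` from [root_tip_paths()].
#' @param profile a [width_profile()].
#' @param skeleton the root `root_skeleton`.
#' @param scale a `scale_info`, or `NULL` for pixel units.
#' @param config a [pipeline_config()] (supplies `f_stem`).
#' @return a partial trait record.
#' @export
compute_stem_traits <- function(paths, profile, skeleton, scale = NULL,
                                config = pipeline_config()) {
  s <- if (!is.null(scale)) scale$pixels_per_mm else 1
  ids <- c("DIA_STM", "DIA_STM_SIMPLE", "RTP_COUNT")
  if (nrow(paths) == 0) return(empty_record(ids))
  r_top <- attr(profile, "r_top")
  H <- attr(profile, "H")
  band_rows <- r_top + max(1, floor(config$f_stem * H)) - 1
  skl <- which(skeleton$mask, arr.ind = TRUE)
  band_rad <- skeleton$radius[skl[skl[, 1] <= band_rows, , drop = FALSE]]
  if (length(band_rad) == 0) {
    band_rad <- skeleton$radius[skl[skl[, 1] <= r_top + 9, , drop = FALSE]]
  }
  dia_stm <- if (length(band_rad) == 0) NA_real_ else
    diameter_px(max(band_rad)) / s
  top_ext <- profile$extent_px[profile$row <= band_rows & profile$extent_px > 0]
  dia_simple <- if (length(top_ext) == 0) NA_real_ else median(top_ext) / s
  dplyr::bind_rows(
    ok_trait("DIA_STM", dia_stm),
    ok_trait("DIA_STM_SIMPLE", dia_simple),
    ok_trait("RTP_COUNT", nrow(paths))
  )
}

#' Root top and bottom angle
#'
#' Using the outermost root pixel per row on each side, fits a
#' total-least-squares line to each side's boundary pixels within the
#' top (`f_top`) and bottom (`f_btm`) depth-fraction bands and reports
#' the mean over the two sides of the absolute angle from the
#' horizontal, in degrees \[0, 90\]. A side with fewer than 5 boundary
#' pixels in the band is skipped; if both are skipped the trait fails.
#'
#' @param scene a `root_scene`.
#' @param profile a [width_profile()].
#' @param config a [pipeline_config()] (supplies `f_top`, `f_btm`).
#' @return a partial trait record with `ANG_TOP` and `ANG_BTM`.
#' @export
compute_angle_traits <- function(scene, profile, config = pipeline_config()) {
  band_angle <- function(in_band) {
    p <- profile[in_band & profile$extent_px > 0, ]
    angs <- c()
    for (side in c("left_c", "right_c")) {
      pts <- cbind(p$row, p[[side]])
      pts <- pts[!is.na(pts[, 2]), , drop = FALSE]
      if (nrow(pts) >= 5) {
        a <- tls_angle(pts)
        if (!is.na(a)) angs <- c(angs, a)
      }
    }
    if (length(angs) == 0) NA_real_ else mean(angs)
  }
  top <- band_angle(profile$depth_frac <= config$f_top)
  btm <- band_angle(profile$depth_frac >= 1 - config$f_btm)
  dplyr::bind_rows(ok_trait("ANG_TOP", top), ok_trait("ANG_BTM", btm))
}
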
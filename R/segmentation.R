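# Scene segmentation: global threshold, speckle removal, 8-connected
# component labeling, classification into root / scale marker / tag, and
# pixel-to-mm calibration from the circular marker.

#' Threshold an image into a binary foreground mask
#'
#' Foreground is every pixel strictly brighter than the threshold (light
#' material on a dark background), followed by one binary opening with a
#' 3x3 cross element to remove speckle.
#'
#' @param image a `root_image`.
#' @param threshold scalar in \[0,1\].
#' @return a `root_mask`: logical matrix plus the threshold used.
#' @export
binary_mask <- function(image, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    stop_input("threshold must be a single value in [0,1]")
  }
  fg <- image$pixels > threshold
  kern <- EBImage::makeBrush(3, shape = "diamond")
  opened <- EBImage::opening(fg * 1, kern) > 0.5
  structure(list(mask = opened, threshold_used = threshold),
            class = "root_mask")
}

#' Threshold calibration sweep
#'
#' Computes one mask per candidate threshold together with summaries
#' (foreground fraction, component count) supporting a visual choice of
#' the segmentation threshold on a representative image.
#'
#' @param image a `root_image`.
#' @param thresholds non-empty numeric vector of values in \[0,1\].
#' @return a tibble (class `calibration_sweep`) with columns `threshold`,
#'   `fg_fraction`, `n_components` and a `mask` list-column.
#' @export
calibration_sweep <- function(image, thresholds) {
  if (length(thresholds) < 1) {
    stop_input("thresholds must be a non-empty list of values in [0,1]")
  }
  if (any(thresholds < 0 | thresholds > 1)) {
    stop_input("all thresholds must lie in [0,1]")
  }
  rows <- lapply(thresholds, function(t) {
    m <- binary_mask(image, t)
    lab <- .cc_label8(m$mask)
    tibble(threshold = t,
           fg_fraction = mean(m$mask),
           n_components = max(lab),
           mask = list(m))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("calibration_sweep", class(out))
  attr(out, "source_id") <- image$source_id
  out
}

#' Write the masks of a calibration sweep as PNG files
#'
#' @param sweep result of [calibration_sweep()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_sweep_masks <- function(sweep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- attr(sweep, "source_id") %||% "image"
  paths <- vapply(seq_len(nrow(sweep)), function(i) {
    p <- file.path(dir, sprintf("%s_mask_t%0.3f.png", id, sweep$threshold[i]))
    write_image(sweep$mask[[i]]$mask, p)
    p
  }, character(1))
  invisible(paths)
}

#' Label connected components of a binary mask
#'
#' 8-connectivity labeling; per component area, perimeter (foreground
#' pixels 4-adjacent to background or to the image border), bounding box
#' (0-based, half-open), centroid and circularity (isoperimetric quotient
#' 4*pi*A/P^2, clipped to \[0, 1.2\]).
#'
#' @param mask a `root_mask` or logical matrix.
#' @return a tibble (class `scene_components`) sorted by area descending,
#'   with the integer label matrix in attribute `"labels"`.
#' @export
label_components <- function(mask) {
  m <- if (inherits(mask, "root_mask")) mask$mask else mask
  lab <- .cc_label8(m)
  nlab <- max(lab)
  empty <- tibble(label = integer(), area = double(), perimeter = double(),
                  r0 = integer(), r1 = integer(), c0 = integer(), c1 = integer(),
                  centroid_r = double(), centroid_c = double(),
                  fill_ratio = double(), circularity = double())
  if (nlab == 0) {
    attr(empty, "labels") <- lab
    class(empty) <- c("scene_components", class(empty))
    return(empty)
  }
  idx <- which(m, arr.ind = TRUE)
  lv <- lab[idx]
  area <- tabulate(lv, nlab)

  # boundary pixels: foreground with a 4-neighbour background or border
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  boundary <- core & !interior
  per <- tabulate(lab[boundary], nlab)

  r0 <- vapply(split(idx[, 1], lv), min, numeric(1))
  present <- as.integer(names(r0))
  r0 <- unname(r0)
  r1 <- unname(vapply(split(idx[, 1], lv), max, numeric(1)))
  c0 <- unname(vapply(split(idx[, 2], lv), min, numeric(1)))
  c1 <- unname(vapply(split(idx[, 2], lv), max, numeric(1)))
  cr <- unname(vapply(split(idx[, 1], lv), mean, numeric(1)))
  cc <- unname(vapply(split(idx[, 2], lv), mean, numeric(1)))

  out <- tibble(
    label = present,
    area = as.numeric(area[present]),
    perimeter = as.numeric(pmax(per[present], 1)),
    r0 = as.integer(r0 - 1), r1 = as.integer(r1),   # 0-based, half-open
    c0 = as.integer(c0 - 1), c1 = as.integer(c1),
    centroid_r = cr, centroid_c = cc,
    fill_ratio = area[present] / ((r1 - r0 + 1) * (c1 - c0 + 1)),
    circularity = clamp(4 * pi * area[present] / pmax(per[present], 1)^2, 0, 1.2)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$area))
  attr(out, "labels") <- lab
  class(out) <- c("scene_components", class(out))
  out
}

#' Classify scene components into root, scale marker and tag
#'
#' The marker is the most circular component with circularity at least
#' `c_min` and area at least `a_min`; the tag is the largest remaining
#' component with a dense bounding box (fill ratio >= 0.75) lying above
#' the largest remaining component; the root is the largest component not
#' claimed as marker or tag. Everything else is residual noise.
#'
#' @param components result of [label_components()].
#' @param image the source `root_image`.
#' @param config a [pipeline_config()] (supplies `c_min`, `a_min`).
#' @return a `root_scene`.
#' @export
classify_components <- function(components, image, config = pipeline_config()) {
  comp <- dplyr::arrange(components, dplyr::desc(.data$area), .data$label)
  if (nrow(comp) == 0) {
    abort("no root found: mask has no foreground components",
          class = "rootcrown_no_root")
  }
  marker_label <- NA_integer_
  elig <- comp$circularity >= config$c_min & comp$area >= config$a_min
  if (any(elig)) {
    cand <- comp[elig, ]
    marker_label <- cand$label[which.max(cand$circularity)]
  }
  rest <- comp[!comp$label %in% marker_label, ]
  if (nrow(rest) == 0) {
    # a lone component is the root even if it looks circular: a scene
    # must have a root, and the marker is optional
    marker_label <- NA_integer_
    rest <- comp
  }
  # tag: densest-box component sitting above the largest remaining
  # component other than itself (so a tag larger than every root
  # segment, as in excised-sample scenes, is still recognized)
  tag_label <- NA_integer_
  if (nrow(rest) > 1) {
    ok <- vapply(seq_len(nrow(rest)), function(i) {
      other_big <- rest[-i, ][1, ]    # rest is area-sorted
      rest$fill_ratio[i] >= 0.75 & rest$centroid_r[i] < other_big$r0
    }, logical(1))
    if (any(ok)) tag_label <- rest$label[ok][which.max(rest$area[ok])]
  }
  root_label <- rest$label[!rest$label %in% tag_label][1]
  residual <- setdiff(comp$label, c(root_label, marker_label, tag_label))
  labels <- attr(components, "labels")
  structure(
    list(
      components = comp,
      labels = labels,
      root_label = root_label,
      marker_label = marker_label,
      tag_label = tag_label,
      residual_labels = residual,
      image = image
    ),
    class = "root_scene"
  )
}

scene_component <- function(scene, which = c("root", "marker", "tag")) {
  which <- match.arg(which)
  lbl <- scene[[paste0(which, "_label")]]
  if (is.na(lbl)) return(NULL)
  scene$components[scene$components$label == lbl, ]
}

#' Logical mask of the root component of a scene
#' @param scene a `root_scene`.
#' @return logical matrix.
#' @export
root_mask_of <- function(scene) {
  scene$labels == scene$root_label
}

#' Pixel-to-millimetre calibration from the circular scale marker
#'
#' The marker's equivalent diameter is `2*sqrt(area/pi)`;
#' `pixels_per_mm` is that diameter divided by the known physical
#' diameter.
#'
#' @param marker a component row (from [label_components()]) or a
#'   `root_scene` with a marker.
#' @param known_diameter_mm physical marker diameter in mm (> 0).
#' @return a `scale_info` list: `pixels_per_mm`,
#'   `marker_known_diameter_mm`, `marker_equivalent_diameter_px`,
#'   `circularity`.
#' @export
scale_from_marker <- function(marker, known_diameter_mm) {
  if (inherits(marker, "root_scene")) {
    marker <- scene_component(marker, "marker")
    if (is.null(marker)) return(NULL)
  }
  if (!is.numeric(known_diameter_mm) || known_diameter_mm <= 0) {
    stop_input("known marker diameter must be a positive number of mm")
  }
  if (nrow(marker) < 1 || marker$area[1] < 1) {
    stop_input("marker component must have at least one pixel")
  }
  d_px <- 2 * sqrt(marker$area[1] / pi)
  structure(
    list(
      pixels_per_mm = d_px / known_diameter_mm,
      marker_known_diameter_mm = known_diameter_mm,
      marker_equivalent_diameter_px = d_px,
      circularity = marker$circularity[1]
    ),
    class = "scale_info"
  )
}

#' Crop the identification tag from the image
#'
#' Returns the tag bounding box padded by 5 px (clipped to the image) for
#' external barcode/QR decoding, or `NULL` when the scene has no tag.
#'
#' @param scene a `root_scene`.
#' @param image the source `root_image` (defaults to the scene's image).
#' @return numeric matrix crop, or `NULL`.
#' @export
crop_tag <- function(scene, image = scene$image) {
  tg <- scene_component(scene, "tag")
  if (is.null(tg)) return(NULL)
  r0 <- max(tg$r0 + 1 - 5, 1)
  r1 <- min(tg$r1 + 5, image$height)
  c0 <- max(tg$c0 + 1 - 5, 1)
  c1 <- min(tg$c1 + 5, image$width)
  image$pixels[r0:r1, c0:c1, drop = FALSE]
}

#' @export
print.root_scene <- function(x, ...) {
  cat(sprintf("<root_scene> root label %d (%d px); marker: %s; tag: %s; %d residual\n",
              x$root_label,
              scene_component(x, "root")$area,
              if (is.na(x$marker_label)) "absent" else paste0("label ", x$marker_label),
              if (is.na(x$tag_label)) "absent" else paste0("label ", x$tag_label),
              length(x$residual_labels)))
  invisible(x)
}
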
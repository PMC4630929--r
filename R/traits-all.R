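# Full-record trait computation: dispatches the trait families for a
# scene according to the configured root class and trait selection,
# containing any family failure as per-trait failure codes.

#' Compute all selected traits for a segmented scene
#'
#' Runs the structural analysis (distance transform, skeleton, graph,
#' spur pruning, collar, collar-to-tip paths) on the scene's root
#' component and dispatches the trait families according to
#' `config$root_class` and `config$trait_selection`. Traits of
#' unselected classes are marked `not-applicable`; a family that errors
#' yields `computation-failed` codes for its traits and never aborts the
#' image.
#'
#' @param scene a `root_scene`.
#' @param config a [pipeline_config()].
#' @return a `trait_record`: a tibble with one row per registry trait
#'   (`trait`, `value`, `status`, `category`, `unit`), with attributes
#'   `image_id`, `units` (`"mm"`, or `"px"` when no marker is present),
#'   `pixels_per_mm`, `threshold` and `params`.
#' @export
compute_all <- function(scene, config = pipeline_config()) {
  reg <- trait_registry()
  scale <- if (!is.na(scene$marker_label)) {
    scale_from_marker(scene, config$marker_diameter_mm)
  } else NULL

  selected_class <- function(cl) {
    config$root_class == "all" || config$root_class == cl ||
      cl == "common"
  }
  want <- function(idset) {
    if (identical(config$trait_selection, "all")) idset
    else intersect(idset, config$trait_selection)
  }

  family <- function(cl, fn) {
    ids <- want(reg$trait[reg$category == cl])
    full <- reg$trait[reg$category == cl]
    if (!selected_class(cl) || length(ids) == 0) {
      return(na_trait(full, "not-applicable"))
    }
    rec <- tryCatch(fn(), error = function(e) empty_record(full))
    rec <- rec[rec$trait %in% full, ]
    missing <- setdiff(full, rec$trait)
    if (length(missing) > 0) rec <- dplyr::bind_rows(rec, empty_record(missing))
    rec$status[!(rec$trait %in% ids)] <- "not-applicable"
    rec$value[!(rec$trait %in% ids)] <- NA_real_
    rec
  }

  # structural substrate (shared by common/monocot/dicot)
  struct <- tryCatch({
    rm <- fill_small_holes(root_mask_of(scene), config$max_hole_area)
    field <- distance_transform(rm)
    skel <- skeletonize(rm, field)
    graph <- prune_spurs(build_skeleton_graph(skel), config$min_spur_len,
                         anchor_col = scene_component(scene, "root")$centroid_c)
    collar <- find_collar(graph, scene)
    paths <- root_tip_paths(graph, collar, scale,
                            tangent_window = config$tangent_window)
    profile <- width_profile(scene)
    list(skel = skel, graph = graph, collar = collar, paths = paths,
         profile = profile)
  }, error = function(e) NULL)

  rec <- dplyr::bind_rows(
    family("common", function() {
      dplyr::bind_rows(
        compute_shape_traits(struct$profile, scene, struct$skel, scale),
        compute_stem_traits(struct$paths, struct$profile, struct$skel,
                            scale, config),
        compute_angle_traits(scene, struct$profile, config)
      )
    }),
    family("monocot", function() {
      compute_monocot_traits(struct$paths, struct$skel, struct$profile,
                             scale, config)
    }),
    family("dicot", function() {
      compute_dicot_traits(struct$paths, struct$graph, struct$profile,
                           scale, config)
    }),
    family("excised", function() {
      compute_excised_traits(scene, scale, config)
    })
  )

  rec <- dplyr::left_join(rec, reg, by = "trait")
  rec <- rec[match(reg$trait, rec$trait), ]
  structure(
    rec,
    class = c("trait_record", class(rec)),
    image_id = scene$image$source_id,
    units = if (is.null(scale)) "px" else "mm",
    pixels_per_mm = if (is.null(scale)) NA_real_ else scale$pixels_per_mm,
    threshold = config$threshold,
    root_class = config$root_class,
    params = config[c("f_top", "f_btm", "f_stem", "c_min", "a_min",
                      "a_root", "min_spur_len", "bin_width",
                      "tangent_window", "max_hole_area")],
    structure = struct
  )
}

#' @export
print.trait_record <- function(x, ...) {
  cat(sprintf("<trait_record> %s (%s units): %d ok, %d not-applicable, %d failed\n",
              attr(x, "image_id"), attr(x, "units"),
              sum(x$status == "ok"),
              sum(x$status == "not-applicable"),
              sum(!x$status %in% c("ok", "not-applicable"))))
  NextMethod()
}

#' Tidy a trait record into a plain tibble
#'
#' @param x a `trait_record`.
#' @param ... unused.
#' @return a tibble `image_id`, `trait`, `category`, `unit`, `value`,
#'   `status`.
#' @export
tidy.trait_record <- function(x, ...) {
  tibble(image_id = attr(x, "image_id"),
         trait = x$trait, category = x$category, unit = x$unit,
         value = x$value, status = x$status)
}

#' One-row summary of a trait record
#'
#' @param x a `trait_record`.
#' @param ... unused.
#' @return a one-row tibble with counts per status, the unit flag and the
#'   calibration.
#' @export
glance.trait_record <- function(x, ...) {
  tibble(
    image_id = attr(x, "image_id"),
    n_ok = sum(x$status == "ok"),
    n_not_applicable = sum(x$status == "not-applicable"),
    n_failed = sum(!x$status %in% c("ok", "not-applicable")),
    units = attr(x, "units"),
    pixels_per_mm = attr(x, "pixels_per_mm"),
    threshold = attr(x, "threshold")
  )
}
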
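# Excised-sample traits: disconnected root segments measured through
# their skeletons (lengths, diameters, tips, branching frequency).

#' Excised root sample traits
#'
#' Every foreground component of at least `a_root` pixels that is not
#' the scale marker or the tag counts as a segment. Segments are
#' skeletonized together; per-segment skeleton lengths, medial
#' diameters, tip counts and the excess-tip branching frequency
#' `(tips - 2*segments, floored at 0) / total length` are reported.
#'
#' @param scene a `root_scene`.
#' @param scale a `scale_info`, or `NULL` for pixel units.
#' @param config a [pipeline_config()] (supplies `a_root`,
#'   `min_spur_len`).
#' @return a partial trait record.
#' @export
compute_excised_traits <- function(scene, scale = NULL,
                                   config = pipeline_config()) {
  s <- if (!is.null(scale)) scale$pixels_per_mm else 1
  reg <- trait_registry()
  ids <- reg$trait[reg$category == "excised"]
  comp <- scene$components
  seg_labels <- setdiff(comp$label[comp$area >= config$a_root],
                        c(scene$marker_label, scene$tag_label))
  if (length(seg_labels) == 0) return(empty_record(ids))

  mask <- matrix(scene$labels %in% seg_labels,
                 nrow(scene$labels), ncol(scene$labels))
  mask <- fill_small_holes(mask, config$max_hole_area)
  sk <- skeletonize(mask)
  g <- prune_spurs(build_skeleton_graph(sk), config$min_spur_len)

  # assign every graph edge to its mask component
  edge_seg <- vapply(g$edges$coords, function(co) {
    scene$labels[co[1, 1], co[1, 2]]
  }, numeric(1))
  seg_len <- tapply(g$edges$length_px, factor(edge_seg, levels = seg_labels),
                    sum)
  seg_len <- as.numeric(seg_len)
  seg_len[is.na(seg_len)] <- 0

  deg <- igraph::degree(g$graph)
  tips <- sum(deg == 1)
  radii <- unlist(g$edges$radii)
  tot_len <- sum(seg_len)

  area <- sum(comp$area[comp$label %in% seg_labels])
  dplyr::bind_rows(
    ok_trait("EXC_SEG_COUNT", length(seg_labels)),
    ok_trait("EXC_TOT_LEN", tot_len / s),
    ok_trait("EXC_AVG_LEN", mean(seg_len) / s),
    ok_trait("EXC_MED_LEN", median(seg_len) / s),
    ok_trait("EXC_MAX_LEN", max(seg_len) / s),
    ok_trait("EXC_AVG_DIA", mean(diameter_px(radii)) / s),
    ok_trait("EXC_MED_DIA", median(diameter_px(radii)) / s),
    ok_trait("EXC_BRA_FRQ",
             max(tips - 2 * length(seg_labels), 0) / (tot_len / s)),
    ok_trait("EXC_TIP_COUNT", tips),
    ok_trait("EXC_AREA", area / s^2)
  )
}
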
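# Dicot (taproot) traits: branch classification by emergence depth along
# the taproot, emergence angles, taproot/hypocotyl diameters and lateral
# branching statistics.

# Direction (unit vector, rows x cols) of a polyline from its first
# point over up to `w` points.
polyline_direction <- function(coords, w = 9) {
  n <- min(nrow(coords), w)
  v <- coords[n, ] - coords[1, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(c(0, 0))
  v / nv
}

# Greedy walk from a node along subtree edges (longest continuation
# first), concatenating polyline geometry until ~2 tangent windows of
# points are collected; gives a stable secant for the emergence angle.
branch_axis_coords <- function(graph, start, in_sub, w) {
  coords <- NULL
  cur <- start
  used <- rep(FALSE, nrow(graph$edges))
  repeat {
    cand <- which(in_sub & !used &
                    (graph$edges$from == cur | graph$edges$to == cur))
    if (length(cand) == 0) break
    eid <- cand[which.max(graph$edges$length_px[cand])]
    used[eid] <- TRUE
    ge <- graph$edges$coords[[eid]]
    if (graph$edges$from[eid] != cur) {
      ge <- ge[rev(seq_len(nrow(ge))), , drop = FALSE]
      cur <- graph$edges$from[eid]
    } else {
      cur <- graph$edges$to[eid]
    }
    coords <- if (is.null(coords)) ge else rbind(coords, ge[-1, , drop = FALSE])
    if (nrow(coords) >= 4 * w) break
  }
  coords
}

# Emergence direction of a branch polyline: the secant over one tangent
# window, taken after skipping the first `skip_px` of arclength (the
# stretch of skeleton still inside the parent root's body, whose
# direction reflects the exit geometry rather than the branch).
branch_direction <- function(coords, skip_px, w) {
  if (is.null(coords) || nrow(coords) < 2) return(c(0, 0))
  cum <- polyline_cumlen(coords)
  i0 <- which(cum >= skip_px)[1]
  if (is.na(i0) || i0 >= nrow(coords)) i0 <- 1
  i1 <- which(cum >= cum[i0] + w)[1]
  if (is.na(i1)) i1 <- nrow(coords)
  coords[i1, ] - coords[i0, ]
}

# Absolute angle between two direction vectors, as lines, in [0, 90].
line_angle_between <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  acos(clamp(abs(sum(a * b)) / (na * nb), 0, 1)) * 180 / pi
}

#' Dicot traits
#'
#' The taproot is the longest collar-to-tip path. Graph edges branching
#' off it are classified by the depth fraction `z` of their junction:
#' adventitious (`z <= 0.05`), basal (`0.05 < z <= 0.15`), else lateral.
#' Emergence angle is the absolute angle between the branch's initial
#' secant and the taproot tangent at the junction. Lateral lengths and
#' diameters are measured over the whole branch subtree hanging off the
#' taproot.
#'
#' @param paths an `rtp_set`.
#' @param graph the pruned `skeleton_graph`.
#' @param profile a [width_profile()].
#' @param scale a `scale_info`, or `NULL` for pixel units.
#' @param config a [pipeline_config()].
#' @return a partial trait record.
#' @export
compute_dicot_traits <- function(paths, graph, profile, scale = NULL,
                                 config = pipeline_config()) {
  s <- if (!is.null(scale)) scale$pixels_per_mm else 1
  reg <- trait_registry()
  ids <- reg$trait[reg$category == "dicot"]
  if (nrow(paths) == 0) return(empty_record(ids))

  r_top <- attr(profile, "r_top")
  H <- attr(profile, "H")
  ci <- which.max(paths$arclength_px)
  tap <- paths$points[[ci]]
  tap_coords <- cbind(tap$row, tap$col)
  tap_edges <- paths$edge_ids[[ci]]
  tap_nodes <- paths$node_ids[[ci]]
  tap_len_mm <- paths$arclength_px[ci] / s
  tw <- attr(paths, "tangent_window") %||% 9

  # taproot diameters at depth fractions of the root depth
  df <- (tap$row - r_top + 1) / H
  dia_at <- function(z) {
    j <- which(df >= z)[1]
    if (is.na(j)) NA_real_ else diameter_px(tap$radius[j]) / s
  }

  # branches off taproot junctions. Thinning leaves small clusters of
  # junction pixels at a physical branch point, so: micro-edges (<= 2 px)
  # between two taproot nodes are not branches; each branch is
  # identified by its subtree off the taproot (deduplicated when a
  # cluster offers several attachments into the same subtree); the
  # emergence direction is the first stretch of the subtree's main axis
  # rather than a possibly 1-px first edge.
  g_resid <- igraph::delete_edges(graph$graph,
                                  which(graph$edges$edge %in% tap_edges))
  # attachment set: path nodes plus their junction-cluster companions
  # (nodes one micro-edge off the path)
  micro <- graph$edges$length_px <= 2 & !(graph$edges$edge %in% tap_edges)
  companions <- setdiff(
    c(graph$edges$to[micro & graph$edges$from %in% tap_nodes],
      graph$edges$from[micro & graph$edges$to %in% tap_nodes]),
    tap_nodes)
  attach_set <- c(setdiff(tap_nodes, tap_nodes[1]), companions)

  branch <- list()
  seen <- character(0)
  for (nid in attach_set) {
    node <- graph$nodes[graph$nodes$id == nid, ]
    # nearest taproot polyline point (the junction's position on the
    # taproot); skip nodes that drifted off the taproot
    dd <- abs(tap$row - node$row) + abs(tap$col - node$col)
    jidx <- which.min(dd)
    if (dd[jidx] > 4) next
    inc <- which((graph$edges$from == nid | graph$edges$to == nid) &
                   !(graph$edges$edge %in% tap_edges))
    for (eid in inc) {
      e <- graph$edges[eid, ]
      other <- if (e$from == nid) e$to else e$from
      if (other %in% attach_set && e$length_px <= 2) next
      if (other == nid) next
      # subtree reachable from `other` without re-entering the taproot
      g_sub <- igraph::delete_vertices(g_resid,
                                       as.character(setdiff(attach_set, other)))
      vids <- as.integer(names(igraph::subcomponent(g_sub, as.character(other))))
      key <- paste(sort(vids), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      in_sub <- (graph$edges$from %in% vids & graph$edges$to %in% vids) |
        graph$edges$edge == e$edge
      in_sub <- in_sub & !(graph$edges$edge %in% tap_edges)
      sub_len <- sum(graph$edges$length_px[in_sub])
      if (sub_len < 3) next     # debris
      coords <- branch_axis_coords(graph, nid, in_sub, tw)
      z <- (node$row - r_top + 1) / H
      i1 <- max(1, jidx - (tw - 1) %/% 2); i2 <- min(nrow(tap), jidx + (tw - 1) %/% 2)
      vt <- tap_coords[i2, ] - tap_coords[i1, ]
      vb <- branch_direction(coords, skip_px = tap$radius[jidx], w = tw)
      branch[[length(branch) + 1]] <- tibble(
        node_id = nid, edge_id = e$edge, z = z,
        emergence_deg = line_angle_between(vt, vb),
        dist_px = tap$cum_px[jidx],
        subtree_len = sub_len,
        subtree_radii = list(unlist(graph$edges$radii[in_sub]))
      )
    }
  }
  branch <- dplyr::bind_rows(branch)

  class_of <- function(z) {
    ifelse(z <= 0.05, "ADVT", ifelse(z <= 0.15, "BASAL", "LT"))
  }

  out <- list(
    ok_trait("HYP_DIA", dia_at(0.025)),
    ok_trait("TAP_DIA", dia_at(0.5))
  )

  if (nrow(branch) == 0) {
    out <- c(out, list(
      ok_trait(c("ADVT_COUNT", "BASAL_COUNT", "LT_BRA_FRQ", "LT_AVG_LEN",
                 "LT_DIST_FIRST", "LT_MED_DIA", "LT_AVG_DIA"), 0),
      na_trait(c("ADVT_ANG", "BASAL_ANG", "LT_AVG_ANG", "LT_ANG_RANGE",
                 "LT_MIN_ANG", "LT_MAX_ANG"), "not-applicable")
    ))
    return(dplyr::bind_rows(out))
  }

  branch$class <- class_of(branch$z)
  adv <- branch[branch$class == "ADVT", ]
  bas <- branch[branch$class == "BASAL", ]
  lat <- branch[branch$class == "LT", ]

  out <- c(out, list(
    ok_trait("ADVT_COUNT", nrow(adv)),
    ok_trait("BASAL_COUNT", nrow(bas)),
    if (nrow(adv) > 0) ok_trait("ADVT_ANG", mean(adv$emergence_deg))
    else na_trait("ADVT_ANG", "not-applicable"),
    if (nrow(bas) > 0) ok_trait("BASAL_ANG", mean(bas$emergence_deg))
    else na_trait("BASAL_ANG", "not-applicable")
  ))

  if (nrow(lat) == 0) {
    out <- c(out, list(
      ok_trait(c("LT_BRA_FRQ", "LT_AVG_LEN", "LT_DIST_FIRST",
                 "LT_MED_DIA", "LT_AVG_DIA"), 0),
      na_trait(c("LT_AVG_ANG", "LT_ANG_RANGE", "LT_MIN_ANG", "LT_MAX_ANG"),
               "not-applicable")
    ))
    return(dplyr::bind_rows(out))
  }

  lat_len <- lat$subtree_len
  lat_radii <- unlist(lat$subtree_radii)

  out <- c(out, list(
    ok_trait("LT_BRA_FRQ", nrow(lat) / tap_len_mm),
    ok_trait("LT_AVG_LEN", mean(lat_len) / s),
    ok_trait("LT_DIST_FIRST", min(lat$dist_px) / s),
    ok_trait("LT_MED_DIA", median(diameter_px(lat_radii)) / s),
    ok_trait("LT_AVG_DIA", mean(diameter_px(lat_radii)) / s),
    ok_trait("LT_AVG_ANG", mean(lat$emergence_deg)),
    ok_trait("LT_ANG_RANGE", diff(range(lat$emergence_deg))),
    ok_trait("LT_MIN_ANG", min(lat$emergence_deg)),
    ok_trait("LT_MAX_ANG", max(lat$emergence_deg))
  ))
  dplyr::bind_rows(out)
}
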
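# Medial-axis structure of the root: Euclidean distance transform,
# topology-preserving thinning, the skeleton graph (tips, junctions,
# degree-2 chains), spur pruning, collar detection and collar-to-tip
# paths.

#' Fill small interior holes of a binary mask
#'
#' Background regions (4-connected, dual to the 8-connected foreground)
#' that do not touch the image border and are at most `max_area` px are
#' filled. Used as cleanup of the root mask before skeletonization:
#' pixel-scale holes from thresholding noise or near-tangent root
#' margins otherwise seed spurious skeleton loops, while genuine gaps
#' between crossing roots are far larger and are preserved.
#'
#' @param mask logical matrix.
#' @param max_area largest hole area (px) to fill.
#' @return logical matrix.
#' @export
fill_small_holes <- function(mask, max_area = 20) {
  if (max_area <= 0) return(mask)
  bg <- EBImage::bwlabel(!mask)   # 4-connectivity
  if (max(bg) == 0) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  sizes <- tabulate(bg, max(bg))
  fill <- setdiff(which(sizes > 0 & sizes <= max_area), border)
  if (length(fill) > 0) mask[bg %in% fill] <- TRUE
  mask
}

#' Euclidean distance transform of a root mask
#'
#' Distance (in px) from every foreground pixel centre to the nearest
#' background pixel centre; zero on background. A single isolated
#' foreground pixel has distance 1.
#'
#' @param mask logical matrix (or `root_mask`).
#' @return numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  m <- if (inherits(mask, "root_mask")) mask$mask else mask
  if (!any(m)) stop_input("distance transform of an empty mask")
  EBImage::distmap(m * 1, metric = "euclidean")
}

#' Medial-axis skeleton of a root mask
#'
#' Topology-preserving (Zhang-Suen) thinning to a 1-px-wide 8-connected
#' skeleton, with the medial radius attached from the distance field.
#'
#' @param mask logical matrix (or `root_mask`) of the root component.
#' @param field optional precomputed [distance_transform()] of `mask`.
#' @return a `root_skeleton`: logical `mask`, numeric `radius` matrix
#'   (zero off the skeleton).
#' @export
skeletonize <- function(mask, field = NULL) {
  m <- if (inherits(mask, "root_mask")) mask$mask else mask
  if (!any(m)) stop_input("cannot skeletonize an empty mask")
  if (is.null(field)) field <- distance_transform(m)
  sk <- .thin_zs(m)
  rad <- matrix(0, nrow(m), ncol(m))
  rad[sk] <- field[sk]
  structure(list(mask = sk, radius = rad), class = "root_skeleton")
}

# 8-neighbour offsets (row, col)
.noff <- cbind(
  r = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  c = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

#' Build the skeleton graph
#'
#' Nodes are skeleton tips (one skeleton neighbour) and junctions (three
#' or more); edges are maximal degree-2 pixel chains with their polyline
#' geometry, arclength (diagonal steps count sqrt(2)) and per-point
#' medial radii. Isolated cycles receive one synthetic anchor node.
#'
#' @param skeleton a `root_skeleton`.
#' @return a `skeleton_graph`: tibbles `nodes` and `edges`, the `igraph`
#'   object, and the source skeleton.
#' @export
build_skeleton_graph <- function(skeleton) {
  sk <- skeleton$mask
  if (!any(sk)) stop_input("cannot build a graph from an empty skeleton")
  ncnt <- .neighbor_count8(sk)
  nr <- nrow(sk)

  node_px <- which(sk & ncnt != 2L)
  # pure cycles: handled after chain extraction
  node_id <- integer(length(sk))
  node_id[node_px] <- seq_along(node_px)

  nodes <- tibble(
    id = seq_along(node_px),
    row = ((node_px - 1L) %% nr) + 1L,
    col = ((node_px - 1L) %/% nr) + 1L,
    type = if (length(node_px) == 0) character(0)
           else ifelse(ncnt[node_px] <= 1L, "tip", "junction")
  )

  visited <- matrix(FALSE, nr, ncol(sk))
  edges_from <- integer(0); edges_to <- integer(0)
  geoms <- list()

  neighbors_of <- function(i, j) {
    rs <- i + .noff[, 1]; cs <- j + .noff[, 2]
    ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= ncol(sk)
    rs <- rs[ok]; cs <- cs[ok]
    keep <- sk[cbind(rs, cs)]
    cbind(rs[keep], cs[keep])
  }

  add_edge <- function(a, b, coords) {
    edges_from <<- c(edges_from, a)
    edges_to <<- c(edges_to, b)
    geoms[[length(geoms) + 1L]] <<- coords
  }

  walk_chain <- function(ni, nj, qi, qj) {
    # from node (ni,nj) through degree-2 pixel (qi,qj) to the next node
    coords <- matrix(c(ni, nj), 1, 2)
    prev_i <- ni; prev_j <- nj
    ci <- qi; cj <- qj
    repeat {
      coords <- rbind(coords, c(ci, cj))
      visited[ci, cj] <<- TRUE
      nb <- neighbors_of(ci, cj)
      nxt <- nb[!(nb[, 1] == prev_i & nb[, 2] == prev_j), , drop = FALSE]
      if (nrow(nxt) == 0) return(coords)          # dead end (shouldn't happen)
      # prefer an unvisited degree-2 continuation, else a node
      is_node <- node_id[(nxt[, 2] - 1L) * nr + nxt[, 1]] > 0L
      if (any(is_node)) {
        k <- which(is_node)[1]
        coords <- rbind(coords, nxt[k, ])
        return(coords)
      }
      un <- !visited[cbind(nxt[, 1], nxt[, 2])]
      if (!any(un)) return(coords)
      k <- which(un)[1]
      prev_i <- ci; prev_j <- cj
      ci <- nxt[k, 1]; cj <- nxt[k, 2]
    }
  }

  # chains leaving each node
  for (v in seq_len(nrow(nodes))) {
    ni <- nodes$row[v]; nj <- nodes$col[v]
    nb <- neighbors_of(ni, nj)
    if (nrow(nb) == 0) next
    for (q in seq_len(nrow(nb))) {
      qi <- nb[q, 1]; qj <- nb[q, 2]
      qid <- node_id[(qj - 1L) * nr + qi]
      if (qid > 0L) {
        if (v < qid) add_edge(v, qid, rbind(c(ni, nj), c(qi, qj)))
      } else if (!visited[qi, qj]) {
        coords <- walk_chain(ni, nj, qi, qj)
        last <- coords[nrow(coords), ]
        tid <- node_id[(last[2] - 1L) * nr + last[1]]
        if (tid > 0L) add_edge(v, tid, coords)
      }
    }
  }

  # isolated cycles: any unvisited degree-2 pixels left
  left <- which(sk & ncnt == 2L & !visited)
  while (length(left) > 0) {
    px <- left[1]
    i <- ((px - 1L) %% nr) + 1L; j <- ((px - 1L) %/% nr) + 1L
    vid <- nrow(nodes) + 1L
    nodes <- dplyr::bind_rows(nodes,
      tibble(id = vid, row = i, col = j, type = "cycle"))
    node_id[px] <- vid
    nb <- neighbors_of(i, j)
    if (nrow(nb) >= 1 && !visited[nb[1, 1], nb[1, 2]]) {
      coords <- walk_chain(i, j, nb[1, 1], nb[1, 2])
      last <- coords[nrow(coords), ]
      if (all(last == c(i, j))) {
        add_edge(vid, vid, coords)
      } else {
        # open chain back to the anchor through the other neighbour
        add_edge(vid, vid, rbind(coords, c(i, j)))
      }
    }
    visited[i, j] <- TRUE
    left <- which(sk & ncnt == 2L & !visited)
  }

  rad <- skeleton$radius
  edges <- tibble(
    edge = seq_along(geoms),
    from = edges_from,
    to = edges_to,
    length_px = vapply(geoms, polyline_length, numeric(1)),
    mean_radius = vapply(geoms, function(g) mean(rad[g]), numeric(1)),
    coords = geoms,
    radii = lapply(geoms, function(g) rad[g])
  )

  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to),
    directed = FALSE,
    vertices = data.frame(name = nodes$id, row = nodes$row, col = nodes$col,
                          type = nodes$type)
  )
  structure(list(nodes = nodes, edges = edges, graph = g, skeleton = skeleton),
            class = "skeleton_graph")
}

#' Prune short terminal spurs from a skeleton graph
#'
#' Iteratively removes tip-terminated edges shorter than
#' `max(min_len_px, 1.5 * radius at their junction)`; junctions reduced
#' to degree 2 are dissolved by rebuilding the graph from the pruned
#' skeleton. Runs to a fixpoint, so pruning is idempotent. An edge whose
#' two endpoints are both tips (an isolated segment) is never pruned.
#'
#' The prospective collar -- the topmost tip, ties broken toward
#' `anchor_col` -- is never pruned: on crowns whose first branches sit
#' close to the collar the stub above them is legitimately shorter than
#' the local radius, yet it anchors every collar-to-tip path.
#'
#' @param graph a `skeleton_graph`.
#' @param min_len_px minimum spur length in px (>= 0).
#' @param anchor_col column used to break ties between equally-top tips
#'   (defaults to the skeleton's mean column; callers pass the root
#'   centroid column).
#' @return a pruned `skeleton_graph`.
#' @export
prune_spurs <- function(graph, min_len_px = 10, anchor_col = NULL) {
  if (min_len_px < 0) stop_input("min_len_px must be >= 0")
  repeat {
    deg <- igraph::degree(graph$graph)
    names_deg <- as.integer(names(deg))
    degree_of <- setNames(as.integer(deg), names_deg)
    e <- graph$edges
    from_deg <- degree_of[as.character(e$from)]
    to_deg <- degree_of[as.character(e$to)]
    tip_end <- (from_deg == 1L) + (to_deg == 1L)
    junc_rad <- vapply(seq_len(nrow(e)), function(i) {
      if (from_deg[i] > 1L) e$radii[[i]][1]
      else if (to_deg[i] > 1L) e$radii[[i]][length(e$radii[[i]])]
      else 0
    }, numeric(1))

    # Thinning leaves small clusters of mutually adjacent junction
    # pixels at branch points; contract nodes linked by <= 2 px
    # junction-junction edges and reason about the cluster's external
    # degree, so a nub of junction pixels on a plain chain is not
    # mistaken for a branch point.
    short_jj <- e$length_px <= 2 & from_deg >= 3L & to_deg >= 3L
    cl_graph <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e$from[short_jj]),
                 to = as.character(e$to[short_jj])),
      directed = FALSE,
      vertices = data.frame(name = as.character(graph$nodes$id)))
    cl <- igraph::components(cl_graph)$membership
    cluster_of <- setNames(as.integer(cl), names(cl))
    e_from_cl <- cluster_of[as.character(e$from)]
    e_to_cl <- cluster_of[as.character(e$to)]
    external <- e_from_cl != e_to_cl
    ext_deg <- tabulate(c(e_from_cl[external], e_to_cl[external]),
                        nbins = max(cl))

    junc_cl <- ifelse(from_deg > 1L, e_from_cl, e_to_cl)
    cut <- tip_end == 1L & external &
      e$length_px < pmax(min_len_px, 1.5 * junc_rad) &
      ext_deg[junc_cl] >= 3L
    if (any(cut)) {
      # never amputate a branch: each cluster keeps external degree >= 2,
      # so cut at most (ext_deg - 2) of its tip edges, shortest first
      for (jc in unique(junc_cl[cut])) {
        at <- which(cut & junc_cl == jc)
        allowed <- max(ext_deg[jc] - 2L, 0L)
        if (length(at) > allowed) {
          keep <- at[order(e$length_px[at], decreasing = TRUE)][seq_len(length(at) - allowed)]
          cut[keep] <- FALSE
        }
      }
    }
    # protect the prospective collar tip
    if (any(cut)) {
      tip_nodes <- as.integer(names(deg)[deg == 1])
      tips <- graph$nodes[graph$nodes$id %in% tip_nodes, ]
      if (nrow(tips) > 0) {
        cand <- tips[tips$row == min(tips$row), ]
        ac <- anchor_col %||% mean(graph$nodes$col)
        collar_id <- cand$id[which.min(abs(cand$col - ac))]
        cut[e$from == collar_id | e$to == collar_id] <- FALSE
      }
    }
    if (!any(cut)) return(graph)
    sk <- graph$skeleton
    for (i in which(cut)) {
      coords <- e$coords[[i]]
      # keep the junction endpoint pixel, drop the rest
      drop <- if (from_deg[i] > 1L) coords[-1, , drop = FALSE]
              else coords[-nrow(coords), , drop = FALSE]
      sk$mask[drop] <- FALSE
      sk$radius[drop] <- 0
    }
    if (!any(sk$mask)) return(graph)
    graph <- build_skeleton_graph(sk)
  }
}

#' Find the collar node of the root skeleton
#'
#' The collar (where the stem meets the root system) is taken as the
#' skeleton tip with the smallest row (topmost); ties are broken by
#' proximity to the root component's centroid column.
#'
#' @param graph a `skeleton_graph`.
#' @param scene optional `root_scene` supplying the root centroid column
#'   for tie-breaking.
#' @return the collar node id.
#' @export
find_collar <- function(graph, scene = NULL) {
  deg <- igraph::degree(graph$graph)
  tips <- graph$nodes[graph$nodes$id %in% as.integer(names(deg)[deg <= 1]), ]
  if (nrow(tips) == 0) tips <- graph$nodes
  cand <- tips[tips$row == min(tips$row), ]
  if (nrow(cand) > 1) {
    cc <- if (!is.null(scene)) scene_component(scene, "root")$centroid_c
          else mean(graph$nodes$col)
    cand <- cand[which.min(abs(cand$col - cc)), ]
  }
  cand$id[1]
}

#' Collar-to-tip paths (root-tip paths)
#'
#' For every tip other than the collar, the minimum-arclength path along
#' the skeleton graph from the collar to that tip, with per-point depth
#' (row), medial radius and tangent angle. The tangent at a point is the
#' secant over a centred window of `tangent_window` polyline points
#' (clipped at the ends), reported as the absolute angle from the
#' horizontal in degrees \[0, 90\]; the side of each path relative to the
#' collar column is kept separately.
#'
#' @param graph a `skeleton_graph`.
#' @param collar collar node id from [find_collar()].
#' @param scale optional `scale_info` for arclength in mm.
#' @param tangent_window secant window width in points (default 9).
#' @return a tibble (class `rtp_set`), one row per path: `path_id`,
#'   `tip_id`, `tip_row`, `tip_col`, `side`, `arclength_px`,
#'   `arclength_mm`, and a `points` list-column of per-point tibbles
#'   (`row`, `col`, `radius`, `cum_px`, `angle_deg`).
#' @export
root_tip_paths <- function(graph, collar, scale = NULL, tangent_window = 9) {
  deg <- igraph::degree(graph$graph)
  tip_ids <- setdiff(as.integer(names(deg)[deg == 1]), collar)
  collar_col <- graph$nodes$col[graph$nodes$id == collar]
  s <- if (!is.null(scale)) scale$pixels_per_mm else NA_real_

  if (length(tip_ids) == 0) {
    out <- tibble(path_id = integer(), tip_id = integer(),
                  tip_row = integer(), tip_col = integer(),
                  side = character(), arclength_px = double(),
                  arclength_mm = double(), points = list())
    class(out) <- c("rtp_set", class(out))
    attr(out, "collar") <- collar
    attr(out, "collar_col") <- collar_col
    return(out)
  }

  sp <- igraph::shortest_paths(
    graph$graph,
    from = as.character(collar),
    to = as.character(tip_ids),
    weights = graph$edges$length_px,
    output = "epath"
  )

  rows <- lapply(seq_along(tip_ids), function(k) {
    ep <- as.integer(sp$epath[[k]])
    if (length(ep) == 0) return(NULL)
    cur <- collar
    coords <- NULL
    radii <- NULL
    node_seq <- collar
    for (eid in ep) {
      ge <- graph$edges$coords[[eid]]
      gr <- graph$edges$radii[[eid]]
      if (graph$edges$from[eid] != cur) {
        ge <- ge[rev(seq_len(nrow(ge))), , drop = FALSE]
        gr <- rev(gr)
        cur <- graph$edges$from[eid]
      } else {
        cur <- graph$edges$to[eid]
      }
      node_seq <- c(node_seq, cur)
      if (is.null(coords)) {
        coords <- ge; radii <- gr
      } else {
        coords <- rbind(coords, ge[-1, , drop = FALSE])
        radii <- c(radii, gr[-1])
      }
    }
    cum <- polyline_cumlen(coords)
    ang <- secant_angles(coords, w = tangent_window)
    tipn <- graph$nodes[graph$nodes$id == tip_ids[k], ]
    tibble(
      path_id = k,
      tip_id = tip_ids[k],
      tip_row = tipn$row,
      tip_col = tipn$col,
      side = if (tipn$col < collar_col) "left" else "right",
      arclength_px = cum[length(cum)],
      arclength_mm = if (is.na(s)) NA_real_ else cum[length(cum)] / s,
      edge_ids = list(ep),
      node_ids = list(node_seq),
      points = list(tibble(
        row = coords[, 1], col = coords[, 2],
        radius = radii, cum_px = cum, angle_deg = ang$angle_deg
      ))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$path_id <- seq_len(nrow(out))
  class(out) <- c("rtp_set", class(out))
  attr(out, "collar") <- collar
  attr(out, "collar_col") <- collar_col
  attr(out, "tangent_window") <- tangent_window
  out
}
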
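# Centerline morphometry: topological thinning of the vessel mask to a
# 1-voxel skeleton, conversion to a node/edge graph in mm coordinates, and
# the stem / branch / maximal-length definitions used for LSA counting:
# a stem is a trunk directly attached to the parent artery (root), a branch
# is a daughter segment with no subordinate branches (terminal edge), and
# an unbranched trunk counts as both.

# list of 13 half-neighbourhood offsets for 26-connectivity
half_offsets <- local({
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  off[as.logical(off$dx > 0 | (off$dx == 0 & off$dy > 0) |
                 (off$dx == 0 & off$dy == 0 & off$dz > 0)), ]
})

# Anchor voxels that thinning must never delete: one root-side source per
# connected component (nearest the parent artery / seed, or the deepest
# voxel by inscribed radius) plus the geodesic tips — local maxima of the
# within-mask geodesic distance from the source. Anchoring the tips is what
# keeps open tube ends from eroding axially, so centerline lengths stay
# faithful; topology preservation then guarantees the anchored curve
# survives thinning.
tip_anchors <- function(mask, spacing, parent_mask = NULL, seed_voxel = NULL) {
  d <- dim(mask)
  adj <- voxel_adjacency(mask, spacing)
  nv <- adj$n
  g <- if (length(adj$from) > 0)
    igraph::graph_from_edgelist(cbind(adj$from, adj$to), directed = FALSE)
  else igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nv - igraph::vcount(g)))
  igraph::E(g)$weight <- adj$weight
  comp <- igraph::components(g)$membership
  coords <- which(mask, arr.ind = TRUE)

  # per-component score for choosing the source voxel
  score <- if (!is.null(parent_mask)) {
    -array(sqrt(.cpp_edt_sq(!as.logical(parent_mask), d,
                            as.numeric(spacing))), dim = d)[coords]
  } else if (!is.null(seed_voxel)) {
    sv <- (as.numeric(seed_voxel) - 1) * spacing
    mm <- sweep(coords - 1, 2, spacing, `*`)
    -sqrt(colSums((t(mm) - sv)^2))
  } else {
    .cpp_edt_sq(as.logical(mask), d, as.numeric(spacing))[which(mask)]
  }
  sources <- vapply(seq_len(max(comp)), function(ci) {
    members <- which(comp == ci)
    members[which.max(score[members])]
  }, integer(1))

  dg <- igraph::distances(g, v = sources)
  dg <- apply(dg, 2, min)
  # tips: non-strict local maxima of the geodesic distance
  is_max <- rep(TRUE, nv)
  lower <- dg[adj$from] < dg[adj$to]
  is_max[adj$from[lower]] <- FALSE
  is_max[adj$to[dg[adj$to] < dg[adj$from]]] <- FALSE
  anchors <- array(FALSE, dim = d)
  keep <- unique(c(sources, which(is_max & is.finite(dg))))
  anchors[coords[keep, , drop = FALSE]] <- TRUE
  anchors
}

# adjacency pairs (i, j, mm distance) between TRUE voxels of a 3D mask
voxel_adjacency <- function(mask, spacing) {
  d <- dim(mask)
  id <- array(0L, dim = d)
  nvox <- sum(mask)
  id[mask] <- seq_len(nvox)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(half_offsets))) {
    o <- as.integer(half_offsets[r, ])
    xs <- seq_len(d[1] - abs(o[1])); ys <- seq_len(d[2] - abs(o[2]))
    zs <- seq_len(d[3] - abs(o[3]))
    a <- id[xs + max(0, -o[1]), ys + max(0, -o[2]), zs + max(0, -o[3])]
    b <- id[xs + max(0, o[1]), ys + max(0, o[2]), zs + max(0, o[3])]
    hit <- a > 0L & b > 0L
    if (any(hit)) {
      from <- c(from, a[hit]); to <- c(to, b[hit])
      w <- c(w, rep(sqrt(sum((o * spacing)^2)), sum(hit)))
    }
  }
  list(from = from, to = to, weight = w, n = nvox, id = id)
}

#' Skeletonize a vessel mask into a centerline graph
#'
#' Thins the mask to a 1-voxel-wide skeleton by topology-preserving erosion,
#' then converts it to a graph: endpoints (1 skeleton neighbour) and
#' junctions (>= 3 neighbours, merged when adjacent) become nodes with mm
#' coordinates; chains of regular voxels become edges whose arc length is
#' the polyline length in mm. Roots are the nodes inside (or nearest to) the
#' parent-artery mask or seed. Skeleton spurs shorter than `prune_mm` are
#' pruned before counting — thinning artifacts otherwise inflate branch
#' counts.
#'
#' @param vessel_mask 3D logical array.
#' @param spacing mm voxel spacing.
#' @param parent_mask 3D logical array marking the parent artery (A1/M1)
#'   attachment region, or NULL.
#' @param seed_voxel 1-based voxel triple used for rooting when no parent
#'   mask is given.
#' @param prune_mm spur-pruning length, mm (default: 2 voxels at mean
#'   spacing).
#' @return object of class `vessel_graph`: `nodes` (id, x, y, z mm,
#'   degree, is_root), `edges` (from, to, length_mm), `roots`, `skeleton`
#'   (logical array).
#' @export
skeletonize_to_graph <- function(vessel_mask, spacing,
                                 parent_mask = NULL, seed_voxel = NULL,
                                 prune_mm = 2 * mean(spacing)) {
  d <- dim(vessel_mask)
  if (!any(vessel_mask)) stop("vessel mask is empty")
  skel <- array(.cpp_thin(as.logical(vessel_mask), d,
                          tip_anchors(vessel_mask, spacing, parent_mask,
                                      seed_voxel)),
                dim = d)
  adj <- voxel_adjacency(skel, spacing)
  coords <- which(skel, arr.ind = TRUE)
  ord <- order(adj$id[skel])            # coords row for voxel id i
  coords <- coords[ord, , drop = FALSE]
  deg <- tabulate(c(adj$from, adj$to), adj$n)

  g_vox <- if (length(adj$from) > 0)
    igraph::graph_from_edgelist(cbind(adj$from, adj$to), directed = FALSE)
  else igraph::make_empty_graph(0, directed = FALSE)
  g_vox <- igraph::add_vertices(g_vox, max(0, adj$n - igraph::vcount(g_vox)))
  igraph::E(g_vox)$weight <- adj$weight

  node_vox <- deg != 2L
  # components with no natural node (pure cycles): nominate one voxel
  comp <- igraph::components(g_vox)$membership
  for (ci in which(tabulate(comp[node_vox], max(comp)) == 0 &
                   tabulate(comp) > 0)) {
    node_vox[which(comp == ci)[1]] <- TRUE
  }

  # cluster adjacent node voxels into graph nodes
  keepv <- which(node_vox)
  sub_nodes <- igraph::induced_subgraph(g_vox, keepv)
  cl <- igraph::components(sub_nodes)$membership
  cluster_of <- integer(adj$n)
  cluster_of[keepv] <- cl
  ncl <- max(cl)
  mm <- sweep(coords - 1, 2, spacing, `*`)
  node_xyz <- t(vapply(seq_len(ncl), function(i) {
    colMeans(mm[keepv[cl == i], , drop = FALSE])
  }, numeric(3)))

  # edges through chains of regular voxels
  ef <- integer(0); et <- integer(0); el <- numeric(0)
  chain_vox <- which(!node_vox)
  if (length(chain_vox) > 0) {
    subc <- igraph::induced_subgraph(g_vox, chain_vox)
    cm <- igraph::components(subc)$membership
    nbrs <- igraph::adjacent_vertices(g_vox, chain_vox)
    for (ci in seq_len(max(cm))) {
      members <- chain_vox[cm == ci]
      msub <- igraph::induced_subgraph(g_vox, members)
      dsub <- igraph::degree(msub)
      ends <- members[dsub <= 1]
      if (length(ends) == 0) next                    # chain cycle: no ends
      if (length(ends) == 1) ends <- c(ends, ends)  # single-voxel chain
      path_len <- sum(igraph::E(msub)$weight)
      # attachment node voxels at each chain end
      att <- lapply(ends[1:2], function(vx) {
        nb <- as.integer(nbrs[[match(vx, chain_vox)]])
        nb[node_vox[nb]]
      })
      if (length(att[[1]]) == 0 || length(att[[2]]) == 0) next
      a1 <- att[[1]][1]; a2 <- att[[2]][length(att[[2]])]
      if (length(ends) > 1 && ends[1] == ends[2] &&
          length(att[[1]]) >= 2) a2 <- att[[1]][2]
      extra <- sqrt(sum((mm[a1, ] - mm[ends[1], ])^2)) +
               sqrt(sum((mm[a2, ] - mm[ends[2], ])^2))
      c1 <- cluster_of[a1]; c2 <- cluster_of[a2]
      if (c1 == c2) next                 # cycle back to the same node: drop
      ef <- c(ef, c1); et <- c(et, c2); el <- c(el, path_len + extra)
    }
  }
  # direct node-node adjacencies across different clusters
  ends_mat <- igraph::as_edgelist(g_vox, names = FALSE)
  both_node <- node_vox[ends_mat[, 1]] & node_vox[ends_mat[, 2]]
  if (any(both_node)) {
    c1 <- cluster_of[ends_mat[both_node, 1]]
    c2 <- cluster_of[ends_mat[both_node, 2]]
    wd <- adj$weight[both_node]
    cross <- c1 != c2
    if (any(cross)) {
      key <- paste(pmin(c1[cross], c2[cross]), pmax(c1[cross], c2[cross]))
      keep <- !duplicated(key)
      ef <- c(ef, c1[cross][keep]); et <- c(et, c2[cross][keep])
      el <- c(el, wd[cross][keep])
    }
  }

  edges <- data.frame(from = ef, to = et, length_mm = el)
  nodes <- data.frame(id = seq_len(ncl),
                      x = node_xyz[, 1], y = node_xyz[, 2], z = node_xyz[, 3])

  # roots: clusters touching the parent mask / seed, searched up to 10 voxels
  roots <- integer(0)
  reach_mm <- 10 * mean(spacing)
  if (!is.null(parent_mask)) {
    pd <- array(sqrt(.cpp_edt_sq(!as.logical(parent_mask), d,
                                 as.numeric(spacing))), dim = d)
    dist_to_parent <- vapply(seq_len(ncl), function(i)
      min(pd[coords[keepv[cl == i], , drop = FALSE]]), numeric(1))
    roots <- which(dist_to_parent == 0)
    if (length(roots) == 0 && min(dist_to_parent) <= reach_mm)
      roots <- which.min(dist_to_parent)
  } else if (!is.null(seed_voxel)) {
    sv <- (as.numeric(seed_voxel) - 1) * spacing
    dseed <- sqrt(colSums((t(node_xyz) - sv)^2))
    if (min(dseed) <= reach_mm) roots <- which.min(dseed)
  }
  if ((!is.null(parent_mask) || !is.null(seed_voxel)) && length(roots) == 0)
    stop("rooting error: no skeleton node within 10 voxels of the parent ",
         "mask / seed")

  gr <- structure(list(nodes = nodes, edges = edges, roots = roots,
                       spacing = spacing, skeleton = skel),
                  class = "vessel_graph")
  gr <- prune_spurs(gr, prune_mm)
  gr$nodes$degree <- node_degrees(gr)
  gr$nodes$is_root <- gr$nodes$id %in% gr$roots
  gr
}

node_degrees <- function(gr) {
  tabulate(c(gr$edges$from, gr$edges$to), nrow(gr$nodes))
}

# remove sub-resolution terminal spurs, then absorb degree-2 pass-through
# nodes so edges correspond to anatomical segments
prune_spurs <- function(gr, prune_mm) {
  repeat {
    deg <- node_degrees(gr)
    leaf <- which(deg == 1 & !(gr$nodes$id %in% gr$roots))
    drop <- integer(0)
    for (l in leaf) {
      e <- which(gr$edges$from == l | gr$edges$to == l)
      other <- setdiff(c(gr$edges$from[e], gr$edges$to[e]), l)
      # spur: short terminal edge ending at a junction
      if (length(e) == 1 && gr$edges$length_mm[e] < prune_mm &&
          deg[other] >= 3) drop <- c(drop, e)
    }
    if (length(drop) == 0) break
    gr$edges <- gr$edges[-drop, , drop = FALSE]
  }
  # absorb pass-through nodes
  repeat {
    deg <- node_degrees(gr)
    mid <- which(deg == 2 & !(gr$nodes$id %in% gr$roots))
    merged <- FALSE
    for (u in mid) {
      e <- which(gr$edges$from == u | gr$edges$to == u)
      if (length(e) != 2) next
      nb <- vapply(e, function(i)
        if (gr$edges$from[i] == u) gr$edges$to[i] else gr$edges$from[i],
        numeric(1))
      if (any(nb == u)) next
      gr$edges <- rbind(gr$edges[-e, , drop = FALSE],
                        data.frame(from = nb[1], to = nb[2],
                                   length_mm = sum(gr$edges$length_mm[e])))
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  gr
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d edges, %d root(s), total arc %.3g mm\n",
              nrow(x$nodes), nrow(x$edges), length(x$roots),
              sum(x$edges$length_mm)))
  invisible(x)
}

as_igraph <- function(gr) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = gr$edges$from, to = gr$edges$to),
    directed = FALSE,
    vertices = data.frame(name = gr$nodes$id))
  igraph::E(g)$weight <- gr$edges$length_mm
  g
}

#' Count LSA stems and branches on a rooted centerline graph
#'
#' Stems are trunks directly attached to the parent artery: edges incident
#' to a root node. Branches are daughter vessels without subordinate
#' branches: terminal edges, i.e. edges ending in a non-root endpoint. A
#' trunk with no daughters is counted as both one stem and one branch.
#'
#' @param graph a [skeletonize_to_graph()] result with roots.
#' @return named integer vector `c(n_stems, n_branches)`.
#' @export
count_stems_branches <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (length(graph$roots) == 0)
    stop("rooting error: graph has no root attachment; supply a parent mask")
  deg <- node_degrees(graph)
  is_root <- graph$nodes$id %in% graph$roots
  stems <- sum(is_root[graph$edges$from] | is_root[graph$edges$to])
  leaf <- deg == 1 & !is_root
  branches <- sum(leaf[graph$edges$from] | leaf[graph$edges$to])
  c(n_stems = stems, n_branches = branches)
}

#' Maximal vessel length
#'
#' Maximum over endpoints of the geodesic arc length along the centerline
#' from the (nearest) root to the endpoint — the distance from the parent
#' artery to the visible end of the longest vessel — reported in cm.
#'
#' @param graph a rooted [skeletonize_to_graph()] result.
#' @return length in cm.
#' @export
longest_vessel_length <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (length(graph$roots) == 0)
    stop("rooting error: graph has no root attachment; supply a parent mask")
  g <- as_igraph(graph)
  dm <- igraph::distances(g, v = match(graph$roots, graph$nodes$id))
  reach <- apply(dm, 2, min)
  reach <- reach[is.finite(reach)]
  if (length(reach) == 0) stop("no endpoint reachable from any root")
  max(reach) / 10
}

#' Maximum intensity projection over a slab
#'
#' Per-pixel maximum over a slab of slices along a viewing axis (RAS
#' convention: sagittal = x, coronal = y, axial = z). The default is the
#' coronal view with a 28 mm slab, the standard reconstruction for LSA
#' length measurement.
#'
#' @param volume a [scalar_volume()].
#' @param axis `"coronal"`, `"axial"` or `"sagittal"`.
#' @param slab_thickness slab thickness, mm.
#' @param slab_center slab centre in world mm along the viewing axis
#'   (default: volume centre).
#' @return a 2D matrix of class `mip_image` with attributes `axis`,
#'   `pixel_spacing` (mm), `slab_range` (mm).
#' @export
project_mip <- function(volume, axis = c("coronal", "axial", "sagittal"),
                        slab_thickness = 28, slab_center = NULL) {
  stopifnot(inherits(volume, "scalar_volume"), slab_thickness > 0)
  axis <- match.arg(axis)
  ax <- c(sagittal = 1L, coronal = 2L, axial = 3L)[[axis]]
  d <- dim(volume$data)
  idx <- matrix(0, d[ax], 3)
  idx[, ax] <- 0:(d[ax] - 1)
  pos <- voxel_to_world(volume$affine, idx)[, ax]
  if (is.null(slab_center)) slab_center <- mean(range(pos))
  sel <- which(pos >= slab_center - slab_thickness / 2 &
               pos <= slab_center + slab_thickness / 2)
  if (length(sel) == 0)
    stop("slab [", slab_center - slab_thickness / 2, ", ",
         slab_center + slab_thickness / 2, "] mm does not intersect the ",
         "volume along the ", axis, " axis")
  slab <- switch(ax,
                 volume$data[sel, , , drop = FALSE],
                 volume$data[, sel, , drop = FALSE],
                 volume$data[, , sel, drop = FALSE])
  mip <- apply(slab, setdiff(1:3, ax), max)
  structure(mip, class = c("mip_image", "matrix"),
            axis = axis,
            pixel_spacing = volume$spacing[setdiff(1:3, ax)],
            slab_range = range(pos[sel]))
}
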
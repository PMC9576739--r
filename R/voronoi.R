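#' Voronoi tessellation of a localization table
#'
#' Computes the Voronoi (Dirichlet) tessellation of the localizations,
#' with every cell clipped to a rectangular window. Small cell area means
#' high local density, which is what the downstream segmentation
#' thresholds. Cells touching the window boundary are flagged: their area
#' is an artifact of the clipping, so they are excluded from clustering.
#'
#' @param table A [loc_table()].
#' @param window A [roi()] giving the tessellation window; default the
#'   bounding box of the points padded by 1% of its span.
#' @return A `voronoi_tess`: list with
#'   \describe{
#'     \item{x, y}{point coordinates (nm);}
#'     \item{area}{clipped cell areas (nm^2);}
#'     \item{boundary}{logical, cell touches the window boundary;}
#'     \item{adjacency}{two-column integer matrix of point-index pairs
#'       whose cells share a Voronoi edge (Delaunay neighbors of the
#'       unclipped diagram);}
#'     \item{edge_len}{length (nm) of each pair's shared Voronoi edge
#'       within the window;}
#'     \item{tiles}{per-point clipped cell polygons (polyclip format);}
#'     \item{window}{the window as c(xmin, xmax, ymin, ymax).}
#'   }
#' @export
compute_tessellation <- function(table, window = NULL) {
  n <- nrow(table)
  if (n < 2)
    stop("tessellation requires at least 2 localizations", call. = FALSE)
  if (diff(range(table$x)) == 0 && diff(range(table$y)) == 0)
    stop("tessellation is degenerate: all localizations coincide",
         call. = FALSE)
  if (is.null(window)) {
    padx <- max(diff(range(table$x)), 1) * 0.01
    pady <- max(diff(range(table$y)), 1) * 0.01
    rw <- c(min(table$x) - padx, max(table$x) + padx,
            min(table$y) - pady, max(table$y) + pady)
  } else {
    rw <- c(window$x_min, window$x_max, window$y_min, window$y_max)
    if (any(table$x < rw[1] | table$x > rw[2] |
            table$y < rw[3] | table$y > rw[4]))
      stop("localizations fall outside the tessellation window; clip first",
           call. = FALSE)
  }
  px <- table$x; py <- table$y
  # deldir drops exact duplicates, which would break index alignment;
  # displace them by a sub-picometer amount instead
  dup <- which(duplicated(cbind(px, py)))
  if (length(dup) > 0) px[dup] <- px[dup] + seq_along(dup) * 1e-6
  dd <- tryCatch(
    deldir::deldir(px, py, rw = rw, suppressMsge = TRUE),
    error = function(e)
      stop(sprintf("tessellation failed: %s", conditionMessage(e)),
           call. = FALSE))
  tl <- deldir::tile.list(dd)
  tiles <- lapply(tl, function(t) list(x = t$x, y = t$y))
  boundary <- vapply(tl, function(t) any(t$bp), logical(1))
  area <- dd$summary$dir.area
  # adjacency from the Delaunay triangulation (the dual of the unclipped
  # Voronoi diagram): a clipped window can hide the shared edge of two
  # boundary cells, but boundary cells never enter clusters anyway
  adj <- cbind(dd$delsgs$ind1, dd$delsgs$ind2)
  # length of the shared (window-clipped) Voronoi edge of each pair; pairs
  # whose shared edge lies outside the window get 0
  di <- dd$dirsgs
  di_len <- sqrt((di$x1 - di$x2)^2 + (di$y1 - di$y2)^2)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  edge_len <- di_len[match(key(adj[, 1], adj[, 2]),
                           key(di$ind1, di$ind2))]
  edge_len[is.na(edge_len)] <- 0
  tile_bbox <- vapply(tiles, function(t)
    c(min(t$x), max(t$x), min(t$y), max(t$y)), numeric(4))
  structure(list(x = px, y = py, area = area,
                 boundary = boundary, adjacency = adj,
                 edge_len = edge_len,
                 tiles = tiles, tile_bbox = tile_bbox, window = rw),
            class = "voronoi_tess")
}

#' @export
print.voronoi_tess <- function(x, ...) {
  cat(sprintf("<voronoi_tess> %d cells in [%g, %g] x [%g, %g] nm; %d on boundary\n",
              length(x$area), x$window[1], x$window[2], x$window[3],
              x$window[4], sum(x$boundary)))
  invisible(x)
}

#' Segment a tessellation into Voronoi clusters
#'
#' A Voronoi cluster is a connected collection of Voronoi polygons whose
#' areas all fall below an area threshold: localizations with cell area
#' `< area_threshold_nm2` (and not on the window boundary) are kept, and
#' clusters are the connected components of the kept set under shared
#' Voronoi-edge adjacency. Components with fewer than `min_cluster_size`
#' members are discarded. Clusters are ordered by their smallest member
#' index, so identical input yields an identical cluster list.
#'
#' @param tess A `voronoi_tess` from [compute_tessellation()].
#' @param area_threshold_nm2 Area threshold in nm^2 (e.g. 0.05 um^2 =
#'   5e4 nm^2 for clathrin, 2.0 um^2 = 2e6 nm^2 for actin).
#' @param min_cluster_size Minimum member count; default 5.
#' @param min_edge_ratio Corner-contact filter: two cells count as
#'   contiguous only when their shared Voronoi edge is at least this
#'   fraction of the smaller cell's diameter (sqrt of its area). Default
#'   0.05; genuine dense-phase contacts run at ~0.4, while degenerate
#'   slivers (nm-scale contacts between cells with distant generators)
#'   sit one to two orders of magnitude lower. 0 disables.
#' @return List of `voronoi_cluster` objects, each with `id`, `members`
#'   (integer indices into the tessellation points), `n_localizations`,
#'   `cell_area_nm2` (sum of member cell areas), and `centroid`.
#'   Footprint polygons are built on demand by [cluster_footprint()].
#' @export
segment_clusters <- function(tess, area_threshold_nm2, min_cluster_size = 5,
                             min_edge_ratio = 0.05) {
  stopifnot(area_threshold_nm2 > 0)
  kept <- which(tess$area < area_threshold_nm2 & !tess$boundary)
  if (length(kept) == 0) return(list())
  adj <- tess$adjacency
  if (!is.null(tess$edge_len) && min_edge_ratio > 0) {
    # corner-contact filter: a shared edge much shorter than the smaller
    # cell's diameter is a degenerate sliver (e.g. a nm-scale contact
    # between cells whose generators are um apart), not contiguity
    floor_len <- min_edge_ratio *
      sqrt(pmin(tess$area[adj[, 1]], tess$area[adj[, 2]]))
    adj <- adj[tess$edge_len >= floor_len, , drop = FALSE]
  }
  in_kept <- adj[, 1] %in% kept & adj[, 2] %in% kept
  sub <- adj[in_kept, , drop = FALSE]
  idx <- match(sub, kept)
  dim(idx) <- dim(sub)
  g <- igraph::make_graph(edges = as.numeric(t(idx)), n = length(kept),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- list()
  for (members in split(kept, comp)) {
    if (length(members) < min_cluster_size) next
    clusters[[length(clusters) + 1]] <- members
  }
  clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  lapply(seq_along(clusters), function(i) {
    members <- sort(clusters[[i]])
    structure(list(id = i, members = members,
                   n_localizations = length(members),
                   cell_area_nm2 = sum(tess$area[members]),
                   centroid = c(mean(tess$x[members]),
                                mean(tess$y[members]))),
              class = "voronoi_cluster")
  })
}

#' Footprint polygon of a Voronoi cluster
#'
#' Builds the spatial footprint of a cluster either as the union of its
#' members' (clipped) Voronoi cells — the default, which tiles the cluster
#' exactly, holes preserved — or as the convex hull of the member
#' coordinates.
#'
#' @param cluster A `voronoi_cluster` from [segment_clusters()].
#' @param tess The `voronoi_tess` the cluster was segmented from.
#' @param method `"voronoi-union"` (default) or `"convex-hull"`.
#' @return A multipolygon in polyclip format (list of contours, each
#'   `list(x, y)`), with attribute `area_nm2`.
#' @export
cluster_footprint <- function(cluster, tess,
                              method = c("voronoi-union", "convex-hull")) {
  method <- match.arg(method)
  members <- cluster$members
  if (length(members) == 0)
    stop("cluster has no members", call. = FALSE)
  if (method == "convex-hull") {
    x <- tess$x[members]; y <- tess$y[members]
    h <- grDevices::chull(x, y)
    if (length(h) < 3) {
      # (near-)collinear member set: fall back to the cell union
      poly <- poly_union(tess$tiles[members])
    } else {
      poly <- list(list(x = x[h], y = y[h]))
    }
  } else {
    poly <- poly_union(tess$tiles[members])
    if (length(poly) == 0)
      stop(sprintf("footprint union failed for cluster %d", cluster$id),
           call. = FALSE)
  }
  poly <- poly_ccw(poly)
  attr(poly, "area_nm2") <- poly_area(poly)
  poly
}

#' Brute-force Delaunay adjacency by empty-circumcircle testing
#'
#' Independent oracle for the tessellation's adjacency structure: two
#' points are Delaunay neighbors (equivalently, their Voronoi cells share
#' an edge) iff they are both vertices of a triangle whose circumcircle
#' contains no other point. Exhaustive over all point triples — O(n^4) —
#' so intended for n <= ~60.
#'
#' @param x,y Point coordinates.
#' @return Two-column matrix of index pairs (i < j).
#' @export
delaunay_adjacency_bruteforce <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  pairs <- matrix(integer(0), ncol = 2)
  seen <- matrix(FALSE, n, n)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 1, n - 1)) {
      for (k in seq(j + 1, n)) {
        # circumcenter of (i, j, k)
        ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
        d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(d) < 1e-12) next  # collinear triple
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
        r2 <- (ax - ux)^2 + (ay - uy)^2
        others <- setdiff(seq_len(n), c(i, j, k))
        if (any((x[others] - ux)^2 + (y[others] - uy)^2 < r2 * (1 - 1e-12)))
          next
        for (e in list(c(i, j), c(i, k), c(j, k))) {
          if (!seen[e[1], e[2]]) {
            seen[e[1], e[2]] <- TRUE
            pairs <- rbind(pairs, e)
          }
        }
      }
    }
  }
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(pairs) <- NULL
  pairs
}
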
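#' Expand a polygon outward by a Euclidean buffer
#'
#' Minkowski dilation of the polygon with a disk of radius `distance_nm`,
#' with round joins at convex corners. This builds the "local area" around
#' a clathrin cluster footprint, expanding the cluster polygon
#' symmetrically by 1 pixel (117 nm).
#'
#' @param poly Multipolygon in polyclip format.
#' @param distance_nm Buffer distance, `>= 0` nm.
#' @param arctol Arc discretization tolerance (nm); default
#'   `distance_nm / 500`, keeping the area error of rounded corners below
#'   about 0.1%.
#' @return The buffered multipolygon (contains the input).
#' @export
expand_polygon <- function(poly, distance_nm, arctol = NULL) {
  stopifnot(distance_nm >= 0)
  if (length(poly) == 0)
    stop("cannot expand an empty polygon", call. = FALSE)
  if (distance_nm == 0) return(poly_ccw(poly))
  if (is.null(arctol)) arctol <- distance_nm / 500
  out <- polyclip::polyoffset(poly_ccw(poly), distance_nm,
                              jointype = "round", arctol = arctol)
  if (length(out) == 0)
    stop("polygon expansion produced empty geometry", call. = FALSE)
  out
}

#' Per-cluster actin-clathrin colocalization record
#'
#' Implements the polygon workflow around one clathrin cluster:
#' \enumerate{
#'   \item clathrin footprint = cluster outline
#'     ([cluster_footprint()], method from `cfg$footprint_method`),
#'     dilated by `cfg$footprint_dilation_nm` to compensate localization
#'     blur;
#'   \item local area = that footprint expanded by
#'     `cfg$expansion_distance_nm` ([expand_polygon()]);
#'   \item `n_actin_local` = actin localizations inside the local area;
#'     only these are considered further;
#'   \item `n_actin_coloc` = those inside the clathrin footprint itself;
#'   \item actin polygon = union over all actin clusters of
#'     (footprint intersected with the local area);
#'   \item joint polygon = union(clathrin footprint, actin polygon);
#'   \item yellow zone = joint polygon minus clathrin footprint (the
#'     non-colocalized actin region); `n_actin_noncoloc` counts actin
#'     localizations inside it.
#' }
#' Percentages are relative to `n_actin_local`; densities are
#' localizations per um^2 of the respective zone. Actin localizations in
#' the local area but in neither polygon (unclustered background) count
#' toward `n_actin_local` only, so the two percentages need not sum
#' to 100.
#'
#' When no actin localization falls in the local area the cluster is
#' actin-negative: `empty_local` is set, percentages are `NA` (excluded
#' from percentage aggregation) and densities are 0, so that density
#' averages run over actin-positive and actin-negative clusters alike.
#'
#' @param clathrin_cluster A `voronoi_cluster` (clathrin channel).
#' @param clathrin_tess Its tessellation (for the footprint).
#' @param actin_table Registered actin [loc_table()].
#' @param actin_clusters List of actin `voronoi_cluster`s.
#' @param actin_tess The actin tessellation.
#' @param cfg A [pipeline_config()].
#' @return A one-row data.frame (`coloc_record`).
#' @export
coloc_per_cluster <- function(clathrin_cluster, clathrin_tess,
                              actin_table, actin_clusters, actin_tess,
                              cfg = pipeline_config()) {
  method <- if (!is.null(cfg$footprint_method)) cfg$footprint_method
            else "convex-hull"
  footprint <- cluster_footprint(clathrin_cluster, clathrin_tess,
                                 method = method)
  dil <- if (!is.null(cfg$footprint_dilation_nm))
    cfg$footprint_dilation_nm else 0
  if (dil > 0) footprint <- expand_polygon(footprint, dil)
  clathrin_area <- poly_area(footprint)
  local_poly <- expand_polygon(footprint, cfg$expansion_distance_nm)
  lb <- poly_bbox(local_poly)

  # candidate actin points by bbox, then exact point-in-polygon
  cand <- which(actin_table$x >= lb["xmin"] & actin_table$x <= lb["xmax"] &
                actin_table$y >= lb["ymin"] & actin_table$y <= lb["ymax"])
  ax <- actin_table$x[cand]; ay <- actin_table$y[cand]
  in_local <- points_in_poly(ax, ay, local_poly)
  n_local <- sum(in_local)
  in_coloc <- points_in_poly(ax[in_local], ay[in_local], footprint)
  n_coloc <- sum(in_coloc)

  # actin polygon: member Voronoi cells of intersecting actin clusters,
  # clipped to the local area (cells are interior-disjoint, so a single
  # clipped union over the collected tiles is their union region)
  tb <- actin_tess$tile_bbox
  tiles <- list()
  for (ac in actin_clusters) {
    mem <- ac$members
    mb <- c(xmin = min(actin_tess$x[mem]), xmax = max(actin_tess$x[mem]),
            ymin = min(actin_tess$y[mem]), ymax = max(actin_tess$y[mem]))
    if (!bbox_overlaps(mb, lb)) next
    keep <- tb[1, mem] <= lb["xmax"] & tb[2, mem] >= lb["xmin"] &
            tb[3, mem] <= lb["ymax"] & tb[4, mem] >= lb["ymin"]
    tiles <- c(tiles, actin_tess$tiles[mem[keep]])
  }
  actin_poly <- if (length(tiles) > 0)
    poly_intersect(tiles, local_poly) else list()

  joint <- poly_union(footprint, actin_poly)
  yellow <- poly_minus(joint, footprint)
  yellow_area <- poly_area(yellow)
  joint_area <- poly_area(joint)
  n_noncoloc <- sum(points_in_poly(ax[in_local], ay[in_local], yellow))

  empty_local <- n_local == 0
  um2 <- 1e-6  # nm^2 -> um^2
  data.frame(
    cluster_id = clathrin_cluster$id,
    n_clathrin = clathrin_cluster$n_localizations,
    clathrin_area_nm2 = clathrin_area,
    expanded_area_nm2 = poly_area(local_poly),
    yellow_area_nm2 = yellow_area,
    joint_area_nm2 = joint_area,
    n_actin_local = n_local,
    n_actin_coloc = n_coloc,
    n_actin_noncoloc = n_noncoloc,
    pct_coloc = if (empty_local) NA_real_ else 100 * n_coloc / n_local,
    pct_noncoloc = if (empty_local) NA_real_ else 100 * n_noncoloc / n_local,
    density_coloc_um2 = if (clathrin_area > 0)
      n_coloc / (clathrin_area * um2) else 0,
    density_noncoloc_um2 = if (yellow_area > 0)
      n_noncoloc / (yellow_area * um2) else 0,
    zero_yellow_flag = yellow_area == 0,
    empty_local_flag = empty_local
  )
}

#' Aggregate per-cluster records into an ROI summary
#'
#' Produces the two ROI-level percentages of the workflow — pooled counts
#' across clusters — together with per-cluster mean and SD. The pooled
#' percentage is `100 * sum(n_actin_coloc) / sum(n_actin_local)` over
#' actin-positive clusters; actin-negative clusters (empty local areas)
#' are excluded from the percentage statistics but included in the density
#' means, which average actin localization densities over actin-positive
#' and actin-negative clathrin clusters alike.
#'
#' @param records data.frame of rows from [coloc_per_cluster()].
#' @param roi_id Identifier carried into the summary.
#' @return A one-row data.frame (`roi_summary`).
#' @export
aggregate_roi <- function(records, roi_id = NA_character_) {
  if (is.null(records) || nrow(records) == 0)
    stop("cannot aggregate an empty record set", call. = FALSE)
  pos <- records[!records$empty_local_flag & records$n_actin_local > 0, ]
  pooled <- if (nrow(pos) > 0)
    100 * sum(pos$n_actin_coloc) / sum(pos$n_actin_local) else NA_real_
  pooled_non <- if (nrow(pos) > 0)
    100 * sum(pos$n_actin_noncoloc) / sum(pos$n_actin_local) else NA_real_
  data.frame(
    roi_id = as.character(roi_id),
    n_clusters = nrow(records),
    n_actin_positive = nrow(pos),
    pooled_pct_coloc = pooled,
    pooled_pct_noncoloc = pooled_non,
    mean_pct_coloc = if (nrow(pos) > 0) mean(pos$pct_coloc) else NA_real_,
    sd_pct_coloc = if (nrow(pos) > 1) stats::sd(pos$pct_coloc) else
      if (nrow(pos) == 1) 0 else NA_real_,
    mean_density_coloc_um2 = mean(records$density_coloc_um2),
    mean_density_noncoloc_um2 = mean(records$density_noncoloc_um2)
  )
}
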
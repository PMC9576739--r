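#' Run the full two-channel colocalization pipeline
#'
#' Composes the stages in acquisition order: fiducial-based fine channel
#' registration (actin as the moving channel by default), removal of
#' fiducial-adjacent localizations, per-channel Voronoi tessellation and
#' threshold segmentation (channel-specific thresholds), ROI filtering,
#' the per-cluster colocalization workflow, and ROI aggregation.
#'
#' @param cfg A [pipeline_config()].
#' @param clathrin,actin [loc_table()]s, or paths readable by
#'   [read_localizations()] with the generic nm dialect.
#' @param rois List of [roi()]s; default one ROI spanning the window.
#' @param window [roi()] tessellation window; default the joint bounding
#'   box of both channels padded by 1%.
#' @param register Run the registration stage; set FALSE for inputs that
#'   are already aligned or contain no fiducials.
#' @param moving Which channel the shift is applied to; default
#'   `"actin"`.
#' @return A `coloc_result`: list with `records` (per-cluster data.frame
#'   including `roi_id`), `roi_summaries`, `shift`
#'   (`translation_shift` or NULL), `clusters` (per-channel cluster
#'   lists), and `manifest` (config snapshot, seed, stage warnings,
#'   counts, timings).
#' @export
run_pipeline <- function(cfg = pipeline_config(), clathrin, actin,
                         rois = NULL, window = NULL, register = TRUE,
                         moving = c("actin", "clathrin")) {
  moving <- match.arg(moving)
  t0 <- proc.time()[["elapsed"]]
  warnings <- c(sprintf(
    "Voronoi area thresholds %.3g (ch1) and %.3g (ch2) interpreted in %s",
    cfg$voronoi_area_threshold_ch1, cfg$voronoi_area_threshold_ch2,
    cfg$area_unit))
  note <- function(msg) warnings <<- c(warnings, msg)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  if (is.character(clathrin))
    clathrin <- stage("input", read_localizations(clathrin,
                                                  channel_label = "clathrin"))
  if (is.character(actin))
    actin <- stage("input", read_localizations(actin,
                                               channel_label = "actin"))
  n_in <- c(clathrin = nrow(clathrin), actin = nrow(actin))

  ## registration
  shift <- NULL
  fid_ref <- NULL
  if (register) {
    fids <- stage("registration", {
      withCallingHandlers({
        fc <- detect_fiducials(clathrin, cfg$fiducial_max_count,
                               cfg$fiducial_persistence,
                               cfg$fiducial_pairing_radius_nm)
        fa <- detect_fiducials(actin, cfg$fiducial_max_count,
                               cfg$fiducial_persistence,
                               cfg$fiducial_pairing_radius_nm)
        list(fc, fa)
      }, warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      }, message = function(m) {
        note(trimws(conditionMessage(m))); invokeRestart("muffleMessage")
      })
    })
    shift <- stage("registration", suppressMessages(
      if (moving == "actin")
        estimate_channel_shift(fids[[1]], fids[[2]])
      else estimate_channel_shift(fids[[2]], fids[[1]])))
    if (moving == "actin") actin <- apply_shift(actin, shift)
    else clathrin <- apply_shift(clathrin, shift)
    fid_ref <- if (moving == "actin") fids[[1]]$centers else fids[[2]]$centers
    ## fiducial-adjacent localizations are artifacts of the bright beads;
    ## drop them before tessellation (ROIs avoid fiducials)
    drop_near <- function(tab, centers, r) {
      keep <- rep(TRUE, nrow(tab))
      for (i in seq_len(nrow(centers))) {
        keep <- keep & !(abs(tab$x - centers$x[i]) <= r &
                         abs(tab$y - centers$y[i]) <= r &
                         (tab$x - centers$x[i])^2 +
                         (tab$y - centers$y[i])^2 <= r^2)
      }
      loc_table(tab$x[keep], tab$y[keep], tab$frame[keep],
                if ("intensity" %in% names(tab)) tab$intensity[keep],
                attr(tab, "channel_label"))
    }
    r_ex <- cfg$fiducial_exclusion_radius_nm
    clathrin <- drop_near(clathrin, fid_ref, r_ex)
    actin <- drop_near(actin, fid_ref, r_ex)
    note(sprintf("registration: shift (%.2f, %.2f) nm from %d fiducials",
                 shift$dx, shift$dy, shift$n_fiducials_used))
  }
  t_reg <- proc.time()[["elapsed"]]

  ## tessellation window and segmentation
  if (is.null(window)) {
    xs <- c(clathrin$x, actin$x); ys <- c(clathrin$y, actin$y)
    padx <- diff(range(xs)) * 0.01; pady <- diff(range(ys)) * 0.01
    window <- roi(min(xs) - padx, min(ys) - pady,
                  max(xs) + padx, max(ys) + pady, id = "window")
  }
  clathrin <- clip_to_roi(clathrin, window)
  actin <- clip_to_roi(actin, window)

  tess_cl <- stage("tessellation", compute_tessellation(clathrin, window))
  tess_ac <- stage("tessellation", compute_tessellation(actin, window))
  clusters_cl <- stage("segmentation",
    segment_clusters(tess_cl, cfg$threshold_ch1_nm2, cfg$min_cluster_size))
  clusters_ac <- stage("segmentation",
    segment_clusters(tess_ac, cfg$threshold_ch2_nm2, cfg$min_cluster_size))
  t_seg <- proc.time()[["elapsed"]]

  if (is.null(rois))
    rois <- list(roi(window$x_min, window$y_min, window$x_max,
                     window$y_max, id = "full_field"))

  ## per-cluster colocalization within each ROI
  records <- list()
  summaries <- list()
  for (r in rois) {
    in_roi <- vapply(clusters_cl, function(cl)
      cl$centroid[1] >= r$x_min && cl$centroid[1] < r$x_max &&
      cl$centroid[2] >= r$y_min && cl$centroid[2] < r$y_max, logical(1))
    roi_clusters <- clusters_cl[in_roi]
    if (length(roi_clusters) == 0) {
      note(sprintf("ROI %s contains no clathrin clusters", r$id))
      next
    }
    recs <- stage("colocalization", do.call(rbind, lapply(
      roi_clusters, coloc_per_cluster,
      clathrin_tess = tess_cl, actin_table = actin,
      actin_clusters = clusters_ac, actin_tess = tess_ac, cfg = cfg)))
    recs <- cbind(roi_id = r$id, recs)
    records[[length(records) + 1]] <- recs
    summaries[[length(summaries) + 1]] <-
      stage("aggregation", aggregate_roi(recs, r$id))
  }
  if (length(records) == 0)
    stop("[colocalization] no clathrin clusters in any ROI", call. = FALSE)
  records <- do.call(rbind, records)
  roi_summaries <- do.call(rbind, summaries)
  t_end <- proc.time()[["elapsed"]]

  manifest <- list(
    package = "stormcoloc",
    version = as.character(utils::packageVersion("stormcoloc")),
    config = unclass(cfg),
    rng_seed = cfg$rng_seed,
    n_localizations_in = as.list(n_in),
    n_localizations_analyzed = list(clathrin = nrow(clathrin),
                                    actin = nrow(actin)),
    n_clusters = list(clathrin = length(clusters_cl),
                      actin = length(clusters_ac)),
    shift = if (!is.null(shift))
      list(dx = shift$dx, dy = shift$dy,
           n_fiducials_used = shift$n_fiducials_used) else NULL,
    warnings = warnings,
    timings_s = list(registration = round(t_reg - t0, 3),
                     segmentation = round(t_seg - t_reg, 3),
                     colocalization = round(t_end - t_seg, 3))
  )
  structure(list(records = records, roi_summaries = roi_summaries,
                 shift = shift,
                 clusters = list(clathrin = clusters_cl,
                                 actin = clusters_ac),
                 tess = list(clathrin = tess_cl, actin = tess_ac),
                 manifest = manifest),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d clathrin clusters in %d ROI(s)\n",
              nrow(x$records), nrow(x$roi_summaries)))
  for (i in seq_len(nrow(x$roi_summaries))) {
    s <- x$roi_summaries[i, ]
    cat(sprintf("  %s: pooled %.2f%% coloc, mean %.2f +/- %.2f%% (n = %d)\n",
                s$roi_id, s$pooled_pct_coloc, s$mean_pct_coloc,
                s$sd_pct_coloc, s$n_clusters))
  }
  invisible(x)
}

#' Write pipeline outputs to a results directory
#'
#' Writes `per_cluster.csv`, `per_roi.csv` and `manifest.json`. The CSVs
#' are fully determined by input and config (no timestamps), so repeated
#' runs with the same seed are byte-identical; stage timings live only in
#' the manifest.
#'
#' @param result A `coloc_result` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$records, file.path(dir, "per_cluster.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$roi_summaries, file.path(dir, "per_roi.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' Render a human-readable summary report from a results directory
#'
#' Reads the CSVs written by [write_pipeline_results()] and renders a
#' Markdown summary in the style "mean +/- SD, n = ... clusters". Every
#' number is taken from a CSV cell; nothing is recomputed, so the report
#' is a faithful view of the stored results and regenerating it from
#' unchanged results yields an identical document.
#'
#' @param dir Results directory.
#' @param file Output path; default `report.md` inside `dir`.
#' @return The path to the written report, invisibly.
#' @export
report_run <- function(dir, file = file.path(dir, "report.md")) {
  pc_path <- file.path(dir, "per_cluster.csv")
  pr_path <- file.path(dir, "per_roi.csv")
  if (!file.exists(pc_path) || !file.exists(pr_path))
    stop(sprintf("no pipeline results found in %s", dir), call. = FALSE)
  pc <- utils::read.csv(pc_path)
  pr <- utils::read.csv(pr_path)
  lines <- c("# Colocalization run summary", "")
  if (nrow(pr) == 0) {
    lines <- c(lines, "No ROI summaries: empty results.")
  } else {
    for (i in seq_len(nrow(pr))) {
      s <- pr[i, ]
      lines <- c(lines,
        sprintf("## ROI %s", s$roi_id),
        "",
        sprintf("- clathrin clusters: %d (%d actin-positive)",
                s$n_clusters, s$n_actin_positive),
        sprintf("- pooled colocalized actin: %.2f%%", s$pooled_pct_coloc),
        sprintf("- pooled non-colocalized actin: %.2f%%",
                s$pooled_pct_noncoloc),
        sprintf("- per-cluster colocalized actin: %.2f +/- %.2f%% (n = %d clusters)",
                s$mean_pct_coloc, s$sd_pct_coloc, s$n_actin_positive),
        sprintf("- mean actin density inside clathrin footprints: %.2f /um^2",
                s$mean_density_coloc_um2),
        sprintf("- mean actin density in non-colocalized zone: %.2f /um^2",
                s$mean_density_noncoloc_um2),
        "")
    }
    lines <- c(lines, "## All clusters", "",
               sprintf("- total clathrin clusters: %d", nrow(pc)),
               sprintf("- actin-positive clusters: %d",
                       sum(!pc$empty_local_flag)))
  }
  writeLines(lines, file)
  invisible(file)
}
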
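#' Parameters of a synthetic two-channel STORM scene
#'
#' The generator emulates the structures the pipeline is built for:
#' clathrin-coated structures as compact filled disks (50-100 nm radius,
#' i.e. 100-200 nm across), actin as localization tracks along thin
#' filament segments, uniform background localizations in both channels,
#' bright persistent fiducial markers shared by the channels, a global
#' inter-channel translation, and Gaussian localization-precision noise.
#' A chosen fraction of the actin localizations is planted uniformly
#' inside clathrin disks, giving a known colocalized fraction for
#' recovery tests.
#'
#' The total actin budget is fixed: `planted_coloc_fraction` of it is
#' planted inside clathrin disks and the filament/background components
#' are scaled by the complement, so scenes at different planted fractions
#' have comparable size and density.
#'
#' With `filament_placement = "peripheral"` (default) each filament runs
#' tangentially past a cluster at a standoff of 40-100 nm from the disk
#' edge — actin skirting the cluster periphery, the geometry the
#' colocalization workflow is aimed at. `"free"` scatters filaments
#' uniformly over the field.
#'
#' @param field_nm Field size (x, y) in nm; default 20 x 20 um.
#' @param n_frames Acquisition length; default 30000 frames.
#' @param n_clusters Clathrin cluster count; default 60.
#' @param cluster_radius_nm Range of disk radii; default c(50, 100).
#' @param locs_per_cluster Mean localizations per cluster (Poisson);
#'   default 150.
#' @param n_filaments Actin filament count; default 60.
#' @param filament_length_nm Segment length; default 280.
#' @param filament_width_nm Full width of the filament cross-section
#'   (Gaussian, SD = width/2); default 10.
#' @param locs_per_filament Mean localizations per filament at planted
#'   fraction 0; default 170.
#' @param filament_placement `"peripheral"` or `"free"`.
#' @param peripheral_standoff_nm Distance range from disk edge to the
#'   filament line for peripheral placement; default c(40, 100).
#' @param planted_coloc_fraction Fraction of actin localizations planted
#'   uniformly inside clathrin disks; default 0.25.
#' @param background_density_um2 Background localization density per
#'   channel (locs/um^2), named c(clathrin=, actin=); default 1 and 1.
#' @param sigma_nm Localization precision SD applied to every non-fiducial
#'   localization; default 20.
#' @param n_fiducials Fiducial marker count; default 50.
#' @param fiducial_emission_prob Per-frame emission probability; default 1.
#' @param fiducial_sigma_nm Per-frame fiducial localization SD; default 10.
#' @param fiducial_min_sep_nm Minimum fiducial separation; default 1500.
#' @param true_shift_nm Translation applied to the actin channel (dx, dy);
#'   default c(0, 0).
#' @param rng_seed Seed; the scene is fully reproducible from it.
#' @return A `scene_params` list.
#' @export
scene_params <- function(field_nm = c(20000, 20000),
                         n_frames = 30000,
                         n_clusters = 60,
                         cluster_radius_nm = c(50, 100),
                         locs_per_cluster = 150,
                         n_filaments = 60,
                         filament_length_nm = 280,
                         filament_width_nm = 10,
                         locs_per_filament = 170,
                         filament_placement = c("peripheral", "free"),
                         peripheral_standoff_nm = c(40, 100),
                         planted_coloc_fraction = 0.25,
                         background_density_um2 = c(clathrin = 1, actin = 1),
                         sigma_nm = 20,
                         n_fiducials = 50,
                         fiducial_emission_prob = 1,
                         fiducial_sigma_nm = 10,
                         fiducial_min_sep_nm = 1500,
                         true_shift_nm = c(0, 0),
                         rng_seed = 1L) {
  filament_placement <- match.arg(filament_placement)
  stopifnot(planted_coloc_fraction >= 0, planted_coloc_fraction <= 1,
            sigma_nm > 0, n_frames >= 1, all(field_nm > 0),
            n_clusters >= 0, n_filaments >= 0, n_fiducials >= 0,
            fiducial_emission_prob >= 0, fiducial_emission_prob <= 1)
  p <- as.list(environment())
  class(p) <- "scene_params"
  p
}

# uniform points in a disk
runif_disk <- function(n, cx, cy, r) {
  th <- stats::runif(n, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(n))
  cbind(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

# rejection-sample n points in the field with pairwise min separation
place_separated <- function(n, lo_x, hi_x, lo_y, hi_y, min_sep,
                            max_tries = 20000L, what = "object") {
  xs <- numeric(0); ys <- numeric(0); tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf("could not place %d %ss with separation %g nm",
                   n, what, min_sep), call. = FALSE)
    x <- stats::runif(1, lo_x, hi_x); y <- stats::runif(1, lo_y, hi_y)
    if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  cbind(x = xs, y = ys)
}

#' Simulate a two-channel localization scene with ground truth
#'
#' Draws a scene from [scene_params()]: returns the clathrin and actin
#' localization tables exactly as a reconstruction pipeline would see them
#' (precision noise applied, actin channel translated by the true shift)
#' plus a ground-truth object holding the pre-noise positions and
#' per-localization labels, from which [oracle_coloc_fraction()] computes
#' the reference colocalized fraction.
#'
#' @param params A [scene_params()].
#' @return List with `clathrin` and `actin` ([loc_table()]s) and `truth`
#'   (`scene_truth`): clathrin disk centers/radii, filament endpoints,
#'   fiducial positions, per-localization labels (`cluster` / `filament` /
#'   `background` / `planted` / `fiducial`), true (pre-noise, pre-shift)
#'   coordinates, the true shift and the realized colocalized fraction.
#' @export
simulate_scene <- function(params = scene_params()) {
  p <- params
  set.seed(p$rng_seed)
  fx <- p$field_nm[1]; fy <- p$field_nm[2]
  field_um2 <- fx * fy * 1e-6
  r_max <- max(p$cluster_radius_nm)
  margin <- r_max + 500

  ## clathrin disks
  if (p$n_clusters > 0) {
    ctr <- place_separated(p$n_clusters, margin, fx - margin,
                           margin, fy - margin,
                           min_sep = 2 * (r_max + 650),
                           what = "cluster")
    radii <- stats::runif(p$n_clusters, p$cluster_radius_nm[1],
                          p$cluster_radius_nm[2])
    disks <- data.frame(x = ctr[, 1], y = ctr[, 2], r = radii)
  } else {
    disks <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
  }

  f <- p$planted_coloc_fraction
  n_bg_actin_nom <- round(p$background_density_um2[["actin"]] * field_um2)
  n_actin_total <- p$n_filaments * p$locs_per_filament + n_bg_actin_nom
  n_planted <- round(f * n_actin_total)
  fil_locs_mean <- p$locs_per_filament * (1 - f)
  n_bg_actin <- round(n_bg_actin_nom * (1 - f))

  ## clathrin channel: cluster points + background
  cl_true <- list(); cl_label <- list()
  if (p$n_clusters > 0) {
    for (i in seq_len(p$n_clusters)) {
      n_i <- stats::rpois(1, p$locs_per_cluster)
      if (n_i == 0) next
      cl_true[[length(cl_true) + 1]] <-
        runif_disk(n_i, disks$x[i], disks$y[i], disks$r[i])
      cl_label[[length(cl_label) + 1]] <- rep("cluster", n_i)
    }
  }
  n_bg_cl <- round(p$background_density_um2[["clathrin"]] * field_um2)
  if (n_bg_cl > 0) {
    cl_true[[length(cl_true) + 1]] <-
      cbind(x = stats::runif(n_bg_cl, 0, fx),
            y = stats::runif(n_bg_cl, 0, fy))
    cl_label[[length(cl_label) + 1]] <- rep("background", n_bg_cl)
  }
  cl_xy <- do.call(rbind, cl_true)
  cl_lab <- unlist(cl_label)

  ## actin channel: filaments (peripheral or free) + planted + background
  segs <- data.frame(x1 = numeric(0), y1 = numeric(0),
                     x2 = numeric(0), y2 = numeric(0), cluster = integer(0))
  ac_true <- list(); ac_label <- list()
  if (p$n_filaments > 0 && fil_locs_mean > 0) {
    for (k in seq_len(p$n_filaments)) {
      if (p$filament_placement == "peripheral" && p$n_clusters > 0) {
        ci <- sample.int(p$n_clusters, 1)
        d <- disks$r[ci] + stats::runif(1, p$peripheral_standoff_nm[1],
                                        p$peripheral_standoff_nm[2])
        phi <- stats::runif(1, 0, 2 * pi)
        cx <- disks$x[ci] + d * cos(phi)
        cy <- disks$y[ci] + d * sin(phi)
        ux <- -sin(phi); uy <- cos(phi)  # tangential direction
      } else {
        ci <- NA_integer_
        cx <- stats::runif(1, margin, fx - margin)
        cy <- stats::runif(1, margin, fy - margin)
        th <- stats::runif(1, 0, 2 * pi)
        ux <- cos(th); uy <- sin(th)
      }
      h <- p$filament_length_nm / 2
      segs <- rbind(segs, data.frame(x1 = cx - h * ux, y1 = cy - h * uy,
                                     x2 = cx + h * ux, y2 = cy + h * uy,
                                     cluster = ci))
      n_k <- stats::rpois(1, fil_locs_mean)
      if (n_k == 0) next
      t_k <- stats::runif(n_k, -h, h)
      perp <- stats::rnorm(n_k, 0, p$filament_width_nm / 2)
      ac_true[[length(ac_true) + 1]] <-
        cbind(x = cx + t_k * ux - perp * uy,
              y = cy + t_k * uy + perp * ux)
      ac_label[[length(ac_label) + 1]] <- rep("filament", n_k)
    }
  }
  if (n_planted > 0) {
    if (p$n_clusters == 0)
      stop("cannot plant colocalized actin without clathrin clusters",
           call. = FALSE)
    which_disk <- sample.int(p$n_clusters, n_planted, replace = TRUE)
    ac_true[[length(ac_true) + 1]] <-
      runif_disk(n_planted, disks$x[which_disk], disks$y[which_disk],
                 disks$r[which_disk])
    ac_label[[length(ac_label) + 1]] <- rep("planted", n_planted)
  }
  if (n_bg_actin > 0) {
    ac_true[[length(ac_true) + 1]] <-
      cbind(x = stats::runif(n_bg_actin, 0, fx),
            y = stats::runif(n_bg_actin, 0, fy))
    ac_label[[length(ac_label) + 1]] <- rep("background", n_bg_actin)
  }
  ac_xy <- do.call(rbind, ac_true)
  ac_lab <- unlist(ac_label)

  ## fiducials: same physical beads in both channels
  if (p$n_fiducials > 0) {
    fid <- place_separated(p$n_fiducials, margin, fx - margin,
                           margin, fy - margin,
                           min_sep = p$fiducial_min_sep_nm,
                           what = "fiducial")
  } else {
    fid <- cbind(x = numeric(0), y = numeric(0))
  }
  emit_fiducials <- function() {
    if (nrow(fid) == 0)
      return(list(xy = cbind(x = numeric(0), y = numeric(0)),
                  frame = integer(0)))
    per_fid <- lapply(seq_len(nrow(fid)), function(i) {
      on <- which(stats::runif(p$n_frames) < p$fiducial_emission_prob) - 1L
      n_on <- length(on)
      list(xy = cbind(x = fid[i, 1] + stats::rnorm(n_on, 0, p$fiducial_sigma_nm),
                      y = fid[i, 2] + stats::rnorm(n_on, 0, p$fiducial_sigma_nm)),
           frame = on)
    })
    list(xy = do.call(rbind, lapply(per_fid, `[[`, "xy")),
         frame = unlist(lapply(per_fid, `[[`, "frame")))
  }
  fid_cl <- emit_fiducials()
  fid_ac <- emit_fiducials()

  ## assemble channels: precision noise on structure, random frames
  noisy <- function(xy) {
    n <- nrow(xy)
    cbind(x = xy[, 1] + stats::rnorm(n, 0, p$sigma_nm),
          y = xy[, 2] + stats::rnorm(n, 0, p$sigma_nm))
  }
  n_cl <- nrow(cl_xy); n_ac <- nrow(ac_xy)
  cl_obs <- noisy(cl_xy)
  ac_obs <- noisy(ac_xy)
  cl_frames <- sample.int(p$n_frames, n_cl, replace = TRUE) - 1L
  ac_frames <- sample.int(p$n_frames, n_ac, replace = TRUE) - 1L

  dx <- p$true_shift_nm[1]; dy <- p$true_shift_nm[2]
  clathrin <- loc_table(
    c(cl_obs[, 1], fid_cl$xy[, 1]),
    c(cl_obs[, 2], fid_cl$xy[, 2]),
    c(cl_frames, fid_cl$frame),
    channel_label = "clathrin")
  actin <- loc_table(
    c(ac_obs[, 1], fid_ac$xy[, 1]) + dx,
    c(ac_obs[, 2], fid_ac$xy[, 2]) + dy,
    c(ac_frames, fid_ac$frame),
    channel_label = "actin")

  actin_labels <- c(ac_lab, rep("fiducial", nrow(fid_ac$xy)))
  clathrin_labels <- c(cl_lab, rep("fiducial", nrow(fid_cl$xy)))
  n_struct_actin <- sum(actin_labels != "fiducial")
  truth <- structure(list(
    params = p,
    clathrin_disks = disks,
    filament_segments = segs,
    fiducial_positions = data.frame(x = fid[, 1], y = fid[, 2]),
    clathrin_labels = clathrin_labels,
    actin_labels = actin_labels,
    clathrin_true = data.frame(
      x = c(cl_xy[, 1], fid_cl$xy[, 1]),
      y = c(cl_xy[, 2], fid_cl$xy[, 2])),
    actin_true = data.frame(
      x = c(ac_xy[, 1], fid_ac$xy[, 1]),
      y = c(ac_xy[, 2], fid_ac$xy[, 2])),
    true_shift_nm = c(dx, dy),
    realized_coloc_fraction = if (n_struct_actin > 0)
      sum(ac_lab == "planted") / n_struct_actin else 0
  ), class = "scene_truth")

  list(clathrin = clathrin, actin = actin, truth = truth)
}

#' Ground-truth colocalized actin fraction (brute-force oracle)
#'
#' Reference value for pipeline recovery tests, computed without any
#' tessellation or polygon step: the percentage of (non-fiducial) actin
#' localizations whose true, pre-noise position lies inside any
#' ground-truth clathrin disk, by direct point-in-disk testing.
#'
#' @param actin The actin [loc_table()] returned with the truth.
#' @param truth The matching `scene_truth`.
#' @return Percentage in `[0, 100]`.
#' @export
oracle_coloc_fraction <- function(actin, truth) {
  if (nrow(actin) != nrow(truth$actin_true))
    stop("actin table does not match ground truth (row count differs)",
         call. = FALSE)
  keep <- truth$actin_labels != "fiducial"
  if (!any(keep)) return(0)
  disks <- truth$clathrin_disks
  if (nrow(disks) == 0) return(0)
  x <- truth$actin_true$x[keep]; y <- truth$actin_true$y[keep]
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(disks))) {
    inside <- inside |
      ((x - disks$x[i])^2 + (y - disks$y[i])^2 <= disks$r[i]^2)
  }
  100 * mean(inside)
}
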
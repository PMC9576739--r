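#' Detect fiducial markers by temporal persistence
#'
#' Fiducial beads are bright and do not blink: their localizations recur at
#' (nearly) the same position across most frames, whereas a blinking
#' fluorophore contributes to only a small fraction of frames. Candidates
#' are found by grouping localizations on a grid of `pairing_radius_nm`
#' spacing (8-connected grid cells are merged, so a marker straddling a
#' grid line is not split), and a group is accepted when it appears in at
#' least `persistence_fraction` of all frames. Accepted candidates are
#' ranked by support (number of contributing localizations) and at most
#' `max_count` are returned.
#'
#' @param table A [loc_table()].
#' @param max_count Maximum number of fiducials to return; default 50.
#' @param persistence_fraction Minimum fraction of frames a candidate must
#'   be present in; default 0.5.
#' @param pairing_radius_nm Grouping radius; default 117 nm (1 pixel).
#' @param n_frames Total frame count of the acquisition; default inferred
#'   as `max(frame) + 1`.
#' @return A `fiducial_set`: list with `centers` (data.frame x, y, sigma,
#'   support, n_frames_seen), `channel_label`, `n_frames`.
#' @export
detect_fiducials <- function(table, max_count = 50,
                             persistence_fraction = 0.5,
                             pairing_radius_nm = 117,
                             n_frames = NULL) {
  if (nrow(table) == 0)
    stop("cannot detect fiducials in an empty table", call. = FALSE)
  stopifnot(persistence_fraction > 0, persistence_fraction <= 1)
  if (is.null(n_frames)) n_frames <- max(table$frame) + 1L
  need_frames <- persistence_fraction * n_frames

  gx <- floor(table$x / pairing_radius_nm)
  gy <- floor(table$y / pairing_radius_nm)
  key <- paste(gx, gy, sep = ",")
  counts <- table(key)
  # a persistent marker contributes >= need_frames localizations even if
  # split across up to 4 neighboring grid cells
  cand <- names(counts)[counts >= need_frames / 4]
  if (length(cand) > 0) {
    # merge 8-connected candidate cells
    parts <- do.call(rbind, strsplit(cand, ","))
    cgx <- as.integer(parts[, 1]); cgy <- as.integer(parts[, 2])
    m <- length(cand)
    edges <- integer(0)
    if (m > 1) {
      idx <- split(seq_len(m), cgx)
      pairs <- list()
      for (i in seq_len(m)) {
        for (dx in -1:1) {
          col <- idx[[as.character(cgx[i] + dx)]]
          if (is.null(col)) next
          nb <- col[abs(cgy[col] - cgy[i]) <= 1 & col > i]
          if (length(nb)) pairs[[length(pairs) + 1]] <- rbind(i, nb)
        }
      }
      if (length(pairs))
        edges <- unlist(pairs, use.names = FALSE)
    }
    g <- igraph::make_graph(edges = as.numeric(edges), n = m,
                            directed = FALSE)
    comp <- igraph::components(g)$membership
    cell_of_loc <- match(key, cand)
    groups <- split(which(!is.na(cell_of_loc)),
                    comp[cell_of_loc[!is.na(cell_of_loc)]])
  } else groups <- list()

  fids <- list()
  for (g_idx in groups) {
    frames_seen <- length(unique(table$frame[g_idx]))
    if (frames_seen < need_frames) next
    fit <- fit_gaussian_2d(cbind(table$x[g_idx], table$y[g_idx]),
                           max_spread_nm = pairing_radius_nm)
    if (!fit$converged) next
    fids[[length(fids) + 1]] <- data.frame(
      x = fit$center[1], y = fit$center[2], sigma = fit$sigma,
      support = length(g_idx), n_frames_seen = frames_seen)
  }
  if (length(fids) == 0)
    stop("no fiducial markers detected: registration cannot proceed",
         call. = FALSE)
  centers <- do.call(rbind, fids)
  centers <- centers[order(-centers$support), , drop = FALSE]
  if (nrow(centers) > max_count) {
    centers <- centers[seq_len(max_count), , drop = FALSE]
  } else if (nrow(centers) < max_count) {
    warning(sprintf("requested %d fiducials, found %d",
                    max_count, nrow(centers)), call. = FALSE)
  }
  rownames(centers) <- NULL
  structure(list(centers = centers,
                 channel_label = attr(table, "channel_label"),
                 n_frames = n_frames),
            class = "fiducial_set")
}

#' Fit an isotropic 2D Gaussian to a point sample
#'
#' Maximum-likelihood fit of an isotropic bivariate Gaussian to localization
#' coordinates: the center is the sample mean and sigma the root mean
#' squared per-axis deviation. This is the per-fiducial position estimator
#' used by the registration stage; operating on the localization list, it
#' is the point-sample analogue of fitting a 2D Gaussian profile to a
#' rendered spot.
#'
#' @param points Two-column matrix (x, y) in nm, `>= 3` rows.
#' @param max_spread_nm Convergence gate: the fit is flagged not converged
#'   when `sigma` exceeds this value (a candidate wider than the pairing
#'   radius is not a point marker). Default `Inf`.
#' @return List with `center` (length-2 numeric), `sigma` (nm) and
#'   `converged` flag.
#' @export
fit_gaussian_2d <- function(points, max_spread_nm = Inf) {
  points <- as.matrix(points)
  if (nrow(points) < 3)
    stop("at least 3 points are required for a 2D Gaussian fit",
         call. = FALSE)
  center <- colMeans(points)
  # MLE of isotropic sigma: pooled variance over both axes
  sigma <- sqrt(sum(sweep(points, 2, center)^2) / (2 * nrow(points)))
  list(center = unname(center), sigma = sigma,
       converged = sigma <= max_spread_nm)
}

#' Estimate the inter-channel translation from paired fiducials
#'
#' Fiducial centers of the two channels are paired by mutual nearest
#' neighbor within `pairing_radius_nm`; the shift is the component-wise
#' mean over pairs of (reference - moving) displacements. Unpaired
#' fiducials are excluded (a message reports how many).
#'
#' @param reference,moving `fiducial_set` objects from [detect_fiducials()].
#' @param pairing_radius_nm Maximum center distance for a valid pair;
#'   default 1000 nm (must exceed the physical shift being estimated).
#' @return A `translation_shift`: list with `dx`, `dy` (nm; add to the
#'   moving channel to align it to the reference), `n_fiducials_used`, and
#'   `per_fiducial` data.frame of the individual displacements.
#' @export
estimate_channel_shift <- function(reference, moving,
                                   pairing_radius_nm = 1000) {
  rc <- reference$centers; mc <- moving$centers
  d2 <- outer(rc$x, mc$x, "-")^2 + outer(rc$y, mc$y, "-")^2
  nn_of_ref <- apply(d2, 1, which.min)
  nn_of_mov <- apply(d2, 2, which.min)
  mutual <- which(nn_of_mov[nn_of_ref] == seq_len(nrow(rc)))
  if (length(mutual) > 0) {
    j <- nn_of_ref[mutual]
    ok <- d2[cbind(mutual, j)] <= pairing_radius_nm^2
    mutual <- mutual[ok]; j <- j[ok]
  }
  if (length(mutual) == 0)
    stop("no mutual nearest-neighbor fiducial pairs within pairing radius",
         call. = FALSE)
  n_unpaired <- (nrow(rc) - length(mutual)) + (nrow(mc) - length(mutual))
  if (n_unpaired > 0)
    message(sprintf("%d unpaired fiducial center(s) excluded", n_unpaired))
  per <- data.frame(ref_index = mutual, mov_index = j,
                    dx = rc$x[mutual] - mc$x[j],
                    dy = rc$y[mutual] - mc$y[j])
  structure(list(dx = mean(per$dx), dy = mean(per$dy),
                 n_fiducials_used = nrow(per),
                 per_fiducial = per),
            class = "translation_shift")
}

#' @export
print.translation_shift <- function(x, ...) {
  cat(sprintf("<translation_shift> dx = %.2f nm, dy = %.2f nm (%d fiducials)\n",
              x$dx, x$dy, x$n_fiducials_used))
  invisible(x)
}

#' Apply a translation to a localization table
#'
#' Adds `(dx, dy)` to every coordinate; frame and intensity are untouched.
#'
#' @param table A [loc_table()].
#' @param shift A `translation_shift` from [estimate_channel_shift()], or a
#'   numeric length-2 vector `(dx, dy)` in nm.
#' @return The translated [loc_table()].
#' @export
apply_shift <- function(table, shift) {
  if (inherits(shift, "translation_shift")) shift <- c(shift$dx, shift$dy)
  stopifnot(length(shift) == 2, all(is.finite(shift)))
  loc_table(table$x + shift[1], table$y + shift[2], table$frame,
            if ("intensity" %in% names(table)) table$intensity,
            attr(table, "channel_label"))
}
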
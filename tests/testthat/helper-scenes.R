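# Scene helpers shared across test files. Unit tests run on compact scenes
# (10 x 10 um field, 200 frames, 6 fiducials) so the whole suite stays
# fast; the acceptance tests use the generator defaults where a criterion
# depends on them.

tiny_scene_params <- function(...) {
  defaults <- list(field_nm = c(10000, 10000), n_frames = 200,
                   n_clusters = 12, n_filaments = 12, n_fiducials = 6,
                   fiducial_min_sep_nm = 1500)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

# Two clathrin-like disks of 150 localizations each (radius 100 nm),
# centers 2 um apart, on a uniform background of 1 loc/um^2 in a
# 6 x 6 um field. Returns the table plus planted labels (1, 2, 0 = bg).
two_disk_scene <- function(seed) {
  set.seed(seed)
  centers <- list(c(2000, 3000), c(4000, 3000))
  xs <- c(); ys <- c(); lab <- c()
  for (i in 1:2) {
    th <- runif(150, 0, 2 * pi); rr <- 100 * sqrt(runif(150))
    xs <- c(xs, centers[[i]][1] + rr * cos(th))
    ys <- c(ys, centers[[i]][2] + rr * sin(th))
    lab <- c(lab, rep(i, 150))
  }
  n_bg <- 36  # 1 / um^2 over 36 um^2
  xs <- c(xs, runif(n_bg, 0, 6000)); ys <- c(ys, runif(n_bg, 0, 6000))
  lab <- c(lab, rep(0, n_bg))
  list(table = loc_table(xs, ys, 0L, channel_label = "test"),
       labels = lab,
       window = roi(0, 0, 6000, 6000))
}

# fiducial_set built directly from known centers (bypasses detection)
as_fiducial_set <- function(x, y, label = "set") {
  structure(list(centers = data.frame(x = x, y = y,
                                      sigma = 0, support = length(x),
                                      n_frames_seen = 1L),
                 channel_label = label, n_frames = 1L),
            class = "fiducial_set")
}

# separated random centers for registration simulations
separated_centers <- function(n, lo, hi, min_sep, max_tries = 2e5) {
  xs <- numeric(0); ys <- numeric(0); tries <- 0
  while (length(xs) < n) {
    tries <- tries + 1
    if (tries > max_tries) stop("cannot place separated centers")
    x <- runif(1, lo, hi); y <- runif(1, lo, hi)
    if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  cbind(xs, ys)
}
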
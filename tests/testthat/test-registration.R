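test_that("2D Gaussian fit recovers symmetric and degenerate centers", {
  sq <- cbind(c(0, 200, 200, 0), c(0, 0, 200, 200))
  fit <- fit_gaussian_2d(sq)
  expect_equal(fit$center, c(100, 100))

  same <- cbind(rep(1500, 3), rep(2500, 3))
  fit0 <- fit_gaussian_2d(same)
  expect_equal(fit0$center, c(1500, 2500))
  expect_equal(fit0$sigma, 0)
  expect_true(fit0$converged)

  expect_error(fit_gaussian_2d(sq[1:2, ]), "3 points")
})

test_that("Gaussian center estimate attains the sqrt(n) error scaling", {
  # 500 draws at sigma = 10 nm: per-axis error < 3 * 10 / sqrt(500) nm
  # should hold with ~99.7% coverage per axis; check empirically
  bound <- 3 * 10 / sqrt(500)
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    pts <- cbind(rnorm(500, 1000, 10), rnorm(500, 2000, 10))
    err <- abs(fit_gaussian_2d(pts)$center - c(1000, 2000))
    if (all(err < bound)) hits <- hits + 1L
  }
  expect_gte(hits, 97)
})

test_that("persistent markers are detected among blinking clusters", {
  set.seed(21)
  n_frames <- 200
  fpos <- cbind(c(2000, 6000, 8500), c(3000, 7000, 2000))
  xs <- c(); ys <- c(); fr <- c()
  for (i in 1:3) {  # present in 95% of frames
    on <- which(runif(n_frames) < 0.95) - 1L
    xs <- c(xs, fpos[i, 1] + rnorm(length(on), 0, 5))
    ys <- c(ys, fpos[i, 2] + rnorm(length(on), 0, 5))
    fr <- c(fr, on)
  }
  for (k in 1:10) {  # blinking clusters, < 5% of frames each
    cx <- runif(1, 500, 9500); cy <- runif(1, 500, 9500)
    n_k <- 8
    xs <- c(xs, cx + rnorm(n_k, 0, 30)); ys <- c(ys, cy + rnorm(n_k, 0, 30))
    fr <- c(fr, sample(0:(n_frames - 1), n_k))
  }
  tab <- loc_table(xs, ys, fr, channel_label = "fid")
  fs <- suppressWarnings(
    detect_fiducials(tab, max_count = 50, persistence_fraction = 0.5,
                     pairing_radius_nm = 117, n_frames = n_frames))
  expect_equal(nrow(fs$centers), 3)
  # centers within localization precision of planted positions
  for (i in 1:3) {
    d <- sqrt((fs$centers$x - fpos[i, 1])^2 + (fs$centers$y - fpos[i, 2])^2)
    expect_lt(min(d), 5)
  }
  # fewer than requested is a warning, not an error
  expect_warning(
    detect_fiducials(tab, max_count = 50, n_frames = n_frames),
    "found 3")
})

test_that("a table without recurring positions yields a no-fiducial error", {
  set.seed(22)
  tab <- loc_table(runif(500, 0, 1e4), runif(500, 0, 1e4),
                   sample(0:199, 500, TRUE))
  expect_error(detect_fiducials(tab, n_frames = 200), "no fiducial")
})

test_that("channel shift estimation is exact on noiseless displacements", {
  a <- as_fiducial_set(c(1000, 5000, 9000), c(2000, 8000, 4000))
  expect_equal(unname(c(estimate_channel_shift(a, a)$dx,
                        estimate_channel_shift(a, a)$dy)), c(0, 0))

  b <- as_fiducial_set(a$centers$x - 30, a$centers$y + 20)
  sh <- estimate_channel_shift(a, b)
  expect_equal(c(sh$dx, sh$dy), c(30, -20))
  expect_equal(sh$n_fiducials_used, 3)

  # antisymmetry: swapping reference and moving negates the shift
  rev <- estimate_channel_shift(b, a)
  expect_equal(c(rev$dx, rev$dy), c(-30, 20))
})

test_that("shift recovery error shrinks with fiducial count", {
  true <- c(25, -40)
  mean_resid <- function(n, n_seeds = 20) {
    r <- numeric(n_seeds)
    for (s in seq_len(n_seeds)) {
      set.seed(1000 + s)
      ctr <- separated_centers(n, 500, 19500, 1700)
      ref <- as_fiducial_set(ctr[, 1] + rnorm(n, 0, 10),
                             ctr[, 2] + rnorm(n, 0, 10))
      mov <- as_fiducial_set(ctr[, 1] - true[1] + rnorm(n, 0, 10),
                             ctr[, 2] - true[2] + rnorm(n, 0, 10))
      sh <- estimate_channel_shift(ref, mov)
      r[s] <- sqrt((sh$dx - true[1])^2 + (sh$dy - true[2])^2)
    }
    mean(r)
  }
  m50 <- mean_resid(50)
  expect_lt(m50, 3 * 10 * sqrt(2) / sqrt(50))
  # monotone improvement with n
  m5 <- mean_resid(5)
  expect_gt(m5, m50)
})

test_that("applying a shift translates coordinates and is invertible", {
  set.seed(23)
  tab <- loc_table(runif(20, 0, 1e4), runif(20, 0, 1e4),
                   sample(0:9, 20, TRUE), intensity = runif(20))
  expect_equal(apply_shift(tab, c(0, 0))$x, tab$x)
  fwd <- apply_shift(tab, c(150, -230))
  expect_equal(fwd$x, tab$x + 150)
  back <- apply_shift(fwd, c(-150, 230))
  expect_equal(back$x, tab$x)
  expect_equal(back$y, tab$y)
  # non-coordinate fields preserved bit-exactly
  expect_identical(back$frame, tab$frame)
  expect_identical(fwd$intensity, tab$intensity)
})

test_that("registration closes the loop on a planted-shift scene", {
  p <- tiny_scene_params(true_shift_nm = c(300, -200), rng_seed = 31,
                         n_clusters = 6, n_filaments = 6)
  sc <- simulate_scene(p)
  fc <- detect_fiducials(sc$clathrin, max_count = 6, n_frames = p$n_frames)
  fa <- detect_fiducials(sc$actin, max_count = 6, n_frames = p$n_frames)
  sh <- suppressMessages(estimate_channel_shift(fc, fa))
  corrected <- apply_shift(sc$actin, sh)
  fa2 <- detect_fiducials(corrected, max_count = 6, n_frames = p$n_frames)
  resid <- suppressMessages(estimate_channel_shift(fc, fa2))
  expect_lt(sqrt(resid$dx^2 + resid$dy^2), 2)
})
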
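test_that("polygon expansion matches closed-form buffered areas", {
  sq <- list(list(x = c(0, 200, 200, 0), y = c(0, 0, 200, 200)))
  expect_equal(expand_polygon(sq, 0), sq)

  # square side 200 buffered 117: area + perimeter*d + pi*d^2
  buf <- expand_polygon(sq, 117)
  want_sq <- 200^2 + 4 * 200 * 117 + pi * 117^2
  got_sq <- abs(sum(vapply(buf, function(cc) {
    n <- length(cc$x); j <- c(2:n, 1)
    0.5 * sum(cc$x * cc$y[j] - cc$x[j] * cc$y)
  }, numeric(1))))
  expect_equal(got_sq, want_sq, tolerance = 0.005)

  # disk radius r buffered d -> pi (r + d)^2
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  disk <- list(list(x = 100 * cos(th), y = 100 * sin(th)))
  bufd <- expand_polygon(disk, 50)
  got_d <- abs(sum(vapply(bufd, function(cc) {
    n <- length(cc$x); j <- c(2:n, 1)
    0.5 * sum(cc$x * cc$y[j] - cc$x[j] * cc$y)
  }, numeric(1))))
  expect_equal(got_d, pi * 150^2, tolerance = 0.005)

  expect_error(expand_polygon(list(), 10), "empty")
})

# shared fixture: one clathrin disk cluster in a small field
coloc_fixture <- function(seed = 51, actin_xy) {
  set.seed(seed)
  th <- runif(150, 0, 2 * pi); rr <- 100 * sqrt(runif(150))
  cx <- 2000 + rr * cos(th); cy <- 2000 + rr * sin(th)
  bg_x <- runif(16, 0, 4000); bg_y <- runif(16, 0, 4000)
  cl_tab <- loc_table(c(cx, bg_x), c(cy, bg_y), 0L, channel_label = "cl")
  w <- roi(0, 0, 4000, 4000)
  cl_tess <- compute_tessellation(cl_tab, w)
  cl_clusters <- segment_clusters(cl_tess, 5e4, 5)
  ac_tab <- loc_table(actin_xy[, 1], actin_xy[, 2], 0L,
                      channel_label = "ac")
  ac_tess <- compute_tessellation(ac_tab, w)
  ac_clusters <- segment_clusters(ac_tess, 2e6, 5)
  list(cl = cl_clusters[[1]], cl_tess = cl_tess, ac_tab = ac_tab,
       ac_clusters = ac_clusters, ac_tess = ac_tess)
}

test_that("actin fully inside the clathrin footprint gives 100% colocalization", {
  set.seed(52)
  th <- runif(60, 0, 2 * pi); rr <- 50 * sqrt(runif(60))
  fx <- coloc_fixture(actin_xy = cbind(2000 + rr * cos(th),
                                       2000 + rr * sin(th)))
  rec <- coloc_per_cluster(fx$cl, fx$cl_tess, fx$ac_tab, fx$ac_clusters,
                           fx$ac_tess, pipeline_config())
  expect_equal(rec$pct_coloc, 100)
  expect_equal(rec$n_actin_noncoloc, 0)
  expect_equal(rec$pct_noncoloc, 0)
  expect_false(rec$empty_local_flag)
})

test_that("a cluster with no nearby actin is flagged actin-negative", {
  set.seed(53)
  fx <- coloc_fixture(actin_xy = cbind(runif(40, 3500, 4000),
                                       runif(40, 3500, 4000)))
  rec <- coloc_per_cluster(fx$cl, fx$cl_tess, fx$ac_tab, fx$ac_clusters,
                           fx$ac_tess, pipeline_config())
  expect_true(rec$empty_local_flag)
  expect_true(is.na(rec$pct_coloc))
  expect_equal(rec$density_coloc_um2, 0)
})

test_that("planted 40/60 split across the footprint boundary is recovered", {
  # 40 actin inside the disk, 60 along a tangent filament crossing the
  # expanded zone but outside the disk; point-in-disk oracle gives 40%
  set.seed(54)
  th <- runif(40, 0, 2 * pi); rr <- 100 * sqrt(runif(40))
  inside <- cbind(2000 + rr * cos(th), 2000 + rr * sin(th))
  t_f <- runif(60, -180, 180)
  fil <- cbind(2000 + t_f, 2000 + 160 + rnorm(60, 0, 5))
  fx <- coloc_fixture(actin_xy = rbind(inside, fil))
  rec <- coloc_per_cluster(fx$cl, fx$cl_tess, fx$ac_tab, fx$ac_clusters,
                           fx$ac_tess, pipeline_config())
  oracle <- 100 * mean(sqrt((fx$ac_tab$x - 2000)^2 +
                            (fx$ac_tab$y - 2000)^2) <= 100)
  expect_equal(oracle, 40)
  expect_lt(abs(rec$pct_coloc - oracle), 5)
  # polygon algebra conservation on this record
  expect_equal(rec$joint_area_nm2,
               rec$clathrin_area_nm2 + rec$yellow_area_nm2,
               tolerance = 1e-6)
})

test_that("colocalized counts agree with an independent point-in-polygon test", {
  skip_if_not_installed("spatstat.geom")
  p <- tiny_scene_params(planted_coloc_fraction = 0.25, rng_seed = 55)
  sc <- simulate_scene(p)
  res <- suppressMessages(run_pipeline(pipeline_config(), sc$clathrin,
                                       sc$actin))
  # rebuild each footprint and recount with spatstat.geom
  cfg <- pipeline_config()
  tess <- res$tess$clathrin
  recs <- res$records
  for (cl in res$clusters$clathrin[1:5]) {
    fp <- expand_polygon(cluster_footprint(cl, tess, "convex-hull"),
                         cfg$footprint_dilation_nm)
    # polyclip contours are already anticlockwise outers / clockwise holes
    w <- spatstat.geom::owin(poly = fp,
                             xrange = range(unlist(lapply(fp, `[[`, "x"))),
                             yrange = range(unlist(lapply(fp, `[[`, "y"))))
    # count all actin localizations inside the footprint; equals the
    # colocalized count because the footprint lies inside the local area
    n_sp <- sum(spatstat.geom::inside.owin(res$tess$actin$x,
                                           res$tess$actin$y, w))
    expect_equal(n_sp, recs$n_actin_coloc[recs$cluster_id == cl$id])
  }
})

test_that("ROI aggregation reproduces closed-form pooled statistics", {
  recs <- rbind(
    data.frame(cluster_id = 1, n_clathrin = 10, clathrin_area_nm2 = 1e4,
               expanded_area_nm2 = 1e5, yellow_area_nm2 = 1e4,
               joint_area_nm2 = 2e4, n_actin_local = 100,
               n_actin_coloc = 20, n_actin_noncoloc = 50, pct_coloc = 20,
               pct_noncoloc = 50, density_coloc_um2 = 2000,
               density_noncoloc_um2 = 5000, zero_yellow_flag = FALSE,
               empty_local_flag = FALSE),
    data.frame(cluster_id = 2, n_clathrin = 10, clathrin_area_nm2 = 1e4,
               expanded_area_nm2 = 1e5, yellow_area_nm2 = 1e4,
               joint_area_nm2 = 2e4, n_actin_local = 100,
               n_actin_coloc = 30, n_actin_noncoloc = 40, pct_coloc = 30,
               pct_noncoloc = 40, density_coloc_um2 = 3000,
               density_noncoloc_um2 = 4000, zero_yellow_flag = FALSE,
               empty_local_flag = FALSE))
  s <- aggregate_roi(recs, "r1")
  expect_equal(s$pooled_pct_coloc, 25)
  expect_equal(s$mean_pct_coloc, 25)
  expect_equal(s$sd_pct_coloc, 7.0710678, tolerance = 1e-6)

  s1 <- aggregate_roi(recs[1, ], "r1")
  expect_equal(s1$pooled_pct_coloc, s1$mean_pct_coloc)
  expect_equal(s1$sd_pct_coloc, 0)

  # empty-local clusters enter density means but not percentage means
  recs$empty_local_flag[2] <- TRUE
  recs$density_coloc_um2[2] <- 0
  s2 <- aggregate_roi(recs, "r1")
  expect_equal(s2$mean_pct_coloc, 20)
  expect_equal(s2$mean_density_coloc_um2, 1000)

  expect_error(aggregate_roi(recs[0, ], "r1"), "empty")
})
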
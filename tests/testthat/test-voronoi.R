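test_that("degenerate inputs raise tessellation errors", {
  expect_error(compute_tessellation(loc_table(1, 1, 0L)), "at least 2")
  expect_error(compute_tessellation(loc_table(rep(5, 4), rep(5, 4), 0L)),
               "coincide")
})

test_that("two symmetric points split the window into halves", {
  tab <- loc_table(c(250, 750), c(500, 500), 0L)
  tess <- compute_tessellation(tab, roi(0, 0, 1000, 1000))
  expect_equal(tess$area, c(5e5, 5e5))
  expect_true(all(tess$boundary))
})

test_that("clipped cell areas conserve the window area", {
  set.seed(41)
  tab <- loc_table(runif(200, 0, 1000), runif(200, 0, 1000), 0L)
  tess <- compute_tessellation(tab, roi(0, 0, 1000, 1000))
  expect_equal(sum(tess$area), 1e6, tolerance = 1e-6)
  # adjacency is symmetric by construction: no self pairs, valid indices
  expect_true(all(tess$adjacency >= 1 & tess$adjacency <= 200))
  expect_true(all(tess$adjacency[, 1] != tess$adjacency[, 2]))
})

test_that("window-interior adjacency equals brute-force Delaunay", {
  set.seed(42)
  tab <- loc_table(runif(30, 0, 1000), runif(30, 0, 1000), 0L)
  tess <- compute_tessellation(tab, roi(-5000, -5000, 6000, 6000))
  got <- unique(cbind(pmin(tess$adjacency[, 1], tess$adjacency[, 2]),
                      pmax(tess$adjacency[, 1], tess$adjacency[, 2])))
  got <- got[order(got[, 1], got[, 2]), ]
  want <- delaunay_adjacency_bruteforce(tab$x, tab$y)
  expect_equal(unname(got), unname(want))
})

test_that("threshold segmentation keeps nested memberships and is deterministic", {
  set.seed(43)
  sc <- two_disk_scene(1)
  tess <- compute_tessellation(sc$table, sc$window)
  t1 <- 2e4; t2 <- 8e4
  c1 <- segment_clusters(tess, t1, min_cluster_size = 2)
  c2 <- segment_clusters(tess, t2, min_cluster_size = 2)
  kept1 <- sort(unlist(lapply(c1, `[[`, "members")))
  kept2 <- sort(unlist(lapply(c2, `[[`, "members")))
  # monotonicity: members kept at the lower threshold survive the higher
  expect_true(all(kept1 %in% kept2))
  # determinism: byte-identical cluster lists on recomputation
  c2b <- segment_clusters(compute_tessellation(sc$table, sc$window), t2,
                          min_cluster_size = 2)
  expect_identical(c2, c2b)
  # threshold below the minimum cell area yields nothing
  expect_length(segment_clusters(tess, min(tess$area) * 0.9), 0)
})

test_that("a dense connected grid forms one cluster of interior points", {
  g <- expand.grid(x = seq(100, 900, by = 100), y = seq(100, 900, by = 100))
  tab <- loc_table(g$x, g$y, 0L)
  tess <- compute_tessellation(tab, roi(0, 0, 1000, 1000))
  cl <- segment_clusters(tess, area_threshold_nm2 = 1e12,
                         min_cluster_size = 1)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, unname(which(!tess$boundary)))
})

test_that("planted disks are recovered with high member recall", {
  for (seed in 1:3) {
    sc <- two_disk_scene(seed)
    tess <- compute_tessellation(sc$table, sc$window)
    # threshold between the dense-cell (~200 nm^2) and background-cell
    # (~1e6 nm^2) area scales, high enough to retain rim cells, which
    # stretch toward the sparse background and reach ~1.1e5 nm^2
    cl <- segment_clusters(tess, 1.2e5, min_cluster_size = 5)
    expect_length(cl, 2)
    # brute-force oracle: match each cluster to the planted disk holding
    # most of its members, then demand >= 95% recall of planted labels
    for (k in 1:2) {
      lab <- sc$labels[cl[[k]]$members]
      disk <- as.integer(names(which.max(table(lab[lab > 0]))))
      recall <- sum(lab == disk) / sum(sc$labels == disk)
      expect_gte(recall, 0.95)
    }
  }
})

test_that("uniform background stays mostly unclustered at the clathrin threshold", {
  set.seed(44)
  n <- 400  # 1 loc/um^2 over 20 x 20 um
  tab <- loc_table(runif(n, 0, 20000), runif(n, 0, 20000), 0L)
  tess <- compute_tessellation(tab, roi(0, 0, 20000, 20000))
  cl <- segment_clusters(tess, 5e4, min_cluster_size = 5)
  frac <- sum(vapply(cl, `[[`, numeric(1), "n_localizations")) / n
  expect_lt(frac, 0.05)
})

test_that("footprints agree with closed forms and cell-area sums", {
  # convex hull of 4 square corners, side 200 nm
  tab <- loc_table(c(0, 200, 200, 0, 100), c(0, 0, 200, 200, 100), 0L)
  tess <- compute_tessellation(tab, roi(-500, -500, 700, 700))
  cl <- structure(list(id = 1L, members = 1:5, n_localizations = 5L,
                       cell_area_nm2 = sum(tess$area),
                       centroid = c(100, 100)),
                  class = "voronoi_cluster")
  hull <- cluster_footprint(cl, tess, method = "convex-hull")
  expect_equal(attr(hull, "area_nm2"), 4e4, tolerance = 1e-9)

  # voronoi-union area equals the sum of member cell areas (cells tile)
  sc <- two_disk_scene(5)
  tess2 <- compute_tessellation(sc$table, sc$window)
  clusters <- segment_clusters(tess2, 5e4, min_cluster_size = 5)
  fp <- cluster_footprint(clusters[[1]], tess2, method = "voronoi-union")
  expect_equal(attr(fp, "area_nm2"), clusters[[1]]$cell_area_nm2,
               tolerance = 1e-6)

  # single member: its clipped Voronoi cell
  single <- structure(list(id = 9L, members = 3L, n_localizations = 1L,
                           cell_area_nm2 = tess2$area[3],
                           centroid = c(tess2$x[3], tess2$y[3])),
                      class = "voronoi_cluster")
  fp1 <- cluster_footprint(single, tess2, method = "voronoi-union")
  expect_equal(attr(fp1, "area_nm2"), tess2$area[3], tolerance = 1e-6)
})
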
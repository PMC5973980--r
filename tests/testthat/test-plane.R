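test_that("rotation grids generate the expected plane counts", {
  v <- c(10, 20, 30)
  n <- c(0, 0, 1)
  expect_length(sample_planes_at_vertex(v, n, rotation_grid(60, 20)), 343)
  expect_length(sample_planes_at_vertex(v, n, rotation_grid(60, 30)), 125)
  p0 <- sample_planes_at_vertex(v, n, rotation_grid(0, 30))
  expect_length(p0, 1)
  # degenerate grid: axis along the inward normal
  expect_equal(p0[[1]]$axis, -n)
  expect_error(sample_planes_at_vertex(v, c(0, 0, 0), rotation_grid()), "normal")
  expect_error(rotation_grid(60, 25), "divide")
})

test_that("plane apex and orthonormal frame are preserved across the grid", {
  set.seed(1)
  nrm <- rnorm(3)
  nrm <- nrm / sqrt(sum(nrm^2))
  planes <- sample_planes_at_vertex(c(5, 5, 5), nrm, rotation_grid(60, 30))
  for (p in planes[c(1, 40, 125)]) {
    expect_equal(p$apex, c(5, 5, 5))
    expect_equal(sum(p$axis^2), 1, tolerance = 1e-12)
    expect_equal(sum(p$normal * p$axis), 0, tolerance = 1e-9)
  }
  # base orientation (all angles zero) is the inward normal
  mid <- planes[[63]]  # centre of the 5x5x5 grid
  expect_equal(mid$axis, -nrm, tolerance = 1e-12)
})

test_that("sector membership respects depth, fan angle and planarity", {
  p <- sector_plane(apex = c(0, 0, 0), axis = c(0, 0, 1), normal = c(1, 0, 0),
                    fan_angle = 120, depth = 50)
  expect_true(point_in_sector(c(0, 0, 49), p))
  expect_false(point_in_sector(c(0, 0, 51), p))
  lat <- p$lateral
  q_in <- 10 * (sin(59 * pi / 180) * lat + cos(59 * pi / 180) * c(0, 0, 1))
  q_out <- 10 * (sin(61 * pi / 180) * lat + cos(61 * pi / 180) * c(0, 0, 1))
  expect_true(point_in_sector(q_in, p))
  expect_false(point_in_sector(q_out, p))
  # out-of-plane offset beyond half a pixel pitch
  expect_false(point_in_sector(c(0, 0, 10) + p$normal * 1, p))
})

test_that("a perpendicular cut through a cylinder yields one disc feature", {
  cyl <- cylinder_volume(radius = 2, length = 60)
  mid_z <- mean(cyl$z_range)
  p <- sector_plane(apex = c(cyl$ax, cyl$ay, mid_z) - c(0, 30, 0),
                    axis = c(0, 1, 0), normal = c(0, 0, 1))
  fts <- intersect_structure(p, extract_centreline(cyl$volume, 1L), cyl$volume)
  expect_length(fts, 1)
  f <- fts[[1]]
  expect_lt(abs(f$area_mm2 - pi * 4) / (pi * 4), 0.15)
  # landmark = centroid of the disc = the cylinder axis
  expect_equal(f$landmark[1:2], c(cyl$ax, cyl$ay), tolerance = 0.3)
  expect_true(point_in_sector(f$landmark, p))
  # tube landmark equals the brute-force pixel-mass centroid
  ras <- eusplan:::sector_raster(p, margin_px = 3L)
  pts <- eusplan:::raster_world(p, as.vector(ras$L), as.vector(ras$A))
  labs <- eusplan:::sample_labels(cyl$volume, pts)
  inside <- matrix(labs == 1L, nrow = length(ras$l)) & ras$inside
  ctr2d <- c(mean(ras$L[inside]), mean(ras$A[inside]))
  oracle <- drop(eusplan:::raster_world(p, ctr2d[1], ctr2d[2]))
  expect_equal(f$landmark, oracle, tolerance = 1e-9)
})

test_that("planes missing a structure return no features", {
  cyl <- cylinder_volume(radius = 2, length = 20)
  p <- sector_plane(apex = c(200, 200, 200), axis = c(0, 0, 1), normal = c(1, 0, 0))
  fts <- intersect_structure(p, extract_centreline(cyl$volume, 1L), cyl$volume)
  expect_length(fts, 0)
})

test_that("two branches crossed by one plane give two distinct features", {
  # two parallel vertical tubes of one label
  d <- c(40, 30, 40)
  arr <- array(0L, d)
  xs <- 0:(d[1] - 1)
  ys <- 0:(d[2] - 1)
  disc1 <- outer((xs - 10)^2, (ys - 15)^2, `+`) <= 9
  disc2 <- outer((xs - 30)^2, (ys - 15)^2, `+`) <= 9
  for (z in 6:34) {
    sl <- arr[, , z]
    sl[disc1 | disc2] <- 1L
    arr[, , z] <- sl
  }
  vol <- labeled_volume(arr, c(1, 1, 1),
                        label_table = data.frame(label = 1L, name = "vessel",
                                                 kind = "tube"))
  p <- sector_plane(apex = c(20, 15, 1), axis = c(0, 0, 1), normal = c(0, 1, 0))
  s <- extract_centreline(vol, 1L)
  fts <- intersect_structure(p, s, vol)
  expect_length(fts, 2)
  # flood-fill oracle for the component count on the same raster
  skip_if_not_installed("igraph")
  ras <- eusplan:::sector_raster(p)
  pts <- eusplan:::raster_world(p, as.vector(ras$L), as.vector(ras$A))
  m <- matrix(eusplan:::sample_labels(vol, pts) == 1L, nrow = length(ras$l)) & ras$inside
  w <- which(m, arr.ind = TRUE)
  adj <- as.matrix(stats::dist(w, method = "maximum")) <= 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  expect_equal(igraph::components(g)$no, 2)
  # distinct bounding boxes
  expect_true(abs(fts[[1]]$landmark[1] - fts[[2]]$landmark[1]) > 10)
})

test_that("organ landmarks sit on the visible boundary segment", {
  an <- ref_anatomy()
  u <- ref_good_plane()
  organ <- Filter(function(f) f$kind == "organ", u$features)
  skip_if(length(organ) == 0)
  f <- organ[[1]]
  # on the boundary: landmark is one of the boundary points
  d <- sqrt(rowSums(sweep(f$boundary_points, 2, f$landmark, `-`)^2))
  expect_lt(min(d), 1e-9)
  expect_true(point_in_sector(f$landmark, u$plane))
  # tube landmarks lie inside their cross-section's bounding box
  tubes <- Filter(function(f) f$kind == "tube", u$features)
  for (tf in tubes) {
    expect_true(point_in_sector(tf$landmark, u$plane))
    rng_l <- range(tf$pix2d[, 1])
    ctr <- colMeans(tf$pix2d)
    expect_true(ctr[1] >= rng_l[1] && ctr[1] <= rng_l[2])
  }
})

test_that("the mid-arc point of a semicircular boundary is its landmark", {
  # boundary arc: semicircle of radius 10 in plane coordinates
  th <- seq(0, pi, length.out = 91)
  arc <- cbind(10 * cos(th), 20 + 10 * sin(th))
  p <- sector_plane(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- fake_feature(50, kind = "organ", boundary2d = arc, plane = p)
  lm <- extract_landmark(f)
  # mean of the arc is (0, 20 + 2r/pi); nearest arc point is the mid-arc top
  expected <- drop(eusplan:::raster_world(p, 0, 30))
  expect_equal(lm, expected, tolerance = 0.2)
})

test_that("feature area is stable under in-plane rotation of the pixel grid", {
  cyl <- cylinder_volume(radius = 4, length = 40)
  mid_z <- mean(cyl$z_range)
  apex <- c(cyl$ax, cyl$ay, mid_z) - c(0, 25, 0)
  nrm <- c(0, 0, 1)
  areas <- vapply(c(-15, 0, 15), function(roll) {
    # rotate the beam axis about the plane normal: same geometric plane,
    # rotated pixel grid
    ax <- drop(eusplan:::rot_axis(nrm, roll) %*% c(0, 1, 0))
    p <- sector_plane(apex, ax, nrm)
    fts <- intersect_structure(p, extract_centreline(cyl$volume, 1L), cyl$volume)
    fts[[1]]$area_mm2
  }, numeric(1))
  expect_lt(max(abs(areas - mean(areas))) / mean(areas), 0.1)
})

test_that("small features are discarded strictly below the area threshold", {
  f4 <- fake_feature(4)
  f5 <- fake_feature(5)
  f9 <- fake_feature(9.25)
  kept <- filter_features(list(f4, f5, f9))
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(f) f$area_mm2, numeric(1)), c(5, 9.25))
  expect_length(filter_features(list()), 0)
})

test_that("plane usability needs three or more features", {
  fs <- replicate(3, fake_feature(10), simplify = FALSE)
  expect_true(plane_is_usable(fs))
  expect_false(plane_is_usable(fs[1:2]))
  expect_false(plane_is_usable(list()))
})

test_that("planes serialise to JSON with pose and geometry", {
  u <- ref_good_plane()
  f <- withr::local_tempfile(fileext = ".json")
  write_planes_json(list(u$plane), f)
  j <- jsonlite::read_json(f)
  expect_equal(j[[1]]$fan_angle_deg, 120)
  expect_equal(j[[1]]$depth_mm, 50)
  expect_equal(unlist(j[[1]]$apex), u$plane$apex, tolerance = 1e-9)
})
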
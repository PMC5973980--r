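test_that("surface extraction reproduces analytic areas of simple solids", {
  # 20 mm cube at 1 mm spacing
  arr <- array(0L, c(30, 30, 30))
  arr[6:25, 6:25, 6:25] <- 1L
  cube <- extract_surface(labeled_volume(arr, c(1, 1, 1)), 1L)
  expect_lt(abs(mesh_area(cube) - 2400) / 2400, 0.10)
  # digitised sphere of radius 15 mm
  sph <- extract_surface(sphere_volume(15), 1L)
  expect_lt(abs(mesh_area(sph) - 4 * pi * 15^2) / (4 * pi * 15^2), 0.05)
})

test_that("extracted meshes are closed, oriented and hug the mask boundary", {
  vol <- sphere_volume(12)
  s <- extract_surface(vol, 1L)
  # closed + orientable: every undirected edge appears in exactly two faces
  e <- rbind(s$faces[, c(1, 2)], s$faces[, c(2, 3)], s$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
  # outward orientation: signed volume positive and close to (4/3) pi r^3
  v1 <- s$points[s$faces[, 1], ]
  v2 <- s$points[s$faces[, 2], ]
  v3 <- s$points[s$faces[, 3], ]
  svol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
              v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
              v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  expect_gt(svol, 0)
  expect_lt(abs(svol - 4 / 3 * pi * 12^3) / (4 / 3 * pi * 12^3), 0.05)
  # vertices within one voxel diagonal of the mask boundary: every vertex's
  # nearest voxel must be adjacent to both inside and outside
  idx <- world_to_voxel(vol, s$points) + 1
  mask <- vol$voxels == 1L
  near_boundary <- vapply(seq_len(nrow(idx)), function(i) {
    w <- pmax(idx[i, ] - 1, 1)
    h <- pmin(idx[i, ] + 1, dim(mask))
    block <- mask[w[1]:h[1], w[2]:h[2], w[3]:h[3]]
    any(block) && !all(block)
  }, logical(1))
  expect_true(all(near_boundary))
})

test_that("surface extraction of an absent label fails loudly", {
  vol <- sphere_volume(8)
  expect_error(extract_surface(vol, 5L), "empty label")
  expect_error(extract_centreline(vol, 5L), "empty label")
})

test_that("decimation hits the requested mean vertex spacing", {
  s <- cached("sphere15_surface", extract_surface(sphere_volume(15), 1L))
  for (target in c(2, 5.33)) {
    dec <- decimate_surface(s, target)
    expect_lt(abs(mean_edge_length(dec) - target) / target, 0.20)
  }
  expect_error(decimate_surface(s, -1), "positive")
  # decimated mesh stays within one target edge of the original surface
  dec <- decimate_surface(s, 5.33)
  dmin <- vapply(seq_len(nrow(dec$points)), function(i) {
    min(sqrt(rowSums(sweep(s$points, 2, dec$points[i, ], `-`)^2)))
  }, numeric(1))
  expect_lt(max(dmin), 5.33)
})

test_that("a decimation target beyond the mesh extent degrades gracefully", {
  s <- extract_surface(sphere_volume(6), 1L)
  expect_warning(dec <- decimate_surface(s, 1000), "minimal tetrahedron")
  expect_equal(nrow(dec$points), 4L)
  expect_equal(nrow(dec$faces), 4L)
})

test_that("cylinder centreline lies on the analytic axis and inside the mask", {
  cyl <- cylinder_volume(radius = 3, length = 60)
  cl <- extract_centreline(cyl$volume, 1L)
  off <- sqrt((cl$points[, 1] - cyl$ax)^2 + (cl$points[, 2] - cyl$ay)^2)
  expect_lt(max(off), 1)  # within one voxel of the axis
  idx <- attr(cl, "voxel_idx") + 1
  expect_true(all(cyl$volume$voxels[idx] == 1L))
})

test_that("a single labelled voxel is its own centreline", {
  arr <- array(0L, c(5, 5, 5))
  arr[3, 3, 3] <- 1L
  cl <- extract_centreline(labeled_volume(arr, c(1, 1, 1)), 1L)
  expect_equal(unname(cl$points), matrix(c(2, 2, 2), 1))
})

test_that("thinning matches an independent simple-point implementation", {
  skip_if_not_installed("igraph")
  # small L-shaped tube, radius ~1.5
  d <- c(18, 18, 8)
  mask <- array(FALSE, d)
  for (x in 3:15) for (y in 3:5) for (z in 3:5) {
    if (sqrt((y - 4)^2 + (z - 4)^2) <= 1.6) mask[x, y, z] <- TRUE
  }
  for (y in 3:15) for (x in 13:15) for (z in 3:5) {
    if (sqrt((x - 14)^2 + (z - 4)^2) <= 1.6) mask[x, y, z] <- TRUE
  }
  mine <- eusplan:::.thin3d(array(as.integer(mask), d), d)
  oracle <- thin3d_oracle(mask)
  expect_identical(array(mine == 1L, d), oracle)
  # unit-wide: interior skeleton voxels have few skeleton neighbours
  sk <- which(mine == 1L, arr.ind = TRUE)
  expect_gt(nrow(sk), 5)
})

test_that("anatomy model resolves roles, contact surfaces and the target", {
  an <- ref_anatomy()
  expect_length(an$structures, 9)
  expect_length(an$contact_surfaces, 1)
  expect_equal(an$target$label, 2L)
  kinds <- vapply(an$structures, function(s) s$kind, character(1))
  expect_equal(sum(kinds == "tube"), 4)
  expect_false(is.null(attr(an$contact_surfaces[[1]], "normals")))
  # missing label in the table is refused
  vol <- ref_phantom()$volume
  vol$label_table <- rbind(vol$label_table,
                           data.frame(label = 77L, name = "duodenum",
                                      kind = "contact_surface_organ",
                                      absent = TRUE))
  expect_error(anatomy_model(vol), "duodenum")
})

test_that("structure writers produce readable PLY and CSV", {
  s <- cached("sphere15_surface", extract_surface(sphere_volume(15), 1L))
  dec <- decimate_surface(s, 6)
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(dec, f, scalar = rep(1.5, nrow(dec$points)))
  lines <- readLines(f)
  expect_equal(lines[1], "ply")
  expect_equal(sum(grepl("^3 ", lines)), nrow(dec$faces))
  cl <- extract_centreline(cylinder_volume(2, 20)$volume, 1L)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_centreline_csv(cl, f2)
  df <- read.csv(f2)
  expect_equal(nrow(df), nrow(cl$points))
  expect_named(df, c("x", "y", "z", "label"))
})
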
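# Shared fixtures, built in code and cached for the whole test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# digitised sphere: radius mm, 1 mm voxels, centre off-grid to avoid symmetry
sphere_volume <- function(radius = 15, label = 1L) {
  n <- 2L * ceiling(radius) + 10L
  ctr <- rep((n - 1) / 2, 3)
  xs <- 0:(n - 1)
  q <- outer(outer((xs - ctr[1])^2, (xs - ctr[2])^2, `+`), (xs - ctr[3])^2, `+`)
  labeled_volume(array(as.integer(q <= radius^2) * label, rep(n, 3)), c(1, 1, 1))
}

# axis-aligned cylinder along z: radius mm, length mm, axis at (ax, ay) mm
cylinder_volume <- function(radius = 3, length = 60, ax = 10.3, ay = 11.7,
                            margin = 6L, label = 1L) {
  d <- c(ceiling(2 * (ax + radius)) + margin, ceiling(2 * (ay + radius)) + margin,
         ceiling(length) + 2L * margin)
  arr <- array(0L, d)
  xs <- 0:(d[1] - 1)
  ys <- 0:(d[2] - 1)
  disc <- outer((xs - ax)^2, (ys - ay)^2, `+`) <= radius^2
  z0 <- margin
  for (z in z0:(z0 + length - 1)) arr[, , z + 1][disc] <- label
  list(volume = labeled_volume(arr, c(1, 1, 1)), ax = ax, ay = ay,
       z_range = c(z0, z0 + length - 1))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function(max_deg = 180) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

ref_phantom <- function() cached("ref_phantom", generate_phantom(reference_phantom()))

ref_anatomy <- function() cached("ref_anatomy", {
  anatomy_model(ref_phantom()$volume, target_label = 2L)
})

# featurised candidate planes on a fixed subsample of contact vertices
ref_usable <- function() cached("ref_usable", {
  an <- ref_anatomy()
  ct <- an$contact_surfaces[[1]]
  nrm <- attr(ct, "normals")
  vids <- unique(round(seq(1, nrow(ct$points), length.out = 8)))
  usable <- list()
  for (vi in vids) {
    planes <- sample_planes_at_vertex(ct$points[vi, ], nrm[vi, ],
                                      rotation_grid(60, 30), vertex_id = vi)
    for (p in planes) {
      fts <- filter_features(plane_features(p, an))
      if (plane_is_usable(fts)) usable[[length(usable) + 1L]] <- list(plane = p, features = fts)
    }
  }
  usable
})

# one well-conditioned usable plane (many features) from the cached set
ref_good_plane <- function() cached("ref_good_plane", {
  usable <- ref_usable()
  nf <- vapply(usable, function(u) length(u$features), numeric(1))
  usable[[which.max(nf)]]
})

# minimal hand-built plane feature for filter/landmark tests
fake_feature <- function(area, kind = "tube", w = 4, h = 4,
                         landmark = c(0, 0, 0), boundary2d = NULL,
                         pix2d = cbind(0, 0), plane = NULL) {
  if (is.null(plane)) {
    plane <- sector_plane(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  }
  structure(
    list(structure_label = 1L, kind = kind, area_mm2 = area,
         bbox_w = w, bbox_h = h, pix2d = pix2d,
         boundary2d = boundary2d, plane = plane, landmark = landmark,
         boundary_points = matrix(numeric(0), 0, 3)),
    class = "plane_feature"
  )
}

# landmarks drawn from the reference anatomy's structure clouds
draw_ref_landmarks <- function(labs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  an <- ref_anatomy()
  pts <- t(vapply(labs, function(l) {
    m <- an$structures[[as.character(l)]]$points
    m[sample(nrow(m), 1), ]
  }, numeric(3)))
  labeled_landmarks(pts, labs)
}
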
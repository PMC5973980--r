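#' Synthetic abdominal phantom specification
#'
#' Describes a labelled volume with known analytic geometry: ellipsoidal
#' organs (optionally hollow shells, e.g. a stomach with a lumen) and tubular
#' vessels/ducts defined by a polyline path and radius. Later structures in
#' the list take precedence where they overlap (vessels may indent organs,
#' as in real anatomy).
#'
#' @param shape integer length-3 volume dimensions (voxels).
#' @param spacing voxel size in mm (length 3); 1 mm isotropic default.
#' @param organs list of lists with `label`, `name`, `center` (mm), `radii`
#'   (mm), optional `shell_thickness` (mm) for hollow organs.
#' @param tubes list of lists with `label`, `name`, `path` (k x 3 matrix of
#'   mm waypoints) and `radius` (mm).
#' @param contact_label label(s) acting as transducer contact surface.
#' @param target_label label of the clinical target structure.
#' @param seed integer recorded with the spec (generation is deterministic).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing = c(1, 1, 1), organs = list(),
                         tubes = list(), contact_label = integer(),
                         target_label = NULL, seed = 1L) {
  labels <- c(vapply(organs, function(o) o$label, numeric(1)),
              vapply(tubes, function(t) t$label, numeric(1)))
  if (anyDuplicated(labels)) stop("phantom labels must be unique")
  ext <- (shape - 1) * spacing
  for (o in organs) {
    if (any(o$center - o$radii < 0) || any(o$center + o$radii > ext)) {
      stop("organ '", o$name, "' extends outside the volume bounds")
    }
  }
  for (tb in tubes) {
    p <- rbind(tb$path)
    if (any(sweep(p, 2, rep(tb$radius, 3), `-`) < 0) ||
        any(sweep(p, 2, ext - tb$radius, `-`) > 0)) {
      stop("tube '", tb$name, "' extends outside the volume bounds")
    }
  }
  structure(
    list(shape = as.integer(shape), spacing = as.numeric(spacing),
         organs = organs, tubes = tubes,
         contact_label = as.integer(contact_label),
         target_label = if (is.null(target_label)) NULL else as.integer(target_label),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

ellipsoid_quad <- function(shape, spacing, center, radii) {
  xs <- ((seq_len(shape[1]) - 1) * spacing[1] - center[1])^2 / radii[1]^2
  ys <- ((seq_len(shape[2]) - 1) * spacing[2] - center[2])^2 / radii[2]^2
  zs <- ((seq_len(shape[3]) - 1) * spacing[3] - center[3])^2 / radii[3]^2
  outer(outer(xs, ys, `+`), zs, `+`)
}

#' Generate a labelled phantom volume
#'
#' Voxelises the spec (implicit-function thresholding for organs, distance
#' to polyline for tubes; voxel centres classified) and returns the volume
#' together with the analytic ground-truth geometry for oracle testing.
#' Generation is deterministic: the same spec always yields a bit-identical
#' volume.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a [labeled_volume()] whose label table is
#'   derived from the spec roles) and `truth` (the spec, with per-tube
#'   segment geometry expanded).
#' @export
generate_phantom <- function(spec) {
  d <- spec$shape
  vox <- array(0L, d)
  for (o in spec$organs) {
    q <- ellipsoid_quad(d, spec$spacing, o$center, o$radii)
    member <- q <= 1
    if (!is.null(o$shell_thickness)) {
      inner <- pmax(o$radii - o$shell_thickness, 0.5)
      member <- member & ellipsoid_quad(d, spec$spacing, o$center, inner) > 1
    }
    vox[member] <- o$label
  }
  for (tb in spec$tubes) {
    p <- rbind(tb$path)
    r <- tb$radius
    for (s in seq_len(nrow(p) - 1)) {
      p1 <- p[s, ]; p2 <- p[s + 1, ]
      lo <- pmax(floor((pmin(p1, p2) - r) / spec$spacing) + 1, 1)
      hi <- pmin(ceiling((pmax(p1, p2) + r) / spec$spacing) + 1, d)
      xs <- (lo[1]:hi[1] - 1) * spec$spacing[1]
      ys <- (lo[2]:hi[2] - 1) * spec$spacing[2]
      zs <- (lo[3]:hi[3] - 1) * spec$spacing[3]
      nx <- length(xs); ny <- length(ys); nz <- length(zs)
      X <- array(xs, c(nx, ny, nz))
      Y <- array(rep(ys, each = nx), c(nx, ny, nz))
      Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
      v <- p2 - p1
      vv <- sum(v^2)
      t <- ((X - p1[1]) * v[1] + (Y - p1[2]) * v[2] + (Z - p1[3]) * v[3]) / vv
      t <- pmin(1, pmax(0, t))
      d2 <- (X - p1[1] - t * v[1])^2 + (Y - p1[2] - t * v[2])^2 +
            (Z - p1[3] - t * v[3])^2
      member <- d2 <= r^2
      if (any(member)) {
        sub <- vox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
        sub[member] <- tb$label
        vox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
      }
    }
  }
  lt <- phantom_label_table(spec)
  list(volume = labeled_volume(vox, spec$spacing, c(0, 0, 0), lt), truth = spec)
}

phantom_label_table <- function(spec) {
  rows <- lapply(spec$organs, function(o) {
    kind <- if (o$label %in% spec$contact_label) "contact_surface_organ" else "organ"
    data.frame(label = o$label, name = o$name, kind = kind)
  })
  rows <- c(rows, lapply(spec$tubes, function(tb) {
    data.frame(label = tb$label, name = tb$name, kind = "tube")
  }))
  do.call(rbind, rows)
}

#' Reference abdominal phantom
#'
#' A fixed synthetic scene at anatomically realistic scales mimicking the upper-abdominal
#' label inventory the planner consumes in practice: a hollow stomach-like
#' shell (the transducer contact surface), an elongated pancreas-like target
#' directly posterior to it, a liver-like and kidney-like organ, a
#' gallbladder, and four vessels (aorta, vena cava, portal and splenic vein
#' analogues, radii 4-7 mm) running within scanning depth of the posterior
#' stomach wall. The arrangement is asymmetric by construction, so no
#' non-identity rigid transform maps the scene onto itself.
#'
#' @return A [phantom_spec()] (1 mm isotropic, 160 x 150 x 130 voxels).
#' @export
reference_phantom <- function() {
  phantom_spec(
    shape = c(160L, 150L, 130L),
    spacing = c(1, 1, 1),
    organs = list(
      list(label = 1L, name = "stomach", center = c(80, 60, 70),
           radii = c(42, 30, 28), shell_thickness = 5),
      list(label = 2L, name = "pancreas", center = c(85, 100, 62),
           radii = c(38, 11, 9)),
      list(label = 3L, name = "liver", center = c(42, 85, 95),
           radii = c(30, 24, 22)),
      list(label = 4L, name = "left_kidney", center = c(125, 105, 45),
           radii = c(13, 10, 17)),
      list(label = 5L, name = "gallbladder", center = c(30, 55, 60),
           radii = c(8, 7, 11))
    ),
    tubes = list(
      list(label = 6L, name = "aorta", radius = 6,
           path = rbind(c(95, 112, 10), c(93, 114, 65), c(95, 112, 120))),
      list(label = 7L, name = "vena_cava", radius = 7,
           path = rbind(c(70, 112, 10), c(72, 110, 120))),
      list(label = 8L, name = "portal_vein", radius = 5,
           path = rbind(c(60, 95, 85), c(75, 100, 75), c(88, 103, 70))),
      list(label = 9L, name = "splenic_vein", radius = 4,
           path = rbind(c(58, 98, 64), c(85, 101, 62), c(115, 104, 60)))
    ),
    contact_label = 1L,
    target_label = 2L,
    seed = 1L
  )
}
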
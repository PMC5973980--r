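#' Ultrasound sector plane
#'
#' A posed fan-shaped EUS field of view in world coordinates: the apex sits at
#' the transducer contact point, `axis` is the unit central beam direction in
#' the plane, `normal` the unit plane normal. Defaults (120 degree fan, 50 mm
#' depth) correspond to a standard clinical EUS transducer.
#'
#' @param apex world position of the transducer (mm).
#' @param axis unit vector from the apex into tissue, in the plane.
#' @param normal unit plane normal, perpendicular to `axis`.
#' @param fan_angle full sector opening angle, degrees, in (0, 180).
#' @param depth scanning depth, mm (> 0).
#' @param pixel_pitch in-plane grid resolution, mm, used when rasterising.
#' @param vertex_id optional id of the contact-surface vertex the plane is
#'   anchored to.
#' @param id optional plane id.
#' @return An object of class `sector_plane`. The third basis vector
#'   (in-plane lateral direction) is `cross(normal, axis)`.
#' @export
sector_plane <- function(apex, axis, normal, fan_angle = 120, depth = 50,
                         pixel_pitch = 0.5, vertex_id = NA_integer_,
                         id = NA_integer_) {
  apex <- as.numeric(apex)
  axis <- as.numeric(axis)
  normal <- as.numeric(normal)
  na <- sqrt(sum(axis^2))
  nn <- sqrt(sum(normal^2))
  if (na < 1e-12 || nn < 1e-12) stop("zero-length plane axis or normal")
  axis <- axis / na
  normal <- normal / nn
  if (abs(sum(axis * normal)) > 1e-6) stop("`normal` must be perpendicular to `axis`")
  if (!(fan_angle > 0 && fan_angle < 180)) stop("`fan_angle` must be in (0, 180) degrees")
  if (depth <= 0) stop("`depth` must be positive (mm)")
  structure(
    list(apex = apex, axis = axis, normal = normal,
         lateral = cross3(normal, axis),
         fan_angle = fan_angle, depth = depth, pixel_pitch = pixel_pitch,
         vertex_id = vertex_id, id = id),
    class = "sector_plane"
  )
}

#' @export
print.sector_plane <- function(x, ...) {
  cat(sprintf("<sector_plane> apex (%s) mm, fan %g deg, depth %g mm\n",
              paste(signif(x$apex, 4), collapse = ", "), x$fan_angle, x$depth))
  invisible(x)
}

#' Rotation grid for plane sampling at a vertex
#'
#' Symmetric grid of rotation angles applied about the three orthogonal axes
#' of the vertex's local frame. The default step of 30 degrees over
#' [-60, 60] gives 5 angles per axis and 125 planes per vertex; a 20 degree
#' step (7 angles per axis, 343 planes) is the finer alternative.
#'
#' @param range_deg symmetric limit in degrees (default 60).
#' @param step_deg increment in degrees; must divide `2 * range_deg`.
#' @return An object of class `rotation_grid` with the angle vector.
#' @export
rotation_grid <- function(range_deg = 60, step_deg = 30) {
  if (range_deg < 0 || step_deg <= 0) stop("invalid rotation grid")
  if (range_deg > 0 && abs((2 * range_deg / step_deg) %% 1) > 1e-9) {
    stop("`step_deg` must divide 2 * `range_deg`")
  }
  angles <- if (range_deg == 0) 0 else seq(-range_deg, range_deg, by = step_deg)
  structure(list(range_deg = range_deg, step_deg = step_deg, angles = angles),
            class = "rotation_grid")
}

rot_axis <- function(u, theta_deg) {
  th <- theta_deg * pi / 180
  c <- cos(th); s <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c + ux^2 * (1 - c), ux * uy * (1 - c) + uz * s, ux * uz * (1 - c) - uy * s,
    ux * uy * (1 - c) - uz * s, c + uy^2 * (1 - c), uy * uz * (1 - c) + ux * s,
    ux * uz * (1 - c) + uy * s, uy * uz * (1 - c) - ux * s, c + uz^2 * (1 - c)
  ), 3, 3)
}

# an arbitrary unit vector perpendicular to u
perp_vector <- function(u) {
  e <- if (abs(u[1]) <= abs(u[2]) && abs(u[1]) <= abs(u[3])) c(1, 0, 0)
       else if (abs(u[2]) <= abs(u[3])) c(0, 1, 0) else c(0, 0, 1)
  v <- cross3(u, e)
  v / sqrt(sum(v^2))
}

#' Sample candidate sector planes anchored at a surface vertex
#'
#' The base plane points along the inward surface normal (into tissue); the
#' grid of intrinsic rotations about the vertex's local frame (two tangents,
#' then the inward normal, applied in that fixed order) generates
#' `length(angles)^3` physically plausible transducer poses.
#'
#' @param vertex world position of the contact-surface vertex (mm).
#' @param normal outward surface normal at the vertex (unit length).
#' @param grid a [rotation_grid()].
#' @param fan_angle,depth,pixel_pitch sector geometry, see [sector_plane()].
#' @param vertex_id id stored on each generated plane.
#' @return List of [sector_plane()] objects.
#' @export
sample_planes_at_vertex <- function(vertex, normal, grid = rotation_grid(),
                                    fan_angle = 120, depth = 50,
                                    pixel_pitch = 0.5, vertex_id = NA_integer_) {
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn < 1e-12) stop("zero-length vertex normal")
  n_in <- -as.numeric(normal) / nn
  t1 <- perp_vector(n_in)
  t2 <- cross3(n_in, t1)
  planes <- vector("list", length(grid$angles)^3)
  k <- 0L
  for (a in grid$angles) for (b in grid$angles) for (cc in grid$angles) {
    R <- rot_axis(t1, a) %*% rot_axis(t2, b) %*% rot_axis(n_in, cc)
    k <- k + 1L
    planes[[k]] <- sector_plane(vertex, drop(R %*% n_in), drop(R %*% t2),
                                fan_angle = fan_angle, depth = depth,
                                pixel_pitch = pixel_pitch,
                                vertex_id = vertex_id, id = k)
  }
  planes
}

#' Test whether a point lies inside a plane's sector
#'
#' True iff the point lies in the plane (within half a pixel pitch), within
#' `depth` of the apex and within `fan_angle / 2` of the central axis.
#'
#' @param p world point (mm), or an n x 3 matrix of points.
#' @param plane a [sector_plane()].
#' @return Logical (vector).
#' @export
point_in_sector <- function(p, plane) {
  p <- rbind(p)
  d <- sweep(p, 2, plane$apex, `-`)
  off <- drop(d %*% plane$normal)
  a <- drop(d %*% plane$axis)
  l <- drop(d %*% plane$lateral)
  r <- sqrt(a^2 + l^2)
  ang <- atan2(abs(l), a) * 180 / pi
  abs(off) <= plane$pixel_pitch / 2 + 1e-9 &
    r <= plane$depth + 1e-9 &
    ang <= plane$fan_angle / 2 + 1e-9
}

# in-plane raster of the sector: pixel centres at pitch spacing,
# optionally extended by `margin_px` pixels beyond the sector's bounding box.
# Returns lateral offsets (l), axial offsets (a) and the in-sector mask.
sector_raster <- function(plane, pitch = plane$pixel_pitch, margin_px = 0L) {
  half <- plane$fan_angle / 2
  w <- plane$depth * sin(pmin(half, 90) * pi / 180)
  l <- seq(-w - margin_px * pitch, w + margin_px * pitch, by = pitch)
  a <- seq(-margin_px * pitch, plane$depth + margin_px * pitch, by = pitch)
  L <- matrix(l, nrow = length(l), ncol = length(a))
  A <- matrix(a, nrow = length(l), ncol = length(a), byrow = TRUE)
  r <- sqrt(L^2 + A^2)
  ang <- atan2(abs(L), A) * 180 / pi
  inside <- r <= plane$depth + 1e-9 & ang <= half + 1e-9 & A >= 0
  list(l = l, a = a, L = L, A = A, inside = inside)
}

# world coordinates of raster pixels given in-plane (l, a) offsets
raster_world <- function(plane, L, A) {
  cbind(plane$apex[1] + L * plane$lateral[1] + A * plane$axis[1],
        plane$apex[2] + L * plane$lateral[2] + A * plane$axis[2],
        plane$apex[3] + L * plane$lateral[3] + A * plane$axis[3])
}

# pixel-centre world points of the sector at a given pitch (for TRE_plane)
sector_grid_points <- function(plane, pitch = 1) {
  ras <- sector_raster(plane, pitch = pitch)
  raster_world(plane, ras$L[ras$inside], ras$A[ras$inside])
}

# nearest-voxel label lookup at world points; 0 outside the volume
sample_labels <- function(volume, pts) {
  idx <- world_to_voxel(volume, pts) + 1  # to 1-based
  d <- dim(volume$voxels)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- integer(nrow(pts))
  if (any(ok)) {
    lin <- (idx[ok, 3] - 1) * d[1] * d[2] + (idx[ok, 2] - 1) * d[1] + idx[ok, 1]
    out[ok] <- volume$voxels[lin]
  }
  out
}

#' Intersect a sector plane with one structure
#'
#' Rasterises the labelled volume on the plane's pixel grid
#' (nearest-neighbour at pixel centres) and returns one feature per
#' 8-connected component of the structure's in-sector cross-section:
#' its area, bounding box, boundary points and automatically extracted
#' landmark (see [extract_landmark()]).
#'
#' @param plane a [sector_plane()].
#' @param s an [eus_structure()].
#' @param volume the [labeled_volume()] the structure came from.
#' @return List of `plane_feature` objects (empty if no intersection).
#' @export
intersect_structure <- function(plane, s, volume) {
  lab_img <- rasterise_plane(plane, volume)
  features_from_raster(plane, lab_img, labels = s$label,
                       kinds = stats::setNames(s$kind, s$label))
}

# label image of the plane raster (with margin for boundary detection)
rasterise_plane <- function(plane, volume, margin_px = 3L) {
  ras <- sector_raster(plane, margin_px = margin_px)
  pts <- raster_world(plane, as.vector(ras$L), as.vector(ras$A))
  labs <- sample_labels(volume, pts)
  list(ras = ras, labels = matrix(labs, nrow = length(ras$l)))
}

# build plane features for the given labels from a rasterised label image
features_from_raster <- function(plane, lab_img, labels, kinds) {
  ras <- lab_img$ras
  pitch <- plane$pixel_pitch
  out <- list()
  for (lab in labels) {
    full <- lab_img$labels == lab
    if (!any(full)) next
    insec <- full & ras$inside
    if (!any(insec)) next
    comp <- .label_components2d(matrix(as.integer(insec), nrow = nrow(insec)))
    # boundary of the *full* in-plane mask (4-neighbourhood), so pixels cut
    # only by the sector edge do not count as anatomical boundary
    bnd <- full & !(shift_mask(full, 1, 0) & shift_mask(full, -1, 0) &
                    shift_mask(full, 0, 1) & shift_mask(full, 0, -1))
    kind <- unname(kinds[as.character(lab)])
    for (k in seq_len(max(comp))) {
      sel <- comp == k
      npix <- sum(sel)
      lpix <- ras$L[sel]
      apix <- ras$A[sel]
      bsel <- sel & bnd
      f <- structure(
        list(structure_label = lab, kind = kind,
             area_mm2 = npix * pitch^2,
             bbox_w = diff(range(lpix)) + pitch,
             bbox_h = diff(range(apix)) + pitch,
             pix2d = cbind(lpix, apix),
             boundary2d = cbind(ras$L[bsel], ras$A[bsel]),
             plane = plane),
        class = "plane_feature"
      )
      f$landmark <- tryCatch(extract_landmark(f), error = function(e) rep(NA_real_, 3))
      f$boundary_points <- if (sum(bsel)) raster_world(plane, ras$L[bsel], ras$A[bsel])
                           else matrix(numeric(0), 0, 3)
      out[[length(out) + 1L]] <- f
    }
  }
  out
}

shift_mask <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  si <- max(1, 1 + di):min(nr, nr + di)
  sj <- max(1, 1 + dj):min(nc, nc + dj)
  out[si, sj] <- m[si - di, sj - dj]
  out
}

#' Extract the anatomical landmark of a plane feature
#'
#' Vessels/ducts: the centroid (centre of mass) of the cross-section.
#' Organs: the boundary point of the visible segment closest to the mean of
#' all visible boundary points (ties broken by lowest point index).
#'
#' @param f a `plane_feature` from [intersect_structure()].
#' @return World coordinates (length-3) of the landmark, which lies in the
#'   plane and inside the sector.
#' @export
extract_landmark <- function(f) {
  plane <- f$plane
  if (nrow(f$pix2d) == 0L) stop("empty feature: no pixels")
  if (f$kind == "tube") {
    ctr <- colMeans(f$pix2d)
    return(drop(raster_world(plane, ctr[1], ctr[2])))
  }
  if (nrow(f$boundary2d) == 0L) stop("organ feature has no visible boundary segment")
  m <- colMeans(f$boundary2d)
  d2 <- (f$boundary2d[, 1] - m[1])^2 + (f$boundary2d[, 2] - m[2])^2
  i <- which.min(d2)  # which.min returns the lowest index on ties
  drop(raster_world(plane, f$boundary2d[i, 1], f$boundary2d[i, 2]))
}

#' All features of a plane across an anatomy model
#'
#' Rasterises the volume once on the plane grid and extracts features for
#' every structure in the model.
#'
#' @param plane a [sector_plane()].
#' @param anatomy an [anatomy_model()].
#' @return List of `plane_feature` objects.
#' @export
plane_features <- function(plane, anatomy) {
  lt <- anatomy$label_table
  kinds <- ifelse(lt$kind == "tube", "tube", "organ")
  names(kinds) <- lt$label
  lab_img <- rasterise_plane(plane, anatomy$volume)
  features_from_raster(plane, lab_img, labels = lt$label, kinds = kinds)
}

#' Discard features too small to identify on EUS
#'
#' Features with cross-sectional areas less than `min_area_mm2` are dropped
#' (strictly less than: a feature exactly at the threshold is retained), as
#' are degenerate features without a landmark. Order is preserved.
#'
#' @param features list of `plane_feature` objects.
#' @param min_area_mm2 area threshold in mm^2; 5 by default, below which a
#'   gastroenterologist could not reliably identify the feature.
#' @return Filtered list.
#' @export
filter_features <- function(features, min_area_mm2 = 5) {
  if (min_area_mm2 < 0) stop("`min_area_mm2` must be >= 0")
  keep <- vapply(features, function(f) {
    f$area_mm2 >= min_area_mm2 && all(is.finite(f$landmark))
  }, logical(1))
  features[keep]
}

#' Is a plane usable for six-degree-of-freedom registration?
#'
#' A rigid transform needs at least three non-degenerate correspondences, so
#' only planes with three or more (area-filtered) features are usable.
#'
#' @param features list of already-filtered `plane_feature` objects.
#' @return `TRUE` iff three or more features are present.
#' @export
plane_is_usable <- function(features) {
  length(features) >= 3L
}

#' Serialise planes to JSON
#'
#' Writes apex, orientation (axis/normal/lateral), fan angle and depth of
#' each plane.
#'
#' @param planes list of [sector_plane()] objects.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_planes_json <- function(planes, path) {
  payload <- lapply(planes, function(p) {
    list(id = p$id, vertex_id = p$vertex_id, apex = p$apex, axis = p$axis,
         normal = p$normal, fan_angle_deg = p$fan_angle, depth_mm = p$depth,
         pixel_pitch_mm = p$pixel_pitch)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
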
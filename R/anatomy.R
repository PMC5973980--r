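#' Anatomical structure as a point cloud
#'
#' A structure is one anatomical entity represented the way the registration
#' consumes it: organs as the vertices (plus triangle faces) of a closed
#' surface mesh, vessels and ducts ("tubes") as an unordered set of centreline
#' points. Both live in world millimetres.
#'
#' @param label integer label of the structure in the source volume.
#' @param kind `"organ"` or `"tube"`.
#' @param points n x 3 numeric matrix of world coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices (organs only).
#' @param name optional human-readable name.
#' @return An object of class `eus_structure`.
#' @export
eus_structure <- function(label, kind, points, faces = NULL, name = NULL) {
  kind <- match.arg(kind, c("organ", "tube"))
  points <- as.matrix(points)
  if (nrow(points) < 1L || !all(is.finite(points))) {
    stop("a structure needs at least one finite point")
  }
  if (kind == "tube" && !is.null(faces)) stop("tube structures carry no faces")
  if (kind == "organ" && is.null(faces)) stop("organ structures need faces")
  structure(
    list(label = as.integer(label), kind = kind, points = points,
         faces = faces, name = name %||% paste0("label", label)),
    class = "eus_structure"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eus_structure <- function(x, ...) {
  cat(sprintf("<eus_structure> %s (label %d, %s): %d points%s\n",
              x$name, x$label, x$kind, nrow(x$points),
              if (!is.null(x$faces)) sprintf(", %d faces", nrow(x$faces)) else ""))
  invisible(x)
}

#' Extract an organ surface from a labelled volume
#'
#' Builds a closed triangle mesh of the boundary of one label. The binary
#' mask is lightly smoothed with a Gaussian (in voxel units) and the 0.5
#' iso-level is triangulated by marching tetrahedra on the Freudenthal
#' decomposition of the voxel lattice, so the mesh is closed, consistently
#' oriented (normals outward) and sub-voxel accurate.
#'
#' @param volume a [labeled_volume()].
#' @param label integer label to extract; must occur in the volume.
#' @param smooth_sigma Gaussian pre-smoothing SD in voxels. 1 preserves
#'   structures a few voxels across while removing voxelisation staircase;
#'   0 disables smoothing.
#' @return An [eus_structure()] of kind `"organ"`.
#' @export
extract_surface <- function(volume, label, smooth_sigma = 1) {
  mask <- volume$voxels == label
  cr <- crop_mask(mask, pad = max(2L, ceiling(3 * smooth_sigma)))
  field <- .gaussian_smooth3(array(as.double(cr$mask), dim(cr$mask)),
                             dim(cr$mask), smooth_sigma)
  origin <- volume$origin + cr$offset * volume$spacing
  mesh <- .marching_tetrahedra(field, dim(cr$mask), 0.5, volume$spacing, origin)
  if (nrow(mesh$vertices) == 0L) {
    stop("empty label: iso-surface extraction produced no geometry for label ", label)
  }
  nm <- structure_name(volume, label)
  eus_structure(label, "organ", mesh$vertices, mesh$faces, name = nm)
}

structure_name <- function(volume, label) {
  lt <- volume$label_table
  if (is.null(lt)) return(NULL)
  i <- match(label, lt$label)
  if (is.na(i)) NULL else lt$name[i]
}

#' Surface area of a triangle mesh
#' @param s an organ [eus_structure()].
#' @return Total area in mm^2.
#' @export
mesh_area <- function(s) {
  V <- s$points
  F <- s$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(key), , drop = FALSE]
}

#' Mean edge length (inter-vertex spacing) of a mesh
#' @param s an organ [eus_structure()].
#' @return Mean length over unique mesh edges, mm.
#' @export
mean_edge_length <- function(s) {
  e <- mesh_edges(s$faces)
  d <- s$points[e[, 1], , drop = FALSE] - s$points[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Per-vertex outward normals of a mesh
#' @param s an organ [eus_structure()].
#' @return n x 3 matrix of unit normals (area-weighted face-normal average).
#' @export
vertex_normals <- function(s) {
  V <- s$points
  F <- s$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  N <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    acc <- rowsum(fn, group = F[, k])
    ids <- as.integer(rownames(acc))
    N[ids, ] <- N[ids, ] + acc
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# empirical ratio of mean edge length to cluster cell size for
# marching-tetrahedra meshes decimated by vertex clustering
.edge_per_cell <- 1.01

#' Decimate an organ surface by vertex clustering
#'
#' Vertices are clustered on a uniform grid, each cluster replaced by its
#' centroid and faces re-indexed, dropping degenerates and duplicates. The
#' grid cell size is chosen so that the decimated mesh's mean inter-vertex
#' spacing approximates `target_edge_mm`; the default, 5.33 mm, corresponds
#' to roughly half the width of a clinical EUS transducer.
#'
#' @param s an organ [eus_structure()].
#' @param target_edge_mm requested mean inter-vertex spacing, mm (> 0).
#' @return A decimated organ [eus_structure()]. If the target exceeds the
#'   mesh extent the mesh collapses; a minimal tetrahedron over extreme
#'   vertices is returned with a warning.
#' @export
decimate_surface <- function(s, target_edge_mm = 5.33) {
  if (s$kind != "organ") stop("only organ surfaces can be decimated")
  if (!is.numeric(target_edge_mm) || target_edge_mm <= 0) {
    stop("`target_edge_mm` must be a positive length in mm")
  }
  V <- s$points
  cell <- target_edge_mm / .edge_per_cell
  g <- floor(sweep(V, 2, apply(V, 2, min), `-`) / cell)
  key <- paste(g[, 1], g[, 2], g[, 3])
  cl <- match(key, unique(key))
  nc <- max(cl)
  newV <- unname(rowsum(V, cl)) / tabulate(cl, nc)  # cl is 1..nc, rowsum sorts likewise
  F <- matrix(cl[s$faces], ncol = 3)
  keep <- F[, 1] != F[, 2] & F[, 2] != F[, 3] & F[, 1] != F[, 3]
  F <- F[keep, , drop = FALSE]
  fkey <- apply(F, 1, function(r) paste(sort(r), collapse = " "))
  F <- F[!duplicated(fkey), , drop = FALSE]
  if (nc < 4L || nrow(F) < 4L) {
    warning("decimation target exceeds mesh extent; returning a minimal tetrahedron")
    return(minimal_tetrahedron(s))
  }
  eus_structure(s$label, "organ", newV, F, name = s$name)
}

minimal_tetrahedron <- function(s) {
  V <- s$points
  i1 <- 1L
  d1 <- rowSums(sweep(V, 2, V[i1, ], `-`)^2)
  i2 <- which.max(d1)
  u <- V[i2, ] - V[i1, ]
  u <- u / sqrt(sum(u^2))
  rel <- sweep(V, 2, V[i1, ], `-`)
  perp <- rel - outer(drop(rel %*% u), u)
  i3 <- which.max(rowSums(perp^2))
  n <- cross3(V[i2, ] - V[i1, ], V[i3, ] - V[i1, ])
  i4 <- which.max(abs(drop(rel %*% n)))
  idx <- c(i1, i2, i3, i4)
  eus_structure(s$label, "organ", V[idx, , drop = FALSE],
                rbind(c(1, 2, 3), c(1, 4, 2), c(2, 4, 3), c(1, 3, 4)),
                name = s$name)
}

#' Extract a vessel/duct centreline from a labelled volume
#'
#' Thins the binary mask of the label to a unit-wide, topology-preserving
#' skeleton (26-connected foreground, 6-connected background; directional
#' sub-iterations deleting simple non-end points) and returns the centres of
#' the surviving voxels in world coordinates.
#'
#' @param volume a [labeled_volume()].
#' @param label integer label of the tubular structure.
#' @return An [eus_structure()] of kind `"tube"`; the 0-based voxel indices
#'   of the skeleton are attached as attribute `"voxel_idx"`.
#' @export
extract_centreline <- function(volume, label) {
  mask <- volume$voxels == label
  cr <- crop_mask(mask, pad = 1L)
  sk <- .thin3d(array(as.integer(cr$mask), dim(cr$mask)), dim(cr$mask))
  w <- which(sk == 1L, arr.ind = TRUE)
  idx0 <- sweep(w - 1L, 2, cr$offset, `+`)  # 0-based indices in full volume
  pts <- voxel_to_world(volume, idx0)
  out <- eus_structure(label, "tube", pts, name = structure_name(volume, label))
  attr(out, "voxel_idx") <- idx0
  out
}

#' Build an anatomy model from a labelled volume
#'
#' Converts every labelled structure into its registration representation:
#' organ labels become decimated surface point clouds, tube labels become
#' centrelines. Contact-surface organs (the stomach and, when present, the
#' duodenum -- where the transducer can sit) additionally get a coarser mesh
#' whose vertices serve as candidate transducer positions.
#'
#' @param volume a [labeled_volume()] whose `label_table` assigns kinds.
#' @param target_label optional label of the clinical target (e.g. pancreas).
#' @param contact_edge_mm mean vertex spacing of the contact-surface mesh;
#'   5.33 mm default (about half the transducer width).
#' @param cloud_edge_mm mean vertex spacing of organ registration clouds;
#'   finer than the contact mesh so nearest-point quantisation stays well
#'   below the landmark noise.
#' @param smooth_sigma see [extract_surface()].
#' @return An object of class `anatomy_model` with elements `structures`
#'   (list keyed by label), `contact_surfaces` (list of coarse meshes with
#'   outward vertex normals attached), `target` and `volume`.
#' @export
anatomy_model <- function(volume, target_label = NULL,
                          contact_edge_mm = 5.33, cloud_edge_mm = 2,
                          smooth_sigma = 1) {
  lt <- volume$label_table
  if (is.null(lt)) stop("the volume needs a `label_table` assigning structure kinds")
  missing <- lt$label[lt$absent]
  if (length(missing)) {
    stop("label(s) named in the configuration are absent from the volume: ",
         paste(sprintf("%s (%d)", lt$name[lt$absent], missing), collapse = ", "))
  }
  structures <- list()
  contact <- list()
  for (i in seq_len(nrow(lt))) {
    lab <- lt$label[i]
    if (lt$kind[i] == "tube") {
      structures[[as.character(lab)]] <- extract_centreline(volume, lab)
    } else {
      surf <- extract_surface(volume, lab, smooth_sigma = smooth_sigma)
      structures[[as.character(lab)]] <- decimate_surface(surf, cloud_edge_mm)
      if (lt$kind[i] == "contact_surface_organ") {
        cs <- decimate_surface(surf, contact_edge_mm)
        attr(cs, "normals") <- vertex_normals(cs)
        contact[[as.character(lab)]] <- cs
      }
    }
  }
  target <- NULL
  if (!is.null(target_label)) {
    key <- as.character(target_label)
    if (is.null(structures[[key]])) {
      stop("target label ", target_label, " is not among the model's structures")
    }
    target <- structures[[key]]
  }
  structure(
    list(structures = structures, contact_surfaces = contact,
         target = target, label_table = lt, volume = volume),
    class = "anatomy_model"
  )
}

#' @export
print.anatomy_model <- function(x, ...) {
  cat(sprintf("<anatomy_model> %d structures, %d contact surface(s)%s\n",
              length(x$structures), length(x$contact_surfaces),
              if (!is.null(x$target)) sprintf(", target: %s", x$target$name) else ""))
  invisible(x)
}

#' Write a mesh (with optional per-vertex scalar) as ASCII PLY
#'
#' @param s an organ [eus_structure()].
#' @param path output `.ply` path.
#' @param scalar optional numeric per-vertex values written as a `quality`
#'   property (NA allowed).
#' @return `path`, invisibly.
#' @export
write_ply <- function(s, path, scalar = NULL) {
  V <- s$points
  F <- s$faces
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z")
  if (!is.null(scalar)) hdr <- c(hdr, "property float quality")
  hdr <- c(hdr, sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vm <- if (is.null(scalar)) V else cbind(V, ifelse(is.finite(scalar), scalar, -1))
  writeLines(apply(vm, 1, function(r) paste(signif(r, 8), collapse = " ")), con)
  writeLines(paste(3, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  invisible(path)
}

#' Write a centreline (or any point structure) as CSV
#' @param s an [eus_structure()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_centreline_csv <- function(s, path) {
  df <- data.frame(x = s$points[, 1], y = s$points[, 2], z = s$points[, 3],
                   label = s$label)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
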
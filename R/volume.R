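#' Labelled 3D volume
#'
#' Container for an integer-labelled image volume (e.g. a segmented abdominal
#' CT) together with its voxel spacing, world origin and a table describing
#' the anatomical role of each label. All package geometry is expressed in
#' world millimetres; a voxel with 0-based index `(i, j, k)` has its centre at
#' `origin + c(i, j, k) * spacing`. Only axis-aligned volumes are supported.
#'
#' @param voxels 3D integer array of labels (0 = background).
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @param label_table `data.frame` with columns `label` (integer), `name`
#'   (character) and `kind` (one of `"organ"`, `"tube"`,
#'   `"contact_surface_organ"`). May be `NULL` and attached later.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(voxels, spacing, origin = c(0, 0, 0), label_table = NULL) {
  stopifnot(length(dim(voxels)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite values (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite values (mm)")
  }
  storage.mode(voxels) <- "integer"
  if (!is.null(label_table)) label_table <- validate_label_table(label_table, voxels)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         label_table = label_table),
    class = "labeled_volume"
  )
}

validate_label_table <- function(label_table, voxels) {
  label_table <- as.data.frame(label_table)
  req <- c("label", "name", "kind")
  if (!all(req %in% names(label_table))) {
    stop("`label_table` needs columns: ", paste(req, collapse = ", "))
  }
  kinds <- c("organ", "tube", "contact_surface_organ")
  bad <- setdiff(label_table$kind, kinds)
  if (length(bad)) stop("unknown structure kind(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(label_table$label)) stop("duplicate labels in `label_table`")
  present <- unique(as.vector(voxels))
  label_table$absent <- !(label_table$label %in% present)
  label_table
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  if (!is.null(x$label_table)) {
    cat(sprintf("  %d labels (%d absent from voxels)\n",
                nrow(x$label_table), sum(x$label_table$absent)))
  }
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based, matching the convention of NIfTI headers; the
#' round trip `world_to_voxel(voxel_to_world(idx))` is exact for in-bounds
#' indices.
#'
#' @param volume a [labeled_volume()].
#' @param idx integer matrix (n x 3) of 0-based voxel indices.
#' @param xyz numeric matrix (n x 3) of world coordinates in mm.
#' @return `voxel_to_world()` returns an n x 3 matrix of world mm;
#'   `world_to_voxel()` an n x 3 integer matrix of 0-based indices (nearest
#'   voxel).
#' @export
voxel_to_world <- function(volume, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx, 2, volume$spacing, `*`), 2, volume$origin, `+`)
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(volume, xyz) {
  xyz <- rbind(xyz)
  out <- sweep(sweep(xyz, 2, volume$origin, `-`), 2, volume$spacing, `/`)
  storage.mode(out) <- "double"
  round(out)
}

#' Read a labelled volume from NIfTI
#'
#' Spacing and origin are taken from the NIfTI transform. Oblique (non
#' axis-aligned) direction matrices are rejected: the planning geometry
#' assumes a world frame aligned with the voxel grid.
#'
#' @param path path to a `.nii` or `.nii.gz` file of integer labels.
#' @param label_table optional label role table (see [labeled_volume()]).
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(path, label_table = NULL) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  dircos <- sweep(rot, 2, spacing, `/`)
  if (max(abs(abs(dircos) - diag(3))) > 1e-4) {
    stop("oblique direction matrices are not supported; resample the volume ",
         "to an axis-aligned grid first")
  }
  # fold any axis flips into the origin by working in index space directly
  if (max(abs(dircos - diag(3))) > 1e-4) {
    warning("axis flips in the NIfTI transform are ignored; using |spacing| ",
            "with the header origin")
  }
  origin <- xf[1:3, 4]
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  arr <- array(as.integer(round(arr)), dim(arr))  # drop RNifti attributes
  labeled_volume(arr, spacing, origin, label_table)
}

#' Write a labelled volume to NIfTI
#'
#' @param volume a [labeled_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(volume, path) {
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(volume$voxels)
  img <- RNifti::`pixdim<-`(img, volume$spacing)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Labels present in a volume
#' @param volume a [labeled_volume()].
#' @return Sorted integer vector of non-zero labels occurring in the voxels.
#' @export
volume_labels <- function(volume) {
  sort(setdiff(unique(as.vector(volume$voxels)), 0L))
}

# crop a binary mask to its bounding box plus `pad` voxels of zeros;
# returns mask array, 0-based index offset of the crop origin
crop_mask <- function(mask, pad) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty label: no voxels carry the requested label")
  lo <- pmax(apply(w, 2, min) - pad, 1L)
  hi <- pmin(apply(w, 2, max) + pad, dim(mask))
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  # guarantee a zero border so that extracted geometry is closed
  d <- dim(sub) + 2L
  padded <- array(FALSE, d)
  padded[2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L)] <- sub
  list(mask = padded, offset = lo - 2L)  # 0-based offset of padded [1,1,1]
}
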
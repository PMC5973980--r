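#' Rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation in mm.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("`rotation` must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param pts n x 3 matrix (or length-3 vector) of points.
#' @return Transformed points, same shape.
#' @export
apply_transform <- function(transform, pts) {
  vec <- is.null(dim(pts))
  pts <- rbind(pts)
  out <- sweep(pts %*% t(transform$rotation), 2, transform$translation, `+`)
  if (vec) drop(out) else out
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%s) mm\n",
              ang, paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

#' Rotation angle of a rotation matrix
#' @param R 3 x 3 rotation matrix.
#' @return Angle in degrees, in [0, 180].
#' @export
rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Transform as a 4 x 4 homogeneous matrix
#' @param transform a [rigid_transform()].
#' @return 4 x 4 numeric matrix.
#' @export
as_homogeneous <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' Closed-form least-squares rigid transform between paired point sets
#'
#' Kabsch/Procrustes solution via SVD of the cross-covariance; reflections
#' are excluded. Requires at least three non-collinear pairs, otherwise the
#' six degrees of freedom are underdetermined.
#'
#' @param moving,fixed n x 3 matrices of paired points (`moving[i, ]`
#'   corresponds to `fixed[i, ]`).
#' @return A [rigid_transform()] mapping `moving` onto `fixed` in the
#'   least-squares sense.
#' @export
solve_rigid <- function(moving, fixed) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("point sets must be paired")
  if (nrow(moving) < 3L) stop("underdetermined: at least 3 point pairs are required")
  ctr <- sweep(moving, 2, colMeans(moving))
  sv <- svd(ctr)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12)) {
    stop("underdetermined: points are collinear")
  }
  fit <- .kabsch_cpp(moving, fixed)
  rigid_transform(fit$rotation, fit$translation)
}

#' Nearest structure point to a query point
#'
#' Exhaustive nearest-neighbour over the structure's point cloud; ties are
#' broken by the lowest point index.
#'
#' @param p length-3 world point (mm).
#' @param s an [eus_structure()].
#' @return List with `point`, `distance` (mm) and `index`.
#' @export
closest_point <- function(p, s) {
  res <- .closest_point_cpp(as.numeric(p), s$points)
  list(point = s$points[res$index, ], distance = res$distance, index = res$index)
}

#' Labelled landmarks
#'
#' Intra-procedure landmarks: 3D points each tagged with the label of the
#' pre-procedure structure it belongs to (not with a specific point on it).
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param labels integer vector of structure labels, one per point.
#' @return Object of class `labeled_landmarks`.
#' @export
labeled_landmarks <- function(points, labels) {
  points <- rbind(points)
  labels <- as.integer(labels)
  if (nrow(points) != length(labels)) stop("one label per landmark point is required")
  structure(list(points = points, labels = labels), class = "labeled_landmarks")
}

#' Landmark-to-structure rigid registration
#'
#' Registers labelled landmarks to an anatomy model: each landmark is
#' constrained to its own structure's point cloud (surface vertices for
#' organs, centreline points for tubes). Each start draws a random point of
#' the corresponding structure as initial correspondence, solves the
#' closed-form rigid fit and then alternates nearest-point correspondence
#' (within the assigned structure only) with the rigid fit, as in iterative
#' closest point, until the RMS change drops below `tol`. The best of
#' `n_starts` results (smallest final RMS) is returned.
#'
#' @param landmarks a [labeled_landmarks()] with at least 3 points.
#' @param anatomy an [anatomy_model()] resolving every landmark label.
#' @param n_starts number of stochastic restarts.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the result is reproducible.
#' @param max_iter,tol convergence controls: iteration cap and minimum RMS
#'   improvement in mm.
#' @param init_tol_mm tolerance of the distance-consistency rejection used
#'   when seeding correspondences: a start draws random structure points for
#'   three anchor landmarks but rejects draws whose pairwise distances differ
#'   from the landmarks' own (rigid-invariant) distances by more than this.
#'   Keeps the stochastic initialisation concentrated on geometrically
#'   plausible poses; should be of the order of the cloud point spacing plus
#'   the expected landmark error.
#' @return A `registration_result`: `transform`, `rms_mm`, `iterations`,
#'   `converged` and the per-iteration RMS `trace` of the winning start.
#' @export
register_landmarks <- function(landmarks, anatomy, n_starts = 10, seed = NULL,
                               max_iter = 100, tol = 1e-4, init_tol_mm = 3) {
  if (!inherits(landmarks, "labeled_landmarks")) stop("need a `labeled_landmarks` object")
  if (nrow(landmarks$points) < 3L) {
    stop("underdetermined: at least 3 landmarks are required for a ",
         "six-degree-of-freedom rigid registration")
  }
  keys <- as.character(landmarks$labels)
  missing <- setdiff(unique(keys), names(anatomy$structures))
  if (length(missing)) stop("landmark label(s) not in the anatomy model: ",
                            paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  clouds <- lapply(unique(keys), function(k) anatomy$structures[[k]]$points)
  cloud_of <- match(keys, unique(keys)) - 1L
  fit <- .icp_register_cpp(landmarks$points, cloud_of, clouds,
                           as.integer(n_starts), as.integer(max_iter), tol,
                           init_tol_mm)
  structure(
    list(transform = rigid_transform(fit$rotation, fit$translation),
         rms_mm = fit$rms_mm, iterations = fit$iterations,
         converged = fit$converged, trace = fit$trace),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> RMS %.4f mm after %d iterations (%s)\n",
              x$rms_mm, x$iterations,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}
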
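#' Landmark and tracking noise model
#'
#' All noises are zero-mean isotropic Gaussians. Organ landmarks get a fixed
#' per-axis SD (2 mm default, a conservative estimate of boundary
#' localisation error). Vessel/duct landmarks get an SD derived from the
#' feature's visible bounding box, `sigma = (1/3) * (1/2) * ((w + h) / 2)`
#' = `(w + h) / 12`: one third of the mean half-extent, so larger visible
#' cross-sections are (proportionally) harder to pinpoint. Tracking noise
#' applies to the pose of a second plane only.
#'
#' @param organ_sigma_mm per-axis SD of organ landmark error, mm.
#' @param tube_sigma_rule function of `(w, h)` (bounding box, mm) returning
#'   the per-axis SD in mm.
#' @param tracking_sigma_pos_mm SD of the second plane's position error, mm.
#' @param tracking_sigma_rot_deg SD of the second plane's per-axis rotation
#'   error, degrees.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(organ_sigma_mm = 2,
                        tube_sigma_rule = function(w, h) (w + h) / 12,
                        tracking_sigma_pos_mm = 0.4,
                        tracking_sigma_rot_deg = 0.36) {
  stopifnot(organ_sigma_mm >= 0, tracking_sigma_pos_mm >= 0,
            tracking_sigma_rot_deg >= 0)
  structure(
    list(organ_sigma_mm = organ_sigma_mm, tube_sigma_rule = tube_sigma_rule,
         tracking_sigma_pos_mm = tracking_sigma_pos_mm,
         tracking_sigma_rot_deg = tracking_sigma_rot_deg),
    class = "noise_model"
  )
}

feature_sigma <- function(f, noise) {
  if (f$kind == "tube") noise$tube_sigma_rule(f$bbox_w, f$bbox_h)
  else noise$organ_sigma_mm
}

#' Perturb plane features into noisy labelled landmarks
#'
#' Each extracted landmark receives an independent isotropic 3D Gaussian
#' offset with the kind-appropriate SD, emulating intra-procedure landmark
#' localisation error.
#'
#' @param features filtered `plane_feature` list (>= 3 for registration use).
#' @param noise a [noise_model()].
#' @param seed optional integer for reproducibility.
#' @return A [labeled_landmarks()] object.
#' @export
perturb_landmarks <- function(features, noise = noise_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- t(vapply(features, function(f) {
    f$landmark + rnorm(3, 0, feature_sigma(f, noise))
  }, numeric(3)))
  labeled_landmarks(pts, vapply(features, function(f) f$structure_label, numeric(1)))
}

tre_points <- function(pts, transform) {
  moved <- apply_transform(transform, pts)
  sqrt(mean(rowSums((moved - pts)^2)))
}

#' Target registration error over a plane's pixel grid
#'
#' RMS of the Euclidean distances between corresponding pixel positions of
#' the ground-truth plane and its image under `transform`
#' (`sqrt(mean(d^2))` over the in-sector pixel centres).
#'
#' @param plane a [sector_plane()] (the ground truth pose).
#' @param transform a [rigid_transform()] (the recovered registration).
#' @param pitch evaluation grid pitch in mm; 1 mm default.
#' @return TRE in mm.
#' @export
tre_plane <- function(plane, transform, pitch = 1) {
  tre_points(sector_grid_points(plane, pitch), transform)
}

#' Target registration error over a target structure's vertices
#'
#' RMS of the distances between corresponding vertices of the target
#' structure and its image under `transform`; estimates the registration
#' accuracy at a clinical region of interest away from the imaging plane.
#'
#' @param target an [eus_structure()] (e.g. the pancreas surface).
#' @param transform a [rigid_transform()].
#' @return TRE in mm.
#' @export
tre_surface <- function(target, transform) {
  tre_points(target$points, transform)
}

#' Monte-Carlo TRE distribution
#'
#' @param samples_mm numeric vector of simulated TREs (all >= 0).
#' @param kind `"plane"` or `"surface"`.
#' @return Object of class `tre_distribution` with summary statistics
#'   (`mean`, `sd`, nearest-rank `p90`, `n`).
#' @export
tre_distribution <- function(samples_mm, kind = c("plane", "surface")) {
  kind <- match.arg(kind)
  stopifnot(length(samples_mm) >= 1, all(samples_mm >= 0))
  structure(
    list(samples_mm = samples_mm, n = length(samples_mm),
         mean = mean(samples_mm), sd = if (length(samples_mm) > 1) sd(samples_mm) else 0,
         p90 = percentile_90(samples_mm), kind = kind),
    class = "tre_distribution"
  )
}

#' @export
print.tre_distribution <- function(x, ...) {
  cat(sprintf("<tre_distribution> %s: n=%d, mean %.2f mm, sd %.2f mm, p90 %.2f mm\n",
              x$kind, x$n, x$mean, x$sd, x$p90))
  invisible(x)
}

#' Monte-Carlo TRE simulation for a single plane
#'
#' Per draw: perturb the plane's landmarks with the noise model, register
#' them to the anatomy (the ground-truth pose being the identity, since
#' landmarks are generated in the pre-procedure frame) and record the TRE on
#' the plane grid and on the target structure.
#'
#' @param plane a [sector_plane()].
#' @param anatomy an [anatomy_model()] (with a target for the surface TRE).
#' @param noise a [noise_model()].
#' @param n_sims number of Monte-Carlo draws (1000 default).
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @param n_starts registration restarts per draw.
#' @param features optionally, precomputed *filtered* features of the plane
#'   (saves re-rasterisation; also used to simulate hypothetical landmark
#'   sets).
#' @param tre_pitch evaluation grid pitch for the plane TRE, mm.
#' @return List with `plane` and `surface` [tre_distribution()]s, the
#'   feature composition (`n_tubes`, `n_organs`) and `n_features`.
#' @export
simulate_plane <- function(plane, anatomy, noise = noise_model(),
                           n_sims = 1000, seed = NULL, n_starts = 10,
                           features = NULL, tre_pitch = 1) {
  if (is.null(features)) {
    features <- filter_features(plane_features(plane, anatomy))
  }
  if (!plane_is_usable(features)) {
    stop("insufficient features: fewer than 3 usable features on this plane")
  }
  if (!is.null(seed)) set.seed(seed)
  grid_pts <- sector_grid_points(plane, tre_pitch)
  target_pts <- if (!is.null(anatomy$target)) anatomy$target$points else NULL
  keys <- vapply(features, function(f) as.character(f$structure_label), character(1))
  uk <- unique(keys)
  clouds <- lapply(uk, function(k) anatomy$structures[[k]]$points)
  cloud_of <- match(keys, uk) - 1L
  lm0 <- t(vapply(features, function(f) f$landmark, numeric(3)))
  sig <- vapply(features, feature_sigma, numeric(1), noise = noise)
  tp <- numeric(n_sims)
  ts <- numeric(n_sims)
  m <- nrow(lm0)
  for (i in seq_len(n_sims)) {
    pts <- lm0 + matrix(rnorm(3 * m, 0, rep(sig, 3)), m, 3)
    fit <- .icp_register_cpp(pts, cloud_of, clouds, as.integer(n_starts), 100L, 1e-4, 3)
    tr <- rigid_transform(fit$rotation, fit$translation)
    tp[i] <- tre_points(grid_pts, tr)
    ts[i] <- if (is.null(target_pts)) NA_real_ else tre_points(target_pts, tr)
  }
  list(plane = tre_distribution(tp, "plane"),
       surface = if (is.null(target_pts)) NULL else tre_distribution(ts, "surface"),
       n_features = m,
       composition = c(n_tubes = sum(vapply(features, function(f) f$kind == "tube", logical(1))),
                       n_organs = sum(vapply(features, function(f) f$kind == "organ", logical(1)))))
}

#' Monte-Carlo TRE simulation for a pair of planes
#'
#' As [simulate_plane()], with landmarks pooled from both planes. On top of
#' the landmark localisation noise, the second plane's landmark set is
#' displaced rigidly per draw by a random tracking-pose error (position SD
#' 0.4 mm; three independent per-axis rotations of SD 0.36 degrees composed
#' about the second plane's apex), reflecting the relative-pose uncertainty
#' of a tracked endoscope. The plane TRE is evaluated over the union of both
#' planes' pixel grids.
#'
#' @param pair list of two usable [sector_plane()]s.
#' @param anatomy an [anatomy_model()].
#' @param noise a [noise_model()].
#' @param n_sims draws (100 default, the per-pair budget).
#' @param seed integer seed.
#' @param n_starts registration restarts per draw.
#' @param features optionally a list of two precomputed filtered feature
#'   lists.
#' @param tre_pitch evaluation grid pitch, mm.
#' @return As [simulate_plane()].
#' @export
simulate_pair <- function(pair, anatomy, noise = noise_model(),
                          n_sims = 100, seed = NULL, n_starts = 10,
                          features = NULL, tre_pitch = 1) {
  stopifnot(length(pair) == 2L)
  if (is.null(features)) {
    features <- lapply(pair, function(p) filter_features(plane_features(p, anatomy)))
  }
  for (k in 1:2) {
    if (!plane_is_usable(features[[k]])) {
      stop("insufficient features: plane ", k, " of the pair has fewer than 3")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  grid_pts <- rbind(sector_grid_points(pair[[1]], tre_pitch),
                    sector_grid_points(pair[[2]], tre_pitch))
  target_pts <- if (!is.null(anatomy$target)) anatomy$target$points else NULL
  all_feat <- c(features[[1]], features[[2]])
  second <- rep(c(FALSE, TRUE), c(length(features[[1]]), length(features[[2]])))
  keys <- vapply(all_feat, function(f) as.character(f$structure_label), character(1))
  uk <- unique(keys)
  clouds <- lapply(uk, function(k) anatomy$structures[[k]]$points)
  cloud_of <- match(keys, uk) - 1L
  lm0 <- t(vapply(all_feat, function(f) f$landmark, numeric(3)))
  sig <- vapply(all_feat, feature_sigma, numeric(1), noise = noise)
  apex2 <- pair[[2]]$apex
  m <- nrow(lm0)
  tp <- numeric(n_sims)
  ts <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    pts <- lm0 + matrix(rnorm(3 * m, 0, rep(sig, 3)), m, 3)
    if (any(second)) {
      ang <- rnorm(3, 0, noise$tracking_sigma_rot_deg)
      Rt <- rot_axis(c(1, 0, 0), ang[1]) %*% rot_axis(c(0, 1, 0), ang[2]) %*%
            rot_axis(c(0, 0, 1), ang[3])
      tt <- rnorm(3, 0, noise$tracking_sigma_pos_mm)
      p2 <- pts[second, , drop = FALSE]
      p2 <- sweep(sweep(p2, 2, apex2, `-`) %*% t(Rt), 2, apex2 + tt, `+`)
      pts[second, ] <- p2
    }
    fit <- .icp_register_cpp(pts, cloud_of, clouds, as.integer(n_starts), 100L, 1e-4, 3)
    tr <- rigid_transform(fit$rotation, fit$translation)
    tp[i] <- tre_points(grid_pts, tr)
    ts[i] <- if (is.null(target_pts)) NA_real_ else tre_points(target_pts, tr)
  }
  list(plane = tre_distribution(tp, "plane"),
       surface = if (is.null(target_pts)) NULL else tre_distribution(ts, "surface"),
       n_features = m,
       composition = c(n_tubes = sum(vapply(all_feat, function(f) f$kind == "tube", logical(1))),
                       n_organs = sum(vapply(all_feat, function(f) f$kind == "organ", logical(1)))))
}

#' Write a TRE distribution to CSV (one row per draw)
#' @param dist a [tre_distribution()].
#' @param path output path.
#' @param id optional identifier column value.
#' @return `path`, invisibly.
#' @export
write_tre_csv <- function(dist, path, id = NA) {
  write.csv(data.frame(id = id, draw = seq_len(dist$n), tre_mm = dist$samples_mm),
            path, row.names = FALSE)
  invisible(path)
}
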
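#' Planning run configuration
#'
#' Collects every tunable of the planning pipeline with defaults matching a
#' standard clinical EUS transducer and the package's simulation settings.
#' Every consumed parameter is persisted in the run manifest, so a run can
#' be reproduced bit-for-bit from it.
#'
#' @param labels `data.frame` (or list of lists) with columns `label`,
#'   `name`, `kind` assigning an anatomical role to each volume label.
#' @param target_label label of the clinical target (surface TRE readout).
#' @param fan_angle_deg,depth_mm,pixel_pitch_mm sector geometry
#'   (see [sector_plane()]).
#' @param grid_range_deg,grid_step_deg rotation grid (see [rotation_grid()]).
#' @param min_area_mm2 feature area filter (see [filter_features()]).
#' @param organ_sigma_mm,tracking_sigma_pos_mm,tracking_sigma_rot_deg noise
#'   model scalars (see [noise_model()]).
#' @param n_sims_single,n_sims_pair Monte-Carlo draws per plane and per pair.
#' @param n_starts registration restarts per draw.
#' @param contact_edge_mm,cloud_edge_mm mesh decimation targets
#'   (see [anatomy_model()]).
#' @param tre_pitch_mm evaluation grid pitch for the plane TRE.
#' @param max_vertices cap on contact vertices examined (NULL = all);
#'   vertices are subsampled evenly when capped.
#' @param pair_budget_factor pairs sampled = factor x number of contact
#'   vertices examined (2 by default).
#' @param reestimate_n fresh draws for the winners' re-estimation.
#' @param simulate_pairs logical; also run the two-plane stage?
#' @return A `run_config` list.
#' @export
run_config <- function(labels, target_label = NULL,
                       fan_angle_deg = 120, depth_mm = 50, pixel_pitch_mm = 0.5,
                       grid_range_deg = 60, grid_step_deg = 30,
                       min_area_mm2 = 5, organ_sigma_mm = 2,
                       tracking_sigma_pos_mm = 0.4, tracking_sigma_rot_deg = 0.36,
                       n_sims_single = 1000, n_sims_pair = 100, n_starts = 10,
                       contact_edge_mm = 5.33, cloud_edge_mm = 2,
                       tre_pitch_mm = 1, max_vertices = NULL,
                       pair_budget_factor = 2, reestimate_n = 1000,
                       simulate_pairs = TRUE) {
  if (is.list(labels) && !is.data.frame(labels)) {
    labels <- do.call(rbind, lapply(labels, as.data.frame))
  }
  cfg <- list(labels = labels, target_label = target_label,
              fan_angle_deg = fan_angle_deg, depth_mm = depth_mm,
              pixel_pitch_mm = pixel_pitch_mm,
              grid_range_deg = grid_range_deg, grid_step_deg = grid_step_deg,
              min_area_mm2 = min_area_mm2, organ_sigma_mm = organ_sigma_mm,
              tracking_sigma_pos_mm = tracking_sigma_pos_mm,
              tracking_sigma_rot_deg = tracking_sigma_rot_deg,
              n_sims_single = n_sims_single, n_sims_pair = n_sims_pair,
              n_starts = n_starts, contact_edge_mm = contact_edge_mm,
              cloud_edge_mm = cloud_edge_mm, tre_pitch_mm = tre_pitch_mm,
              max_vertices = max_vertices,
              pair_budget_factor = pair_budget_factor,
              reestimate_n = reestimate_n, simulate_pairs = simulate_pairs)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  labels <- do.call(rbind, lapply(y$labels, as.data.frame))
  y$labels <- labels
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$labels <- lapply(seq_len(nrow(config$labels)), function(i) {
    as.list(config$labels[i, c("label", "name", "kind")])
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

# evenly subsample n indices down to k (deterministic)
subsample_idx <- function(n, k) {
  if (is.null(k) || k >= n) return(seq_len(n))
  unique(round(seq(1, n, length.out = k)))
}

#' Run the full planning pipeline
#'
#' End-to-end composition: load (or accept) the labelled volume, build the
#' anatomy model, sample candidate sector planes on the contact surface,
#' extract and filter per-plane landmarks, simulate TRE distributions for
#' every usable plane (and Latin-hypercube-sampled plane pairs), rank by
#' 90th-percentile TRE, re-estimate the winners on independent simulations
#' and write the result bundle.
#'
#' @param volume a [labeled_volume()] or a path to a NIfTI file.
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); NULL writes nothing.
#' @param seed integer seed governing all randomness of the run.
#' @return A result bundle (list) with the anatomy model, plane scores,
#'   TRE map, winners and re-estimated statistics; file paths when
#'   `out_dir` is set. Returned invisibly.
#' @export
run_pipeline <- function(volume, config, out_dir = NULL, seed = 1L) {
  t0 <- Sys.time()
  if (is.character(volume)) volume <- read_labeled_volume(volume)
  volume$label_table <- validate_label_table(config$labels, volume$voxels)
  absent <- volume$label_table$absent
  if (any(absent)) {
    stop("config error: label(s) absent from the volume: ",
         paste(sprintf("%s (%d)", volume$label_table$name[absent],
                       volume$label_table$label[absent]), collapse = ", "))
  }
  set.seed(seed)
  noise <- noise_model(config$organ_sigma_mm,
                       tracking_sigma_pos_mm = config$tracking_sigma_pos_mm,
                       tracking_sigma_rot_deg = config$tracking_sigma_rot_deg)
  anatomy <- anatomy_model(volume, target_label = config$target_label,
                           contact_edge_mm = config$contact_edge_mm,
                           cloud_edge_mm = config$cloud_edge_mm)
  grid <- rotation_grid(config$grid_range_deg, config$grid_step_deg)
  log_stage <- function(fmt, ...) {
    message(sprintf("[eusplan %6.1fs] ", as.numeric(Sys.time() - t0, units = "secs")),
            sprintf(fmt, ...))
  }
  log_stage("anatomy model: %d structures, %d contact surface(s)",
            length(anatomy$structures), length(anatomy$contact_surfaces))

  # candidate planes on the contact surface
  contact <- anatomy$contact_surfaces[[1]]
  if (length(anatomy$contact_surfaces) > 1) {
    warning("multiple contact surfaces supplied; the TRE map covers the first")
  }
  normals <- attr(contact, "normals")
  vids <- subsample_idx(nrow(contact$points), config$max_vertices)
  usable <- list()
  for (vi in vids) {
    planes <- sample_planes_at_vertex(contact$points[vi, ], normals[vi, ],
                                      grid = grid,
                                      fan_angle = config$fan_angle_deg,
                                      depth = config$depth_mm,
                                      pixel_pitch = config$pixel_pitch_mm,
                                      vertex_id = vi)
    for (p in planes) {
      fts <- filter_features(plane_features(p, anatomy), config$min_area_mm2)
      if (plane_is_usable(fts)) usable[[length(usable) + 1L]] <- list(plane = p, features = fts)
    }
  }
  log_stage("plane sampling: %d vertices, %d usable planes", length(vids), length(usable))
  if (!length(usable)) stop("no usable planes: no plane sees 3 or more features")

  sims <- lapply(usable, function(u) {
    simulate_plane(u$plane, anatomy, noise, n_sims = config$n_sims_single,
                   n_starts = config$n_starts, features = u$features,
                   tre_pitch = config$tre_pitch_mm)
  })
  scores <- plane_scores(seq_along(usable), sims,
                         vertex_ids = vapply(usable, function(u) u$plane$vertex_id,
                                             numeric(1)))
  tre_map <- build_tre_map(contact, scores)
  best <- select_optimal(scores, 1L)
  best_plane <- usable[[best$plane_id]]$plane
  log_stage("single-plane stage: best p90 %.2f mm (plane %d, vertex %d)",
            best$p90_mm, best$plane_id, best$vertex_id)

  pair_out <- NULL
  if (isTRUE(config$simulate_pairs) && length(usable) >= 2) {
    n_pairs <- max(1L, round(config$pair_budget_factor * length(vids)))
    pairs <- sample_pairs_lhs(seq_along(usable), n_pairs)
    pair_sims <- lapply(seq_len(nrow(pairs)), function(i) {
      simulate_pair(list(usable[[pairs[i, 1]]]$plane, usable[[pairs[i, 2]]]$plane),
                    anatomy, noise, n_sims = config$n_sims_pair,
                    n_starts = config$n_starts,
                    features = list(usable[[pairs[i, 1]]]$features,
                                    usable[[pairs[i, 2]]]$features),
                    tre_pitch = config$tre_pitch_mm)
    })
    pair_scores <- plane_scores(seq_len(nrow(pairs)), pair_sims)
    pair_scores$first <- pairs[, 1]
    pair_scores$second <- pairs[, 2]
    best_pair_row <- select_optimal(pair_scores, 1L)
    pair_out <- list(pairs = pairs, scores = pair_scores, best = best_pair_row)
    log_stage("two-plane stage: %d pairs, best p90 %.2f mm", nrow(pairs),
              best_pair_row$p90_mm)
  }

  # unbiased re-estimation of the winners on an independent seed
  fresh_seed <- (seed + 1000003L) %% .Machine$integer.max
  re_single <- reestimate(best_plane, anatomy, noise, n = config$reestimate_n,
                          fresh_seed = fresh_seed, opt_seed = seed,
                          n_starts = config$n_starts,
                          features = usable[[best$plane_id]]$features,
                          tre_pitch = config$tre_pitch_mm)
  re_pair <- NULL
  if (!is.null(pair_out)) {
    bp <- pair_out$best
    re_pair <- reestimate(list(usable[[bp$first]]$plane, usable[[bp$second]]$plane),
                          anatomy, noise, n = config$reestimate_n,
                          fresh_seed = fresh_seed + 1L, opt_seed = seed,
                          n_starts = config$n_starts,
                          features = list(usable[[bp$first]]$features,
                                          usable[[bp$second]]$features),
                          tre_pitch = config$tre_pitch_mm)
  }
  log_stage("re-estimation: single p90 %.2f mm%s", re_single$plane$p90,
            if (!is.null(re_pair)) sprintf(", pair p90 %.2f mm", re_pair$plane$p90) else "")

  bundle <- list(anatomy = anatomy, usable = usable, scores = scores,
                 tre_map = tre_map, best_single = best, best_plane = best_plane,
                 pairs = pair_out, reestimated_single = re_single,
                 reestimated_pair = re_pair,
                 manifest = list(config = unclass(config), seed = seed,
                                 fresh_seed = fresh_seed,
                                 n_vertices = length(vids),
                                 package_version = as.character(utils::packageVersion("eusplan"))))
  if (!is.null(out_dir)) bundle$files <- write_bundle(bundle, out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  anatomy <- bundle$anatomy
  for (key in names(anatomy$structures)) {
    s <- anatomy$structures[[key]]
    f <- file.path(out_dir, sprintf("structure_%s_%s.%s", key, s$name,
                                    if (s$kind == "organ") "ply" else "csv"))
    if (s$kind == "organ") write_ply(s, f) else write_centreline_csv(s, f)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "planes_usable.json")
  write_planes_json(lapply(bundle$usable, `[[`, "plane"), f)
  files <- c(files, f)
  f <- file.path(out_dir, "ranking_single.csv")
  write.csv(bundle$scores[order(bundle$scores$p90_mm, bundle$scores$mean_mm,
                                bundle$scores$plane_id), ],
            f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(bundle$pairs)) {
    f <- file.path(out_dir, "ranking_pairs.csv")
    ps <- bundle$pairs$scores
    write.csv(ps[order(ps$p90_mm, ps$mean_mm, ps$plane_id), ], f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "tre_map.ply")
  write_tre_map_ply(bundle$tre_map, f)
  files <- c(files, f)
  f <- file.path(out_dir, "best_single_tre.csv")
  write_tre_csv(bundle$reestimated_single$plane, f, id = bundle$best_single$plane_id)
  files <- c(files, f)
  if (!is.null(bundle$reestimated_pair)) {
    f <- file.path(out_dir, "best_pair_tre.csv")
    write_tre_csv(bundle$reestimated_pair$plane, f)
    files <- c(files, f)
  }
  summary <- list(
    best_single = as.list(bundle$best_single),
    reestimated_single = list(mean_mm = bundle$reestimated_single$plane$mean,
                              sd_mm = bundle$reestimated_single$plane$sd,
                              p90_mm = bundle$reestimated_single$plane$p90,
                              n = bundle$reestimated_single$plane$n),
    best_pair = if (!is.null(bundle$pairs)) as.list(bundle$pairs$best) else NULL,
    reestimated_pair = if (!is.null(bundle$reestimated_pair))
      list(mean_mm = bundle$reestimated_pair$plane$mean,
           sd_mm = bundle$reestimated_pair$plane$sd,
           p90_mm = bundle$reestimated_pair$plane$p90,
           n = bundle$reestimated_pair$plane$n) else NULL
  )
  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, f)
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, f)
  files
}

#' Re-run a pipeline from a persisted manifest
#'
#' Reads the manifest written by [run_pipeline()] and repeats the run with
#' the identical configuration and seed, regenerating every output file
#' identically.
#'
#' @param manifest_path path to `manifest.json`.
#' @param volume the input volume ([labeled_volume()] or NIfTI path).
#' @param out_dir output directory.
#' @return The result bundle, invisibly.
#' @export
run_from_manifest <- function(manifest_path, volume, out_dir = NULL) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- m$config
  cfg$labels <- as.data.frame(cfg$labels)
  if (!is.null(cfg$max_vertices) && length(cfg$max_vertices) == 0) cfg$max_vertices <- NULL
  config <- do.call(run_config, cfg)
  run_pipeline(volume, config, out_dir = out_dir, seed = m$seed)
}

#' Default run configuration for the reference phantom
#'
#' Convenience wrapper binding the [reference_phantom()] label roles to a
#' [run_config()]; extra arguments override the defaults.
#'
#' @param ... overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
reference_config <- function(...) {
  spec <- reference_phantom()
  args <- list(labels = phantom_label_table(spec), target_label = spec$target_label)
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}
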
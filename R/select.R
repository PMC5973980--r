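#' Nearest-rank 90th percentile
#'
#' The sorted sample at index `ceiling(0.9 * n)`: the estimated upper bound
#' of the nonparametric 90% prediction interval, i.e. the TRE that will be
#' met or bettered with 90% probability.
#'
#' @param samples numeric vector (n >= 1).
#' @param p percentile in (0, 1]; 0.9 by default.
#' @return The nearest-rank percentile value.
#' @export
percentile_90 <- function(samples, p = 0.9) {
  n <- length(samples)
  if (n < 1L) stop("empty sample")
  sort(samples)[max(1L, ceiling(p * n))]
}

#' Score table for simulated planes
#'
#' Builds one row per simulated plane/pair with the selection statistics.
#'
#' @param ids vector of plane (or pair) identifiers.
#' @param sims list of [simulate_plane()]/[simulate_pair()] results, same
#'   order.
#' @param vertex_ids optional vector of apex vertex ids.
#' @return `data.frame` with columns `plane_id`, `vertex_id`, `p90_mm`,
#'   `mean_mm`, `sd_mm`, `n_sims`, `n_tubes`, `n_organs`.
#' @export
plane_scores <- function(ids, sims, vertex_ids = NA_integer_) {
  data.frame(
    plane_id = ids,
    vertex_id = rep_len(vertex_ids, length(sims)),
    p90_mm = vapply(sims, function(s) s$plane$p90, numeric(1)),
    mean_mm = vapply(sims, function(s) s$plane$mean, numeric(1)),
    sd_mm = vapply(sims, function(s) s$plane$sd, numeric(1)),
    n_sims = vapply(sims, function(s) s$plane$n, numeric(1)),
    n_tubes = vapply(sims, function(s) unname(s$composition["n_tubes"]), numeric(1)),
    n_organs = vapply(sims, function(s) unname(s$composition["n_organs"]), numeric(1))
  )
}

#' Select the optimal plane(s) by 90th-percentile TRE
#'
#' Ascending by `p90_mm`; ties broken by lower mean, then lower id.
#'
#' @param scores a [plane_scores()] data frame.
#' @param k how many top rows to return.
#' @return The top-`k` rows (fewer if `k` exceeds the table).
#' @export
select_optimal <- function(scores, k = 1L) {
  if (nrow(scores) < 1L) stop("no scores to select from")
  ord <- order(scores$p90_mm, scores$mean_mm, scores$plane_id)
  scores[head(ord, k), , drop = FALSE]
}

#' Latin-hypercube sample of plane pairs
#'
#' Draws `n_pairs` pairs from the (plane index x plane index) domain with a
#' 2D Latin hypercube: each of the `n_pairs` equal index strata of each
#' dimension is sampled exactly once before self-pairs and unordered
#' duplicates are removed, giving uniform coverage of the pair space at a
#' fraction of the quadratic cost.
#'
#' @param usable_ids vector (length >= 2) of usable plane identifiers.
#' @param n_pairs number of pairs to draw.
#' @param seed optional integer seed.
#' @return Two-column matrix of plane ids (one row per pair, first != second).
#' @export
sample_pairs_lhs <- function(usable_ids, n_pairs, seed = NULL) {
  n <- length(usable_ids)
  if (n < 2L) stop("at least 2 usable planes are required to sample pairs")
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n_pairs, 2)
  idx <- matrix(pmin(pmax(ceiling(u * n), 1), n), ncol = 2)
  keep <- idx[, 1] != idx[, 2]
  idx <- idx[keep, , drop = FALSE]
  key <- paste(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2]))
  idx <- idx[!duplicated(key), , drop = FALSE]
  cbind(first = usable_ids[idx[, 1]], second = usable_ids[idx[, 2]])
}

#' Re-estimate a selected plane or pair on independent simulations
#'
#' The optimisation-time p90 of the winner is biased low (winner's curse);
#' reported statistics are therefore recomputed from a fresh set of
#' simulations (1000 by default) whose seed must differ from the
#' optimisation seed.
#'
#' @param plane a [sector_plane()] or a list of two (a pair).
#' @param anatomy an [anatomy_model()].
#' @param noise a [noise_model()].
#' @param n number of fresh draws.
#' @param fresh_seed integer seed for the fresh simulations.
#' @param opt_seed the seed used during optimisation; a collision is refused.
#' @param ... passed on to [simulate_plane()] / [simulate_pair()].
#' @return The simulation result (see [simulate_plane()]).
#' @export
reestimate <- function(plane, anatomy, noise = noise_model(), n = 1000,
                       fresh_seed, opt_seed = NULL, ...) {
  if (!is.null(opt_seed) && identical(as.integer(fresh_seed), as.integer(opt_seed))) {
    stop("refused: re-estimation seed collides with the optimisation seed")
  }
  if (inherits(plane, "sector_plane")) {
    simulate_plane(plane, anatomy, noise, n_sims = n, seed = fresh_seed, ...)
  } else {
    simulate_pair(plane, anatomy, noise, n_sims = n, seed = fresh_seed, ...)
  }
}

#' Per-vertex TRE map over the contact surface
#'
#' Reduces plane scores to their apex vertices: each vertex carries the
#' minimum p90 over its planes (the value relevant for planning, i.e. the
#' best achievable at that transducer position); vertices where fewer than
#' three features were identifiable on every plane are flagged unusable and
#' carry no value.
#'
#' @param contact an organ [eus_structure()] (the contact-surface mesh).
#' @param scores a [plane_scores()] data frame with `vertex_id` filled in.
#' @return Object of class `tre_map`: the mesh, per-vertex `value` (NA where
#'   unusable) and logical `usable`.
#' @export
build_tre_map <- function(contact, scores) {
  nv <- nrow(contact$points)
  value <- rep(NA_real_, nv)
  ok <- !is.na(scores$vertex_id)
  if (any(ok)) {
    agg <- tapply(scores$p90_mm[ok], scores$vertex_id[ok], min)
    vid <- as.integer(names(agg))
    value[vid[vid >= 1 & vid <= nv]] <- agg[vid >= 1 & vid <= nv]
  }
  structure(list(mesh = contact, value = value, usable = !is.na(value)),
            class = "tre_map")
}

#' @export
print.tre_map <- function(x, ...) {
  cat(sprintf("<tre_map> %d vertices, %d usable; best p90 %.2f mm\n",
              length(x$value), sum(x$usable),
              if (any(x$usable)) min(x$value, na.rm = TRUE) else NA))
  invisible(x)
}

#' Export a TRE map as PLY with a per-vertex scalar
#'
#' Unusable vertices are written with quality -1 so standard mesh viewers
#' can display them as a distinct (white) region.
#'
#' @param map a [build_tre_map()] result.
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_tre_map_ply <- function(map, path) {
  write_ply(map$mesh, path, scalar = map$value)
}
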
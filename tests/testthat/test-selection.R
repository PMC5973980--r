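test_that("nearest-rank 90th percentile follows the definition", {
  expect_equal(percentile_90(1:10), 9)
  expect_equal(percentile_90(rep(4.2, 17)), 4.2)
  expect_equal(percentile_90(c(5)), 5)
  expect_error(percentile_90(numeric(0)), "empty")
  x <- rexp(37)
  expect_equal(percentile_90(x), sort(x)[ceiling(0.9 * 37)])
  expect_true(percentile_90(x) >= min(x) && percentile_90(x) <= max(x))
})

test_that("the p90 of a large exponential sample matches the analytic quantile", {
  set.seed(1)
  x <- rexp(1e5, rate = 1)
  expect_lt(abs(percentile_90(x) - log(10)) / log(10), 0.01)
})

test_that("optimal selection sorts by p90 with documented tie-breaks", {
  sc <- data.frame(plane_id = 1:3, p90_mm = c(12, 8, 15),
                   mean_mm = c(5, 6, 7), sd_mm = 1, n_sims = 10,
                   n_tubes = 2, n_organs = 1, vertex_id = 1)
  expect_equal(select_optimal(sc, 1)$plane_id, 2)
  tie <- data.frame(plane_id = c(1, 2), p90_mm = c(10, 10),
                    mean_mm = c(7, 5), sd_mm = 1, n_sims = 10,
                    n_tubes = 2, n_organs = 1, vertex_id = 1)
  expect_equal(select_optimal(tie, 1)$plane_id, 2)
  expect_equal(nrow(select_optimal(sc, 10)), 3)
  expect_equal(select_optimal(sc, 10)$p90_mm, c(8, 12, 15))
  # never returns a plane worse than an excluded one
  top2 <- select_optimal(sc, 2)
  expect_lte(max(top2$p90_mm), min(sc$p90_mm[!sc$plane_id %in% top2$plane_id]))
})

test_that("Latin hypercube pair sampling stratifies both index dimensions", {
  pairs <- sample_pairs_lhs(1:100, 4, seed = 10)
  stratum <- function(i) ceiling(i / 25)
  expect_setequal(stratum(pairs[, 1]), 1:4)
  expect_setequal(stratum(pairs[, 2]), 1:4)
  expect_true(all(pairs[, 1] != pairs[, 2]))
  one <- sample_pairs_lhs(1:10, 1, seed = 2)
  expect_equal(nrow(one), 1)
  expect_true(one[1, 1] != one[1, 2])
  again <- sample_pairs_lhs(1:100, 4, seed = 10)
  expect_identical(pairs, again)
  expect_error(sample_pairs_lhs(1L, 3), "at least 2")
})

test_that("re-estimation refuses seed collisions and is reproducible", {
  an <- ref_anatomy()
  u <- ref_good_plane()
  expect_error(reestimate(u$plane, an, n = 10, fresh_seed = 5, opt_seed = 5),
               "refused")
  r1 <- reestimate(u$plane, an, n = 15, fresh_seed = 6, opt_seed = 5,
                   n_starts = 5, features = u$features)
  r2 <- reestimate(u$plane, an, n = 15, fresh_seed = 6, opt_seed = 5,
                   n_starts = 5, features = u$features)
  expect_identical(r1$plane$samples_mm, r2$plane$samples_mm)
  expect_equal(r1$plane$n, 15)
})

test_that("the TRE map keeps the per-vertex minimum and flags unusable vertices", {
  contact <- ref_anatomy()$contact_surfaces[[1]]
  sc <- data.frame(plane_id = 1:5, vertex_id = c(3, 3, 3, 7, 7),
                   p90_mm = c(11, 9, 20, 14, 13), mean_mm = 1, sd_mm = 1,
                   n_sims = 10, n_tubes = 2, n_organs = 1)
  map <- build_tre_map(contact, sc)
  expect_equal(map$value[3], 9)
  expect_equal(map$value[7], 13)
  expect_true(all(is.na(map$value[-c(3, 7)])))
  expect_equal(sum(map$usable), 2)
  f <- withr::local_tempfile(fileext = ".ply")
  write_tre_map_ply(map, f)
  lines <- readLines(f)
  expect_true(any(grepl("property float quality", lines)))
})

test_that("map values are lower where the transducer faces the anatomy", {
  # contact sphere with all structures on one side: vertices facing them get
  # usable planes and finite p90; vertices facing away stay unusable
  spec <- phantom_spec(
    shape = c(135L, 100L, 80L), spacing = c(1, 1, 1),
    organs = list(
      list(label = 1L, name = "contact", center = c(30, 50, 40),
           radii = c(18, 18, 18), shell_thickness = 5),
      list(label = 2L, name = "organ_a", center = c(90, 52, 42),
           radii = c(14, 12, 11)),
      list(label = 3L, name = "organ_b", center = c(85, 30, 38),
           radii = c(10, 8, 9))
    ),
    tubes = list(
      list(label = 4L, name = "vessel_a", radius = 3,
           path = rbind(c(78, 60, 10), c(80, 64, 70))),
      list(label = 5L, name = "vessel_b", radius = 4,
           path = rbind(c(98, 40, 10), c(100, 44, 70)))
    ),
    contact_label = 1L, target_label = 2L
  )
  ph <- generate_phantom(spec)
  an <- anatomy_model(ph$volume, target_label = 2L)
  ct <- an$contact_surfaces[[1]]
  nrm <- attr(ct, "normals")
  # beam direction is the inward normal: "towards" = inner-wall vertices whose
  # beam points at the anatomy (+x); "away" = the far (-x) side of the shell,
  # from which every structure lies beyond the 50 mm scanning depth
  inward_x <- -nrm[, 1]
  towards <- head(which(inward_x > 0.8 & ct$points[, 1] > 35), 2)
  away <- head(which(ct$points[, 1] < 25), 2)
  scores <- NULL
  for (vi in c(towards, away)) {
    planes <- sample_planes_at_vertex(ct$points[vi, ], nrm[vi, ],
                                      rotation_grid(60, 60), vertex_id = vi)
    for (p in planes) {
      fts <- filter_features(plane_features(p, an))
      if (plane_is_usable(fts)) {
        sim <- simulate_plane(p, an, n_sims = 10, seed = vi, n_starts = 5,
                              features = fts)
        scores <- rbind(scores, plane_scores(vi, list(sim), vertex_ids = vi))
      }
    }
  }
  map <- build_tre_map(ct, scores)
  expect_true(all(map$usable[towards]))
  expect_true(all(!map$usable[away]))
  expect_true(all(is.finite(map$value[towards])))
})
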
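test_that("the vessel noise rule follows the bounding-box formula", {
  nm <- noise_model()
  f <- fake_feature(30, kind = "tube", w = 6, h = 6)
  expect_equal(eusplan:::feature_sigma(f, nm), 1)  # (6 + 6) / 12
  f2 <- fake_feature(30, kind = "tube", w = 10, h = 2)
  expect_equal(eusplan:::feature_sigma(f2, nm), 1)
  forg <- fake_feature(30, kind = "organ")
  expect_equal(eusplan:::feature_sigma(forg, nm), 2)
})

test_that("zero noise leaves landmarks untouched", {
  nm <- noise_model(organ_sigma_mm = 0, tube_sigma_rule = function(w, h) 0)
  fts <- list(fake_feature(10, landmark = c(1, 2, 3)),
              fake_feature(10, kind = "organ", landmark = c(4, 5, 6)))
  lm <- perturb_landmarks(fts, nm, seed = 1)
  expect_equal(lm$points, rbind(c(1, 2, 3), c(4, 5, 6)), ignore_attr = TRUE)
})

test_that("empirical perturbation SD matches the configured sigma per axis", {
  fts <- replicate(5, fake_feature(10, kind = "organ", landmark = c(0, 0, 0)),
                   simplify = FALSE)
  set.seed(123)
  draws <- vapply(seq_len(2e4), function(i) {
    perturb_landmarks(fts, noise_model())$points
  }, matrix(0, 5, 3))
  offsets <- matrix(aperm(draws, c(3, 1, 2)), ncol = 3)  # 1e5 x 3
  expect_equal(nrow(offsets), 1e5)
  sds <- apply(offsets, 2, sd)
  expect_true(all(abs(sds - 2) / 2 < 0.05))
  expect_lt(max(abs(colMeans(offsets))), 0.05)
})

test_that("plane and surface TREs are exact for pure translations", {
  p <- sector_plane(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  tr <- rigid_transform(diag(3), c(2, -2, 1))
  expect_equal(tre_plane(p, rigid_transform()), 0)
  expect_equal(tre_plane(p, tr), 3, tolerance = 1e-12)
  target <- ref_anatomy()$target
  expect_equal(tre_surface(target, rigid_transform()), 0)
  expect_equal(tre_surface(target, tr), 3, tolerance = 1e-12)
})

test_that("rotational TREs match per-point brute force and closed form", {
  p <- sector_plane(c(10, -5, 30), c(0, 1, 0), c(0, 0, 1))
  R <- rot_z(5)
  apex_t <- c(10, -5, 30) - drop(R %*% c(10, -5, 30))
  tr <- rigid_transform(R, apex_t)  # 5 degree rotation about the apex
  # brute force: explicit loop over the same evaluation grid
  pts <- eusplan:::sector_grid_points(p, 1)
  d2 <- vapply(seq_len(nrow(pts)), function(i) {
    sum((drop(R %*% pts[i, ]) + apex_t - pts[i, ])^2)
  }, numeric(1))
  expect_equal(tre_plane(p, tr), sqrt(mean(d2)), tolerance = 1e-9)
  # closed form for rotation about the target centroid: r_i * 2 sin(theta/2)
  target <- ref_anatomy()$target
  ctr <- colMeans(target$points)
  trc <- rigid_transform(R, ctr - drop(R %*% ctr))
  rad <- sqrt(rowSums(sweep(target$points, 2, ctr, `-`)[, 1:2]^2))  # z-rotation
  expected <- sqrt(mean((rad * 2 * sin(2.5 * pi / 180))^2))
  expect_equal(tre_surface(target, trc), expected, tolerance = 1e-9)
})

test_that("TREs are invariant under a global rigid change of world frame", {
  # moving the whole world by G and conjugating the registration transform
  # (T' = G T G^-1) must leave both TRE metrics unchanged
  an <- ref_anatomy()
  u <- ref_good_plane()
  set.seed(4)
  G_R <- random_rotation(70)
  G_t <- c(25, -10, 8)
  for (rep in 1:5) {
    T_R <- random_rotation(6)
    T_t <- rnorm(3, sd = 3)
    tr <- rigid_transform(T_R, T_t)
    tre1 <- tre_plane(u$plane, tr)
    tre1s <- tre_surface(an$target, tr)
    p2 <- sector_plane(drop(G_R %*% u$plane$apex) + G_t,
                       drop(G_R %*% u$plane$axis), drop(G_R %*% u$plane$normal))
    target2 <- an$target
    target2$points <- sweep(an$target$points %*% t(G_R), 2, G_t, `+`)
    R2 <- G_R %*% T_R %*% t(G_R)
    t2 <- drop(G_R %*% T_t) + G_t - drop(R2 %*% G_t)
    tr2 <- rigid_transform(R2, t2)
    expect_equal(tre_plane(p2, tr2), tre1, tolerance = 1e-9)
    expect_equal(tre_surface(target2, tr2), tre1s, tolerance = 1e-9)
  }
})

test_that("simulations are deterministic given a seed and refuse unusable planes", {
  an <- ref_anatomy()
  u <- ref_good_plane()
  r1 <- simulate_plane(u$plane, an, n_sims = 20, seed = 6, n_starts = 5,
                       features = u$features)
  r2 <- simulate_plane(u$plane, an, n_sims = 20, seed = 6, n_starts = 5,
                       features = u$features)
  expect_identical(r1$plane$samples_mm, r2$plane$samples_mm)
  expect_identical(r1$surface$samples_mm, r2$surface$samples_mm)
  expect_true(all(is.finite(r1$plane$samples_mm)))
  expect_error(simulate_plane(u$plane, an, features = u$features[1:2]),
               "insufficient features")
  expect_error(simulate_pair(list(u$plane, u$plane), an,
                             features = list(u$features, u$features[1:2])),
               "insufficient features")
})

test_that("the noiseless limit recovers the ground truth pose", {
  # with landmarks placed exactly on the structure clouds and zero noise the
  # global optimum is the identity, so every draw's TRE must vanish
  an <- ref_anatomy()
  u <- ref_good_plane()
  snapped <- lapply(u$features, function(f) {
    f$landmark <- closest_point(f$landmark, an$structures[[as.character(f$structure_label)]])$point
    f
  })
  nm <- noise_model(organ_sigma_mm = 0, tube_sigma_rule = function(w, h) 0)
  res <- simulate_plane(u$plane, an, noise = nm, n_sims = 5, seed = 2,
                        n_starts = 30, features = snapped)
  expect_lt(max(res$plane$samples_mm), 0.1)
})

test_that("TRE distributions are non-degenerate and grow with noise", {
  an <- ref_anatomy()
  u <- ref_good_plane()
  res1 <- simulate_plane(u$plane, an, n_sims = 120, seed = 14, n_starts = 5,
                         features = u$features)
  expect_gt(res1$plane$sd, 0)
  nm2 <- noise_model(organ_sigma_mm = 4, tube_sigma_rule = function(w, h) (w + h) / 6)
  res2 <- simulate_plane(u$plane, an, noise = nm2, n_sims = 120, seed = 15,
                         n_starts = 5, features = u$features)
  # doubling all sigmas must not reduce the mean TRE
  tt <- wilcox.test(res2$plane$samples_mm, res1$plane$samples_mm,
                    alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("a self-pair with zero tracking noise matches doubled landmarks", {
  an <- ref_anatomy()
  u <- ref_good_plane()
  nm0 <- noise_model(tracking_sigma_pos_mm = 0, tracking_sigma_rot_deg = 0)
  pair <- simulate_pair(list(u$plane, u$plane), an, noise = nm0, n_sims = 300,
                        seed = 41, n_starts = 5,
                        features = list(u$features, u$features))
  doubled <- simulate_plane(u$plane, an, n_sims = 300, seed = 42, n_starts = 5,
                            features = c(u$features, u$features))
  ks <- suppressWarnings(ks.test(pair$plane$samples_mm, doubled$plane$samples_mm))
  expect_gt(ks$p.value, 0.01)
})

test_that("pair simulations honour the tracking noise defaults and budget", {
  nm <- noise_model()
  expect_equal(nm$tracking_sigma_pos_mm, 0.4)
  expect_equal(nm$tracking_sigma_rot_deg, 0.36)
  expect_equal(formals(simulate_pair)$n_sims, 100)
  expect_equal(formals(simulate_plane)$n_sims, 1000)
  an <- ref_anatomy()
  u <- ref_good_plane()
  res <- simulate_pair(list(u$plane, u$plane), an, n_sims = 25, seed = 9,
                       n_starts = 5, features = list(u$features, u$features))
  expect_equal(res$plane$n, 25)
})

test_that("TRE csv export writes one row per draw", {
  d <- tre_distribution(c(1, 2, 3), "plane")
  f <- withr::local_tempfile(fileext = ".csv")
  write_tre_csv(d, f, id = 7)
  df <- read.csv(f)
  expect_equal(nrow(df), 3)
  expect_equal(df$tre_mm, c(1, 2, 3))
})
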
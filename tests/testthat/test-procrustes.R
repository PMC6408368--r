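test_that("centroid size has its closed form and scaling behaviour", {
  # four corners each sqrt(0.5) from the centroid: CS = sqrt(4 * 0.5)
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(square), sqrt(2))
  set.seed(20)
  cfg <- rand_config(10)
  expect_equal(centroid_size(cfg * 3.7), 3.7 * centroid_size(cfg))
  # brute-force formula
  ctr <- colMeans(cfg)
  expect_equal(centroid_size(cfg),
               sqrt(sum(apply(cfg, 1, function(p) sum((p - ctr)^2)))),
               tolerance = 1e-12)
  expect_error(centroid_size(rbind(c(1, 1), c(1, 1))), "degenerate")
})

test_that("optimal 2D rotation recovers known angles and beats a fine grid", {
  set.seed(21)
  src <- scale(rand_config(7), scale = FALSE)
  expect_equal(optimal_rotation_2d(src, src)$theta, 0)
  expect_equal(optimal_rotation_2d(src, src)$rss, 0)

  rot30 <- locomorph:::rotate2d(src, pi / 6)
  got <- optimal_rotation_2d(src, rot30)
  expect_equal(got$theta, pi / 6, tolerance = 1e-9)
  expect_lt(got$rss, 1e-18)

  tgt <- scale(rand_config(7), scale = FALSE)
  got <- optimal_rotation_2d(src, tgt)
  grid <- seq(-pi, pi, by = 0.01 * pi / 180)
  rss_grid <- vapply(grid, function(a) sum((locomorph:::rotate2d(src, a) - tgt)^2),
                     numeric(1))
  expect_lte(got$rss, min(rss_grid) + 1e-9)
  expect_equal(got$theta, grid[which.min(rss_grid)], tolerance = 0.02 * pi / 180)

  expect_error(optimal_rotation_2d(src, tgt[-1, ]), "same landmark count")
})

test_that("GPA collapses the similarity orbit of a single shape", {
  set.seed(22)
  base <- rand_config(9)
  shapes <- lapply(1:10, function(i) rand_similarity(base))
  al <- gpa(shapes, tol = 1e-12)
  expect_true(al$converged)
  for (i in 1:10) {
    expect_lt(max(abs(al$coords[, , i] - al$mean_shape)), 1e-9)
  }
  ref <- locomorph:::center_config(base)
  ref <- ref / sqrt(sum(ref^2))
  expect_lt(procrustes_distance(al$mean_shape, ref), 1e-9)
})

test_that("GPA output satisfies the aligned-dataset invariants", {
  sim <- small_sim(seed = 23L)
  al <- gpa(sim$shapes, sliders = sim$sliders)
  n <- dim(al$coords)[3]
  for (i in seq_len(n)) {
    expect_lt(sqrt(sum(colMeans(al$coords[, , i])^2)), 1e-9)   # centred
    expect_lt(abs(sqrt(sum(al$coords[, , i]^2)) - 1), 1e-9)    # unit CS
  }
  expect_lt(abs(sqrt(sum(al$mean_shape^2)) - 1), 1e-9)
  expect_true(al$converged)
  expect_gt(al$centroid_sizes[1], 0)
})

test_that("for two shapes the GPA mean is equidistant from both", {
  set.seed(24)
  a <- rand_config(5); b <- rand_config(5)
  al <- gpa(list(a, b), tol = 1e-12)
  da <- procrustes_distance(al$mean_shape, a)
  db <- procrustes_distance(al$mean_shape, b)
  expect_equal(da, db, tolerance = 1e-8)
})

test_that("GPA is invariant to similarity transforms and input order", {
  set.seed(25)
  shapes <- lapply(1:6, function(i) rand_config(8))
  al1 <- gpa(shapes, tol = 1e-12)
  # transform one input arbitrarily
  shapes2 <- shapes
  shapes2[[3]] <- rand_similarity(shapes2[[3]])
  al2 <- gpa(shapes2, tol = 1e-12)
  expect_lt(procrustes_distance(al1$mean_shape, al2$mean_shape), 1e-8)
  for (i in 1:6) {
    expect_lt(procrustes_distance(al1$coords[, , i], al2$coords[, , i]), 1e-8)
  }
  # permute input order: same mean shape
  perm <- c(4, 1, 6, 2, 5, 3)
  al3 <- gpa(shapes[perm], tol = 1e-12)
  expect_lt(procrustes_distance(al1$mean_shape, al3$mean_shape), 1e-8)
})

test_that("objective trace is non-increasing for plain and distance-slid GPA", {
  for (seed in 1:5) {
    set.seed(seed)
    shapes <- lapply(1:7, function(i) rand_config(10) + rand_config(10) * 0.05)
    al <- gpa(shapes, max_iter = 1000L)
    expect_true(all(diff(al$objective_trace) <= 1e-10))
  }
  sim <- small_sim(seed = 26L)
  al <- gpa(sim$shapes, sliders = sim$sliders, criterion = "procrustes_distance")
  expect_true(all(diff(al$objective_trace) <= 1e-10))
})

test_that("GPA matches an independently coded classical GPA to 1e-9", {
  set.seed(27)
  mats <- lapply(1:5, function(i) rand_config(6))
  al <- gpa(mats, tol = 1e-13, max_iter = 1000L)
  oracle <- gpa_complex_oracle(mats, tol = 1e-13)
  # remove the arbitrary global rotation before comparing
  rot <- optimal_rotation_2d(oracle$mean, al$mean_shape)
  expect_lt(sqrt(rot$rss), 1e-9)
  for (i in 1:5) {
    expect_lt(max(abs(locomorph:::rotate2d(oracle$aligned[[i]], rot$theta) -
                        al$coords[, , i])), 1e-9)
  }
})

test_that("sliding leaves optima and fixed landmarks untouched", {
  set.seed(28)
  t <- seq(0, pi, length.out = 9)
  ref <- cbind(cos(t) + 0.1 * sin(3 * t), 0.7 * sin(t))
  ref <- locomorph:::center_config(ref); ref <- ref / sqrt(sum(ref^2))
  sliders <- slider_table(1:7, 2:8, 3:9, n_landmarks = 9L)
  # configs identical to the reference: nothing moves, under both criteria
  arr <- array(ref, c(9, 2, 2))
  for (crit in c("bending_energy", "procrustes_distance")) {
    out <- slide_semilandmarks(arr, ref, sliders, crit)
    expect_lt(max(abs(out - arr)), 1e-9)
  }
  # perturbed config: landmarks 1 and 9 (non-sliders) never move
  cfg <- ref + matrix(rnorm(18, 0, 0.01), 9)
  out <- slide_semilandmarks(array(cfg, c(9, 2, 1)), ref, sliders, "bending_energy")
  expect_equal(out[c(1, 9), , 1], cfg[c(1, 9), ])
})

test_that("single-semilandmark sliding matches a dense 1-D grid search", {
  set.seed(29)
  t <- seq(0, pi, length.out = 7)
  ref <- cbind(cos(t), 0.6 * sin(t) + 0.1 * cos(2 * t))
  ref <- locomorph:::center_config(ref); ref <- ref / sqrt(sum(ref^2))
  cfg <- ref + matrix(rnorm(14, 0, 0.015), 7)
  sliders <- slider_table(3L, 4L, 5L, n_landmarks = 7L)
  tang <- cfg[5, ] - cfg[3, ]; tang <- tang / sqrt(sum(tang^2))
  B <- bending_energy_matrix(ref)

  crit_val <- list(
    bending_energy = function(l) {
      c2 <- cfg; c2[4, ] <- c2[4, ] + l * tang
      sum(c2[, 1] * (B %*% c2[, 1])) + sum(c2[, 2] * (B %*% c2[, 2]))
    },
    procrustes_distance = function(l) {
      c2 <- cfg; c2[4, ] <- c2[4, ] + l * tang
      sum((c2 - ref)^2)
    }
  )
  grid <- seq(-0.3, 0.3, by = 1e-6)
  for (crit in names(crit_val)) {
    out <- slide_semilandmarks(array(cfg, c(7, 2, 1)), ref, sliders, crit)
    lambda_hat <- sum((out[4, , 1] - cfg[4, ]) * tang)
    vals <- vapply(grid, crit_val[[crit]], numeric(1))
    expect_lt(abs(lambda_hat - grid[which.min(vals)]), 1.1e-6)
    # criterion never increases
    expect_lte(crit_val[[crit]](lambda_hat), crit_val[[crit]](0) + 1e-12)
  }
})

test_that("tangent projection is exact at the mean and orthogonal to it", {
  sim <- small_sim(seed = 30L)
  al <- gpa(sim$shapes)
  tang <- tangent_projection(al)
  m <- as.numeric(t(al$mean_shape))
  m_hat <- m / sqrt(sum(m^2))
  # every projected row minus the mean is orthogonal to the mean vector
  for (i in seq_len(nrow(tang))) {
    expect_lt(abs(sum((tang[i, ] - m_hat) * m_hat)), 1e-9)
  }
  # projecting the mean itself returns the mean
  al1 <- al
  al1$coords <- array(al$mean_shape, c(dim(al$mean_shape), 2L))
  al1$ids <- c("m1", "m2")
  tm <- tangent_projection(al1)
  expect_equal(tm[1, ], m_hat, tolerance = 1e-12)

  # small-variation data: PCA on projected vs raw coordinates agrees
  tiny <- simulate_outline_dataset(simulation_params(
    n_per_class = 6L, n_fossils = 0L, seed = 31L, class_effect_size = 0.02,
    individual_sd = 5e-4, landmark_noise_sd = 2e-4
  ))
  alt <- gpa(tiny$shapes, tol = 1e-12)
  tang_t <- tangent_projection(alt)
  raw <- t(apply(alt$coords, 3L, function(m) as.numeric(t(m))))
  p1 <- pca_covariance(tang_t); p2 <- pca_covariance(raw)
  expect_equal(p1$eigenvalues[1:3], p2$eigenvalues[1:3], tolerance = 1e-6)
  expect_equal(abs(unname(p1$scores[, 1])), abs(unname(p2$scores[, 1])),
               tolerance = 1e-6)
})
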
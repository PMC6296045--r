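test_that("gradient features capture step edges and flats", {
  flat <- compute_features(list(row = 1L, col = 1L, p = 4L),
                           image_grid(matrix(9, 8, 8)))
  expect_true(all(flat$grad_mag == 0))
  expect_true(all(flat$grad_angle == 0))

  # vertical step edge: left half 0, right half 255 -> max change along the
  # horizontal orientation (angle 0) for interior columns
  step <- matrix(0, 8, 8); step[, 5:8] <- 255
  f <- compute_features(list(row = 2L, col = 2L, p = 4L), image_grid(step))
  expect_true(all(f$grad_mag[, 2:3] > 0))
  expect_true(all(f$grad_angle[, 2:3] == 0))

  ft <- compute_features(list(row = 2L, col = 2L, p = 4L), image_grid(t(step)))
  expect_true(all(ft$grad_angle[2:3, ] == pi / 2))
})

test_that("pixel distance reproduces hand-evaluated cases", {
  expect_equal(pixel_distance(5, 5, 0, 0, 0, 0), 0)
  expect_equal(pixel_distance(10, 14, 2, 3, 0, pi / 4), 11)
  expect_equal(pixel_distance(14, 10, 3, 2, pi / 4, 0), 11)  # symmetric
  # folded angle: |0 - pi| is orientation-equivalent to 0
  expect_equal(pixel_distance(1, 1, 0, 0, 0, pi), 0)
  # pi/2 difference hits the tangent cap
  expect_equal(pixel_distance(0, 0, 0, 0, 0, pi / 2),
               0.5 * tan(pi / 2 - 0.01))
  expect_error(pixel_distance(0, 0, 0, 0, 0.3, 0), "angles")
})

test_that("geodesic distance equals the per-pixel oracle on random patches", {
  for (s in 1:100) {
    a <- random_features(4, s)
    b <- random_features(4, s + 1000)
    expect_equal(geodesic_distance(a, b), naive_geodesic(a, b),
                 tolerance = 1e-9)
  }
})

test_that("geodesic distance is symmetric, non-negative, and constant-patch exact", {
  for (s in 1:25) {
    a <- random_features(5, s)
    b <- random_features(5, s + 500)
    dab <- geodesic_distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, geodesic_distance(b, a), tolerance = 1e-12)
  }
  # identical zero-gradient constant patches -> exactly 0
  z <- list(values = matrix(4, 3, 3), grad_mag = matrix(0, 3, 3),
            grad_angle = matrix(0, 3, 3))
  expect_identical(geodesic_distance(z, z), 0)
  # mean of identical per-pixel terms: every pixel the 10/14 hand case
  a <- list(values = matrix(10, 3, 3), grad_mag = matrix(2, 3, 3),
            grad_angle = matrix(0, 3, 3))
  b <- list(values = matrix(14, 3, 3), grad_mag = matrix(3, 3, 3),
            grad_angle = matrix(pi / 4, 3, 3))
  expect_equal(geodesic_distance(a, b), 11)
})

test_that("self-distance follows the printed form unless strict", {
  a <- random_features(4, 7)
  expect_equal(geodesic_distance(a, a), mean(a$grad_mag))
  expect_equal(geodesic_distance(a, a, strict = TRUE), 0)
})

test_that("euclidean distance matches its oracle and the zero-gradient limit", {
  expect_equal(euclidean_distance(matrix(0, 3, 3), matrix(2, 3, 3)), 4)
  for (s in 1:50) {
    set.seed(s)
    a <- matrix(runif(16, 0, 30), 4, 4)
    b <- matrix(runif(16, 0, 30), 4, 4)
    expect_equal(euclidean_distance(a, b), naive_mse(a, b), tolerance = 1e-9)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
    # zero gradients and equal angles: geodesic = 0.5 * euclidean
    fa <- list(values = a, grad_mag = 0 * a, grad_angle = 0 * a)
    fb <- list(values = b, grad_mag = 0 * b, grad_angle = 0 * b)
    expect_equal(geodesic_distance(fa, fb), 0.5 * euclidean_distance(a, b),
                 tolerance = 1e-9)
  }
})

test_that("vectorized cross-distances agree with the pairwise functions", {
  set.seed(31)
  img <- image_grid(matrix(runif(144, 0, 50), 12, 12))
  ps <- extract_patches(img, 4, 2)
  fr <- geodenoise:::patch_feature_rows(img, ps)
  G <- geodenoise:::cross_geodesic(fr$V, fr$T, fr$A, fr$V, fr$T, fr$A)
  E <- geodenoise:::cross_euclidean(fr$V, fr$V)
  feats <- lapply(seq_len(nrow(ps$coords)), function(i)
    compute_features(list(row = ps$coords[i, 1], col = ps$coords[i, 2], p = 4L),
                     img))
  for (i in c(1, 3, 8)) for (j in c(2, 5, nrow(ps$coords))) {
    expect_equal(G[i, j], geodesic_distance(feats[[i]], feats[[j]]),
                 tolerance = 1e-8)
    expect_equal(E[i, j], euclidean_distance(feats[[i]]$values,
                                             feats[[j]]$values),
                 tolerance = 1e-8)
  }
})

test_that("match_blocks assigns nearest references with threshold and ties", {
  # image with two flat motifs: candidates match the reference of their level
  m <- matrix(10, 6, 12); m[, 7:12] <- 200
  img <- image_grid(m)
  ps <- extract_patches(img, 3, 3)
  lvl <- patch_values(img, ps)[, 1]
  refs <- c(which(lvl == 10)[1], which(lvl == 200)[1])
  res <- match_blocks(img, ps, refs, metric = "euclidean")
  expect_identical(res$assignments[lvl == 10],
                   rep(1L, sum(lvl == 10)))
  expect_identical(res$assignments[lvl == 200],
                   rep(2L, sum(lvl == 200)))
  expect_equal(res$distances[refs[1]], 0)

  # threshold leaves far candidates unassigned
  res_t <- match_blocks(img, ps, refs[1], metric = "euclidean", threshold = 1)
  expect_true(all(is.na(res_t$assignments[lvl == 200])))
  expect_true(all(!is.na(res_t$assignments[lvl == 10])))

  expect_error(match_blocks(img, ps, integer(0)), "reference")
})

test_that("grouping is deterministic and separates motifs", {
  ph <- make_phantom(phantom_spec(size = 96, n_particles = 4, radius = 8,
                                  motif = c("ring", "disk"), seed = 5))
  g1 <- build_groups(ph$image, p = 5, stride = 2, n_refs = 12,
                     group_size = 10, seed = 42)
  g2 <- build_groups(ph$image, p = 5, stride = 2, n_refs = 12,
                     group_size = 10, seed = 42)
  expect_identical(lapply(g1, `[[`, "members"), lapply(g2, `[[`, "members"))
  expect_identical(vapply(g1, `[[`, 1L, "ref"), vapply(g2, `[[`, 1L, "ref"))

  # repeated identical flat motifs: all group members at distance ~0
  flat <- image_grid(matrix(50, 20, 20))
  gf <- build_groups(flat, p = 4, stride = 4, n_refs = 2, group_size = 4,
                     seed = 1)
  for (g in gf) {
    expect_equal(g$Yc, matrix(0, 16, 4))
    expect_true(all(abs(rowSums(g$Yc)) < 1e-9))
  }
  expect_error(build_groups(flat, p = 4, stride = 4, group_size = 1000,
                            seed = 1), "exceeds")
})
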
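# Ring statistics, edge correction, null moments, thresholding, coupling.

test_that("ring sets and ring assignment follow the half-open convention", {
  r <- ring_set(16, 15)
  expect_equal(r$radii, seq(0, 240, 15))
  expect_equal(r$r_max, 240)
  expect_true(all(diff(r$radii) > 0))
  # d = 40 falls in the ring (30, 45]
  expect_equal(rsoda:::ring_of(40, r), 3L)
  expect_equal(rsoda:::ring_of(15, r), 1L)      # boundary is inclusive
  expect_equal(rsoda:::ring_of(15.0001, r), 2L)
  expect_equal(rsoda:::ring_of(0, r), 1L)
  expect_true(is.na(rsoda:::ring_of(241, r)))
})

test_that("candidate pairs match exhaustive enumeration", {
  rings <- ring_set()
  # boundary: 250 nm apart -> no pair; 40 nm apart -> one pair in ring 3
  far <- pairwise_candidate_distances(cluster_table(0, 0),
                                      cluster_table(250, 0), rings)
  expect_equal(nrow(far), 0)
  near <- pairwise_candidate_distances(cluster_table(0, 0),
                                       cluster_table(40, 0), rings)
  expect_equal(nrow(near), 1)
  expect_equal(near$ring, 3L)
  expect_equal(near$distance, 40)

  # oracle equivalence on a dense random instance
  mask <- matrix(TRUE, 200, 200)
  c1 <- withr::with_seed(5, random_clusters(500, mask))
  c2 <- withr::with_seed(6, random_clusters(500, mask))
  fast <- pairwise_candidate_distances(c1, c2, rings)
  slow <- oracle_pairs(c1, c2, rings$r_max, rings$ring_width)
  expect_equal(nrow(fast), nrow(slow))
  expect_equal(fast$id1, slow$id1)
  expect_equal(fast$id2, slow$id2)
  expect_equal(fast$distance, slow$distance)
  expect_equal(fast$ring, slow$ring)
})

test_that("edge-correction weights reflect ROI geometry", {
  mask <- matrix(TRUE, 200, 200)
  # deep interior: weight exactly 1
  expect_equal(edge_correction_weights(1500, 1500, 240, mask, 15), 1)

  # straight edge of a half plane, circle crossing it: weight ~ 2
  half <- mask; half[, 101:200] <- FALSE
  w <- edge_correction_weights(100 * 15, 100 * 15, 200, half, 15,
                               n_angles = 4096)
  expect_equal(w, 2, tolerance = 0.1)

  # refinement: 64-angle sampling within 5% of 4096-angle sampling
  band <- generate_roi_mask(c(256, 256), "dendrite_band", seed = 9)
  pts <- withr::with_seed(10, random_clusters(80, band))
  r <- withr::with_seed(11, runif(80, 30, 240))
  w64 <- edge_correction_weights(pts$x_nm, pts$y_nm, r, band, 15, 64)
  w4096 <- edge_correction_weights(pts$x_nm, pts$y_nm, r, band, 15, 4096)
  expect_lt(max(abs(w64 - w4096) / w4096), 0.05)

  expect_error(edge_correction_weights(-300, -300, 10, mask, 15),
               "outside the image frame")
})

test_that("G vector construction matches its definition", {
  rings <- ring_set()
  empty <- data.frame(id1 = integer(), id2 = integer(),
                      distance = numeric(), ring = integer())
  expect_equal(compute_G_vector(empty, numeric(0), 10, 10, 1e6, rings),
               rep(0, 16))
  expect_error(compute_G_vector(empty, numeric(0), 0, 10, 1e6, rings),
               "no clusters")

  one <- data.frame(id1 = 1L, id2 = 1L, distance = 40, ring = 3L)
  G <- compute_G_vector(one, 1, 20, 30, 5e6, rings)
  expect_equal(G[3], 5e6 / (20 * 30))
  expect_equal(sum(G[-3]), 0)
  expect_true(all(G >= 0))
})

test_that("null moments: analytic mean, positive sd, MC convergence", {
  rings <- ring_set()
  mask <- matrix(TRUE, 192, 192)
  expect_equal(pi * diff(rings$radii^2)[1], pi * 225)  # ring 1: ~706.9 nm^2

  expect_error(null_moments(rings, mask, 15, 50, 50, n_reps = 5), "at least 10")
  expect_warning(null_moments(rings, mask, 15, 30, 30, n_reps = 10),
                 "fewer than 100")

  nm <- null_moments(rings, mask, 15, 500, 500, mode = "monte_carlo",
                     n_reps = 500, seed = 3)
  expect_true(all(nm$sigma > 0))
  analytic <- pi * diff(rings$radii^2)
  expect_lt(max(abs(nm$mu - analytic) / analytic), 0.03)
})

test_that("reduction and thresholding implement the universal threshold", {
  rings <- ring_set()
  mu <- pi * diff(rings$radii^2)
  sigma <- rep(50, 16)

  # G = mu exactly -> G0 = 0 everywhere
  s0 <- reduce_and_threshold(mu, mu, sigma, rings = rings)
  expect_equal(s0$G0, rep(0, 16))
  expect_equal(s0$threshold, 2 * log(16))
  expect_equal(s0$threshold, 5.545, tolerance = 1e-3)

  # one ring 10 sigma above the mean: retained (10 > 5.545)
  G <- mu; G[1] <- mu[1] + 10 * sigma[1]
  s1 <- reduce_and_threshold(G, mu, sigma, rings = rings)
  expect_equal(s1$G0[1], 10)
  expect_equal(s1$G0[-1], rep(0, 15))

  # a 4 sigma excursion is below the threshold -> zeroed
  G4 <- mu; G4[5] <- mu[5] + 4 * sigma[5]
  expect_equal(reduce_and_threshold(G4, mu, sigma, rings = rings)$G0,
               rep(0, 16))

  # idempotence
  s2 <- reduce_and_threshold(s1$G0 * sigma + mu, mu, sigma, rings = rings)
  expect_equal(s2$G0, s1$G0)

  # correction-matrix modes
  A <- diag(16)
  expect_equal(reduce_and_threshold(G, mu, sigma, A, rings)$G0, s1$G0)
  expect_equal(reduce_and_threshold(G, mu, sigma, A, rings,
                                    a_method = "inv_sqrt")$G0, s1$G0)
  expect_error(reduce_and_threshold(G, mu, sigma, matrix(0, 16, 16), rings),
               "singular")
})

test_that("mc-estimated ring correlation keeps strong signals significant", {
  rings <- ring_set()
  mask <- matrix(TRUE, 128, 128)
  nm <- suppressWarnings(null_moments(rings, mask, 15, 40, 40,
                                      n_reps = 200, seed = 7))
  A <- ring_correlation(nm$G_null)
  expect_equal(diag(A), rep(1, 16))
  expect_true(all(abs(A) <= 1 + 1e-12))
  G <- nm$mu; G[3] <- nm$mu[3] + 30 * nm$sigma[3]
  s <- reduce_and_threshold(G, nm$mu, nm$sigma, A, rings,
                            a_method = "inv_sqrt")
  expect_gt(s$G0[3], s$threshold)
})

test_that("coupling probability follows the excess-fraction identity", {
  rings <- ring_set()
  mu <- pi * diff(rings$radii^2)
  sigma <- rep(1e-3, 16)  # tiny null sd: every excess is significant
  G <- mu
  G[3] <- 2 * mu[3]       # ring with G = 2 mu -> P = (G - mu)/G = 0.5
  s <- reduce_and_threshold(G, mu, sigma, rings = rings)
  pairs <- data.frame(id1 = 1:2, id2 = 1:2, distance = c(40, 100),
                      ring = c(3L, 7L))
  rec <- pair_coupling_probability(s, pairs)
  expect_equal(rec$coupling_probability[1], 0.5)
  expect_equal(rec$coupling_probability[2], 0)  # non-significant ring
  expect_true(all(rec$coupling_probability >= 0 &
                    rec$coupling_probability <= 1))
})

test_that("summaries aggregate pairs to clusters by the max-P rule", {
  rings <- ring_set()
  c1 <- cluster_table(c(0, 1000, 2000), c(0, 0, 0))
  c2 <- cluster_table(c(40, 1100, 2500), c(0, 0, 0))
  rec <- data.frame(id1 = c(1L, 1L), id2 = c(1L, 2L),
                    distance = c(40, 130), ring = c(3L, 9L),
                    coupling_probability = c(0.3, 0.8))
  s <- summarize_coupling(rec, c1, c2, rings)
  ct <- s$cluster_table
  expect_equal(ct$coupling_probability[ct$channel == 1 & ct$id == 1], 0.8)
  expect_equal(ct$coupling_distance[ct$channel == 1 & ct$id == 1], 130)
  expect_equal(unname(s$coupling_index["ch1"]), 1 / 3)
  expect_equal(s$n_coupled_pairs, 2)

  none <- summarize_coupling(rec[0, ], c1, c2, rings)
  expect_equal(unname(none$coupling_index), c(0, 0))
  expect_equal(sum(none$ring_probability$n_pairs), 0)
})

test_that("dual-label point sets give near-certain first-ring coupling", {
  # identical centroids with 3 nm jitter: the positive control situation
  mask <- generate_roi_mask(c(1024, 1024), "dendrite_band", seed = 41)
  c1 <- withr::with_seed(42, random_clusters(400, mask))
  c2 <- withr::with_seed(43, {
    cluster_table(c1$x_nm + rnorm(400, 0, 3), c1$y_nm + rnorm(400, 0, 3))
  })
  keep <- rsoda:::point_in_mask(c2$x_nm, c2$y_nm, mask, 15)
  c2 <- cluster_table(c2$x_nm[keep], c2$y_nm[keep])
  res <- soda_analysis(c1, c2, mask, 15, seed = 44)
  ring1 <- res$pairs[res$pairs$ring == 1, ]
  expect_gte(mean(ring1$coupling_probability), 0.98)
  expect_gte(unname(res$summary$coupling_index["ch1"]), 0.95)
  expect_equal(which.max(res$summary$ring_probability$n_pairs), 1L)
})

test_that("soda_analysis errors on empty channels", {
  mask <- matrix(TRUE, 128, 128)
  expect_error(soda_analysis(cluster_table(numeric(0), numeric(0)),
                             cluster_table(10, 10), mask, 15),
               "no clusters")
})
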
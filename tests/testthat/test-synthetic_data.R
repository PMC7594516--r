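# Synthetic image and feature generator.

test_that("roi masks honour style, occupancy and the size precondition", {
  full <- generate_roi_mask(c(512, 512), "full", seed = 1)
  expect_true(all(full))

  for (s in 1:5) {
    band <- generate_roi_mask(c(512, 512), "dendrite_band", seed = s)
    frac <- mean(band)
    expect_gte(frac, 0.2)
    expect_lte(frac, 0.8)
    # connectedness: one component dominates the foreground
    lab <- label_components(band)
    expect_gte(max(tabulate(lab[lab > 0])) / sum(band), 0.99)
  }
  expect_error(generate_roi_mask(c(16, 16), "dendrite_band"), "64x64")
})

test_that("simulate_cluster_pairs places the configured pair structure", {
  base <- function(...) simulation_config(image_shape = c(256, 256),
                                          n_clusters_ch1 = 50,
                                          n_clusters_ch2 = 50, ...)
  t0 <- simulate_cluster_pairs(base(coupling_fraction = 0, seed = 2))
  expect_equal(nrow(t0$coupled_pairs), 0)
  expect_equal(nrow(t0$positions_ch1), 50)
  expect_equal(nrow(t0$positions_ch2), 50)

  # degenerate distribution: f = 1, sd = 0 -> every offset exactly 45 nm
  cfg <- simulation_config(image_shape = c(512, 512), n_clusters_ch1 = 200,
                           n_clusters_ch2 = 200, coupling_fraction = 1,
                           coupling_distance_mean = 45,
                           coupling_distance_sd = 0, seed = 3)
  t1 <- simulate_cluster_pairs(cfg)
  expect_equal(nrow(t1$coupled_pairs), 200)
  expect_equal(t1$coupled_pairs$offset_nm, rep(45, 200))
  d <- sqrt(rowSums((t1$positions_ch1 - t1$positions_ch2)^2))
  expect_equal(d, rep(45, 200), tolerance = 1e-12)

  # pair count and mask membership
  cfg5 <- simulation_config(image_shape = c(512, 512), n_clusters_ch1 = 400,
                            n_clusters_ch2 = 400, coupling_fraction = 0.5,
                            seed = 7)
  t5 <- simulate_cluster_pairs(cfg5)
  expect_equal(nrow(t5$coupled_pairs), 200)
  p2 <- t5$positions_ch2[t5$coupled_pairs$id2, , drop = FALSE]
  expect_true(all(rsoda:::point_in_mask(p2[, 1], p2[, 2], t5$roi_mask, 15)))

  expect_error(simulation_config(coupling_distance_mean = -5), ">= 0")
  expect_error(simulation_config(coupling_fraction = 1.2), "\\[0, 1\\]")
})

test_that("simulation is bit-identical given config and seed", {
  cfg <- simulation_config(image_shape = c(256, 256), n_clusters_ch1 = 40,
                           n_clusters_ch2 = 40, coupling_fraction = 0.5,
                           seed = 11)
  a <- simulate_cluster_pairs(cfg)
  b <- simulate_cluster_pairs(cfg)
  expect_identical(a$positions_ch1, b$positions_ch1)
  expect_identical(a$positions_ch2, b$positions_ch2)
  ia <- render_image_pair(a, cfg)
  ib <- render_image_pair(b, cfg)
  expect_identical(ia, ib)
})

test_that("coupled offsets follow the configured truncated normal", {
  cfg <- simulation_config(image_shape = c(1024, 1024),
                           n_clusters_ch1 = 1000, n_clusters_ch2 = 1000,
                           coupling_fraction = 1,
                           coupling_distance_mean = 45,
                           coupling_distance_sd = 5, seed = 13)
  tr <- simulate_cluster_pairs(cfg)
  # truncation at 0 is negligible at mean/sd = 9, so plain normal CDF works
  ks <- suppressWarnings(ks.test(tr$coupled_pairs$offset_nm, "pnorm", 45, 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("rendering produces count images with the expected structure", {
  cfg <- simulation_config(image_shape = c(128, 128), n_clusters_ch1 = 0,
                           n_clusters_ch2 = 0, background_rate = 3, seed = 5)
  empty <- structure(list(positions_ch1 = matrix(numeric(0), ncol = 2),
                          positions_ch2 = matrix(numeric(0), ncol = 2),
                          coupled_pairs = data.frame(),
                          roi_mask = matrix(TRUE, 128, 128), config = cfg),
                     class = "soda_ground_truth")
  img <- render_image_pair(empty, cfg)
  expect_equal(mean(img$ch1), 3, tolerance = 0.1)

  # single centroid at the frame centre, no noise -> argmax at that pixel
  ctr <- (64 - 1) * 15
  single <- empty
  single$positions_ch1 <- cbind(x_nm = ctr, y_nm = ctr)
  img1 <- render_image_pair(single, cfg, noise = FALSE)$ch1
  peak <- which(img1 == max(img1), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(64, 64))
})

test_that("segmentation recovers rendered cluster fields", {
  cfg <- simulation_config(n_clusters_ch1 = 200, n_clusters_ch2 = 200,
                           coupling_fraction = 0, roi_style = "full",
                           seed = 2)
  tr <- simulate_cluster_pairs(cfg)
  img <- render_image_pair(tr, cfg)
  cl <- segment_channel(img$ch1, matrix(TRUE, 1024, 1024), 15, 1L)
  d <- sqrt(outer(tr$positions_ch1[, 1], cl$x_nm, "-")^2 +
              outer(tr$positions_ch1[, 2], cl$y_nm, "-")^2)
  recovered <- mean(apply(d, 1, min) <= 30)
  expect_gte(recovered, 0.9)
})

test_that("CSR channels pass a Monte-Carlo Ripley envelope test", {
  mask <- matrix(TRUE, 300, 300)
  rings <- ring_set(16, 15)
  area <- sum(mask) * 15^2
  k240 <- function(c1, c2) {
    pr <- pairwise_candidate_distances(c1, c2, rings)
    area * nrow(pr) / (nrow(c1) * nrow(c2))
  }
  cfg <- simulation_config(image_shape = c(300, 300), n_clusters_ch1 = 150,
                           n_clusters_ch2 = 150, coupling_fraction = 0,
                           roi_style = "full", seed = 21)
  tr <- simulate_cluster_pairs(cfg)
  obs <- k240(cluster_table(tr$positions_ch1[, 1], tr$positions_ch1[, 2]),
              cluster_table(tr$positions_ch2[, 1], tr$positions_ch2[, 2]))
  env <- withr::with_seed(99, replicate(39, {
    k240(random_clusters(150, mask), random_clusters(150, mask))
  }))
  expect_gte(obs, min(env))
  expect_lte(obs, max(env))
})

test_that("feature blobs honour shape, balance and the k precondition", {
  expect_error(simulate_feature_blobs(1), "k must be >= 2")
  fb <- simulate_feature_blobs(4, n_per_group = 100, separation = 0.5,
                               seed = 3)
  expect_equal(dim(fb$features), c(400, 7))
  expect_equal(unname(table(fb$labels)), rep(100L, 4), ignore_attr = TRUE)
  cd <- dist(fb$centres)
  expect_gte(min(cd), 0.5)
})

test_that("ground truth round-trips through CSV", {
  cfg <- simulation_config(image_shape = c(256, 256), n_clusters_ch1 = 40,
                           n_clusters_ch2 = 40, coupling_fraction = 0.5,
                           seed = 4)
  tr <- simulate_cluster_pairs(cfg)
  f <- tempfile(fileext = ".csv")
  write_ground_truth(tr, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 80)
  expect_equal(sum(!is.na(df$partner_id[df$channel == 1])), 20)
  expect_equal(df$x_nm[df$channel == 1], tr$positions_ch1[, 1])
})
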
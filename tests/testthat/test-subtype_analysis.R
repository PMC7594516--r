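# Feature scaling, 2-D embedding, KDE subtype discovery, grouping,
# assignment and cross-dataset mapping.
#
# UMAP runs go through one batched python call per file where possible to
# keep the JIT cost bounded.

blobs3 <- simulate_feature_blobs(3, n_per_group = 80, separation = 0.6,
                                 seed = 101)
blobs3_tab <- build_feature_table(as.data.frame(blobs3$features),
                                  condition = rep(c("a", "b"), 120),
                                  drop_uncoupled = FALSE)

test_that("feature tables scale, warn and invert correctly", {
  df <- as.data.frame(blobs3$features)
  expect_error(build_feature_table(df[, -1]), "missing feature column")

  tab <- build_feature_table(df, drop_uncoupled = FALSE)
  expect_equal(dim(tab$scaled), dim(df))
  expect_true(all(tab$scaled >= 0 & tab$scaled <= 1))
  expect_equal(unname(apply(tab$scaled, 2, max)), rep(1, 7))
  # round trip
  back <- inverse_scale(tab, tab$scaled)
  expect_equal(unname(back), unname(as.matrix(df)), tolerance = 1e-12)
  expect_equal(unname(apply_scale(tab, back)), unname(tab$scaled),
               tolerance = 1e-12)

  dfc <- df; dfc$eccentricity <- 0.5
  expect_warning(tabc <- build_feature_table(dfc, drop_uncoupled = FALSE),
                 "constant feature")
  expect_equal(unique(tabc$scaled[, "eccentricity"]), 0)

  # only coupled clusters are retained by default
  dfu <- df; dfu$coupling_probability[1:10] <- 0
  tabu <- build_feature_table(dfu)
  expect_equal(nrow(tabu$scaled), nrow(df) - 10)
})

test_that("pca embedding separates blobs and enforces preconditions", {
  emb <- embed_2d(blobs3_tab, method = "pca")
  expect_equal(ncol(emb$coords), 2)
  sil <- rsoda:::.silhouette_mean(emb$coords, blobs3$labels)
  expect_gt(sil, 0.5)
})

test_that("umap embedding is deterministic and separates blobs", {
  e1 <- embed_2d(blobs3_tab, seed = 7)
  e2 <- embed_2d(blobs3_tab, seed = 7)
  expect_equal(unname(e1$coords), unname(e2$coords), tolerance = 1e-8)
  sil <- rsoda:::.silhouette_mean(e1$coords, blobs3$labels)
  expect_gt(sil, 0.5)

  expect_error(embed_2d(blobs3_tab$scaled[1:20, ], n_neighbors = 25),
               "at least n_neighbors")
})

test_that("density maps are normalized with sensible maxima", {
  pts <- withr::with_seed(21, cbind(rnorm(200, 0, 0.3), rnorm(200, 5, 0.3)))
  dm <- density_map(pts, grid_size = 128)
  g <- dm$grids[["all"]]
  # integrates to ~1 (Riemann sum)
  cell <- mean(diff(dm$x)) * mean(diff(dm$y))
  expect_equal(sum(g) * cell, 1, tolerance = 0.02)
  # unimodal, argmax at the blob centre
  peak <- which(g == max(g), arr.ind = TRUE)
  expect_equal(dm$x[peak[1, 2]], 0, tolerance = 0.2)
  expect_equal(dm$y[peak[1, 1]], 5, tolerance = 0.2)
  expect_length(dm$contour_levels[["all"]], 10)

  # two equal blobs -> two near-equal maxima
  pts2 <- withr::with_seed(22, rbind(cbind(rnorm(150, 0, 0.2), rnorm(150, 0, 0.2)),
                                     cbind(rnorm(150, 4, 0.2), rnorm(150, 4, 0.2))))
  dm2 <- density_map(pts2, grid_size = 128)
  mx <- detect_subtype_maxima(dm2, "all", pts2,
                              matrix(runif(300 * 7), 300, 7),
                              min_separation = 10)
  expect_equal(nrow(mx), 2)
  expect_lt(abs(diff(mx$height)) / max(mx$height), 0.3)

  expect_error(density_map(matrix(1, 20, 2)), "degenerate")
  expect_error(density_map(pts[1:5, ]), "at least 10")
})

test_that("maxima prototypes average the local feature vectors", {
  emb <- rbind(matrix(0, 30, 2), matrix(6, 30, 2)) +
    withr::with_seed(23, matrix(rnorm(120, 0, 0.05), 60, 2))
  feats <- rbind(matrix(0.2, 30, 7), matrix(0.8, 30, 7))
  colnames(feats) <- rsoda:::.feature_columns
  dm <- density_map(emb, grid_size = 128)
  mx <- detect_subtype_maxima(dm, "all", emb, feats, min_separation = 10)
  expect_equal(nrow(mx), 2)
  protos <- as.matrix(mx[, rsoda:::.feature_columns])
  expect_equal(sort(protos[, 1]), c(0.2, 0.8), tolerance = 1e-9)

  expect_error(detect_subtype_maxima(dm, "nope", emb, feats), "no density")
})

test_that("hierarchical grouping selects k by silhouette", {
  centres <- matrix(c(0, 0, 0, 0, 0, 0, 0,
                      1, 1, 1, 0, 0, 0, 0,
                      0, 0, 0, 1, 1, 1, 1), 3, byrow = TRUE)
  protos <- centres[rep(1:3, each = 3), ] +
    withr::with_seed(24, matrix(rnorm(63, 0, 0.03), 9, 7))
  g <- hierarchical_grouping(protos)
  expect_equal(g$k, 3L)
  expect_equal(length(unique(g$labels[1:3])), 1)
  expect_equal(length(unique(g$labels)), 3)
  # selected k maximizes the silhouette over the candidate range
  expect_gte(g$silhouettes[as.character(g$k)], max(g$silhouettes))

  expect_warning(g2 <- hierarchical_grouping(matrix(1, 2, 7)), "fewer than 3")
  expect_equal(g2$k, 1L)
  expect_warning(g3 <- hierarchical_grouping(matrix(1, 5, 7)), "identical")
  expect_equal(g3$k, 1L)
})

test_that("nearest-prototype assignment recovers blob labels", {
  protos <- blobs3$centres
  colnames(protos) <- rsoda:::.feature_columns
  scaled_protos <- apply_scale(blobs3_tab, protos)
  asg <- assign_to_subtypes(blobs3_tab, scaled_protos, groups = 1:3)
  expect_gte(mean(asg$group == blobs3$labels), 0.95)
  # a cluster equal to a prototype gets that prototype's group
  asg1 <- assign_to_subtypes(scaled_protos, scaled_protos, groups = 1:3)
  expect_equal(asg1$group, 1:3)
  # per-condition proportions sum to 1
  expect_equal(unname(rowSums(asg$proportions)), rep(1, 2))
})

test_that("full chain discovers the planted group count (pca backend)", {
  model <- discover_subtypes(blobs3_tab, method = "pca")
  expect_equal(model$k, 3L)
  expect_gte(mean(vapply(split(model$assignment$group, blobs3$labels),
                         function(g) max(table(g)) / length(g), 0)), 0.95)
})

test_that("full chain discovers k = 2 through the umap backend", {
  fb <- simulate_feature_blobs(2, n_per_group = 100, separation = 0.7,
                               seed = 102)
  tab <- build_feature_table(as.data.frame(fb$features),
                             condition = rep(c("a", "b"), 100),
                             drop_uncoupled = FALSE)
  model <- discover_subtypes(tab, seed = 5)
  expect_equal(model$k, 2L)
})

test_that("cross-dataset mapping is row-stochastic and identity-dominant", {
  fb_a <- simulate_feature_blobs(3, n_per_group = 90, separation = 0.6,
                                 seed = 103)
  fb_b <- simulate_feature_blobs(3, n_per_group = 90, separation = 0.6,
                                 seed = 103)  # same model, same blobs
  fb_b$features <- fb_b$features +
    withr::with_seed(25, matrix(rnorm(length(fb_b$features), 0, 0.01),
                                nrow(fb_b$features)))
  mk <- function(fb) {
    tab <- build_feature_table(as.data.frame(fb$features),
                               condition = rep(c("a", "b"),
                                               nrow(fb$features) / 2),
                               drop_uncoupled = FALSE)
    discover_subtypes(tab, method = "pca")
  }
  ma <- mk(fb_a); mb <- mk(fb_b)
  map <- cross_dataset_mapping(ma, mb)
  expect_equal(unname(rowSums(map$M_ab)), rep(1, nrow(map$M_ab)))
  expect_equal(unname(rowSums(map$M_ba)), rep(1, nrow(map$M_ba)))
  expect_true(all(apply(map$M_ab, 1, max) > 0.9))
  expect_true(all(apply(map$M_ba, 1, max) > 0.9))
  # mapping a model onto itself is diagonal-dominant
  self_map <- cross_dataset_mapping(ma, ma)
  expect_true(all(apply(self_map$M_ab, 1, which.max) ==
                    seq_len(nrow(self_map$M_ab))))

  mb2 <- mb
  colnames(mb2$table$scaled)[1] <- "volume"
  expect_error(cross_dataset_mapping(ma, mb2), "feature definitions")
})
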
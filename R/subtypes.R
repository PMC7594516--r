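## Unsupervised subtype discovery in the 7-dimensional feature space of
## coupled clusters: min-max scaled features, 2-D embedding, per-condition
## kernel density estimation, local-maxima prototypes, silhouette-selected
## Ward grouping, nearest-prototype assignment, and cross-dataset mapping.

.feature_columns <- c("area", "eccentricity", "perimeter",
                      "major_axis_length", "minor_axis_length",
                      "coupling_distance", "coupling_probability")

#' Build the 7-D feature table of coupled clusters
#'
#' Joins the five morphological features with the coupling distance and
#' probability, keeps only coupled clusters (coupling probability > 0),
#' and min-max scales every column to \[0, 1\] over the pooled dataset
#' (all conditions of one experiment together). Scaling parameters are
#' stored for reuse and inversion.
#'
#' @param features data.frame containing the columns `area`,
#'   `eccentricity`, `perimeter`, `major_axis_length`, `minor_axis_length`,
#'   `coupling_distance`, `coupling_probability` (one row per cluster) —
#'   e.g. assembled from [filter_and_label_clusters()] and
#'   [summarize_coupling()] output via [collect_features()].
#' @param condition condition label per row (recycled if scalar).
#' @param drop_uncoupled keep only rows with `coupling_probability > 0`.
#' @return object of class `soda_features`: list `scaled` (matrix),
#'   `raw` (data.frame), `condition`, `scale_min`, `scale_range`.
#' @export
build_feature_table <- function(features, condition = "all",
                                drop_uncoupled = TRUE) {
  missing_cols <- setdiff(.feature_columns, names(features))
  if (length(missing_cols) > 0)
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  condition <- rep_len(as.character(condition), nrow(features))
  if (drop_uncoupled) {
    keep <- features$coupling_probability > 0
    features <- features[keep, , drop = FALSE]
    condition <- condition[keep]
  }
  if (nrow(features) == 0) stop("no coupled clusters in the feature table")
  raw <- features[, .feature_columns, drop = FALSE]
  mins <- vapply(raw, min, 0)
  rngs <- vapply(raw, max, 0) - mins
  zero <- rngs == 0
  if (any(zero)) {
    warning("constant feature column(s) scaled to zero: ",
            paste(.feature_columns[zero], collapse = ", "))
    rngs[zero] <- 1
  }
  scaled <- sweep(sweep(as.matrix(raw), 2, mins), 2, rngs, "/")
  structure(list(scaled = scaled, raw = raw, condition = condition,
                 scale_min = mins, scale_range = rngs),
            class = "soda_features")
}

#' Apply or invert the stored min-max scaling
#'
#' @param table a `soda_features` object.
#' @param values matrix in the scaled (for `inverse_scale`) or raw (for
#'   `apply_scale`) space, columns in feature order.
#' @return matrix in the other space.
#' @export
inverse_scale <- function(table, values) {
  sweep(sweep(as.matrix(values), 2, table$scale_range, "*"), 2,
        table$scale_min, "+")
}

#' @rdname inverse_scale
#' @export
apply_scale <- function(table, values) {
  sweep(sweep(as.matrix(values), 2, table$scale_min), 2,
        table$scale_range, "/")
}

#' Assemble the per-cluster feature table from pipeline outputs
#'
#' Joins a segmented cluster table with a coupling summary into the
#' 7-column feature layout expected by [build_feature_table()].
#'
#' @param clusters `soda_clusters` table of one channel.
#' @param summary `soda_summary` from [summarize_coupling()].
#' @param channel channel to extract.
#' @return data.frame with the 7 feature columns plus `id`.
#' @export
collect_features <- function(clusters, summary, channel = 1L) {
  ct <- summary$cluster_table
  ct <- ct[ct$channel == channel, , drop = FALSE]
  i <- match(clusters$id, ct$id)
  data.frame(id = clusters$id,
             area = clusters$area_um2,
             eccentricity = clusters$eccentricity,
             perimeter = clusters$perimeter_um,
             major_axis_length = clusters$major_axis_um,
             minor_axis_length = clusters$minor_axis_um,
             coupling_distance = ct$coupling_distance[i],
             coupling_probability = ct$coupling_probability[i])
}

# ---------------------------------------------------------------------------
# 2-D embedding

.umap_available <- function() {
  python <- Sys.which("python")
  if (python == "") return(FALSE)
  isTRUE(suppressWarnings(system2(python, c("-c", shQuote("import umap")),
                                  stdout = FALSE, stderr = FALSE)) == 0)
}

# Batch UMAP through the bundled python runner; one process for all
# matrices so the JIT cost is paid once. Deterministic given seed.
.umap_batch <- function(mats, n_neighbors, min_dist, seed) {
  python <- Sys.which("python")
  if (python == "")
    stop("UMAP backend needs `python` with umap-learn on the PATH; ",
         "use method = \"pca\" otherwise")
  script <- system.file("python", "umap_embed.py", package = "rsoda")
  work <- tempfile("umap")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE))
  ins <- file.path(work, sprintf("in_%03d.csv", seq_along(mats)))
  outs <- file.path(work, sprintf("out_%03d.csv", seq_along(mats)))
  for (i in seq_along(mats))
    write.table(mats[[i]], ins[i], sep = ",", row.names = FALSE,
                col.names = FALSE)
  job <- file.path(work, "job.json")
  jsonlite::write_json(list(n_neighbors = n_neighbors, min_dist = min_dist,
                            seed = seed, inputs = I(ins), outputs = I(outs)),
                       job, auto_unbox = TRUE)
  cache <- file.path(tempdir(), "rsoda_numba_cache")
  if (!dir.exists(cache)) dir.create(cache)
  res <- system2(python, c(script, job), stdout = TRUE, stderr = TRUE,
                 env = paste0("NUMBA_CACHE_DIR=", cache))
  status <- attr(res, "status") %||% 0
  if (status != 0 || !all(file.exists(outs)))
    stop("UMAP embedding failed:\n", paste(res, collapse = "\n"))
  lapply(outs, function(f)
    as.matrix(read.csv(f, header = FALSE,
                       col.names = c("dim1", "dim2"))))
}

#' Embed the scaled feature space in two dimensions
#'
#' UMAP embedding of the scaled 7-D features (default: 25 neighbours to
#' balance local and broad structure, minimal embedded distance 0.05 to
#' avoid over-compression). The UMAP backend runs through the bundled
#' python runner (umap-learn) and is deterministic given the seed;
#' `method = "pca"` provides a dependency-free linear alternative.
#'
#' @param table `soda_features` from [build_feature_table()], or a plain
#'   numeric matrix of scaled features.
#' @param n_neighbors UMAP neighbourhood size; needs at least
#'   `n_neighbors + 1` rows.
#' @param min_dist minimal distance in the embedded space.
#' @param seed integer seed.
#' @param method `"umap"` or `"pca"`.
#' @return object of class `soda_embedding`: list `coords` (n x 2 matrix),
#'   `method`, `params`.
#' @export
embed_2d <- function(table, n_neighbors = 25L, min_dist = 0.05, seed = 1L,
                     method = c("umap", "pca")) {
  method <- match.arg(method)
  x <- if (inherits(table, "soda_features")) table$scaled else as.matrix(table)
  if (method == "umap" && nrow(x) < n_neighbors + 1)
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1,
         " rows for UMAP, got ", nrow(x))
  coords <- if (method == "umap") {
    .umap_batch(list(x), n_neighbors, min_dist, seed)[[1]]
  } else {
    p <- prcomp(x, center = TRUE, scale. = FALSE)
    cbind(dim1 = p$x[, 1], dim2 = if (ncol(p$x) > 1) p$x[, 2] else 0)
  }
  structure(list(coords = coords, method = method,
                 params = list(n_neighbors = n_neighbors,
                               min_dist = min_dist, seed = seed)),
            class = "soda_embedding")
}

# ---------------------------------------------------------------------------
# Density maps and subtype maxima

#' Kernel density maps of the embedding, per condition
#'
#' Bivariate Gaussian KDE (product kernel, Scott's rule bandwidth) of each
#' condition's embedded points on one shared grid spanning all conditions
#' (so maps are directly comparable), with ten uniformly spaced contour
#' levels per map for visualization.
#'
#' @param embedding `soda_embedding` or n x 2 matrix.
#' @param condition condition label per point.
#' @param grid_size grid resolution per axis.
#' @param pad fractional padding of the pooled bounding box.
#' @return object of class `soda_density`: list `x`, `y` (grid axes),
#'   `grids` (named list of matrices, rows = y, cols = x),
#'   `contour_levels` (named list), `bandwidth`.
#' @export
density_map <- function(embedding, condition = "all", grid_size = 256L,
                        pad = 0.05) {
  pts <- if (inherits(embedding, "soda_embedding")) embedding$coords
         else as.matrix(embedding)
  condition <- rep_len(as.character(condition), nrow(pts))
  if (nrow(pts) < 10) stop("need at least 10 points for a density map")
  if (all(apply(pts, 2, function(v) diff(range(v))) == 0))
    stop("degenerate embedding: all points identical")
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  px <- diff(rx) * pad; py <- diff(ry) * pad
  gx <- seq(rx[1] - px, rx[2] + px, length.out = grid_size)
  gy <- seq(ry[1] - py, ry[2] + py, length.out = grid_size)
  grids <- list(); levels <- list(); bw <- list()
  for (cond in unique(condition)) {
    p <- pts[condition == cond, , drop = FALSE]
    n <- nrow(p)
    # Scott's rule for 2-D: h_j = sd_j * n^(-1/6)
    hx <- sd(p[, 1]) * n^(-1 / 6)
    hy <- sd(p[, 2]) * n^(-1 / 6)
    if (hx <= 0 || hy <= 0)
      stop("degenerate embedding for condition ", cond)
    kx <- dnorm(outer(gx, p[, 1], "-") / hx) / hx   # grid x n
    ky <- dnorm(outer(gy, p[, 2], "-") / hy) / hy
    g <- (ky %*% t(kx)) / n                          # rows = y, cols = x
    grids[[cond]] <- g
    levels[[cond]] <- seq(0, max(g), length.out = 11)[-1]
    bw[[cond]] <- c(hx = hx, hy = hy)
  }
  structure(list(x = gx, y = gy, grids = grids, contour_levels = levels,
                 bandwidth = bw),
            class = "soda_density")
}

#' Detect subtype maxima on a density grid
#'
#' Local maxima of the KDE grid (8-neighbourhood, above a floor of
#' `floor_frac` times the grid maximum, greedily separated by at least
#' `min_separation` grid pixels), each summarized by a prototype: the mean
#' scaled 7-D feature vector of the clusters whose embedded points fall
#' within `min_separation` grid units of the maximum (nearest point if
#' none).
#'
#' @param density `soda_density` from [density_map()].
#' @param cond which condition's grid.
#' @param embedding `soda_embedding` or n x 2 matrix of all points.
#' @param table `soda_features` (scaled rows aligned with the embedding).
#' @param subset logical/integer index of the rows belonging to `cond`
#'   (default all rows).
#' @param min_separation minimal separation in grid pixels.
#' @param floor_frac floor as a fraction of the grid maximum.
#' @return data.frame with grid positions (`gx`, `gy`), embedding
#'   coordinates (`x`, `y`), `height`, and the prototype feature columns.
#' @export
detect_subtype_maxima <- function(density, cond, embedding, table,
                                  subset = NULL, min_separation = 10L,
                                  floor_frac = 0.05) {
  g <- density$grids[[cond]]
  if (is.null(g)) stop("no density grid for condition ", cond)
  pts <- if (inherits(embedding, "soda_embedding")) embedding$coords
         else as.matrix(embedding)
  scaled <- if (inherits(table, "soda_features")) table$scaled
            else as.matrix(table)
  if (!is.null(subset)) {
    pts <- pts[subset, , drop = FALSE]
    scaled <- scaled[subset, , drop = FALSE]
  }
  nr <- nrow(g); nc <- ncol(g)
  floor_v <- floor_frac * max(g)
  # 8-neighbour local maxima via shifted comparisons
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- g
  is_max <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (g >= pad[2:(nr + 1) + di, 2:(nc + 1) + dj])
  }
  is_max <- is_max & (g > floor_v)
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0) stop("no density maxima above the floor")
  ord <- order(g[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep) == 0) { keep <- i; next }
    dsep <- sqrt((cand[keep, 1] - cand[i, 1])^2 +
                   (cand[keep, 2] - cand[i, 2])^2)
    if (all(dsep >= min_separation)) keep <- c(keep, i)
  }
  cand <- cand[keep, , drop = FALSE]
  # grid -> embedding coordinates (rows = y, cols = x)
  mx <- density$x[cand[, 2]]
  my <- density$y[cand[, 1]]
  cell <- c(mean(diff(density$x)), mean(diff(density$y)))
  protos <- matrix(NA_real_, nrow(cand), ncol(scaled))
  for (i in seq_len(nrow(cand))) {
    d2 <- (pts[, 1] - mx[i])^2 + (pts[, 2] - my[i])^2
    rad2 <- (min_separation^2) * (cell[1]^2 + cell[2]^2) / 2
    near <- which(d2 <= rad2)
    if (length(near) == 0) near <- which.min(d2)
    protos[i, ] <- colMeans(scaled[near, , drop = FALSE])
  }
  colnames(protos) <- colnames(scaled)
  out <- data.frame(gy = cand[, 1], gx = cand[, 2], x = mx, y = my,
                    height = g[cand])
  cbind(out, as.data.frame(protos))
}

# ---------------------------------------------------------------------------
# Grouping

# mean silhouette width for a labelling of points (Euclidean)
.silhouette_mean <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }  # singleton clusters score 0
    a <- mean(d[i, own])
    bs <- vapply(setdiff(unique(labels), labels[i]),
                 function(l) mean(d[i, labels == l]), 0)
    b <- min(bs)
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Hierarchical grouping of subtype prototypes
#'
#' Agglomerative grouping of the prototype vectors with Euclidean distance
#' and Ward linkage; the group count k is chosen to maximize the mean
#' silhouette width over `k_range` (default 2 .. m - 1 for m prototypes),
#' ties broken toward smaller k. Fewer than 3 prototypes, or identical
#' prototypes, yield the trivial k = 1 with a warning.
#'
#' @param prototypes numeric matrix, one prototype per row.
#' @param k_range candidate group counts.
#' @return list `linkage` (hclust or NULL), `k`, `labels`,
#'   `silhouettes` (named vector over `k_range`).
#' @export
hierarchical_grouping <- function(prototypes, k_range = NULL) {
  prototypes <- as.matrix(prototypes)
  m <- nrow(prototypes)
  if (m < 3) {
    warning("fewer than 3 prototypes: returning a single group")
    return(list(linkage = NULL, k = 1L, labels = rep(1L, m),
                silhouettes = NULL))
  }
  if (all(dist(prototypes) == 0)) {
    warning("all prototypes identical: silhouette undefined, single group")
    return(list(linkage = NULL, k = 1L, labels = rep(1L, m),
                silhouettes = NULL))
  }
  if (is.null(k_range)) k_range <- 2:(m - 1)
  k_range <- k_range[k_range >= 2 & k_range <= m - 1]
  if (length(k_range) == 0) k_range <- 2L
  hc <- hclust(dist(prototypes), method = "ward.D2")
  sil <- vapply(k_range, function(k)
    .silhouette_mean(prototypes, cutree(hc, k)), 0)
  names(sil) <- k_range
  k <- k_range[which.max(sil)]  # which.max takes the first (smallest) tie
  list(linkage = hc, k = as.integer(k), labels = cutree(hc, k),
       silhouettes = sil)
}

#' Assign clusters to subtype groups
#'
#' Nearest-prototype assignment in the scaled 7-D space (Euclidean): each
#' cluster inherits the group of its closest prototype.
#'
#' @param table `soda_features` or scaled matrix.
#' @param prototypes matrix of prototype feature vectors.
#' @param groups group label per prototype.
#' @return list `group` (per cluster), `prototype` (index of the nearest
#'   prototype), `proportions` (condition x group matrix of row fractions,
#'   when the table carries conditions).
#' @export
assign_to_subtypes <- function(table, prototypes, groups) {
  x <- if (inherits(table, "soda_features")) table$scaled else as.matrix(table)
  prototypes <- as.matrix(prototypes)
  stopifnot(ncol(x) == ncol(prototypes),
            length(groups) == nrow(prototypes))
  # squared distances points x prototypes
  d2 <- outer(rowSums(x^2), rep(1, nrow(prototypes))) -
    2 * x %*% t(prototypes) +
    outer(rep(1, nrow(x)), rowSums(prototypes^2))
  nearest <- max.col(-d2, ties.method = "first")
  grp <- groups[nearest]
  props <- NULL
  if (inherits(table, "soda_features")) {
    tab <- base::table(factor(table$condition),
                       factor(grp, levels = sort(unique(groups))))
    props <- sweep(unclass(tab), 1, pmax(1, rowSums(tab)), "/")
  }
  list(group = grp, prototype = nearest, proportions = props)
}

#' Full subtype-discovery chain
#'
#' Embeds the scaled feature table, estimates per-condition density maps,
#' detects per-condition maxima, pools the prototypes, groups them with
#' silhouette-selected Ward linkage, and assigns every cluster to a group.
#'
#' @param table `soda_features` from [build_feature_table()].
#' @inheritParams embed_2d
#' @inheritParams density_map
#' @inheritParams detect_subtype_maxima
#' @param embedding optional precomputed `soda_embedding` (rows aligned
#'   with `table`); when supplied, `method`/`n_neighbors`/`min_dist`/`seed`
#'   are ignored.
#' @return object of class `soda_subtype_model`: list `table`,
#'   `embedding`, `density`, `maxima` (prototype data.frame with a
#'   `condition` column), `grouping`, `k`, `assignment`.
#' @export
discover_subtypes <- function(table, n_neighbors = 25L, min_dist = 0.05,
                              seed = 1L, method = c("umap", "pca"),
                              grid_size = 256L, min_separation = 10L,
                              floor_frac = 0.05, embedding = NULL) {
  stopifnot(inherits(table, "soda_features"))
  if (is.null(embedding))
    embedding <- embed_2d(table, n_neighbors, min_dist, seed, method)
  dens <- density_map(embedding, table$condition, grid_size)
  conds <- unique(table$condition)
  maxima <- do.call(rbind, lapply(conds, function(cond) {
    mx <- detect_subtype_maxima(dens, cond, embedding, table,
                                subset = table$condition == cond,
                                min_separation = min_separation,
                                floor_frac = floor_frac)
    mx$condition <- cond
    mx
  }))
  protos <- as.matrix(maxima[, .feature_columns, drop = FALSE])
  grouping <- hierarchical_grouping(protos)
  assignment <- assign_to_subtypes(table, protos, grouping$labels)
  structure(list(table = table, embedding = embedding, density = dens,
                 maxima = maxima, grouping = grouping, k = grouping$k,
                 assignment = assignment),
            class = "soda_subtype_model")
}

#' Cross-dataset mapping of subtype groups
#'
#' Projects every cluster of dataset A onto the prototypes of dataset B
#' (each dataset keeps its own min-max scaling) and vice versa, giving two
#' row-stochastic matrices M\[g_A, g_B\] = fraction of A's clusters in
#' group g_A assigned (nearest prototype, Euclidean) to B's group g_B.
#' Fractions above `link_threshold` (0.4: the "major connection" rule)
#' are flagged.
#'
#' @param model_a,model_b `soda_subtype_model`s built on the same 7
#'   feature definitions.
#' @param link_threshold fraction above which a link is flagged.
#' @return list `M_ab`, `M_ba` (row-stochastic matrices), `links`
#'   (data.frame of flagged connections in both directions).
#' @export
cross_dataset_mapping <- function(model_a, model_b, link_threshold = 0.4) {
  stopifnot(inherits(model_a, "soda_subtype_model"),
            inherits(model_b, "soda_subtype_model"))
  fa <- colnames(model_a$table$scaled); fb <- colnames(model_b$table$scaled)
  if (!identical(fa, fb)) stop("feature definitions differ between datasets")
  project <- function(from, to) {
    protos_to <- as.matrix(to$maxima[, .feature_columns, drop = FALSE])
    asg <- assign_to_subtypes(from$table$scaled, protos_to,
                              to$grouping$labels)
    home <- from$assignment$group
    ga <- sort(unique(from$grouping$labels))
    gb <- sort(unique(to$grouping$labels))
    M <- matrix(0, length(ga), length(gb), dimnames = list(ga, gb))
    tab <- table(factor(home, levels = ga), factor(asg$group, levels = gb))
    M[] <- sweep(tab, 1, pmax(1, rowSums(tab)), "/")
    M
  }
  M_ab <- project(model_a, model_b)
  M_ba <- project(model_b, model_a)
  link_df <- function(M, direction) {
    hit <- which(M > link_threshold, arr.ind = TRUE)
    if (nrow(hit) == 0)
      return(data.frame(direction = character(), from = character(),
                        to = character(), fraction = numeric()))
    data.frame(direction = direction,
               from = rownames(M)[hit[, 1]], to = colnames(M)[hit[, 2]],
               fraction = M[hit])
  }
  list(M_ab = M_ab, M_ba = M_ba,
       links = rbind(link_df(M_ab, "a_to_b"), link_df(M_ba, "b_to_a")),
       link_threshold = link_threshold)
}
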
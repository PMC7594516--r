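## Statistical object distance analysis (SODA).
##
## Given two channels of cluster centroids inside a region of interest,
## SODA bins all cross-channel centroid distances into concentric rings,
## compares the boundary-corrected ring counts (in Ripley K units) with
## their distribution under complete spatial randomness, keeps rings whose
## standardized excess exceeds a universal threshold, and converts the
## excess into a per-pair coupling probability: the estimated fraction of
## pairs in that distance ring that are not explained by chance.

#' Concentric ring set
#'
#' Defines the distance rings over which coupling is assessed: `n_rings`
#' annuli of width `ring_width` nm, radii r_i = i * ring_width. The
#' defaults (16 rings of 15 nm, maximal distance 240 nm) match a 15 nm
#' pixel acquisition and span beyond the largest distances reported
#' between synaptic scaffold proteins.
#'
#' @param n_rings number of rings.
#' @param ring_width ring width, nm.
#' @return object of class `soda_rings`.
#' @export
ring_set <- function(n_rings = 16L, ring_width = 15) {
  stopifnot(n_rings >= 1, ring_width > 0)
  structure(list(n_rings = as.integer(n_rings), ring_width = ring_width,
                 radii = (0:n_rings) * ring_width,
                 r_max = n_rings * ring_width),
            class = "soda_rings")
}

# ring index (1-based) of distances; ring i covers (r_{i-1}, r_i], with
# d = 0 assigned to ring 1. NA outside (0, r_max].
ring_of <- function(d, rings) {
  r <- pmax(1, ceiling(d / rings$ring_width))
  r[d > rings$r_max] <- NA_integer_
  as.integer(r)
}

#' Cross-channel candidate pairs within the ring span
#'
#' All channel-1 x channel-2 cluster pairs whose centroid distance is at
#' most the outer ring radius, annotated with the ring index. Uses a
#' uniform grid spatial index (cell size = maximal distance), with output
#' identical to exhaustive enumeration.
#'
#' @param clusters1,clusters2 data.frames with columns `id`, `x_nm`,
#'   `y_nm` (e.g. from [filter_and_label_clusters()]).
#' @param rings a [ring_set()].
#' @return data.frame `id1`, `id2`, `distance`, `ring`, ordered by
#'   (`id1`, `id2`).
#' @export
pairwise_candidate_distances <- function(clusters1, clusters2, rings) {
  r_max <- rings$r_max
  n1 <- nrow(clusters1); n2 <- nrow(clusters2)
  empty <- data.frame(id1 = integer(), id2 = integer(),
                      distance = numeric(), ring = integer())
  if (n1 == 0 || n2 == 0) return(empty)
  x1 <- clusters1$x_nm; y1 <- clusters1$y_nm
  x2 <- clusters2$x_nm; y2 <- clusters2$y_nm
  key <- function(x, y) {
    ci <- floor(x / r_max); cj <- floor(y / r_max)
    paste(ci, cj)
  }
  idx2 <- split(seq_len(n2), key(x2, y2))
  cells1 <- split(seq_len(n1), key(x1, y1))
  out <- vector("list", length(cells1))
  ptr <- 0L
  for (cell in names(cells1)) {
    i1 <- cells1[[cell]]
    cc <- as.numeric(strsplit(cell, " ")[[1]])
    nb_keys <- as.vector(outer(cc[1] + (-1:1), cc[2] + (-1:1), paste))
    i2 <- unlist(idx2[nb_keys], use.names = FALSE)
    if (is.null(i2) || length(i2) == 0) next
    dx <- outer(x1[i1], x2[i2], "-")
    dy <- outer(y1[i1], y2[i2], "-")
    d <- sqrt(dx^2 + dy^2)
    hit <- which(d <= r_max, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    ptr <- ptr + 1L
    out[[ptr]] <- data.frame(id1 = clusters1$id[i1[hit[, 1]]],
                             id2 = clusters2$id[i2[hit[, 2]]],
                             distance = d[hit])
  }
  if (ptr == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(ptr)])
  res <- res[order(res$id1, res$id2), , drop = FALSE]
  rownames(res) <- NULL
  res$ring <- ring_of(res$distance, rings)
  res
}

#' Boundary-correction weights
#'
#' Ripley-style edge correction: the weight of a pair is the reciprocal of
#' the fraction of the circle (centred on the channel-1 object, radius =
#' pair distance) that lies inside the region of interest, estimated by
#' sampling the circle at `n_angles` equally spaced angles. Pixels outside
#' the frame count as outside the ROI. Circles that provably lie entirely
#' inside the mask (via a precomputed interior depth map) are assigned
#' weight 1 without sampling; this is exact and independent of `n_angles`.
#' Weights are capped at `cap` to bound the variance contributed by
#' centroids in very thin processes.
#'
#' @param cx,cy circle centres, nm.
#' @param distance circle radii, nm (> 0; a radius of 0 gets weight 1).
#' @param mask `soda_mask` or logical matrix.
#' @param pixel_size nm per pixel.
#' @param n_angles number of equally spaced angles sampled.
#' @param cap maximal weight.
#' @param depth optional precomputed [mask_interior_depth()] of the mask.
#' @return numeric vector of weights (>= 1).
#' @export
edge_correction_weights <- function(cx, cy, distance, mask, pixel_size,
                                    n_angles = 64L, cap = 8,
                                    depth = NULL) {
  mask <- as_soda_mask(mask)$mask
  n <- length(cx)
  if (n == 0) return(numeric(0))
  stopifnot(length(cy) == n, length(distance) == n)
  if (is.null(depth)) depth <- mask_interior_depth(mask)
  w <- rep(1, n)
  col <- round(cx / pixel_size) + 1
  row <- round(cy / pixel_size) + 1
  inside_centre <- row >= 1 & row <= nrow(mask) & col >= 1 & col <= ncol(mask)
  if (!all(inside_centre)) stop("circle centre outside the image frame")
  d_px <- depth[cbind(row, col)]
  # chamfer distances err by < 9%; keep a conservative margin
  safe <- d_px >= distance / pixel_size * 1.09 + 2
  todo <- which(!safe & distance > 0)
  if (length(todo) > 0) {
    theta <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
    # chunk to bound memory at large pair counts
    chunk <- max(1L, floor(4e6 / n_angles))
    for (s in split(todo, ceiling(seq_along(todo) / chunk))) {
      # n_s x n_angles matrices of circle sample coordinates, nm
      px_x <- cx[s] + outer(distance[s], cos(theta))
      px_y <- cy[s] + outer(distance[s], sin(theta))
      cc <- round(px_x / pixel_size) + 1
      rr <- round(px_y / pixel_size) + 1
      ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
      ins <- matrix(FALSE, nrow(cc), ncol(cc))
      ins[ok] <- mask[cbind(rr[ok], cc[ok])]
      frac <- rowMeans(ins)
      if (any(frac == 0))
        stop("sampled circle entirely outside the ROI; increase n_angles ",
             "or check that centres lie inside the ROI")
      w[s] <- pmin(1 / frac, cap)
    }
  }
  w
}

#' Ring count vector G in Ripley K units
#'
#' K(r) = (ROI area / (n1 n2)) * sum over pairs with d <= r of the
#' boundary-correction weight; G_i = K(r_i) - K(r_{i-1}), i.e. the
#' weighted pair count of ring i scaled to K units. Under complete
#' spatial randomness E\[G_i\] = pi (r_i^2 - r_{i-1}^2).
#'
#' @param pairs data.frame from [pairwise_candidate_distances()].
#' @param weights boundary-correction weight per pair.
#' @param n1,n2 cluster counts of the two channels (> 0).
#' @param roi_area_nm2 foreground area in nm^2.
#' @param rings a [ring_set()].
#' @return numeric vector of length `n_rings`.
#' @export
compute_G_vector <- function(pairs, weights, n1, n2, roi_area_nm2, rings) {
  if (n1 <= 0 || n2 <= 0) stop("no clusters in channel")
  G <- numeric(rings$n_rings)
  if (nrow(pairs) > 0) {
    stopifnot(length(weights) == nrow(pairs))
    s <- tapply(weights, factor(pairs$ring, levels = seq_len(rings$n_rings)),
                sum)
    s[is.na(s)] <- 0
    G <- as.numeric(s) * roi_area_nm2 / (n1 * n2)
  }
  G
}

# One CSR draw of both channels over the mask + its G vector.
# Draw protocol (shared with the brute-force oracle in the test suite):
# channel 1 then channel 2, each: foreground pixel index sampled with
# replacement, then a uniform sub-pixel offset in each coordinate.
.csr_G_draw <- function(n1, n2, mask, pixel_size, rings, roi_area_nm2,
                        n_angles, cap, depth) {
  p1 <- sample_positions_in_mask(n1, mask, pixel_size)
  p2 <- sample_positions_in_mask(n2, mask, pixel_size)
  c1 <- data.frame(id = seq_len(n1), x_nm = p1[, 1], y_nm = p1[, 2])
  c2 <- data.frame(id = seq_len(n2), x_nm = p2[, 1], y_nm = p2[, 2])
  pr <- pairwise_candidate_distances(c1, c2, rings)
  w <- edge_correction_weights(c1$x_nm[match(pr$id1, c1$id)],
                               c1$y_nm[match(pr$id1, c1$id)],
                               pr$distance, mask, pixel_size,
                               n_angles, cap, depth)
  compute_G_vector(pr, w, n1, n2, roi_area_nm2, rings)
}

#' Null moments of the ring vector under complete spatial randomness
#'
#' Mean and standard deviation of each ring count G_i when both channels
#' are placed uniformly at random over the ROI (counts preserved). The
#' mean has the closed form mu_i = pi (r_i^2 - r_{i-1}^2) in K units
#' (`mode = "analytic"`); the standard deviation is always estimated by
#' Monte Carlo, as is the mean when `mode = "monte_carlo"`.
#'
#' @param rings a [ring_set()].
#' @param mask `soda_mask` or logical matrix (the ROI).
#' @param pixel_size nm per pixel.
#' @param n1,n2 cluster counts (>= 2).
#' @param mode `"analytic"` or `"monte_carlo"` for the mean.
#' @param n_reps Monte-Carlo redraws (>= 10).
#' @param seed integer seed.
#' @param n_angles,cap see [edge_correction_weights()].
#' @return list `mu`, `sigma`, and `G_null` (the n_reps x n_rings matrix
#'   of null draws, reusable for ring-correlation estimation).
#' @export
null_moments <- function(rings, mask, pixel_size, n1, n2,
                         mode = c("analytic", "monte_carlo"),
                         n_reps = 100L, seed = 1L,
                         n_angles = 64L, cap = 8) {
  mode <- match.arg(mode)
  if (n_reps < 10) stop("n_reps must be at least 10")
  if (n1 < 2 || n2 < 2) stop("need at least 2 clusters per channel")
  if (n1 + n2 <= 100)
    warning("fewer than 100 objects in total: normal approximation of the ",
            "ring counts may be poor")
  mask <- as_soda_mask(mask)
  roi_area <- mask$area_px * pixel_size^2
  depth <- mask_interior_depth(mask$mask)
  G_null <- with_seed(seed, {
    t(vapply(seq_len(n_reps), function(r)
      .csr_G_draw(n1, n2, mask$mask, pixel_size, rings, roi_area,
                  n_angles, cap, depth),
      numeric(rings$n_rings)))
  })
  mu_analytic <- pi * diff(rings$radii^2)
  mu <- if (mode == "analytic") mu_analytic else colMeans(G_null)
  sigma <- apply(G_null, 2, sd)
  if (any(sigma <= 0))
    sigma[sigma <= 0] <- .Machine$double.eps
  list(mu = mu, sigma = sigma, G_null = G_null)
}

#' Ring-overlap correction matrix from null draws
#'
#' Estimates the correlation structure of the ring counts under complete
#' spatial randomness. Rings are disjoint annuli so this is close to the
#' identity; the boundary correction and shared point positions induce
#' weak correlations that this matrix captures.
#'
#' @param G_null matrix of null ring vectors (draws x rings), e.g. from
#'   [null_moments()].
#' @return correlation matrix.
#' @export
ring_correlation <- function(G_null) {
  A <- stats::cor(G_null)
  A[!is.finite(A)] <- 0
  diag(A) <- 1
  A
}

#' Reduce and threshold the ring vector
#'
#' Computes the reduced (standardized) ring vector
#' G0 = diag(1/sigma) A^-1 (G - mu) and keeps only components strictly
#' greater than the universal threshold T(N) = 2 log(N) (natural log,
#' following the Donoho universal-threshold convention; T(16) ~ 5.545);
#' all other components are set to zero. With `a_method = "inv_sqrt"` the
#' correction is applied as A^-1/2 on the standardized vector
#' (a symmetric decorrelation appropriate when `A` is a correlation
#' matrix).
#'
#' @param G,mu,sigma numeric vectors of equal length.
#' @param A ring-overlap correction matrix, or `NULL` for the identity.
#' @param rings a [ring_set()] (stored in the result).
#' @param threshold significance threshold; default 2 log(n_rings).
#' @param a_method `"inverse"` (literal A^-1) or `"inv_sqrt"`.
#' @return object of class `soda_ripley`: list `G`, `mu`, `sigma`, `A`,
#'   `G0`, `threshold`, `rings`.
#' @export
reduce_and_threshold <- function(G, mu, sigma, A = NULL, rings = NULL,
                                 threshold = NULL,
                                 a_method = c("inverse", "inv_sqrt")) {
  a_method <- match.arg(a_method)
  N <- length(G)
  stopifnot(length(mu) == N, length(sigma) == N, all(sigma > 0))
  if (is.null(threshold)) threshold <- 2 * log(N)
  centred <- G - mu
  if (is.null(A)) {
    g0 <- centred / sigma
    A_used <- diag(N)
  } else {
    stopifnot(all(dim(A) == N))
    A_used <- A
    if (a_method == "inverse") {
      Ainv <- tryCatch(solve(A), error = function(e)
        stop("ring correction matrix is singular"))
      g0 <- as.numeric((1 / sigma) * (Ainv %*% centred))
    } else {
      eg <- eigen(A, symmetric = TRUE)
      if (any(eg$values <= 1e-10))
        stop("ring correction matrix is singular")
      Ainv_sqrt <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
      g0 <- as.numeric(Ainv_sqrt %*% (centred / sigma))
    }
  }
  g0[g0 <= threshold] <- 0
  structure(list(G = G, mu = mu, sigma = sigma, A = A_used, G0 = g0,
                 threshold = threshold, rings = rings),
            class = "soda_ripley")
}

#' Per-pair coupling probabilities
#'
#' For a pair whose distance falls in ring i,
#' P = sigma_i G0_i / G_i when ring i is significant (G0_i retained by the
#' threshold), else 0; clipped to \[0, 1\]. With an identity correction
#' matrix this is (G_i - mu_i) / G_i: the estimated fraction of ring-i
#' pairs in excess of chance. A pair with P > 0 is "coupled".
#'
#' @param stats a [reduce_and_threshold()] result.
#' @param pairs data.frame from [pairwise_candidate_distances()].
#' @return `pairs` with a `coupling_probability` column appended.
#' @export
pair_coupling_probability <- function(stats, pairs) {
  stopifnot(inherits(stats, "soda_ripley"))
  sig <- stats$G0 > 0
  if (any(sig & stats$G <= 0))
    stop("internal error: significant ring with zero observed count")
  P_ring <- ifelse(sig, pmin(1, pmax(0, stats$sigma * stats$G0 / stats$G)), 0)
  pairs$coupling_probability <- P_ring[pairs$ring]
  pairs
}

#' Summarize coupling at the cluster and image level
#'
#' Aggregates pair records to clusters: a cluster's coupling probability
#' is the maximum over its pairs (its coupling distance is the distance of
#' that maximal pair, nearest pair on ties) and a cluster is coupled when
#' any of its pairs has P > 0. Also reports the per-channel coupling index
#' (fraction of clusters coupled), the mean coupling probability per ring
#' across coupled pairs, and the mean coupling distance.
#'
#' @param records pair records with `coupling_probability` (from
#'   [pair_coupling_probability()]).
#' @param clusters1,clusters2 the cluster tables of both channels.
#' @param rings a [ring_set()].
#' @return object of class `soda_summary`.
#' @export
summarize_coupling <- function(records, clusters1, clusters2, rings) {
  per_cluster <- function(ids, channel, side) {
    id_col <- if (side == 1) "id1" else "id2"
    res <- data.frame(channel = channel, id = ids,
                      coupling_probability = 0, coupling_distance = NA_real_)
    if (nrow(records) > 0 && length(ids) > 0) {
      sp <- split(seq_len(nrow(records)), records[[id_col]])
      for (key in names(sp)) {
        rows <- sp[[key]]
        p <- records$coupling_probability[rows]
        best <- rows[p == max(p)]
        best <- best[which.min(records$distance[best])]
        i <- match(as.integer(key), ids)
        if (is.na(i)) next
        res$coupling_probability[i] <- records$coupling_probability[best]
        if (records$coupling_probability[best] > 0)
          res$coupling_distance[i] <- records$distance[best]
      }
    }
    res$coupled <- res$coupling_probability > 0
    res
  }
  t1 <- per_cluster(clusters1$id, 1L, 1)
  t2 <- per_cluster(clusters2$id, 2L, 2)
  coupled_pairs <- records[records$coupling_probability > 0, , drop = FALSE]
  ring_tab <- data.frame(
    ring = seq_len(rings$n_rings),
    r_lo = rings$radii[-length(rings$radii)],
    r_hi = rings$radii[-1],
    n_pairs = as.integer(table(factor(coupled_pairs$ring,
                                      levels = seq_len(rings$n_rings)))),
    mean_P = as.numeric(tapply(coupled_pairs$coupling_probability,
                               factor(coupled_pairs$ring,
                                      levels = seq_len(rings$n_rings)),
                               mean))
  )
  structure(list(
    cluster_table = rbind(t1, t2),
    coupling_index = c(ch1 = if (nrow(t1)) mean(t1$coupled) else 0,
                       ch2 = if (nrow(t2)) mean(t2$coupled) else 0),
    ring_probability = ring_tab,
    mean_coupling_distance = if (nrow(coupled_pairs))
      mean(coupled_pairs$distance) else NA_real_,
    n_coupled_pairs = nrow(coupled_pairs)
  ), class = "soda_summary")
}

#' @export
print.soda_summary <- function(x, ...) {
  cat("SODA coupling summary\n")
  cat(sprintf("  coupling index: ch1 %.3f, ch2 %.3f\n",
              x$coupling_index[1], x$coupling_index[2]))
  cat(sprintf("  coupled pairs: %d, mean coupling distance: %s nm\n",
              x$n_coupled_pairs,
              if (is.na(x$mean_coupling_distance)) "-" else
                sprintf("%.1f", x$mean_coupling_distance)))
  sig <- x$ring_probability[x$ring_probability$n_pairs > 0, ]
  if (nrow(sig)) {
    cat("  per-ring mean coupling probability (coupled pairs):\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    (%g, %g] nm: P = %.3f (n = %d)\n", sig$r_lo[i],
                  sig$r_hi[i], sig$mean_P[i], sig$n_pairs[i]))
  }
  invisible(x)
}

#' Run the full SODA analysis on two cluster sets
#'
#' Candidate pairs, boundary-corrected ring counts, Monte-Carlo null
#' moments, reduction and thresholding, per-pair coupling probabilities
#' and the cluster/image level summary, in one call.
#'
#' @param clusters1,clusters2 cluster tables with `id`, `x_nm`, `y_nm`.
#' @param mask ROI mask (`soda_mask` or logical matrix).
#' @param pixel_size nm per pixel.
#' @param rings a [ring_set()].
#' @param mu_mode `"analytic"` (closed-form mean) or `"monte_carlo"`.
#' @param a_method `"identity"` (rings treated as independent),
#'   `"mc_correlation"` (correction matrix estimated from the null draws,
#'   applied as an inverse square root).
#' @param n_reps null Monte-Carlo redraws.
#' @param seed integer seed for the null draws.
#' @param n_angles,edge_cap see [edge_correction_weights()].
#' @param threshold significance threshold, default 2 log(n_rings).
#' @return list with `stats` (`soda_ripley`), `pairs` (pair records with
#'   coupling probabilities), `summary` (`soda_summary`), `rings`,
#'   and `params`.
#' @export
soda_analysis <- function(clusters1, clusters2, mask, pixel_size,
                          rings = ring_set(),
                          mu_mode = c("analytic", "monte_carlo"),
                          a_method = c("identity", "mc_correlation"),
                          n_reps = 100L, seed = 1L, n_angles = 64L,
                          edge_cap = 8, threshold = NULL) {
  mu_mode <- match.arg(mu_mode)
  a_method <- match.arg(a_method)
  n1 <- nrow(clusters1); n2 <- nrow(clusters2)
  if (n1 == 0 || n2 == 0) stop("no clusters in channel")
  mask <- as_soda_mask(mask)
  roi_area <- mask$area_px * pixel_size^2
  depth <- mask_interior_depth(mask$mask)
  pairs <- pairwise_candidate_distances(clusters1, clusters2, rings)
  w <- edge_correction_weights(clusters1$x_nm[match(pairs$id1, clusters1$id)],
                               clusters1$y_nm[match(pairs$id1, clusters1$id)],
                               pairs$distance, mask, pixel_size,
                               n_angles, edge_cap, depth)
  G <- compute_G_vector(pairs, w, n1, n2, roi_area, rings)
  nm <- null_moments(rings, mask, pixel_size, n1, n2,
                     mode = mu_mode, n_reps = n_reps, seed = seed,
                     n_angles = n_angles, cap = edge_cap)
  A <- if (a_method == "mc_correlation") ring_correlation(nm$G_null) else NULL
  stats <- reduce_and_threshold(G, nm$mu, nm$sigma, A, rings, threshold,
                                a_method = "inv_sqrt")
  records <- pair_coupling_probability(stats, pairs)
  summary <- summarize_coupling(records, clusters1, clusters2, rings)
  list(stats = stats, pairs = records, summary = summary, rings = rings,
       params = list(pixel_size = pixel_size, mu_mode = mu_mode,
                     a_method = a_method, n_reps = n_reps, seed = seed,
                     n_angles = n_angles, edge_cap = edge_cap,
                     threshold = stats$threshold))
}
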
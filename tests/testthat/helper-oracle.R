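# Independent brute-force SODA oracle.
#
# Deliberately avoids the package's spatial index, interior-depth shortcut
# and vectorized weight code: exhaustive O(n1 n2) pair enumeration,
# per-pair angle-sampled edge weights, and its own reduction/threshold
# arithmetic. The null-draw protocol (pixel index + sub-pixel jitter,
# channel 1 then channel 2 per rep) matches the package's documented
# protocol so that seeded null moments are comparable.

oracle_pairs <- function(c1, c2, r_max, ring_width) {
  out <- NULL
  for (i in seq_len(nrow(c1))) {
    for (j in seq_len(nrow(c2))) {
      d <- sqrt((c1$x_nm[i] - c2$x_nm[j])^2 + (c1$y_nm[i] - c2$y_nm[j])^2)
      if (d <= r_max) {
        ring <- max(1, ceiling(d / ring_width))
        out <- rbind(out, data.frame(id1 = c1$id[i], id2 = c2$id[j],
                                     distance = d, ring = ring))
      }
    }
  }
  if (is.null(out))
    return(data.frame(id1 = integer(), id2 = integer(),
                      distance = numeric(), ring = integer()))
  out[order(out$id1, out$id2), , drop = FALSE]
}

oracle_weight_one <- function(cx, cy, r, mask, pixel_size, n_angles, cap) {
  if (r <= 0) return(1)
  inside <- 0L
  for (a in seq_len(n_angles)) {
    th <- 2 * pi * (a - 1) / n_angles
    col <- round((cx + r * cos(th)) / pixel_size) + 1
    row <- round((cy + r * sin(th)) / pixel_size) + 1
    if (row >= 1 && row <= nrow(mask) && col >= 1 && col <= ncol(mask) &&
        mask[row, col]) inside <- inside + 1L
  }
  if (inside == 0) stop("oracle: circle entirely outside ROI")
  min(n_angles / inside, cap)
}

oracle_G <- function(c1, c2, mask, pixel_size, rings, n_angles, cap) {
  pr <- oracle_pairs(c1, c2, rings$r_max, rings$ring_width)
  G <- numeric(rings$n_rings)
  area <- sum(mask) * pixel_size^2
  if (nrow(pr) > 0) {
    for (k in seq_len(nrow(pr))) {
      i <- match(pr$id1[k], c1$id)
      w <- oracle_weight_one(c1$x_nm[i], c1$y_nm[i], pr$distance[k], mask,
                             pixel_size, n_angles, cap)
      G[pr$ring[k]] <- G[pr$ring[k]] + w
    }
    G <- G * area / (nrow(c1) * nrow(c2))
  }
  G
}

# same draw protocol as the package: per rep, channel1 then channel2;
# each draw = pixel index then runif x offsets then runif y offsets
oracle_null <- function(rings, mask, pixel_size, n1, n2, n_reps, seed,
                        n_angles, cap) {
  fg <- which(mask)
  draw <- function(n) {
    idx <- fg[sample.int(length(fg), n, replace = TRUE)]
    rows <- ((idx - 1L) %% nrow(mask)) + 1L
    cols <- ((idx - 1L) %/% nrow(mask)) + 1L
    x <- (cols - 1 + runif(n, -0.5, 0.5)) * pixel_size
    y <- (rows - 1 + runif(n, -0.5, 0.5)) * pixel_size
    cluster_table(x, y)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  Gs <- matrix(0, n_reps, rings$n_rings)
  for (r in seq_len(n_reps)) {
    c1 <- draw(n1)
    c2 <- draw(n2)
    Gs[r, ] <- oracle_G(c1, c2, mask, pixel_size, rings, n_angles, cap)
  }
  list(mu = colMeans(Gs), sigma = apply(Gs, 2, sd), G_null = Gs)
}

oracle_soda <- function(c1, c2, mask, pixel_size, rings, n_reps, seed,
                        n_angles, cap) {
  G <- oracle_G(c1, c2, mask, pixel_size, rings, n_angles, cap)
  nl <- oracle_null(rings, mask, pixel_size, nrow(c1), nrow(c2), n_reps,
                    seed, n_angles, cap)
  N <- rings$n_rings
  thr <- 2 * log(N)
  mu <- pi * diff(rings$radii^2)          # analytic mode
  g0 <- (G - mu) / nl$sigma
  g0[g0 <= thr] <- 0
  P_ring <- ifelse(g0 > 0, pmin(1, pmax(0, nl$sigma * g0 / G)), 0)
  pr <- oracle_pairs(c1, c2, rings$r_max, rings$ring_width)
  pr$coupling_probability <- P_ring[pr$ring]
  list(G = G, mu = mu, sigma = nl$sigma, G0 = g0, pairs = pr)
}
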
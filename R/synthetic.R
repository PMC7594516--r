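## Synthetic two-channel nanoscopy data with known ground truth.
##
## The generator emulates sparse elliptical fluorescent clusters on a
## dendrite-shaped region, imaged at 15 nm pixels with a ~70 nm FWHM point
## spread function and photon-counting (Poisson) noise. A controllable
## fraction f of channel-1 clusters receives a channel-2 partner at a
## controllable centroid offset; all remaining clusters are placed by
## complete spatial randomness (CSR) over the region of interest.

#' Simulation configuration
#'
#' Collects all parameters of the synthetic image generator. Positions and
#' distances are in nm throughout; images are in photon counts.
#'
#' @param image_shape integer c(rows, cols) in pixels.
#' @param pixel_size pixel size in nm (15 for the targeted acquisitions).
#' @param psf_fwhm point-spread-function FWHM in nm, one value per channel
#'   (recycled if scalar).
#' @param n_clusters_ch1,n_clusters_ch2 cluster counts per channel.
#' @param coupling_fraction fraction f in \[0, 1\] of channel-1 clusters
#'   given a channel-2 partner.
#' @param coupling_distance_mean,coupling_distance_sd centroid offset of
#'   coupled pairs, nm. Offset lengths are drawn from a Normal truncated at
#'   zero with uniform random direction (`offset_model = "radial_normal"`),
#'   or each coordinate receives independent Normal(0, sd) jitter
#'   (`offset_model = "gaussian_xy"`, emulating pure localization error of
#'   a dual-labelled epitope; the mean is ignored in that model).
#' @param offset_model `"radial_normal"` or `"gaussian_xy"`.
#' @param cluster_area_range pre-PSF cluster area range, nm^2.
#' @param cluster_eccentricity_range eccentricity range of the elliptical
#'   clusters, in \[0, 1).
#' @param photon_scale expected peak photon count of a cluster.
#' @param background_rate Poisson background, counts per pixel.
#' @param roi_style `"full"` or `"dendrite_band"`.
#' @param seed integer seed; every derived draw is deterministic in it.
#' @return object of class `soda_sim_config`.
#' @export
simulation_config <- function(image_shape = c(1024L, 1024L),
                              pixel_size = 15,
                              psf_fwhm = c(70, 70),
                              n_clusters_ch1 = 300L,
                              n_clusters_ch2 = 300L,
                              coupling_fraction = 0,
                              coupling_distance_mean = 45,
                              coupling_distance_sd = 5,
                              offset_model = c("radial_normal", "gaussian_xy"),
                              cluster_area_range = c(2000, 20000),
                              cluster_eccentricity_range = c(0, 0.9),
                              photon_scale = 500,
                              background_rate = 0.5,
                              roi_style = c("dendrite_band", "full"),
                              seed = 1L) {
  offset_model <- match.arg(offset_model)
  roi_style <- match.arg(roi_style)
  if (length(psf_fwhm) == 1) psf_fwhm <- rep(psf_fwhm, 2)
  if (coupling_fraction < 0 || coupling_fraction > 1)
    stop("coupling_fraction must be in [0, 1]")
  if (n_clusters_ch1 < 0 || n_clusters_ch2 < 0) stop("cluster counts must be >= 0")
  if (coupling_distance_mean < 0) stop("coupling_distance_mean must be >= 0")
  if (any(psf_fwhm <= pixel_size))
    stop("psf_fwhm must exceed pixel_size (undersampled PSF)")
  structure(list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    psf_fwhm = psf_fwhm, n_clusters_ch1 = as.integer(n_clusters_ch1),
    n_clusters_ch2 = as.integer(n_clusters_ch2),
    coupling_fraction = coupling_fraction,
    coupling_distance_mean = coupling_distance_mean,
    coupling_distance_sd = coupling_distance_sd,
    offset_model = offset_model,
    cluster_area_range = cluster_area_range,
    cluster_eccentricity_range = cluster_eccentricity_range,
    photon_scale = photon_scale, background_rate = background_rate,
    roi_style = roi_style, seed = as.integer(seed)
  ), class = "soda_sim_config")
}

#' Generate a region-of-interest mask
#'
#' `"full"` returns an all-ones mask. `"dendrite_band"` draws a smooth
#' curved band (a random-phase sinusoid mixture for the centreline and a
#' slowly varying half-width) with blob-like protrusions, emulating a
#' dendrite with spines.
#'
#' @param shape integer c(rows, cols), each >= 64.
#' @param style `"full"` or `"dendrite_band"`.
#' @param seed integer seed.
#' @return logical matrix.
#' @export
generate_roi_mask <- function(shape, style = c("dendrite_band", "full"),
                              seed = 1L) {
  style <- match.arg(style)
  shape <- as.integer(shape)
  if (any(shape < 64))
    stop("image shape must be at least 64x64 pixels, got ",
         paste(shape, collapse = "x"))
  h <- shape[1]; w <- shape[2]
  if (style == "full") return(matrix(TRUE, h, w))
  with_seed(seed, {
    x <- seq_len(w)
    # centreline: mixture of 2-3 low-frequency sinusoids across the frame
    nwave <- sample(2:3, 1)
    centre <- rep(h / 2, w)
    for (i in seq_len(nwave)) {
      centre <- centre + (h * runif(1, 0.04, 0.12)) *
        sin(2 * pi * runif(1, 0.5, 1.5) * x / w + runif(1, 0, 2 * pi))
    }
    # half-width: slowly varying around ~16% of the frame height
    half <- h * 0.16 * (1 + 0.3 * sin(2 * pi * x / w + runif(1, 0, 2 * pi)))
    rows <- matrix(seq_len(h), h, w)
    mask <- abs(rows - matrix(centre, h, w, byrow = TRUE)) <=
      matrix(half, h, w, byrow = TRUE)
    # protrusions: small discs touching the band edge (spine-like)
    n_prot <- max(4L, round(w / 110))
    for (i in seq_len(n_prot)) {
      cx <- sample.int(w, 1)
      side <- sample(c(-1, 1), 1)
      cy <- centre[cx] + side * half[cx]
      r <- runif(1, 0.02, 0.045) * h
      rr <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
      ccol <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
      sub <- outer(rr, ccol, function(a, b) (a - cy)^2 + (b - cx)^2 <= r^2)
      mask[rr, ccol] <- mask[rr, ccol] | sub
    }
    frac <- mean(mask)
    stopifnot(frac > 0)
    mask
  })
}

# Draw n points uniformly over the foreground of a pixel mask, continuous
# within pixels. Returns a 2-column matrix (x_nm, y_nm).
sample_positions_in_mask <- function(n, mask, pixel_size) {
  fg <- which(mask)
  if (length(fg) == 0) stop("mask has no foreground")
  idx <- fg[sample.int(length(fg), n, replace = TRUE)]
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  cbind(x_nm = (cols - 1 + runif(n, -0.5, 0.5)) * pixel_size,
        y_nm = (rows - 1 + runif(n, -0.5, 0.5)) * pixel_size)
}

#' Simulate ground-truth cluster positions for two channels
#'
#' Channel-1 centroids are uniform over the ROI. A fraction
#' `coupling_fraction` of them receives a channel-2 partner displaced
#' according to the configured offset model; the remaining channel-2
#' centroids are uniform over the ROI (CSR). Deterministic given the
#' config seed.
#'
#' @param config a [simulation_config()].
#' @return object of class `soda_ground_truth`: list with `positions_ch1`,
#'   `positions_ch2` (matrices of x_nm, y_nm), `coupled_pairs` (data.frame
#'   `id1`, `id2`, `offset_nm`), `roi_mask`, and the config.
#' @export
simulate_cluster_pairs <- function(config) {
  stopifnot(inherits(config, "soda_sim_config"))
  mask <- generate_roi_mask(config$image_shape, config$roi_style, config$seed)
  with_seed(config$seed + 1L, {
    n1 <- config$n_clusters_ch1; n2 <- config$n_clusters_ch2
    p1 <- sample_positions_in_mask(n1, mask, config$pixel_size)
    n_pairs <- min(round(config$coupling_fraction * n1), n2)
    pairs <- data.frame(id1 = integer(), id2 = integer(), offset_nm = numeric())
    p2 <- matrix(numeric(0), ncol = 2)
    if (n_pairs > 0) {
      partners <- matrix(NA_real_, n_pairs, 2)
      offs <- numeric(n_pairs)
      for (i in seq_len(n_pairs)) {
        repeat {
          if (config$offset_model == "gaussian_xy") {
            dxy <- rnorm(2, 0, config$coupling_distance_sd)
          } else {
            len <- rnorm(1, config$coupling_distance_mean,
                         config$coupling_distance_sd)
            while (len < 0) len <- rnorm(1, config$coupling_distance_mean,
                                         config$coupling_distance_sd)
            ang <- runif(1, 0, 2 * pi)
            dxy <- len * c(cos(ang), sin(ang))
          }
          cand <- p1[i, ] + dxy
          if (point_in_mask(cand[1], cand[2], mask, config$pixel_size)) {
            partners[i, ] <- cand
            offs[i] <- sqrt(sum(dxy^2))
            break
          }
        }
      }
      pairs <- data.frame(id1 = seq_len(n_pairs), id2 = seq_len(n_pairs),
                          offset_nm = offs)
      p2 <- partners
    }
    n_free <- n2 - n_pairs
    if (n_free > 0)
      p2 <- rbind(p2, sample_positions_in_mask(n_free, mask, config$pixel_size))
    colnames(p2) <- c("x_nm", "y_nm")
    structure(list(positions_ch1 = p1, positions_ch2 = p2,
                   coupled_pairs = pairs, roi_mask = mask, config = config),
              class = "soda_ground_truth")
  })
}

# TRUE if the nm position falls on a foreground pixel of the mask.
point_in_mask <- function(x_nm, y_nm, mask, pixel_size) {
  col <- round(x_nm / pixel_size) + 1
  row <- round(y_nm / pixel_size) + 1
  ok <- row >= 1 & row <= nrow(mask) & col >= 1 & col <= ncol(mask)
  out <- logical(length(x_nm))
  out[ok] <- mask[cbind(row[ok], col[ok])]
  out
}

#' Render a two-channel image pair from ground truth
#'
#' Each cluster becomes an anisotropic Gaussian blob (area and eccentricity
#' drawn from the config ranges, random orientation) convolved with the
#' channel PSF; Poisson noise is applied to signal plus background.
#'
#' @param truth a [simulate_cluster_pairs()] result.
#' @param config the same [simulation_config()].
#' @param noise set `FALSE` for noise-free expectation images.
#' @return list `ch1`, `ch2`: numeric count matrices.
#' @export
render_image_pair <- function(truth, config = truth$config, noise = TRUE) {
  stopifnot(inherits(truth, "soda_ground_truth"))
  h <- config$image_shape[1]; w <- config$image_shape[2]
  px <- config$pixel_size
  render <- function(pos, fwhm, subseed) {
    img <- matrix(0, h, w)
    if (nrow(pos) > 0) with_seed(subseed, {
      sigma_psf <- fwhm / (2 * sqrt(2 * log(2)))
      n <- nrow(pos)
      areas <- runif(n, config$cluster_area_range[1], config$cluster_area_range[2])
      eccs <- runif(n, config$cluster_eccentricity_range[1],
                    config$cluster_eccentricity_range[2])
      thetas <- runif(n, 0, pi)
      amps <- config$photon_scale * runif(n, 0.5, 1.5)
      for (i in seq_len(n)) {
        # ellipse semi-axes a >= b with pi*a*b = area, ecc = sqrt(1-b^2/a^2)
        ratio <- sqrt(1 - eccs[i]^2)             # b / a
        a <- sqrt(areas[i] / (pi * ratio))
        b <- a * ratio
        # cluster rendered as Gaussian with sd = semi-axis / 2, plus PSF
        sx <- sqrt((a / 2)^2 + sigma_psf^2)
        sy <- sqrt((b / 2)^2 + sigma_psf^2)
        ct <- cos(thetas[i]); st <- sin(thetas[i])
        r_ext <- ceiling(3.5 * max(sx, sy) / px)
        cx <- pos[i, 1] / px + 1; cy <- pos[i, 2] / px + 1
        ccol <- max(1, floor(cx - r_ext)):min(w, ceiling(cx + r_ext))
        rrow <- max(1, floor(cy - r_ext)):min(h, ceiling(cy + r_ext))
        if (length(ccol) == 0 || length(rrow) == 0) next
        dx <- outer(rep(1, length(rrow)), (ccol - cx) * px)
        dy <- outer((rrow - cy) * px, rep(1, length(ccol)))
        u <- dx * ct + dy * st
        v <- -dx * st + dy * ct
        img[rrow, ccol] <- img[rrow, ccol] +
          amps[i] * exp(-0.5 * ((u / sx)^2 + (v / sy)^2))
      }
    })
    img <- img + config$background_rate
    if (noise) with_seed(subseed + 7919L, {
      img <- matrix(rpois(length(img), lambda = img), h, w)
    })
    img
  }
  list(ch1 = render(truth$positions_ch1, config$psf_fwhm[1], config$seed + 101L),
       ch2 = render(truth$positions_ch2, config$psf_fwhm[2], config$seed + 202L))
}

#' Simulate Gaussian feature blobs in the 7-D feature space
#'
#' Test bed for the subtype-discovery chain: `k` spherical Gaussian blobs
#' in \[0, 1\]^7 whose centres are at least `separation` apart.
#'
#' @param k number of blobs (>= 2).
#' @param n_per_group points per blob.
#' @param separation minimum pairwise centre distance in scaled space.
#' @param sd within-blob standard deviation per dimension.
#' @param seed integer seed.
#' @return list `features` (matrix, columns named as the 7 cluster
#'   features), `labels` (true blob of each row).
#' @export
simulate_feature_blobs <- function(k, n_per_group = 100L, separation = 0.5,
                                   sd = 0.025, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  with_seed(seed, {
    centres <- matrix(runif(7), 1)
    tries <- 0
    while (nrow(centres) < k) {
      cand <- runif(7)
      if (min(sqrt(colSums((t(centres) - cand)^2))) >= separation)
        centres <- rbind(centres, cand)
      tries <- tries + 1
      if (tries > 20000)
        stop("could not place ", k, " centres at separation ", separation)
    }
    feats <- do.call(rbind, lapply(seq_len(k), function(g) {
      matrix(rnorm(7 * n_per_group, mean = rep(centres[g, ], each = n_per_group),
                   sd = sd), n_per_group, 7)
    }))
    colnames(feats) <- c("area", "eccentricity", "perimeter",
                         "major_axis_length", "minor_axis_length",
                         "coupling_distance", "coupling_probability")
    list(features = feats, labels = rep(seq_len(k), each = n_per_group),
         centres = centres)
  })
}

#' Write ground truth to CSV
#'
#' One row per cluster: `channel`, `id`, `x_nm`, `y_nm`, `partner_id`
#' (NA when unpaired), `offset_nm`.
#'
#' @param truth a [simulate_cluster_pairs()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  p1 <- truth$positions_ch1; p2 <- truth$positions_ch2
  pair <- truth$coupled_pairs
  d1 <- data.frame(channel = 1L, id = seq_len(nrow(p1)),
                   x_nm = p1[, 1], y_nm = p1[, 2],
                   partner_id = NA_integer_, offset_nm = NA_real_)
  d2 <- data.frame(channel = 2L, id = seq_len(nrow(p2)),
                   x_nm = p2[, 1], y_nm = p2[, 2],
                   partner_id = NA_integer_, offset_nm = NA_real_)
  if (nrow(pair) > 0) {
    d1$partner_id[pair$id1] <- pair$id2
    d1$offset_nm[pair$id1] <- pair$offset_nm
    d2$partner_id[pair$id2] <- pair$id1
    d2$offset_nm[pair$id2] <- pair$offset_nm
  }
  out <- rbind(d1, d2)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
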
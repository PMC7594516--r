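## Segmentation of raw two-channel STED-class images into filtered,
## feature-annotated cluster records.
##
## Pipeline: foreground mask from the blurred channel sum; per-channel
## a-trous wavelet spot detection; size/extent filtering; weighted
## centroids computed on the raw image; morphological features from the
## pixel support. All physical quantities are nm or um as documented.

#' Compute the foreground mask of an image pair
#'
#' Gaussian-blurs the sum of both channels (default sd 10 px) and
#' thresholds at a fraction (default 50%) of the mean intensity of the
#' blurred frame.
#'
#' @param ch1,ch2 numeric count matrices of equal shape.
#' @param blur_sd blur standard deviation in pixels.
#' @param threshold_fraction threshold as a fraction of the blurred mean.
#' @return object of class `soda_mask`: list with `mask` (logical matrix)
#'   and `area_px`.
#' @export
compute_foreground_mask <- function(ch1, ch2, blur_sd = 10,
                                    threshold_fraction = 0.5) {
  stopifnot(is.matrix(ch1), all(dim(ch1) == dim(ch2)))
  total <- ch1 + ch2
  if (all(total == 0)) {
    warning("all-zero input images: foreground mask is empty")
    mask <- matrix(FALSE, nrow(ch1), ncol(ch1))
  } else {
    blurred <- gaussian_blur(total, blur_sd)
    mask <- blurred > threshold_fraction * mean(blurred)
  }
  structure(list(mask = mask, area_px = sum(mask)), class = "soda_mask")
}

as_soda_mask <- function(mask) {
  if (inherits(mask, "soda_mask")) return(mask)
  if (!is.logical(mask)) mask <- mask > 0
  structure(list(mask = mask, area_px = sum(mask)), class = "soda_mask")
}

#' A-trous wavelet spot detection
#'
#' Undecimated B3-spline wavelet decomposition; each requested detail
#' plane is hard-thresholded at `k_mad` times its robust noise scale
#' (median absolute deviation / 0.6745), and a pixel is detected when it
#' is significant in every requested plane (intersection).
#'
#' @param image numeric count matrix, at least `2^max(scales)` pixels in
#'   each dimension.
#' @param scales integer wavelet scales to combine (default 3 and 4,
#'   suppressing small low-intensity speckle while keeping ~70 nm spots).
#' @param k_mad threshold multiplier.
#' @return logical detection matrix.
#' @export
wavelet_spot_detection <- function(image, scales = c(3L, 4L), k_mad = 2.0) {
  stopifnot(is.matrix(image))
  need <- 2^max(scales)
  if (any(dim(image) < need))
    stop("image must be at least ", need, " pixels in each dimension for scale ",
         max(scales))
  planes <- atrous_planes(image, max(scales))
  det <- matrix(TRUE, nrow(image), ncol(image))
  for (j in scales) {
    w <- planes[[j]]
    noise <- mad(w)  # 1.4826 * median(|w - median(w)|)
    det <- det & (w > k_mad * noise)
  }
  det
}

#' Filter and label detected clusters
#'
#' Removes components with area below `min_area_px` or bounding-box width
#' or height below `min_extent_px`, and components whose intensity-weighted
#' centroid (computed on the raw image) falls outside the foreground mask.
#'
#' @param detection logical detection matrix (from
#'   [wavelet_spot_detection()]).
#' @param mask `soda_mask` (or logical matrix) of the foreground.
#' @param raw raw count matrix the weighted centroids are computed on.
#' @param pixel_size nm per pixel.
#' @param channel channel id stored in the records.
#' @param min_area_px minimum component area, pixels.
#' @param min_extent_px minimum bounding-box width and height, pixels.
#' @return data.frame of cluster records (class `soda_clusters`): `id`,
#'   `channel`, `x_nm`, `y_nm` (weighted centroid), `area_um2`,
#'   `eccentricity`, `perimeter_um`, `major_axis_um`, `minor_axis_um`,
#'   `total_intensity`, `area_px`, `bbox_w`, `bbox_h`, with the label image
#'   in attribute `labels`.
#' @export
filter_and_label_clusters <- function(detection, mask, raw, pixel_size,
                                      channel = 1L, min_area_px = 5L,
                                      min_extent_px = 3L) {
  mask <- as_soda_mask(mask)
  stopifnot(all(dim(detection) == dim(raw)),
            all(dim(detection) == dim(mask$mask)))
  labels <- label_components(detection)
  props <- region_props(labels, raw)
  keep <- props$area_px >= min_area_px &
    props$bbox_w >= min_extent_px & props$bbox_h >= min_extent_px
  props <- props[keep, , drop = FALSE]
  if (nrow(props) > 0) {
    inside <- point_in_mask((props$xc_px - 1) * pixel_size,
                            (props$yc_px - 1) * pixel_size,
                            mask$mask, pixel_size)
    props <- props[inside, , drop = FALSE]
  }
  # zero out discarded labels in the label image, renumber survivors
  relabel <- integer(max(labels, 1L))
  if (nrow(props) > 0) relabel[props$label] <- seq_len(nrow(props))
  lab_img <- labels
  lab_img[labels > 0] <- relabel[labels[labels > 0]]
  um <- pixel_size / 1000
  out <- data.frame(
    id = seq_len(nrow(props)),
    channel = rep(as.integer(channel), nrow(props)),
    x_nm = (props$xc_px - 1) * pixel_size,
    y_nm = (props$yc_px - 1) * pixel_size,
    area_um2 = props$area_px * um^2,
    eccentricity = props$eccentricity,
    perimeter_um = props$perimeter_px * um,
    major_axis_um = props$major_px * um,
    minor_axis_um = props$minor_px * um,
    total_intensity = props$total_intensity,
    area_px = props$area_px,
    bbox_w = props$bbox_w,
    bbox_h = props$bbox_h
  )
  class(out) <- c("soda_clusters", "data.frame")
  attr(out, "labels") <- lab_img
  attr(out, "pixel_size") <- pixel_size
  out
}

#' Segment one channel of a raw image
#'
#' Convenience wrapper: wavelet detection, then filtering and labelling
#' against a foreground mask.
#'
#' @inheritParams filter_and_label_clusters
#' @inheritParams wavelet_spot_detection
#' @param image raw count matrix.
#' @return see [filter_and_label_clusters()].
#' @export
segment_channel <- function(image, mask, pixel_size, channel = 1L,
                            scales = c(3L, 4L), k_mad = 2.0,
                            min_area_px = 5L, min_extent_px = 3L) {
  det <- wavelet_spot_detection(image, scales, k_mad)
  filter_and_label_clusters(det, mask, image, pixel_size, channel,
                            min_area_px, min_extent_px)
}

#' Morphological features of one labelled cluster
#'
#' Area, eccentricity, perimeter and axis lengths from the unweighted
#' second central moments of the pixel support, in physical units.
#' Primarily useful for ad-hoc supports; [filter_and_label_clusters()]
#' computes the same quantities for whole images.
#'
#' @param rows,cols pixel coordinates of the support.
#' @param intensities raw intensities of those pixels.
#' @param pixel_size nm per pixel.
#' @return one-row data.frame with the feature columns of
#'   [filter_and_label_clusters()].
#' @export
compute_cluster_features <- function(rows, cols, intensities, pixel_size) {
  stopifnot(length(rows) > 0, length(rows) == length(cols),
            length(rows) == length(intensities))
  lab <- matrix(0L, max(rows) + 1L, max(cols) + 1L)
  raw <- matrix(0, max(rows) + 1L, max(cols) + 1L)
  lab[cbind(rows, cols)] <- 1L
  raw[cbind(rows, cols)] <- intensities
  p <- region_props(lab, raw)
  um <- pixel_size / 1000
  data.frame(area_um2 = p$area_px * um^2, eccentricity = p$eccentricity,
             perimeter_um = p$perimeter_px * um,
             major_axis_um = p$major_px * um,
             minor_axis_um = p$minor_px * um,
             x_nm = (p$xc_px - 1) * pixel_size,
             y_nm = (p$yc_px - 1) * pixel_size,
             total_intensity = p$total_intensity)
}

#' Localization error of a weighted centroid
#'
#' Propagates an independent relative uncertainty on each pixel's photon
#' count (0.5% for the targeted photon-counting detectors) through the
#' intensity-weighted centroid. For centroid x = sum(I_i x_i) / sum(I_i),
#' d x / d I_j = (x_j - x) / sum(I), so
#' var(x) = sum(((x_j - x) / S)^2 (u I_j)^2). The returned error is the
#' quadrature sum of the x and y components, in nm.
#'
#' @param rows,cols pixel coordinates of the support.
#' @param intensities raw counts (must not be all zero).
#' @param pixel_size nm per pixel.
#' @param count_uncertainty relative count uncertainty per pixel.
#' @return localization error, nm.
#' @export
estimate_localization_error <- function(rows, cols, intensities, pixel_size,
                                        count_uncertainty = 0.005) {
  s <- sum(intensities)
  if (s <= 0) stop("total intensity must be positive")
  x <- (cols - 1) * pixel_size
  y <- (rows - 1) * pixel_size
  xc <- sum(intensities * x) / s
  yc <- sum(intensities * y) / s
  vx <- sum(((x - xc) / s)^2 * (count_uncertainty * intensities)^2)
  vy <- sum(((y - yc) / s)^2 * (count_uncertainty * intensities)^2)
  sqrt(vx + vy)
}

#' Lorentzian FWHM of a line profile
#'
#' Least-squares fit of amplitude, centre, half-width gamma and offset of
#' a Lorentzian A / (1 + ((x - x0)/gamma)^2) + b to a 1-D intensity
#' profile; the full width at half maximum is 2 * gamma * pixel_size.
#' Used for resolution quality control on isolated spots.
#'
#' @param profile numeric vector with a single dominant peak.
#' @param pixel_size nm per pixel.
#' @return list `fwhm_nm`, `gamma_px`, `center_px`, `fit` (the nls object).
#' @export
fit_fwhm_line_profile <- function(profile, pixel_size) {
  stopifnot(length(profile) >= 5)
  x <- seq_along(profile)
  b0 <- min(profile)
  a0 <- max(profile) - b0
  if (a0 <= 0) stop("profile is flat: no peak to fit")
  x0 <- x[which.max(profile)]
  above <- which(profile - b0 > a0 / 2)
  g0 <- max(1, (max(above) - min(above)) / 2)
  fit <- tryCatch(
    nls(profile ~ A / (1 + ((x - x0) / g)^2) + b,
        start = list(A = a0, x0 = x0, g = g0, b = b0),
        # scaleOffset makes the convergence test robust to the
        # zero-residual (noise-free) case
        control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) {
      stop("Lorentzian fit did not converge: ", conditionMessage(e),
           " (residual sd of flat model: ", signif(sd(profile), 4), ")")
    })
  g <- abs(coef(fit)[["g"]])
  list(fwhm_nm = 2 * g * pixel_size, gamma_px = g,
       center_px = coef(fit)[["x0"]], fit = fit)
}
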
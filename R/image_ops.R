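## Low-level image operations shared by the segmentation and simulation
## modules. Images are numeric matrices; coordinates follow the package
## convention x = column, y = row, origin at the centre of pixel [1, 1],
## physical position (nm) = (index - 1) * pixel_size.

#' Gaussian blur of an image
#'
#' Separable Gaussian convolution with reflective boundaries. The kernel is
#' truncated at 4 standard deviations.
#'
#' @param image numeric matrix.
#' @param sd standard deviation in pixels.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(image, sd) {
  stopifnot(is.matrix(image), sd > 0)
  r <- max(1L, ceiling(4 * sd))
  k <- dnorm(seq(-r, r), sd = sd)
  k <- k / sum(k)
  .conv_sep(image, k, 1L)
}

# a-trous (undecimated) B3-spline wavelet detail planes.
# Plane j is c_{j-1} - c_j where c_j is the image smoothed with the
# B3-spline kernel [1,4,6,4,1]/16 dilated by 2^(j-1).
atrous_planes <- function(image, max_scale) {
  k <- c(1, 4, 6, 4, 1) / 16
  planes <- vector("list", max_scale)
  c_prev <- image
  for (j in seq_len(max_scale)) {
    c_j <- .conv_sep(c_prev, k, as.integer(2^(j - 1)))
    planes[[j]] <- c_prev - c_j
    c_prev <- c_j
  }
  planes
}

#' Label connected components
#'
#' 8-connected component labelling of a logical/binary matrix.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @return integer matrix; 0 is background, components are numbered from 1.
#' @export
label_components <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  .label_components(mask)
}

# Distance (in pixels, chamfer approximation) from each foreground pixel to
# the nearest background pixel or frame edge. Used to short-circuit edge
# correction for circles that are certainly inside the ROI.
mask_interior_depth <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  .chamfer_dt(mask)
}

# Moore boundary tracing of one connected component given its pixel
# coordinates (rows, cols). Returns the chain length: 1 per axial step,
# sqrt(2) per diagonal step. Single-pixel support has length 0.
.boundary_chain_length <- function(rows, cols) {
  n <- length(rows)
  if (n == 1) return(0)
  rr <- rows - min(rows) + 2L; cc <- cols - min(cols) + 2L  # 1-px pad
  m <- matrix(FALSE, max(rr) + 1L, max(cc) + 1L)
  m[cbind(rr, cc)] <- TRUE
  # start: top-most pixel of the left-most column
  start <- c(min(rr[cc == 2L]), 2L)
  # 8 directions clockwise starting from W
  dirs <- cbind(c(0, -1, -1, -1, 0, 1, 1, 1), c(-1, -1, 0, 1, 1, 1, 0, -1))
  cur <- start; backtrack <- 1L  # pretend we entered from the west
  len <- 0
  repeat {
    found <- FALSE
    for (s in seq_len(8)) {
      d <- (backtrack + s - 1L) %% 8L + 1L
      nb <- cur + dirs[d, ]
      if (m[nb[1], nb[2]]) {
        len <- len + if (sum(abs(dirs[d, ])) == 2) sqrt(2) else 1
        backtrack <- (d + 4L) %% 8L  # direction back toward previous pixel
        cur <- nb
        found <- TRUE
        break
      }
    }
    if (!found) return(0)  # isolated pixel (cannot happen for n > 1, 8-conn)
    if (all(cur == start)) break
  }
  len
}

# Region properties of labelled components, computed the way standard
# image-analysis toolkits define them: centroids weighted by the raw
# intensity image, shape descriptors from the unweighted second central
# moments of the pixel support (ellipse-of-equal-moments convention:
# axis length = 4 * sqrt(eigenvalue)).
# Returns a data.frame, one row per label, with pixel-unit quantities.
region_props <- function(labels, raw) {
  stopifnot(all(dim(labels) == dim(raw)))
  idx <- which(labels > 0)
  if (length(idx) == 0) {
    return(data.frame(label = integer(), area_px = numeric(),
                      bbox_w = integer(), bbox_h = integer(),
                      xc_px = numeric(), yc_px = numeric(),
                      major_px = numeric(), minor_px = numeric(),
                      eccentricity = numeric(), perimeter_px = numeric(),
                      total_intensity = numeric()))
  }
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  ints <- raw[idx]
  ord <- order(lab)
  lab <- lab[ord]; rows <- rows[ord]; cols <- cols[ord]; ints <- ints[ord]
  groups <- split(seq_along(lab), lab)

  out <- lapply(groups, function(g) {
    r <- rows[g]; cc <- cols[g]; w <- ints[g]
    s <- sum(w)
    xc <- if (s > 0) sum(w * cc) / s else mean(cc)
    yc <- if (s > 0) sum(w * r) / s else mean(r)
    # unweighted central moments of the support
    mx <- mean(cc); my <- mean(r)
    mu20 <- mean((cc - mx)^2); mu02 <- mean((r - my)^2)
    mu11 <- mean((cc - mx) * (r - my))
    tr <- mu20 + mu02
    det_ <- mu20 * mu02 - mu11^2
    disc <- sqrt(max(0, (tr / 2)^2 - det_))
    l1 <- tr / 2 + disc; l2 <- max(0, tr / 2 - disc)
    data.frame(label = lab[g[1]],
               area_px = length(g),
               bbox_w = diff(range(cc)) + 1L,
               bbox_h = diff(range(r)) + 1L,
               xc_px = xc, yc_px = yc,
               major_px = 4 * sqrt(l1), minor_px = 4 * sqrt(l2),
               eccentricity = if (l1 > 0) sqrt(1 - l2 / l1) else 0,
               perimeter_px = .boundary_chain_length(r, cc),
               total_intensity = s)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
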
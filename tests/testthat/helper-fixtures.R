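# Shared fixtures, built in code at test time.

# disc-shaped binary support in an h x w frame
make_disc <- function(h, w, cy, cx, r) {
  outer(seq_len(h), seq_len(w), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

# noise-free rendered image with a single Gaussian spot (nm coordinates)
make_spot_image <- function(h, w, x_nm, y_nm, sigma_nm, amp, pixel_size = 15,
                            background = 0) {
  xs <- (seq_len(w) - 1) * pixel_size
  ys <- (seq_len(h) - 1) * pixel_size
  outer(ys, xs, function(y, x)
    amp * exp(-((x - x_nm)^2 + (y - y_nm)^2) / (2 * sigma_nm^2))) + background
}

# quick cluster table from centroid coordinates (nm)
cluster_table <- function(x_nm, y_nm) {
  data.frame(id = seq_along(x_nm), x_nm = x_nm, y_nm = y_nm)
}

# uniform positions over a logical mask, as a cluster table
random_clusters <- function(n, mask, pixel_size = 15) {
  p <- rsoda:::sample_positions_in_mask(n, mask, pixel_size)
  cluster_table(p[, 1], p[, 2])
}
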
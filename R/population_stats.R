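## Population-level statistics: randomization tests on means and
## F-statistics with label shuffling, chi-square subtype-prevalence tests,
## and per-unit binned distributions (histograms and cumulative frequency
## curves).

#' Randomization test on the difference of means
#'
#' Two-sided permutation test of H0: A and B come from the same
#' distribution, using D = |mean(A) - mean(B)|. Group labels are shuffled
#' `n_reps` times preserving group sizes; the p-value uses the +1
#' correction p = (#\{D_rand >= D_obs\} + 1) / (n_reps + 1), so it is never
#' exactly zero.
#'
#' @param A,B numeric vectors (each of length >= 2).
#' @param n_reps number of shuffles.
#' @param seed integer seed; the test is deterministic given it.
#' @return list `p_value`, `statistic` (observed D), `n_reps`, `seed`.
#' @export
permutation_mean_test <- function(A, B, n_reps = 10000L, seed = 1L) {
  A <- A[!is.na(A)]; B <- B[!is.na(B)]
  if (length(A) < 2 || length(B) < 2)
    stop("each group needs at least 2 values")
  d_obs <- abs(mean(A) - mean(B))
  pooled <- c(A, B)
  nA <- length(A); n <- length(pooled)
  d_rand <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      idx <- sample.int(n, nA)
      sA <- sum(pooled[idx])
      abs(sA / nA - (sum(pooled) - sA) / (n - nA))
    }, 0)
  })
  p <- (sum(d_rand >= d_obs) + 1) / (n_reps + 1)
  list(p_value = p, statistic = d_obs, n_reps = n_reps, seed = seed)
}

# one-way ANOVA F statistic for a list of groups
.f_statistic <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  n <- sum(ns)
  means <- vapply(groups, mean, 0)
  grand <- sum(ns * means) / n
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Resampled F-statistic test for three or more groups
#'
#' Permutation analogue of one-way ANOVA: the observed F statistic is
#' compared with its distribution under `n_reps` label shuffles preserving
#' group sizes. When the global null is rejected at `alpha`, pairwise
#' [permutation_mean_test()]s are run post hoc (raw p-values; a Bonferroni
#' significance flag is also reported).
#'
#' @param groups list of >= 3 numeric vectors, each of length >= 2.
#' @param n_reps number of shuffles.
#' @param seed integer seed.
#' @param alpha confidence level for running the post-hoc tests.
#' @return list `p_value`, `statistic` (observed F), `post_hoc`
#'   (data.frame or NULL), `n_reps`, `seed`.
#' @export
permutation_F_test <- function(groups, n_reps = 10000L, seed = 1L,
                               alpha = 0.05) {
  if (length(groups) < 3) stop("need at least 3 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  f_obs <- .f_statistic(groups)
  pooled <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  f_rand <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      sh <- pooled[sample.int(length(pooled))]
      .f_statistic(lapply(seq_along(sizes), function(g) sh[starts[g]:ends[g]]))
    }, 0)
  })
  p <- (sum(f_rand >= f_obs) + 1) / (n_reps + 1)
  post <- NULL
  if (p < alpha) {
    cmb <- utils::combn(length(groups), 2)
    post <- data.frame(group_a = cmb[1, ], group_b = cmb[2, ],
                       p_value = NA_real_)
    n_cmp <- ncol(cmb)
    for (i in seq_len(n_cmp)) {
      post$p_value[i] <- permutation_mean_test(
        groups[[cmb[1, i]]], groups[[cmb[2, i]]],
        n_reps = n_reps, seed = seed + i)$p_value
    }
    post$significant <- post$p_value < alpha
    post$significant_bonferroni <- post$p_value < alpha / n_cmp
  }
  list(p_value = p, statistic = f_obs, post_hoc = post,
       n_reps = n_reps, seed = seed)
}

#' Chi-square tests on subtype prevalence
#'
#' Global chi-square test of independence on a subtype x condition
#' contingency table, followed by per-subtype post-hoc tests: each subtype
#' against all other subtypes pooled (2 x condition table). Continuity
#' correction is disabled throughout so that the post-hoc test on a
#' two-subtype table reproduces the global test. Raw p-values are primary;
#' Bonferroni-adjusted significance flags are also reported.
#'
#' @param counts matrix of non-negative counts, rows = subtypes,
#'   columns = conditions.
#' @param alpha significance level for the flags.
#' @return list `global_p`, `global_statistic`, `post_hoc` (data.frame
#'   with one row per subtype).
#' @export
chi_square_subtypes <- function(counts, alpha = 0.05) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least 2 subtypes and 2 conditions")
  exp_counts <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(exp_counts < 1))
    stop("expected counts below 1: chi-square approximation invalid")
  if (any(exp_counts < 5))
    warning("expected counts below 5: chi-square approximation may be poor")
  glob <- suppressWarnings(chisq.test(counts, correct = FALSE))
  m <- nrow(counts)
  post <- data.frame(subtype = seq_len(m), p_value = NA_real_,
                     statistic = NA_real_)
  for (i in seq_len(m)) {
    tab <- rbind(counts[i, ], colSums(counts[-i, , drop = FALSE]))
    ph <- suppressWarnings(chisq.test(tab, correct = FALSE))
    post$p_value[i] <- ph$p.value
    post$statistic[i] <- unname(ph$statistic)
  }
  post$significant <- post$p_value < alpha
  post$significant_bonferroni <- post$p_value < alpha / m
  list(global_p = glob$p.value, global_statistic = unname(glob$statistic),
       post_hoc = post)
}

#' Per-unit binned distribution
#'
#' Bins each unit's (e.g. neuron's or image's) measurements, then averages
#' across units with standard error per bin: the histogram and
#' cumulative-frequency representations used for coupling probabilities
#' and distances (15 nm bins for distances).
#'
#' @param values_per_unit list of numeric vectors, one per unit.
#' @param bin_width bin width in value units, or `NULL` with `bin_edges`.
#' @param bin_edges optional explicit bin edges (increasing).
#' @param cumulative if `TRUE`, each unit's curve is the cumulative
#'   fraction of its values up to the bin's upper edge (reaching 1 at the
#'   last bin).
#' @return object of class `binned_distribution`: list `bin_edges`,
#'   `per_unit` (units x bins matrix), `mean`, `se`, `cumulative`.
#' @export
build_distribution <- function(values_per_unit, bin_width = NULL,
                               bin_edges = NULL, cumulative = FALSE) {
  stopifnot(is.list(values_per_unit), length(values_per_unit) >= 1)
  all_v <- unlist(values_per_unit, use.names = FALSE)
  all_v <- all_v[!is.na(all_v)]
  if (is.null(bin_edges)) {
    if (is.null(bin_width) || bin_width <= 0)
      stop("bin_width must be positive when bin_edges is not given")
    lo <- min(0, floor(min(all_v) / bin_width) * bin_width)
    hi <- ceiling(max(all_v) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    bin_edges <- seq(lo, hi, by = bin_width)
  }
  stopifnot(all(diff(bin_edges) > 0))
  nb <- length(bin_edges) - 1
  per_unit <- t(vapply(values_per_unit, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(rep(NA_real_, nb))
    h <- hist(v, breaks = bin_edges, plot = FALSE, include.lowest = TRUE,
              right = TRUE)$counts
    f <- h / length(v)
    if (cumulative) cumsum(f) / sum(f) else f
  }, numeric(nb)))
  if (length(values_per_unit) == 1) per_unit <- matrix(per_unit, nrow = 1)
  m <- colMeans(per_unit, na.rm = TRUE)
  n_ok <- colSums(!is.na(per_unit))
  se <- apply(per_unit, 2, sd, na.rm = TRUE) / sqrt(pmax(1, n_ok))
  se[n_ok <= 1] <- 0
  structure(list(bin_edges = bin_edges, per_unit = per_unit, mean = m,
                 se = se, cumulative = cumulative),
            class = "binned_distribution")
}

#' Per-bin randomization tests between two binned distributions
#'
#' For each bin, tests |mean_A - mean_B| of the per-unit bin values with a
#' randomization test over unit labels. By default one global set of
#' shuffles is shared across bins (`null = "global"`); `"per_bin"`
#' re-randomizes independently per bin.
#'
#' @param dist_a,dist_b [build_distribution()] results on identical bins.
#' @param n_reps shuffles.
#' @param seed integer seed.
#' @param null `"global"` or `"per_bin"`.
#' @return data.frame `bin`, `upper_edge`, `d_obs`, `p_value`.
#' @export
compare_binned_distributions <- function(dist_a, dist_b, n_reps = 10000L,
                                         seed = 1L,
                                         null = c("global", "per_bin")) {
  null <- match.arg(null)
  stopifnot(identical(dist_a$bin_edges, dist_b$bin_edges))
  Am <- dist_a$per_unit; Bm <- dist_b$per_unit
  nb <- ncol(Am)
  nA <- nrow(Am)
  pooled <- rbind(Am, Bm)
  n <- nrow(pooled)
  d_obs <- abs(colMeans(Am, na.rm = TRUE) - colMeans(Bm, na.rm = TRUE))
  p <- numeric(nb)
  with_seed(seed, {
    if (null == "global") {
      exceed <- matrix(0, n_reps, nb)
      for (i in seq_len(n_reps)) {
        idx <- sample.int(n, nA)
        d_rand <- abs(colMeans(pooled[idx, , drop = FALSE], na.rm = TRUE) -
                        colMeans(pooled[-idx, , drop = FALSE], na.rm = TRUE))
        exceed[i, ] <- as.numeric(d_rand >= d_obs)
      }
      p <- (colSums(exceed) + 1) / (n_reps + 1)
    } else {
      for (b in seq_len(nb)) {
        v <- pooled[, b]
        cnt <- 0
        for (i in seq_len(n_reps)) {
          idx <- sample.int(n, nA)
          if (abs(mean(v[idx], na.rm = TRUE) -
                  mean(v[-idx], na.rm = TRUE)) >= d_obs[b]) cnt <- cnt + 1
        }
        p[b] <- (cnt + 1) / (n_reps + 1)
      }
    }
  })
  data.frame(bin = seq_len(nb), upper_edge = dist_a$bin_edges[-1],
             d_obs = d_obs, p_value = p)
}
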
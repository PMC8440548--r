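#' Z-score a vector (sample SD)
#'
#' Isotopic baselines differ between regions, so isotope values are
#' standardized within each region before any cross-region comparison.
#'
#' @param values Numeric vector with at least two values and nonzero SD.
#' @return `(x - mean) / sd` with the n-1 sample SD.
#' @export
zscore <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two values to z-score")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector")
  (values - mean(values)) / s
}

#' Standard ellipse area of a bivariate point cloud
#'
#' `SEA = pi * sqrt(det(S))` where `S` is the sample covariance matrix of the
#' two coordinates (equivalently pi times the square root of the product of
#' its eigenvalues). With `small_sample_correction`, the result is scaled by
#' `(n - 1) / (n - 2)` (SEAc).
#'
#' @param points Two-column numeric matrix or data frame.
#' @param small_sample_correction Apply the SEAc correction (default FALSE).
#' @return Ellipse area (same squared units as the coordinates).
#' @export
standard_ellipse_area <- function(points, small_sample_correction = FALSE) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have exactly two columns")
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points")
  S <- stats::cov(pts)
  d <- det(S)
  if (d <= 1e-14) stop("points are (near-)collinear: covariance determinant <= 0")
  area <- pi * sqrt(d)
  if (small_sample_correction) area <- area * (n - 1) / (n - 2)
  area
}

#' Convex hull area of a point cloud
#'
#' Area of the smallest convex polygon containing all points (hull vertices
#' from [grDevices::chull()], area by the shoelace formula). Collinear input
#' returns 0.
#'
#' @param points Two-column numeric matrix or data frame, at least 3 points.
#' @return Hull area (0 for collinear points).
#' @export
convex_hull_area <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have exactly two columns")
  if (nrow(pts) < 3L) stop("need at least 3 points")
  h <- grDevices::chull(pts)
  if (length(h) < 3L) return(0)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over the pooled sample points of the absolute
#' difference between the two empirical CDFs; the p-value comes from the
#' asymptotic Kolmogorov distribution with effective sample size
#' `n_a * n_b / (n_a + n_b)`.
#'
#' @param a,b Nonempty numeric vectors.
#' @return A list with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty input sample")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Resample equal-size communities and compute niche metrics per iteration
#'
#' Draws `community_size` individuals without replacement from each of two
#' standardized isotope clouds, `n_iter` times; per iteration computes the
#' standard ellipse area and convex hull area of each subsampled community
#' and a KS comparison of the two communities on each isotope axis.
#' Iteration `i` seeds the RNG with `seed + i`.
#'
#' @param a,b Two-column matrices/data frames (columns `d13C`, `d15N`,
#'   already z-scored within group).
#' @param community_size Number of individuals per community; must not
#'   exceed either cloud.
#' @param n_iter Number of resampled community pairs (default 500).
#' @param seed Integer base seed.
#' @return Data frame, one row per iteration: `iteration`, `community_size`,
#'   `sea_a`, `sea_b`, `hull_a`, `hull_b`, `ks_d13C_D`, `ks_d13C_p`,
#'   `ks_d15N_D`, `ks_d15N_p`.
#' @export
resample_communities <- function(a, b, community_size, n_iter = 500, seed = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 2L, ncol(b) == 2L)
  if (community_size > min(nrow(a), nrow(b))) {
    stop("community_size (", community_size, ") exceeds a group size (",
         min(nrow(a), nrow(b)), ")")
  }
  out <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(seed + i)
    sa <- a[sample.int(nrow(a), community_size), , drop = FALSE]
    sb <- b[sample.int(nrow(b), community_size), , drop = FALSE]
    k1 <- ks_two_sample(sa[, 1], sb[, 1])
    k2 <- ks_two_sample(sa[, 2], sb[, 2])
    out[[i]] <- data.frame(
      iteration = i, community_size = community_size,
      sea_a = standard_ellipse_area(sa), sea_b = standard_ellipse_area(sb),
      hull_a = convex_hull_area(sa), hull_b = convex_hull_area(sb),
      ks_d13C_D = k1$D, ks_d13C_p = k1$p, ks_d15N_D = k2$D, ks_d15N_p = k2$p)
  }
  do.call(rbind, out)
}

#' Summarise a community-resampling run
#'
#' Percentages of iterations in which the KS test is significant per isotope
#' axis, the standard ellipse of group b is larger than group a, and the
#' convex hull of group b is larger.
#'
#' @param results Data frame from [resample_communities()].
#' @param alpha Significance level for the KS tests (default 0.05).
#' @return One-row data frame of percentages (0-100).
#' @export
summarize_niche <- function(results, alpha = 0.05) {
  if (!nrow(results)) stop("empty resampling results")
  data.frame(
    community_size = results$community_size[1],
    n_iter = nrow(results),
    pct_ks_d13C_significant = 100 * mean(results$ks_d13C_p < alpha),
    pct_ks_d15N_significant = 100 * mean(results$ks_d15N_p < alpha),
    pct_sea_b_larger = 100 * mean(results$sea_b > results$sea_a),
    pct_hull_b_larger = 100 * mean(results$hull_b > results$hull_a))
}

#' Regional isotopic-niche comparison at several community sizes
#'
#' Z-scores both isotope axes within each region, then for each requested
#' community size runs [resample_communities()] and [summarize_niche()].
#'
#' @param table Individual-level table with `region`, `d13C`, `d15N` columns;
#'   exactly two regions expected (the first sorted level is group a).
#' @param sizes Community sizes to test (default `c(250, 375, 450)`).
#' @param n_iter Iterations per size (default 500).
#' @param alpha KS significance level.
#' @param seed Integer base seed (size k uses `seed + 1000 * k`).
#' @return A list with `summary` (one row per size) and `iterations` (all
#'   per-iteration rows).
#' @export
run_question2_niche <- function(table, sizes = c(250, 375, 450), n_iter = 500,
                                alpha = 0.05, seed = 1L) {
  need <- c("region", "d13C", "d15N")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab <- table[stats::complete.cases(table[, need]), need]
  regions <- sort(unique(as.character(tab$region)))
  if (length(regions) != 2L) stop("expected exactly two regions, found ", length(regions))
  clouds <- lapply(regions, function(r) {
    sub <- tab[tab$region == r, ]
    cbind(d13C = zscore(sub$d13C), d15N = zscore(sub$d15N))
  })
  names(clouds) <- regions
  res <- list(); summ <- list()
  for (k in seq_along(sizes)) {
    it <- resample_communities(clouds[[1]], clouds[[2]], sizes[k],
                               n_iter = n_iter, seed = seed + 1000 * k)
    res[[k]] <- it
    summ[[k]] <- summarize_niche(it, alpha = alpha)
  }
  list(summary = do.call(rbind, summ), iterations = do.call(rbind, res),
       group_a = regions[1], group_b = regions[2])
}
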
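# Shared fixtures: a fixed 8-tip ultrametric tree (depth 2) and a frozen
# trait vector with an interior lambda optimum, plus small builders.

fixture_tree8 <- function() {
  ape::read.tree(text = paste0(
    "(((A:0.5,B:0.5):0.5,(C:0.7,D:0.7):0.3):1.0,",
    "((E:0.4,F:0.4):0.6,(G:0.8,H:0.8):0.2):1.0);"))
}

fixture_values8 <- function() {
  c(A = -2.0917, B = -0.3059, C = -0.6685, D = -2.5160,
    E = -0.1529, F = 0.3419, G = 0.3070, H = 1.3323)
}

star_tree <- function(n = 8, depth = 1) {
  ape::read.tree(text = paste0(
    "(", paste0("t", seq_len(n), ":", depth, collapse = ","), ");"))
}

# Gaussian log-likelihood of y ~ N(mu 1, s2 V) with mu, s2 profiled by GLS,
# written with explicit solve()/determinant() so it is independent of the
# package's Cholesky-based code path.
oracle_profile_loglik <- function(y, C, lam) {
  V <- C * lam
  diag(V) <- diag(C)
  n <- length(y)
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  r <- y - mu
  s2 <- as.numeric(r %*% Vi %*% r) / n
  -0.5 * (n * log(2 * pi * s2) +
            as.numeric(determinant(V)$modulus) + n)
}

# Brute-force convex hull area: find hull edges by exhaustive sidedness test,
# then sum fan triangles from an extreme point.
oracle_hull_area <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- (pts[, 1] - pts[i, 1]) * (pts[j, 2] - pts[i, 2]) -
         (pts[, 2] - pts[i, 2]) * (pts[j, 1] - pts[i, 1])
    if (all(d >= -1e-12) || all(d <= 1e-12)) on_hull[c(i, j)] <- TRUE
  }
  h <- unique(pts[on_hull, , drop = FALSE])
  if (nrow(h) < 3) return(0)
  ctr <- colMeans(h)
  h <- h[order(atan2(h[, 2] - ctr[2], h[, 1] - ctr[1])), , drop = FALSE]
  area <- 0
  for (k in 2:(nrow(h) - 1)) {
    area <- area + abs((h[k, 1] - h[1, 1]) * (h[k + 1, 2] - h[1, 2]) -
                         (h[k + 1, 1] - h[1, 1]) * (h[k, 2] - h[1, 2])) / 2
  }
  area
}

# Brute-force two-sample KS D: evaluate both ECDFs at every pooled point.
oracle_ks_D <- function(a, b) {
  pool <- c(a, b)
  max(abs(vapply(pool, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# Small balanced two-region table for family/region tests: `k` families,
# two species per family x region cell, `m` individuals per species (cell
# means stay estimable alongside species-level random effects).
balanced_family_table <- function(k = 4, m = 6, sd = 1, seed = 1,
                                  family_means = rep(0, k),
                                  region_offsets = rep(0, k)) {
  set.seed(seed)
  rows <- list()
  for (f in seq_len(k)) for (r in c("a", "b")) for (s in 1:2) {
    sp <- paste0("fam", f, "_", r, s)
    rows[[paste(f, r, s)]] <- data.frame(
      species = sp, family = paste0("fam", f), region = r,
      y = rnorm(m, family_means[f] + if (r == "b") region_offsets[f] else 0, sd),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
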
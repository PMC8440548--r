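test_that("z-scoring centers and scales with the sample SD", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  z <- zscore(rnorm(50, 5, 3))
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_error(zscore(rep(2, 10)), "constant")
  expect_error(zscore(1), "two values")
})

test_that("standard ellipse area matches the covariance-determinant definition", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1))
  S <- stats::cov(pts)
  expect_equal(S, matrix(c(1/3, -1/6, -1/6, 1/3), 2), ignore_attr = TRUE)
  expect_equal(standard_ellipse_area(pts), pi / sqrt(12))
  # SEAc at n = 3 doubles the area: (n-1)/(n-2) = 2
  expect_equal(standard_ellipse_area(pts, small_sample_correction = TRUE),
               2 * pi / sqrt(12))
  expect_error(standard_ellipse_area(cbind(1:5, 2 * (1:5))), "collinear")
  expect_error(standard_ellipse_area(pts[1:2, ]), "3 points")
})

test_that("areas are invariant under rotation of the point cloud", {
  set.seed(7)
  pts <- cbind(rnorm(40), rnorm(40, sd = 2))
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- pts %*% R
  expect_equal(standard_ellipse_area(rot), standard_ellipse_area(pts),
               tolerance = 1e-9)
  expect_equal(convex_hull_area(rot), convex_hull_area(pts), tolerance = 1e-9)
})

test_that("convex hull area handles squares, collinearity, and subsets", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(convex_hull_area(square), 1)
  expect_equal(convex_hull_area(cbind(1:5, 1:5)), 0)
  expect_error(convex_hull_area(square[1:2, ]), "3 points")
  # hull of a subsample never exceeds the hull of the full sample
  set.seed(3)
  pts <- cbind(rnorm(100), rnorm(100))
  full <- convex_hull_area(pts)
  for (s in 1:10) {
    set.seed(s)
    expect_lte(convex_hull_area(pts[sample(100, 30), ]), full + 1e-12)
  }
})

test_that("KS statistic and p behave at the boundaries and on the worked example", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  apart <- ks_two_sample(1:5, 101:105)
  expect_equal(apart$D, 1)
  ex <- ks_two_sample(c(1, 2, 3), c(1.5, 2.5))
  expect_equal(ex$D, 1 / 3)
  expect_equal(ex$D, oracle_ks_D(c(1, 2, 3), c(1.5, 2.5)))
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("community resampling is exact-size, seeded, and symmetric under identical clouds", {
  set.seed(11)
  cloud <- cbind(d13C = rnorm(120), d15N = rnorm(120))
  r1 <- resample_communities(cloud, cloud, community_size = 40, n_iter = 200, seed = 5)
  r2 <- resample_communities(cloud, cloud, community_size = 40, n_iter = 200, seed = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 200L)
  expect_true(all(r1$community_size == 40))
  # same parent cloud: hull_a > hull_b about half the time
  p <- mean(r1$hull_a > r1$hull_b)
  expect_gt(p, 0.5 - 1.96 * sqrt(0.25 / 200) - 0.05)
  expect_lt(p, 0.5 + 1.96 * sqrt(0.25 / 200) + 0.05)
  expect_error(resample_communities(cloud, cloud, 500), "exceeds")
})

test_that("niche summaries report percentages over iterations", {
  res <- data.frame(iteration = 1:4, community_size = 10,
                    sea_a = c(1, 1, 1, 1), sea_b = c(2, 2, 0.5, 2),
                    hull_a = 1, hull_b = c(2, 2, 2, 0.5),
                    ks_d13C_p = c(0.01, 0.2, 0.01, 0.01),
                    ks_d15N_p = c(0.5, 0.5, 0.5, 0.01),
                    ks_d13C_D = 0.5, ks_d15N_D = 0.2)
  s <- summarize_niche(res, alpha = 0.05)
  expect_equal(s$pct_ks_d13C_significant, 75)
  expect_equal(s$pct_ks_d15N_significant, 25)
  expect_equal(s$pct_sea_b_larger, 75)
  expect_equal(s$pct_hull_b_larger, 75)
  expect_error(summarize_niche(res[0, ]), "empty")
})

test_that("the regional niche comparison emits one summary row per community size", {
  # z-scoring removes scale, so regions are made to differ in shape: region a
  # has strongly correlated axes (narrow ellipse), region b independent axes
  set.seed(21)
  z1 <- rnorm(150); z2 <- rnorm(150)
  tab <- data.frame(region = rep(c("a", "b"), each = 150),
                    d13C = c(-14 + z1, rnorm(150, -10, 1.5)),
                    d15N = c(8 + 0.9 * z1 + sqrt(1 - 0.81) * z2, rnorm(150, 9, 1.5)))
  out <- run_question2_niche(tab, sizes = c(30, 60, 90), n_iter = 50, seed = 2)
  expect_equal(nrow(out$summary), 3L)
  expect_equal(out$summary$community_size, c(30, 60, 90))
  expect_equal(out$group_a, "a")
  # uncorrelated axes in b give larger standardized ellipses nearly always
  expect_gt(out$summary$pct_sea_b_larger[3], 90)
})
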
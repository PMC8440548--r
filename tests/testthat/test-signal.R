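test_that("species means average non-missing individuals and log dropped species", {
  tab <- data.frame(species = c("A", "A", "B", "C", "C"),
                    x = c(1, 3, 5, NA, NA))
  expect_message(m <- species_means(tab, "x"), "C")
  expect_equal(unname(m[c("A", "B")]), c(2, 5))
  expect_false("C" %in% names(m))
  expect_equal(attr(m, "n_per_species"), c(2L, 1L))
  expect_error(species_means(tab[0, ], "x"), "empty")
})

test_that("lambda ML matches a fine-grid brute-force oracle on the fixture", {
  tr <- fixture_tree8()
  C <- phylo_vcv(tr)
  y <- fixture_values8()
  est <- pagels_lambda_ml(y, C)
  grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(grid, function(l) oracle_profile_loglik(y, C, l), numeric(1))
  expect_equal(est$estimate, grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(est$loglik, max(ll), tolerance = 1e-6)
  # maximality: the profile likelihood at the optimum beats both endpoints
  expect_gte(est$loglik, oracle_profile_loglik(y, C, 0))
  expect_gte(est$loglik, oracle_profile_loglik(y, C, 1))
})

test_that("on a star phylogeny lambda is flagged unidentifiable and the likelihood is iid", {
  depth <- 3
  C <- phylo_vcv(star_tree(8, depth = depth))
  set.seed(5)
  y <- stats::setNames(rnorm(8), rownames(C))
  est <- pagels_lambda_ml(y, C)
  expect_true(est$unidentifiable)
  expect_equal(est$estimate, 0)
  # V = s2 * depth * I: max loglik equals the iid-normal value with MLE variance
  s2_hat <- mean((y - mean(y))^2)
  ll_iid <- -0.5 * (8 * log(2 * pi * s2_hat) + 8)
  expect_equal(est$loglik, ll_iid, tolerance = 1e-8)
})

test_that("lambda ML agrees with an independent implementation and is scale invariant", {
  tr <- fixture_tree8()
  C <- phylo_vcv(tr)
  y <- fixture_values8()
  mine <- pagels_lambda_ml(y, C)$estimate
  ref <- phytools::phylosig(tr, y, method = "lambda")$lambda
  expect_equal(mine, min(ref, 1), tolerance = 0.01)
  # branch-length rescaling leaves lambda unchanged
  expect_equal(pagels_lambda_ml(y, 3.7 * C)$estimate, mine, tolerance = 1e-4)
  # degenerate input
  expect_error(pagels_lambda_ml(stats::setNames(rep(1, 8), rownames(C)), C),
               "variance")
})

test_that("Blomberg's K matches the direct-formula oracle, reference code, and is affine invariant", {
  tr <- fixture_tree8()
  C <- phylo_vcv(tr)
  y <- fixture_values8()
  K <- blombergs_K(y, C)$estimate
  # independent oracle with explicit matrix inverse
  n <- 8; one <- rep(1, n); Ci <- solve(C)
  a_hat <- as.numeric(one %*% Ci %*% y) / as.numeric(one %*% Ci %*% one)
  r <- y - a_hat
  K_oracle <- (sum(r^2) / as.numeric(r %*% Ci %*% r)) /
    ((sum(diag(C)) - n / as.numeric(one %*% Ci %*% one)) / (n - 1))
  expect_equal(K, K_oracle, tolerance = 1e-10)
  expect_equal(K, as.numeric(phytools::phylosig(tr, y, method = "K")),
               tolerance = 1e-8)
  # affine transform of the trait leaves K unchanged
  expect_equal(blombergs_K(-2.5 * y + 7, C)$estimate, K, tolerance = 1e-10)
  # star tree: observed and expected variance ratios coincide, K = 1 exactly
  Cs <- phylo_vcv(star_tree(8, depth = 2))
  ys <- stats::setNames(rnorm(8), rownames(Cs))
  expect_equal(blombergs_K(ys, Cs)$estimate, 1, tolerance = 1e-12)
})

test_that("randomization test is deterministic, bounded below, and detects strong signal", {
  tr <- simulate_tree(32, seed = 2)
  C <- phylo_vcv(tr)
  y <- simulate_traits_bm(tr, lambda = 1, sigma2 = 1, seed = 9)
  p1 <- signal_randomization_test(y, C, "K", n_perm = 99, seed = 4)$p_randomization
  p2 <- signal_randomization_test(y, C, "K", n_perm = 99, seed = 4)$p_randomization
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 100)       # add-one estimator lower bound
  expect_lte(p1, 0.05)          # strong Brownian signal is detected
})

test_that("bootstrap collapses for singleton species and has the right shape", {
  tr <- fixture_tree8()
  C <- phylo_vcv(tr)
  tab <- data.frame(species = rownames(C), x = as.numeric(fixture_values8()))
  bt <- bootstrap_signal(tab, "x", C, "lambda", n_iter = 25, seed = 3)
  expect_length(bt$draws, 25)
  point <- pagels_lambda_ml(fixture_values8(), C)$estimate
  expect_true(all(abs(bt$draws - point) < 1e-12))
})

test_that("bootstrap lambda spread shrinks as within-species sample size grows", {
  tr <- simulate_tree(32, seed = 6)
  C <- phylo_vcv(tr)
  means <- simulate_traits_bm(tr, 1, 1, seed = 8)
  small <- simulate_individuals(means, 4, sigma2_individual = 1, seed = 11)
  names(small)[2] <- "x"
  big <- simulate_individuals(means, 40, sigma2_individual = 1, seed = 12)
  names(big)[2] <- "x"
  sd_small <- stats::sd(bootstrap_signal(small, "x", C, "lambda", n_iter = 120, seed = 1)$draws)
  sd_big <- stats::sd(bootstrap_signal(big, "x", C, "lambda", n_iter = 120, seed = 1)$draws)
  expect_lt(sd_big, sd_small)
})

test_that("group comparison reports paired exceedance and flags separation sensibly", {
  tr <- simulate_tree(16, seed = 6)
  C <- phylo_vcv(tr)
  means <- simulate_traits_bm(tr, 1, 1, seed = 8)
  tab <- simulate_individuals(means, 6, sigma2_individual = 0.5, seed = 13)
  names(tab)[2] <- "x"
  a <- bootstrap_signal(tab, "x", C, "K", n_iter = 200, seed = 100, group_label = "a")
  b <- bootstrap_signal(tab, "x", C, "K", n_iter = 200, seed = 900, group_label = "b")
  cmp <- compare_signal_groups(a, b)
  # same generating table: exceedance within a generous binomial envelope of 0.5
  expect_gt(cmp$prop_a_gt_b, 0.35)
  expect_lt(cmp$prop_a_gt_b, 0.65)
  expect_false(cmp$separated)
  # mismatched lengths warn; empty errors
  short <- b; short$draws <- short$draws[1:50]
  expect_warning(compare_signal_groups(a, short), "unequal")
  empty <- b; empty$draws <- numeric(0)
  expect_error(compare_signal_groups(a, empty), "empty")
  mism <- b; mism$statistic <- "lambda"
  expect_error(compare_signal_groups(a, mism), "statistic")
})
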
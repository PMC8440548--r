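# Small simulated datasets for the mixed-model machinery.
make_pglmm_data <- function(n_sp = 40, n_ind = 6, s2_phylo = 1, s2_resid = 0.5,
                            beta_x = 0, lambda = 1, seed = 1) {
  tree <- simulate_tree(n_sp, seed = seed)
  C <- phylo_vcv(tree)
  u <- simulate_traits_bm(tree, lambda, s2_phylo, seed = seed + 1)
  tab <- simulate_individuals(u, n_ind, sigma2_individual = s2_resid,
                              seed = seed + 2)
  set.seed(seed + 3)
  tab$x <- rnorm(nrow(tab))
  tab$y <- tab$value + beta_x * tab$x
  list(table = tab, tree = tree, C = C)
}

test_that("build_design standardizes, treatment-codes, and counts drops", {
  d <- make_pglmm_data(seed = 21)
  tab <- d$table
  tab$tg <- sample(c("herbivore", "invertivore", "omnivore", "predator"),
                   nrow(tab), replace = TRUE)
  tab$region <- sample(c("a", "b"), nrow(tab), replace = TRUE)
  tab$y[1:5] <- NA
  des <- build_design(tab, "y", c("x", "tg", "region"), d$C,
                      reference_levels = list(region = "a"))
  expect_equal(des$n_dropped, 5L)
  expect_equal(mean(des$X[, "x"]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(des$X[, "x"]), 1, tolerance = 1e-12)
  expect_length(grep("^tg", des$terms), 3L)          # 4 levels -> 3 indicators
  expect_true("regionb" %in% des$terms)              # region a is the intercept
  expect_error(build_design(tab, "y", "y", d$C), "fixed effect")
  tab$const <- 1
  expect_error(build_design(tab, "y", "const", d$C), "constant")
})

test_that("identical seeds give identical draws", {
  d <- make_pglmm_data(n_sp = 20, n_ind = 4, seed = 31)
  des <- build_design(d$table, "y", "x", d$C)
  f1 <- fit_pglmm(des, n_iter = 600, n_burnin = 100, thin = 2, seed = 99)
  f2 <- fit_pglmm(des, n_iter = 600, n_burnin = 100, thin = 2, seed = 99)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma2, f2$sigma2)
  f3 <- fit_pglmm(des, n_iter = 600, n_burnin = 100, thin = 2, seed = 100)
  expect_false(identical(f1$sigma2, f3$sigma2))
})

test_that("with an identity phylogeny the fit matches a REML random-intercept oracle", {
  d <- make_pglmm_data(n_sp = 60, n_ind = 8, s2_phylo = 1, s2_resid = 1,
                       beta_x = 0.5, seed = 41)
  I_C <- diag(nrow(d$C)); dimnames(I_C) <- dimnames(d$C)
  des <- build_design(d$table, "y", "x", I_C)
  # generate under the identity structure too: species effects iid
  set.seed(42)
  u <- stats::setNames(rnorm(60), rownames(I_C))
  tab <- simulate_individuals(u, 8, sigma2_individual = 1, seed = 43)
  set.seed(44)
  tab$x <- rnorm(nrow(tab))
  tab$y <- tab$value + 0.5 * tab$x
  des <- build_design(tab, "y", "x", I_C)
  fit <- fit_pglmm(des, n_iter = 6000, n_burnin = 1000, thin = 5, seed = 7)
  ref <- lme4::lmer(y ~ x + (1 | species), data = tab, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))
  s2_sp_ref <- vc$vcov[vc$grp == "species"]
  s2_e_ref <- vc$vcov[vc$grp == "Residual"]
  expect_equal(mean(fit$sigma2[, "phylo"]), s2_sp_ref, tolerance = 0.1 * s2_sp_ref + 0.05)
  expect_equal(mean(fit$sigma2[, "resid"]), s2_e_ref, tolerance = 0.1 * s2_e_ref)
  expect_equal(fit$fixed_effect_summaries$mean[2], lme4::fixef(ref)[["x"]],
               tolerance = 0.05)
})

test_that("R2 partition is 0 for intercept-only fixed effects and ordered per draw", {
  d <- make_pglmm_data(n_sp = 25, n_ind = 4, seed = 51)
  ponly <- fit_phylogeny_only(d$table, "y", d$C, n_iter = 800, n_burnin = 200,
                              thin = 2, seed = 3)
  expect_true(all(ponly$r2_fixed == 0))
  expect_true(is.finite(dic(ponly)))
  des <- build_design(d$table, "y", "x", d$C)
  fit <- fit_pglmm(des, n_iter = 800, n_burnin = 200, thin = 2, seed = 3)
  expect_true(all(fit$r2_fixed <= fit$r2_full))
  ve <- variance_explained(fit)
  expect_lte(ve$r2_fixed, ve$r2_full)
  expect_gte(ve$r2_fixed_lo, 0)
  expect_lte(ve$r2_full_hi, 1)
})

test_that("a degenerate single-draw posterior has pD = 0", {
  d <- make_pglmm_data(n_sp = 15, n_ind = 3, seed = 61)
  des <- build_design(d$table, "y", "x", d$C)
  fit <- fit_pglmm(des, n_iter = 301, n_burnin = 300, thin = 1, seed = 5)
  expect_equal(nrow(fit$beta), 1L)
  expect_equal(fit$p_d, 0, tolerance = 1e-9)
  expect_equal(dic(fit), fit$deviance[1], tolerance = 1e-9)
})

test_that("the sampler leaves the prior invariant (successive-conditional check)", {
  # Joint (theta, sigma2, y) updates with y redrawn each sweep sample the
  # prior; the marginal of sigma2_phylo must match its inverse-gamma prior.
  tree <- simulate_tree(6, seed = 71)
  C <- phylo_vcv(tree)
  sp <- factor(rep(rownames(C), each = 3), levels = rownames(C))
  Z <- stats::model.matrix(~ 0 + sp)
  X <- matrix(1, nrow(Z), 1)
  W <- cbind(X, Z)
  shape <- 3; rate <- 2
  set.seed(123)
  raw <- reefchem:::.gibbs_lmm_cpp(rnorm(nrow(W)), W, 1L, list(solve(C)),
                                   prior_shape = c(shape, shape),
                                   prior_rate = c(rate, rate),
                                   beta_prec = 1, n_iter = 110000,
                                   n_burnin = 10000, thin = 20,
                                   init_sigma2 = c(1, 1), redraw_y = TRUE)
  draws <- raw$sigma2[, 1]
  pinvgamma <- function(q) stats::pgamma(1 / q, shape, rate, lower.tail = FALSE)
  ks <- suppressWarnings(stats::ks.test(draws, pinvgamma))
  expect_gt(ks$p.value, 0.01)
})
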
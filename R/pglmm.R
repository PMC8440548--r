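#' Build the design bundle for a phylogenetic mixed model
#'
#' Assembles the response, fixed-effect design matrix, species incidence
#' matrix and species-level phylogenetic covariance for one trait model.
#' Rows with a missing response or missing predictors are dropped and
#' counted; continuous predictors are z-scored so coefficients are
#' comparable standardized effect sizes; categorical predictors are
#' treatment-coded against the supplied reference levels.
#'
#' @param table Individual-level trait table (one row per individual) with a
#'   `species` column.
#' @param response Name of the response trait column.
#' @param fixed_effects Character vector of predictor column names. Factors
#'   and character columns are treatment-coded; numeric columns are
#'   standardized.
#' @param C Species-level phylogenetic covariance matrix; species in the
#'   table but absent from `C` are dropped with a message.
#' @param reference_levels Named list mapping categorical predictors to their
#'   reference level (e.g. `list(region = "a")`).
#' @return A list of class `pglmm_design`: `y`, `X`, `Z`, `C`, `species`
#'   (factor), `n_dropped`, `terms` (column names of `X`).
#' @export
build_design <- function(table, response, fixed_effects = character(), C,
                         reference_levels = list()) {
  stopifnot(is.data.frame(table), "species" %in% names(table))
  if (response %in% fixed_effects) stop("response cannot also be a fixed effect")
  need <- c("species", response, fixed_effects)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dat <- table[, need, drop = FALSE]
  complete <- stats::complete.cases(dat)
  n_dropped_na <- sum(!complete)
  dat <- dat[complete, , drop = FALSE]
  in_tree <- dat$species %in% rownames(C)
  if (any(!in_tree)) {
    message("dropping ", sum(!in_tree), " individuals of ",
            length(unique(dat$species[!in_tree])), " species absent from the phylogeny")
  }
  dat <- dat[in_tree, , drop = FALSE]
  if (!nrow(dat)) stop("no rows remain after filtering")

  for (v in fixed_effects) {
    if (is.numeric(dat[[v]])) {
      s <- stats::sd(dat[[v]])
      if (!is.finite(s) || s == 0) stop("predictor constant after filtering: ", v)
      dat[[v]] <- (dat[[v]] - mean(dat[[v]])) / s
    } else {
      lev <- unique(as.character(dat[[v]]))
      if (length(lev) < 2L) stop("predictor constant after filtering: ", v)
      ref <- reference_levels[[v]]
      if (!is.null(ref) && ref %in% lev) lev <- c(ref, setdiff(lev, ref))
      else lev <- sort(lev)
      dat[[v]] <- factor(as.character(dat[[v]]), levels = lev)
    }
  }
  form <- if (length(fixed_effects)) {
    stats::as.formula(paste("~", paste(fixed_effects, collapse = " + ")))
  } else ~1
  X <- stats::model.matrix(form, dat)
  species <- factor(as.character(dat$species),
                    levels = intersect(rownames(C), unique(as.character(dat$species))))
  Z <- stats::model.matrix(~ 0 + species)
  colnames(Z) <- levels(species)
  Cs <- C[levels(species), levels(species), drop = FALSE]
  structure(list(y = as.numeric(dat[[response]]), X = X, Z = Z, C = Cs,
                 species = species, n_dropped = n_dropped_na + sum(!in_tree),
                 terms = colnames(X), response = response),
            class = "pglmm_design")
}

#' Fit a Bayesian phylogenetic mixed model by blocked Gibbs sampling
#'
#' Samples from the posterior of the animal model
#' `y = X beta + Z u + e`, with `u ~ N(0, sigma2_phylo * C)` and
#' `e ~ N(0, sigma2_resid * I)`. `(beta, u)` are drawn jointly from their
#' multivariate-normal full conditional via Cholesky of the mixed-model
#' equations; variances from conjugate inverse-gamma full conditionals with
#' a weakly informative inverse-gamma(`prior_shape`, `prior_rate`) prior.
#'
#' Defaults are desk-scale (4,000 iterations, 1,000 burn-in, thin 3);
#' publication-scale settings in this literature are 80,000 iterations with
#' 10,000 burn-in and thin 10, available through the arguments.
#'
#' @param design A `pglmm_design` from [build_design()].
#' @param n_iter,n_burnin,thin MCMC run length, burn-in, thinning interval.
#' @param prior_shape,prior_rate Inverse-gamma prior parameters shared by all
#'   variance components (default 0.001, 0.001: the conventional vague
#'   choice).
#' @param seed Integer seed; identical seeds give identical draws.
#' @param extra_blocks Optional list of additional random-effect precision
#'   structures (named square matrices over species levels), e.g. an iid
#'   species intercept via an identity matrix.
#' @return A `pglmm_fit` list with retained draws (`beta`, `sigma2` with one
#'   column per variance component, residual last), per-draw `var_fixed` and
#'   `deviance`, fixed-effect summaries, R2 partition, DIC, the design, and
#'   a split-chain convergence diagnostic.
#' @export
fit_pglmm <- function(design, n_iter = 4000, n_burnin = 1000, thin = 3,
                      prior_shape = 0.001, prior_rate = 0.001, seed = 1L,
                      extra_blocks = list()) {
  stopifnot(inherits(design, "pglmm_design"), n_iter > n_burnin)
  Cinv <- solve_cov(design$C)
  blocks <- c(list(phylo = Cinv), extra_blocks)
  W <- cbind(design$X, do.call(cbind, rep(list(design$Z), length(blocks))))
  p <- ncol(design$X)
  n_comp <- length(blocks) + 1L
  set.seed(seed)
  raw <- .gibbs_lmm_cpp(design$y, W, p, unname(blocks),
                        prior_shape = rep(prior_shape, n_comp),
                        prior_rate = rep(prior_rate, n_comp),
                        beta_prec = 1e-8,
                        n_iter = n_iter, n_burnin = n_burnin, thin = thin,
                        init_sigma2 = rep(stats::var(design$y) / n_comp, n_comp),
                        redraw_y = FALSE)
  finalize_pglmm_fit(raw, design, blocks, p,
                     settings = list(n_iter = n_iter, n_burnin = n_burnin,
                                     thin = thin, seed = seed,
                                     prior_shape = prior_shape,
                                     prior_rate = prior_rate))
}

finalize_pglmm_fit <- function(raw, design, blocks, p, settings) {
  beta <- raw$theta[, seq_len(p), drop = FALSE]
  colnames(beta) <- design$terms
  sigma2 <- raw$sigma2
  colnames(sigma2) <- c(names(blocks), "resid")
  # fixed-effect summaries: mean, 95% CI, significance (CI excludes zero)
  qs <- t(apply(beta, 2, stats::quantile, probs = c(0.025, 0.975)))
  fx <- data.frame(term = colnames(beta), mean = colMeans(beta),
                   lo95 = qs[, 1], hi95 = qs[, 2],
                   significant = qs[, 1] > 0 | qs[, 2] < 0,
                   row.names = NULL, stringsAsFactors = FALSE)
  # R2 partition per draw (see variance_explained)
  denom <- raw$var_fixed + rowSums(sigma2)
  r2_fixed <- raw$var_fixed / denom
  r2_full <- (raw$var_fixed + rowSums(sigma2[, setdiff(colnames(sigma2), "resid"),
                                             drop = FALSE])) / denom
  theta_bar <- colMeans(raw$theta)
  W <- cbind(design$X, do.call(cbind, rep(list(design$Z), length(blocks))))
  fitted_bar <- as.numeric(W %*% theta_bar)
  resid_cond <- design$y - fitted_bar
  s2e_bar <- mean(sigma2[, "resid"])
  n <- length(design$y)
  d_hat <- n * log(2 * pi * s2e_bar) + sum(resid_cond^2) / s2e_bar
  d_bar <- mean(raw$deviance)
  p_d <- d_bar - d_hat
  fit <- structure(list(
    beta = beta, sigma2 = sigma2, var_fixed = raw$var_fixed,
    deviance = raw$deviance, theta_mean = theta_bar,
    fixed_effect_summaries = fx,
    r2_fixed = r2_fixed, r2_full = r2_full,
    r2_fixed_mean = mean(r2_fixed), r2_full_mean = mean(r2_full),
    r2_fixed_ci = stats::quantile(r2_fixed, c(0.025, 0.975), names = FALSE),
    r2_full_ci = stats::quantile(r2_full, c(0.025, 0.975), names = FALSE),
    dic = d_bar + p_d, p_d = p_d,
    residuals = resid_cond, fitted = fitted_bar,
    design = design, settings = settings,
    psrf = apply(sigma2, 2, split_chain_psrf)), class = "pglmm_fit")
  bad <- fit$psrf[is.finite(fit$psrf) & fit$psrf > 1.1]
  if (length(bad)) {
    warning("possible non-convergence: split-chain PSRF > 1.1 for ",
            paste(names(bad), collapse = ", "))
  }
  fit
}

# Potential scale reduction factor from splitting one chain in half.
split_chain_psrf <- function(x) {
  m <- length(x) %/% 2
  if (m < 10) return(NA_real_)
  half <- list(x[seq_len(m)], x[(length(x) - m + 1):length(x)])
  w <- mean(vapply(half, stats::var, numeric(1)))
  b <- m * stats::var(vapply(half, mean, numeric(1)))
  if (w <= 0) return(NA_real_)
  sqrt(((m - 1) / m * w + b / m) / w)
}

#' @export
print.pglmm_fit <- function(x, ...) {
  cat("Phylogenetic mixed model fit (", nrow(x$beta), " retained draws)\n", sep = "")
  cat(sprintf("  R2 fixed  %.3f [%.3f, %.3f]\n", x$r2_fixed_mean,
              x$r2_fixed_ci[1], x$r2_fixed_ci[2]))
  cat(sprintf("  R2 full   %.3f [%.3f, %.3f]\n", x$r2_full_mean,
              x$r2_full_ci[1], x$r2_full_ci[2]))
  cat(sprintf("  DIC       %.1f (pD %.1f)\n", x$dic, x$p_d))
  print(x$fixed_effect_summaries, digits = 3)
  invisible(x)
}

#' Variance explained by fixed effects and by fixed plus random effects
#'
#' Per retained draw, the marginal R2 is `Var(X beta)` over
#' `Var(X beta) + sum of variance components + residual variance`, and the
#' conditional R2 adds the non-residual variance components to the
#' numerator; `Var` is the sample variance of the linear predictor for that
#' draw. Reported as posterior means with 95% credible intervals.
#'
#' @param fit A `pglmm_fit`.
#' @return A one-row data frame with `r2_fixed`, `r2_full` and their CIs.
#' @export
variance_explained <- function(fit) {
  stopifnot(inherits(fit, "pglmm_fit"))
  data.frame(r2_fixed = fit$r2_fixed_mean,
             r2_fixed_lo = fit$r2_fixed_ci[1], r2_fixed_hi = fit$r2_fixed_ci[2],
             r2_full = fit$r2_full_mean,
             r2_full_lo = fit$r2_full_ci[1], r2_full_hi = fit$r2_full_ci[2])
}

#' Fit the phylogeny-only (intercept-only) model
#'
#' Same model as [fit_pglmm()] with the fixed effects reduced to an
#' intercept: variation is explained only by the phylogenetic random effect
#' and residual noise.
#'
#' @param table,response,C As in [build_design()].
#' @param ... Passed to [fit_pglmm()].
#' @return A `pglmm_fit`.
#' @export
fit_phylogeny_only <- function(table, response, C, ...) {
  design <- build_design(table, response, character(), C)
  fit_pglmm(design, ...)
}

#' Deviance information criterion of a fitted model
#'
#' Conditional DIC: the deviance is computed from the likelihood of `y`
#' given `(beta, u, sigma2_resid)` per draw, `pD = Dbar - D(theta_bar)`, and
#' `DIC = Dbar + pD`. Computed at fit time; this accessor returns it.
#'
#' @param fit A `pglmm_fit`.
#' @return A single number.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "pglmm_fit"))
  fit$dic
}

#' Default fixed-effect sets for the nine chemical traits
#'
#' Mass-corrected excretion responses exclude mass as a predictor; body
#' nutrient predictors never include the response's own numerator or
#' denominator. `region` is always included.
#'
#' @param mass_corrected If `FALSE`, excretion responses are the uncorrected
#'   rates and mass is kept as a predictor (the supplementary variant).
#' @return Named list mapping trait name to character vector of predictors.
#' @export
default_trait_models <- function(mass_corrected = TRUE) {
  base <- c("trophic_group", "d13C", "d15N", "region")
  exc_fixed <- if (mass_corrected) base else c(base, "log10_mass")
  list(
    exc_N_mass   = c(exc_fixed, "body_pct_N"),
    exc_P_mass   = c(exc_fixed, "body_pct_P"),
    exc_NP_molar = c(exc_fixed, "body_pct_N", "body_pct_P"),
    body_pct_C   = c(base, "log10_mass", "body_pct_N", "body_pct_P"),
    body_pct_N   = c(base, "log10_mass", "body_pct_C", "body_pct_P"),
    body_pct_P   = c(base, "log10_mass", "body_pct_C", "body_pct_N"),
    body_CN      = c(base, "log10_mass", "body_pct_P"),
    body_CP      = c(base, "log10_mass", "body_pct_N"),
    body_NP      = c(base, "log10_mass", "body_pct_C")
  )
}

#' Variance partitioning across all configured traits (Question 1)
#'
#' For each trait, fits the full model (ecological fixed effects plus the
#' phylogenetic random effect) and the phylogeny-only model, and reports the
#' marginal R2 ("ecology"), conditional R2 ("full model"), the phylogeny-only
#' R2, and the DIC difference between the two models (positive favours the
#' full model; > 2 is the conventional selection threshold).
#'
#' @param table Individual-level trait table including derived traits (see
#'   [derive_chemical_traits()]).
#' @param tree Phylogeny covering the species (made ultrametric internally).
#' @param trait_models Named list trait -> fixed-effect character vector;
#'   default [default_trait_models()], restricted to traits present.
#' @param reference_levels Passed to [build_design()].
#' @param seed Integer seed; trait k uses `seed + k` for each of its two fits.
#' @param ... MCMC settings passed to [fit_pglmm()].
#' @return A list with `comparison` (one row per trait) and `coefficients`
#'   (standardized effect sizes with CIs, one row per trait x term), plus
#'   `fits` (the full-model fits, named by trait).
#' @export
run_question1 <- function(table, tree, trait_models = NULL,
                          reference_levels = list(), seed = 1L, ...) {
  if (is.null(trait_models)) {
    trait_models <- default_trait_models()
    trait_models <- trait_models[names(trait_models) %in% names(table)]
  }
  if (!length(trait_models)) stop("no configured traits present in the table")
  tree <- force_ultrametric(tree)
  tree <- prune_to_taxa(tree, unique(as.character(table$species)))
  C <- phylo_vcv(tree)
  rows <- list(); coefs <- list(); fits <- list()
  for (k in seq_along(trait_models)) {
    trait <- names(trait_models)[k]
    fx <- intersect(trait_models[[k]], names(table))
    design <- build_design(table, trait, fx, C, reference_levels)
    full <- fit_pglmm(design, seed = seed + k, ...)
    ponly <- fit_phylogeny_only(table, trait, C, seed = seed + k, ...)
    rows[[trait]] <- data.frame(
      trait = trait, n = length(design$y),
      r2_fixed = full$r2_fixed_mean, r2_full = full$r2_full_mean,
      r2_phylo_only = ponly$r2_full_mean,
      dic_full = full$dic, dic_phylo_only = ponly$dic,
      delta_dic = ponly$dic - full$dic, stringsAsFactors = FALSE)
    cf <- full$fixed_effect_summaries
    cf <- cbind(trait = trait, cf, stringsAsFactors = FALSE)
    coefs[[trait]] <- cf
    fits[[trait]] <- full
  }
  list(comparison = do.call(rbind, c(rows, make.row.names = FALSE)),
       coefficients = do.call(rbind, c(coefs, make.row.names = FALSE)),
       fits = fits)
}
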
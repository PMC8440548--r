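# Question 3: do con-familial species differ between regions beyond what
# phylogenetic relatedness predicts? Paired models:
#   (1) trait ~ 1 + family:region                      (cell-means ANOVA)
#   (2) trait ~ 1 + family:region + iid species + phylogenetic species

# Restrict a table to families observed in both regions with at least
# `min_cell` non-missing individuals per family x region cell.
shared_family_data <- function(table, trait, min_cell = 2L) {
  need <- c("species", "family", "region", trait)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dat <- table[stats::complete.cases(table[, need]), need]
  regions <- sort(unique(as.character(dat$region)))
  if (length(regions) != 2L) stop("expected exactly two regions, found ", length(regions))
  counts <- table(dat$family, dat$region)
  ok <- rownames(counts)[counts[, regions[1]] >= min_cell &
                         counts[, regions[2]] >= min_cell]
  dropped <- setdiff(unique(as.character(dat$family)), ok)
  if (length(dropped)) {
    message("dropping families without >=", min_cell,
            " individuals in both regions: ", paste(dropped, collapse = ", "))
  }
  if (length(ok) < 2L) stop("fewer than 2 families shared across regions")
  dat <- dat[dat$family %in% ok, ]
  dat$family <- factor(as.character(dat$family))
  dat$region <- factor(as.character(dat$region), levels = regions)
  dat$cell <- interaction(dat$family, dat$region, sep = ":", drop = FALSE)
  dat
}

#' Family-by-region trait contrasts without phylogenetic correction
#'
#' Least-squares fit of the cell-means model `trait ~ 0 + family:region` on
#' families present in both regions; for each family, the region-b minus
#' region-a mean difference with its standard error and a t test at `alpha`.
#' A Holm-adjusted significance column is also reported.
#'
#' @param table Individual-level trait table with `species`, `family`,
#'   `region` columns.
#' @param trait Trait column name.
#' @param alpha Significance level (default 0.05, unadjusted per family).
#' @return A list of class `family_contrast_fit`: `contrasts` data frame,
#'   `residuals`, `data`, `model` ("anova").
#' @export
fit_anova_family_region <- function(table, trait, alpha = 0.05) {
  dat <- shared_family_data(table, trait)
  fit <- stats::lm(stats::reformulate("0 + cell", response = trait), data = dat)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  fams <- levels(dat$family)
  regions <- levels(dat$region)
  rows <- lapply(fams, function(f) {
    ca <- paste0("cell", f, ":", regions[1])
    cb <- paste0("cell", f, ":", regions[2])
    d <- cf[cb] - cf[ca]
    se <- sqrt(V[ca, ca] + V[cb, cb] - 2 * V[ca, cb])
    tstat <- d / se
    p <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
    data.frame(family = f, trait = trait, difference = unname(d),
               se = unname(se), lo95 = unname(d - stats::qt(0.975, fit$df.residual) * se),
               hi95 = unname(d + stats::qt(0.975, fit$df.residual) * se),
               p = unname(p), stringsAsFactors = FALSE)
  })
  contrasts <- do.call(rbind, rows)
  contrasts$significant <- contrasts$p < alpha
  contrasts$significant_holm <- stats::p.adjust(contrasts$p, "holm") < alpha
  structure(list(contrasts = contrasts, residuals = stats::residuals(fit),
                 data = dat, model = "anova", lm_fit = fit),
            class = "family_contrast_fit")
}

#' Family-by-region trait contrasts under the phylogenetic mixed model
#'
#' Same cell-means fixed structure as [fit_anova_family_region()] plus an
#' independent species intercept and a phylogenetic species effect, fitted
#' by the blocked Gibbs sampler. A family's region difference is declared
#' significant when its 95% credible interval excludes zero; under this
#' model, trait divergence attributable purely to phylogenetic relatedness
#' of the species involved is absorbed by the random effects.
#'
#' @inheritParams fit_anova_family_region
#' @param tree Phylogeny covering the species (made ultrametric and pruned
#'   internally).
#' @param ... MCMC settings passed to [fit_pglmm()].
#' @return A `family_contrast_fit` with conditional residuals and the
#'   underlying `pglmm_fit` as `gibbs_fit`.
#' @export
fit_phylo_family_region <- function(table, trait, tree, ...) {
  dat <- shared_family_data(table, trait)
  tree <- force_ultrametric(tree)
  tree <- prune_to_taxa(tree, unique(as.character(dat$species)))
  keep <- dat$species %in% tree$tip.label
  if (any(!keep)) {
    message("dropping ", sum(!keep), " individuals of species absent from the tree")
    dat <- dat[keep, , drop = FALSE]
    dat$family <- droplevels(dat$family)
    dat$cell <- droplevels(dat$cell)
  }
  C <- phylo_vcv(tree)
  X <- stats::model.matrix(~ 0 + cell, dat)
  colnames(X) <- levels(dat$cell)
  species <- factor(as.character(dat$species),
                    levels = intersect(rownames(C), unique(as.character(dat$species))))
  Z <- stats::model.matrix(~ 0 + species)
  colnames(Z) <- levels(species)
  Cs <- C[levels(species), levels(species), drop = FALSE]
  design <- structure(list(y = as.numeric(dat[[trait]]), X = X, Z = Z, C = Cs,
                           species = species, n_dropped = 0L,
                           terms = colnames(X), response = trait),
                      class = "pglmm_design")
  sp_iid <- diag(nlevels(species))
  dimnames(sp_iid) <- list(levels(species), levels(species))
  fit <- fit_pglmm(design, extra_blocks = list(species_iid = sp_iid), ...)
  fams <- levels(dat$family)
  regions <- levels(dat$region)
  rows <- lapply(fams, function(f) {
    ca <- paste0(f, ":", regions[1]); cb <- paste0(f, ":", regions[2])
    dr <- fit$beta[, cb] - fit$beta[, ca]
    qs <- stats::quantile(dr, c(0.025, 0.975), names = FALSE)
    data.frame(family = f, trait = trait, difference = mean(dr),
               se = stats::sd(dr), lo95 = qs[1], hi95 = qs[2],
               p = NA_real_, significant = qs[1] > 0 | qs[2] < 0,
               significant_holm = NA, stringsAsFactors = FALSE)
  })
  structure(list(contrasts = do.call(rbind, rows), residuals = fit$residuals,
                 data = dat, model = "phylo", gibbs_fit = fit),
            class = "family_contrast_fit")
}

#' Compare residual distributions of the paired Question-3 models
#'
#' @param anova_fit,phylo_fit `family_contrast_fit` objects fitted on the
#'   same rows.
#' @return A list: `trait`, residual vectors, `sd_anova`, `sd_phylo`,
#'   deciles of each residual distribution, and `phylo_more_constrained`
#'   (TRUE when the phylogenetic model's residual SD is no larger).
#' @export
compare_residuals <- function(anova_fit, phylo_fit) {
  stopifnot(inherits(anova_fit, "family_contrast_fit"),
            inherits(phylo_fit, "family_contrast_fit"))
  ra <- as.numeric(anova_fit$residuals); rp <- as.numeric(phylo_fit$residuals)
  if (length(ra) != length(rp)) stop("models were fitted on different row counts")
  probs <- seq(0.1, 0.9, by = 0.1)
  list(trait = anova_fit$contrasts$trait[1],
       residuals_anova = ra, residuals_phylo = rp,
       sd_anova = stats::sd(ra), sd_phylo = stats::sd(rp),
       quantiles_anova = stats::quantile(ra, probs),
       quantiles_phylo = stats::quantile(rp, probs),
       phylo_more_constrained = stats::sd(rp) <= stats::sd(ra))
}

#' Run the full Question-3 contrast analysis for several traits
#'
#' @param table Individual-level trait table.
#' @param tree Phylogeny covering the species.
#' @param traits Character vector of trait columns (default: the nine
#'   derived chemical traits present in the table).
#' @param seed Base seed; trait k uses `seed + k`.
#' @param ... MCMC settings passed to [fit_phylo_family_region()].
#' @return A list with `contrasts` (both models, all traits) and
#'   `residual_comparison` (one row per trait).
#' @export
run_question3 <- function(table, tree, traits = NULL, seed = 1L, ...) {
  if (is.null(traits)) {
    traits <- intersect(names(default_trait_models()), names(table))
  }
  if (!length(traits)) stop("no traits to analyse")
  contrasts <- list(); rescomp <- list()
  for (k in seq_along(traits)) {
    tr <- traits[k]
    an <- fit_anova_family_region(table, tr)
    ph <- fit_phylo_family_region(table, tr, tree, seed = seed + k, ...)
    shared <- intersect(an$contrasts$family, ph$contrasts$family)
    a <- an$contrasts[an$contrasts$family %in% shared, ]
    p <- ph$contrasts[ph$contrasts$family %in% shared, ]
    contrasts[[tr]] <- data.frame(
      trait = tr, family = a$family,
      difference_anova = a$difference, significant_anova = a$significant,
      difference_phylo = p$difference[match(a$family, p$family)],
      significant_phylo = p$significant[match(a$family, p$family)],
      stringsAsFactors = FALSE)
    cr <- compare_residuals(an, ph)
    rescomp[[tr]] <- data.frame(trait = tr, sd_anova = cr$sd_anova,
                                sd_phylo = cr$sd_phylo,
                                phylo_more_constrained = cr$phylo_more_constrained)
  }
  list(contrasts = do.call(rbind, c(contrasts, make.row.names = FALSE)),
       residual_comparison = do.call(rbind, c(rescomp, make.row.names = FALSE)))
}
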
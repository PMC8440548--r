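# reefchem

Comparative-phylogenetic analysis of consumer **chemical traits** — body
%C/%N/%P, their molar ratios, and mass-specific N and P excretion rates —
for individual-level data collected across two biogeographic regions.
Written for ecosystem ecologists and comparative biologists who want to ask:
how much of the trait variation that drives consumer-mediated nutrient
cycling is contemporary ecology, and how much is evolutionary history?

The package implements three linked analyses over a trait table and a time
tree, plus a synthetic-data generator with known ground truth so that every
stage is testable end to end:

1. **Variance partitioning** — a Bayesian phylogenetic mixed model (animal
   model) per trait,

   y = Xβ + Zu + e,  u ~ N(0, σ²_phylo C),  e ~ N(0, σ²_resid I),

   where C is the species-by-species phylogenetic covariance matrix
   (shared root-to-ancestor branch lengths). Fitted by a blocked Gibbs
   sampler (joint multivariate-normal draw of (β, u) via the mixed-model
   equations, conjugate inverse-gamma variance draws). Reports marginal R²
   (fixed effects), conditional R² (fixed + phylogeny), the phylogeny-only
   model's R², and conditional DIC for model comparison.
2. **Phylogenetic signal and isotopic niche by region** — maximum-likelihood
   Pagel's λ and Blomberg's K with 999-permutation randomization tests; an
   individual-level bootstrap (resampling individuals within species) that
   makes λ distributions comparable across regions; and an isotopic-niche
   comparison that z-scores δ13C/δ15N within region, resamples equal-size
   communities without replacement, and compares standard ellipse areas
   (π·√det S), convex hulls, and per-axis Kolmogorov–Smirnov tests.
3. **Family-by-region contrasts** — paired models
   `trait ~ 0 + family:region` (cell-means ANOVA) and the same cells plus
   iid-species and phylogenetic random effects, asking whether con-familial
   differences between regions exceed what relatedness alone predicts.

## Worked example

```r
library(reefchem)

# a two-region synthetic assemblage with known ground truth
sim <- simulate_two_region_dataset(sim_config(
  n_species_per_region = c(20, 28), n_shared_families = 4,
  individuals_per_species = c(2, 6), seed = 3))
tab  <- derive_chemical_traits(sim$table)
tree <- force_ultrametric(sim$tree)
C    <- phylo_vcv(tree)

design <- build_design(tab, "body_pct_P",
                       c("d13C", "d15N", "trophic_group", "region", "log10_mass"),
                       C, reference_levels = list(region = "a"))
fit <- fit_pglmm(design, seed = 1)
fit
```

```
Phylogenetic mixed model fit (1000 retained draws)
  R2 fixed  0.168 [0.073, 0.278]
  R2 full   0.924 [0.876, 0.959]
  DIC       326.6 (pD 43.3)
                      term    mean   lo95   hi95 significant
1              (Intercept)  2.6716  1.065  4.247        TRUE
2                     d13C  0.2463  0.106  0.389        TRUE
3                     d15N  0.3953  0.192  0.586        TRUE
4 trophic_groupinvertivore -0.0118 -0.757  0.723       FALSE
5    trophic_groupomnivore  0.3026 -0.564  1.156       FALSE
6    trophic_grouppredator  0.4955 -0.328  1.297       FALSE
7                  regionb  0.8740  0.283  1.511        TRUE
8               log10_mass -0.2446 -0.440 -0.047        TRUE
```

Read: ecological predictors alone explain ~17% of the variation in body %P
(marginal R², with δ15N and δ13C the strongest standardized effects), while
fixed effects plus the phylogenetic species effect explain ~92%
(conditional R²) — the trait is dominated by phylogenetic structure, which
is exactly how these data were generated (`sim$truth` holds the generating
values). The region coefficient is the region-b offset relative to region a
(the intercept); 0.87 [0.28, 1.51] recovers the generating +0.8 body-P
offset. At only 48 species, individual coefficients can stray (the mass
effect here is significantly negative although its generating value is a
small positive number); the simulation studies in the test suite quantify
this at scale.

The numbered scripts under `analysis/` run the full workflow in sequence
(simulate → Question 1 → signal → niche → contrasts), writing tidy CSVs
under `results/`; `run_all()` does the same in one call.

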
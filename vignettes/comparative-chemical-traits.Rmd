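---
title: "Partitioning chemical-trait variation between ecology and phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning chemical-trait variation between ecology and phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefchem)
```

## The scientific problem

Consumers shape nutrient cycling through their "chemical traits": the
carbon, nitrogen and phosphorus stored in body tissue (body %C, %N, %P and
their molar ratios) and the rates at which they excrete N and P. On coral
reefs, where fishes are a dominant nutrient pool, two kinds of explanation
compete for why species differ in these traits: contemporary ecology (diet,
trophic position, body size, nutrient demand) and evolutionary history
(related species resembling each other because the traits are
phylogenetically conserved). `reefchem` implements a comparative-phylogenetic
workflow that separates the two for individual-level trait data collected in
two biogeographic regions, and a synthetic-data generator with known ground
truth so every stage can be validated end to end.

The workflow answers three questions:

1. **Variance partitioning.** How much trait variation do ecological
   predictors explain relative to phylogenetic relatedness?
2. **Regional conservatism.** Is the phylogenetic signal of each trait
   stronger in one region, and do the regions differ in isotopic niche
   breadth?
3. **Family-by-region contrasts.** Do differences between con-familial
   species across regions exceed what relatedness alone predicts?

## Models and statistics

### Phylogenetic covariance

All phylogenetic structure enters through the species-by-species matrix
\(C\), where \(C_{ij}\) is the branch length shared from the root to the
most recent common ancestor of species \(i\) and \(j\) (the trait covariance
expected under Brownian motion). Trees are first forced ultrametric by
non-negative least squares: per-edge adjusted lengths minimise the sum of
squared changes subject to equal root-to-tip sums and nonnegative lengths.
Pruning preserves the original root (the stem to the retained clade is kept
as a root edge and added to \(C\)), so building \(C\) and pruning commute.
We work with \(C\) and its Cholesky factorization throughout rather than a
sparse-inverse representation; the results are identical, only the
factorization route differs.

### The phylogenetic mixed model (Question 1)

For individual \(k\) of species \(s\),

\[ y_k = x_k^\top \beta + u_{s(k)} + e_k, \qquad
   u \sim \mathcal N(0, \sigma^2_{\text{phylo}} C), \qquad
   e \sim \mathcal N(0, \sigma^2_{\text{resid}} I). \]

Continuous predictors are z-scored so the \(\beta\) are standardized effect
sizes; categorical predictors are treatment-coded (region a — the Caribbean
analogue — is the reference level). Sampling is by blocked Gibbs:
\((\beta, u)\) jointly from their multivariate-normal full conditional via a
Cholesky factorization of the mixed-model equations, and each variance from
its conjugate inverse-gamma full conditional. Priors are inverse-gamma
\((\varepsilon, \varepsilon)\) with \(\varepsilon = 0.001\) as the
conventional vague default; \(\varepsilon\) is an argument because
"uninformative" is a family, not a number, and sensitivity to it should be
checkable. The sampler's correctness is tested with a successive-conditional
simulator (redrawing \(y\) from the current parameters each sweep leaves the
prior invariant), and its reduction to an ordinary random-intercept model at
\(C = I\) is checked against a REML fit.

Variance is partitioned per retained draw: the marginal
\(R^2_{\text{fixed}} = \operatorname{Var}(X\beta) / (\operatorname{Var}(X\beta)
+ \sigma^2_{\text{phylo}} + \sigma^2_{\text{resid}})\) and the conditional
\(R^2_{\text{full}}\) adds \(\sigma^2_{\text{phylo}}\) to the numerator;
\(\operatorname{Var}(X\beta)\) is the sample variance of the linear
predictor for that draw (the population variance is not available for
arbitrary designs and the sample version keeps \(R^2_{\text{fixed}} \le
R^2_{\text{full}}\) per draw by construction). Model comparison uses the
conditional DIC — deviance of \(y\) given \((\beta, u,
\sigma^2_{\text{resid}})\), \(p_D = \bar D - D(\bar\theta)\) — the
convention of the MCMC software family this style of analysis descends
from.

Per-trait fixed-effect sets follow stoichiometric practice: mass-corrected
excretion responses exclude mass as a predictor; a body-percent response
never has its own numerator or denominator among its predictors; region is
always included.

### Phylogenetic signal and its regional comparison (Question 2)

Pagel's \(\lambda\) rescales the off-diagonal of \(C\); the estimate
maximises the Gaussian likelihood of species means with the phylogenetic
mean and rate profiled out by GLS at each candidate \(\lambda\), searched on
\([0, 1]\) by bounded scalar optimization (tolerance \(10^{-6}\)) with both
endpoints checked. On a star phylogeny the profile likelihood is flat in
\(\lambda\); we return 0 with an `unidentifiable` flag rather than an
arbitrary interior optimum. Blomberg's \(K\) is computed from the closed
form: the observed ratio of tip variance about the GLS mean to the
phylogenetically corrected error variance, divided by its Brownian
expectation \((\operatorname{tr}(C) - n / \mathbf 1^\top C^{-1} \mathbf 1)
/ (n - 1)\). The randomization test shuffles trait values across tips and
uses the add-one p-value \((1 + \#\{\text{perm} \ge \text{obs}\}) / (1 +
n_{\text{perm}})\), which cannot be exactly zero.

Species means are estimates — individual counts per species span two orders
of magnitude in data of this kind — so regions are compared with an
individual-level bootstrap: each iteration resamples individuals within
species with replacement (not species within regions; the motivating
uncertainty is within-species sampling), recomputes species means and the
statistic. Iteration \(i\) uses seed \(+i\), so distributions bootstrapped
for different groups are pairable by iteration. Two regions are flagged
"separated" when at least 97.5% of paired draws order one way; the original
analysis reported significance from bootstrap spread without stating a rule,
so the paired-draw exceedance rule is this package's documented choice.

### Isotopic niche (Question 2)

Isotope baselines differ between regions, so \(\delta^{13}\)C and
\(\delta^{15}\)N are z-scored within region before any comparison; only
shape, not location or scale, is compared. Equal-size communities are drawn
without replacement from each region (the community unit is the individual
— the stated community sizes count individuals, so we resample individuals
rather than species), and per community pair we compute the standard
ellipse area \(\mathrm{SEA} = \pi\sqrt{\det S}\) (S the sample covariance;
the \((n-1)/(n-2)\) small-sample correction is available but off by
default, matching the standard rather than corrected ellipse), the convex
hull area (vertex set by the standard planar hull algorithm, area by the
shoelace formula; collinear input gives 0), and a two-sample
Kolmogorov–Smirnov test per axis with the asymptotic p-value (the R default
at these sample sizes). The asymptotic test is mildly conservative — its
measured size at \(n = 250\) per group is about 0.041 at nominal 0.05
because the statistic lives on a lattice — which slightly depresses
percent-significant figures but does not affect the power comparisons. The
KS significance threshold is 0.05, the same \(\alpha\) used elsewhere.

Because z-scoring removes scale, regional differences in standardized niche
metrics can only arise from shape: the cross-axis correlation (narrower
ellipses) and tail weight (wider hulls and detectable KS differences). The
synthetic generator therefore varies exactly those two features between
regions.

### Family-by-region contrasts (Question 3)

Two models are fitted per trait on families present in both regions (a
family missing from either region, or with fewer than two usable
individuals in a cell, never yields a contrast):

1. the cell-means ANOVA `trait ~ 0 + family:region`, with per-family
   region contrasts tested at unadjusted \(\alpha = 0.05\) (a Holm-adjusted
   column is also emitted, since eleven-odd simultaneous contrasts deserve
   one), and
2. the same fixed cells plus an iid species intercept and a phylogenetic
   species effect, fitted with the Gibbs sampler; a contrast is significant
   when its 95% credible interval excludes zero.

Residuals for the model comparison are conditional (given the random
effects). When regional divergence is generated purely by deep clade
structure, the ANOVA finds family contrasts but the phylogenetic model
absorbs them into relatedness — the qualitative signature the workflow is
designed to detect. The end-to-end check operationalises that signature per
replicate as: at least one family significant under ANOVA, and fewer than
half of those families significant under the phylogenetic model.

## The synthetic generator

`simulate_two_region_dataset()` builds one Yule tree (depth 1), slices it
at a configurable depth (default 0.7, deep enough that a depth-1 Yule tree yields tens of clades) into family clades — giving
family-level trait clustering without a separate taxonomy simulator —
allocates species to two regions with a configured number of clades shared,
and generates traits as region-specific \(\lambda\)-scaled Brownian motion
plus covariate effects, region offsets, and Gaussian within-species noise.
Trophic group is a BM-evolved latent thresholded into four classes, so the
categorical covariate itself carries phylogenetic signal, mirroring the
collinearity a real analysis confronts. Default scale matches the
motivating study system: 71 + 107 species, 11 shared of ~40 families, a
negative-binomial (mu 7.6, size 0.8) + 1 individuals-per-species
distribution emulating observed 1–115 spreads, generating \(\lambda\) of
0.95 (region a) vs 0.7 (region b), body %P raised by +0.8 and N excretion
lowered by 0.6 in region b, and isotope clouds with correlation 0.6 /
Gaussian tails in region a vs correlation 0.1 / t(3) tails in region b.
Excretion is emitted as a whole-fish rate (latent trait times wet mass) so
the standard mass correction recovers a Gaussian analysis-scale trait.

What the generator does *not* emulate: measurement protocol artefacts
(chamber effects, control correction), non-Brownian trait evolution (OU),
within-region spatial structure, and non-Gaussian trait noise. Passing
recovery tests on these data therefore demonstrates that the estimators and
samplers are correct under their assumed model, not that the assumed model
is adequate for any particular field dataset.

## Numerical choices and problem sizes

- \(\lambda\)-likelihoods and the Gibbs sampler use Cholesky
  factorizations; a failed factorization gets one small-ridge retry and then
  errors. Non-finite variance draws abort with a diagnostic rather than
  propagate.
- MCMC defaults are desk-scale — 4,000 iterations, 1,000 burn-in, thin 3
  (1,000 retained draws) — chosen so that the full simulation studies in the
  test suite (hundreds of fits) complete in minutes on one core;
  publication-scale runs (80,000 / 10,000 / thin 10) are a matter of
  arguments. A split-chain potential-scale-reduction diagnostic on the
  variance components warns above 1.1.
- The end-to-end replication study runs at study scale (71 + 107 species,
  11 shared families) with a fixed 8 individuals per species and 300
  bootstrap iterations per region: smaller assemblages lack the power to
  separate bootstrap lambda distributions or detect the region offset
  reliably. Its clade-driven variant sets all covariate effects and region
  offsets to zero so that regional divergence is Brownian motion on the
  shared tree and nothing else.
- Randomization-test calibration uses Blomberg's K (closed form) rather
  than \(\lambda\) (an optimization per permutation) purely for speed; the
  test machinery is statistic-agnostic.
- Species present in the trait table but absent from the tree are dropped
  and logged, never imputed; how the original analysis handled them is not
  recorded, so this is a documented package choice.

## Known limitations

- Gaussian responses only; heavy-tailed or zero-inflated excretion data
  would need transformation before modelling.
- \(K\)'s bootstrap spread is not monotone in within-species sample size
  (attenuation pushes noisy estimates toward a variance-compressed range),
  which is why the regional comparison defaults to \(\lambda\).
- The paired-draw separation rule treats bootstrap draws as exchangeable
  across groups; it is a descriptive flag, not a calibrated test.
- Conditional DIC is reported because it matches the convention of the
  software family this analysis style descends from; marginal-likelihood
  comparison would penalise the random effect differently.
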
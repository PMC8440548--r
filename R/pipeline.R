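# Trait derivation, input validation, and the end-to-end driver.

ATOMIC_MASS <- c(C = 12.011, N = 14.007, P = 30.974)

#' Derive mass-corrected excretion rates and molar ratios
#'
#' Adds to the table: `exc_N_mass`, `exc_P_mass` (excretion rate divided by
#' wet body mass), `exc_NP_molar`, and the molar body ratios `body_CN`,
#' `body_CP`, `body_NP`, computed as `(%X / M_X) / (%Y / M_Y)` with atomic
#' masses C 12.011, N 14.007, P 30.974. Missing inputs propagate missing
#' outputs; rows with nonpositive mass are rejected with a message.
#'
#' @param table Trait table with `wet_mass` and any of `exc_N`, `exc_P`,
#'   `body_pct_C`, `body_pct_N`, `body_pct_P`.
#' @return The table with derived columns appended (and a `log10_mass`
#'   column if absent).
#' @export
derive_chemical_traits <- function(table) {
  stopifnot(is.data.frame(table))
  if (!"wet_mass" %in% names(table)) stop("table needs a 'wet_mass' column")
  bad <- !is.na(table$wet_mass) & table$wet_mass <= 0
  if (any(bad)) {
    message("rejecting ", sum(bad), " rows with nonpositive wet_mass")
    table <- table[!bad, , drop = FALSE]
  }
  molar <- function(pct, el) pct / ATOMIC_MASS[[el]]
  has <- function(v) v %in% names(table)
  if (has("exc_N")) table$exc_N_mass <- table$exc_N / table$wet_mass
  if (has("exc_P")) table$exc_P_mass <- table$exc_P / table$wet_mass
  if (has("exc_N") && has("exc_P")) {
    table$exc_NP_molar <- molar(table$exc_N, "N") / molar(table$exc_P, "P")
  }
  if (has("body_pct_C") && has("body_pct_N")) {
    table$body_CN <- molar(table$body_pct_C, "C") / molar(table$body_pct_N, "N")
  }
  if (has("body_pct_C") && has("body_pct_P")) {
    table$body_CP <- molar(table$body_pct_C, "C") / molar(table$body_pct_P, "P")
  }
  if (has("body_pct_N") && has("body_pct_P")) {
    table$body_NP <- molar(table$body_pct_N, "N") / molar(table$body_pct_P, "P")
  }
  if (!has("log10_mass")) table$log10_mass <- log10(table$wet_mass)
  table
}

#' Validate a trait table against a phylogeny
#'
#' Reports (without failing) species absent from the tree, out-of-range
#' values (nonpositive mass, body percentages outside 0-100), and duplicated
#' rows. Fails only on structural problems: missing required columns or no
#' species overlap with the tree.
#'
#' @param table Trait table.
#' @param tree Phylogeny.
#' @return A list report: `species_not_in_tree`, `tips_not_in_table`,
#'   `out_of_range` (row indices by check), `duplicate_rows`, `clean`
#'   (TRUE when all reports are empty).
#' @export
validate_inputs <- function(table, tree) {
  required <- c("species", "family", "region", "wet_mass")
  miss <- setdiff(required, names(table))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  validate_phylo(tree)
  sp <- unique(as.character(table$species))
  not_in_tree <- setdiff(sp, tree$tip.label)
  if (length(not_in_tree) == length(sp)) stop("no species overlap between table and tree")
  fam_per_sp <- tapply(as.character(table$family), as.character(table$species),
                       function(f) length(unique(f)))
  multi_family <- names(fam_per_sp)[fam_per_sp > 1]
  out_of_range <- list(
    nonpositive_mass = which(!is.na(table$wet_mass) & table$wet_mass <= 0))
  for (v in intersect(c("body_pct_C", "body_pct_N", "body_pct_P"), names(table))) {
    out_of_range[[v]] <- which(!is.na(table[[v]]) &
                               (table[[v]] < 0 | table[[v]] > 100))
  }
  dup <- which(duplicated(table))
  report <- list(species_not_in_tree = not_in_tree,
                 tips_not_in_table = setdiff(tree$tip.label, sp),
                 species_with_multiple_families = multi_family,
                 out_of_range = out_of_range,
                 duplicate_rows = dup)
  report$clean <- length(not_in_tree) == 0 && length(multi_family) == 0 &&
    all(lengths(out_of_range) == 0) && length(dup) == 0
  report
}

#' Read a trait table from CSV
#'
#' UTF-8, comma-separated, header row, "." decimal, empty fields as missing.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_trait_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' Run the full comparative analysis end to end
#'
#' Derives chemical traits, validates inputs, then runs variance
#' partitioning (Question 1), phylogenetic-signal bootstrap comparison and
#' isotopic-niche resampling (Question 2), and family-by-region contrasts
#' (Question 3); writes tidy CSV outputs plus a JSON run manifest when
#' `outdir` is given.
#'
#' @param table Individual-level trait table (raw columns; derived traits
#'   are added internally), or NULL to simulate from `config$sim`.
#' @param tree Phylogeny, or NULL in synthetic mode.
#' @param config List of settings: `sim` (a [sim_config()], synthetic mode),
#'   `seed`, `signal_trait` (trait for the bootstrap comparison, default
#'   `body_pct_P`), `boot_iter`, `community_sizes`, `niche_iter`, `mcmc`
#'   (list passed to the Gibbs fits), `q1_traits`, `q3_traits`.
#' @param outdir Output directory (created if needed), or NULL to skip
#'   writing.
#' @return A list: `q1`, `signal`, `niche`, `q3`, `validation`, `manifest`.
#' @export
run_all <- function(table = NULL, tree = NULL, config = list(), outdir = NULL) {
  seed <- config$seed %||% 1L
  if (is.null(table)) {
    simcfg <- config$sim %||% sim_config(seed = seed)
    sim <- simulate_two_region_dataset(simcfg)
    table <- sim$table; tree <- sim$tree
  }
  if (is.null(tree)) stop("a tree is required when a table is supplied")
  n_input <- nrow(table)
  table <- derive_chemical_traits(table)
  n_rejected <- n_input - nrow(table)
  validation <- validate_inputs(table, tree)
  tree <- force_ultrametric(tree)
  tree <- prune_to_taxa(tree, unique(as.character(table$species)))
  keep <- table$species %in% tree$tip.label
  table <- table[keep, , drop = FALSE]
  mcmc <- config$mcmc %||% list()

  # Question 1: variance partitioning per trait
  q1_traits <- config$q1_traits %||% names(default_trait_models())
  tm <- default_trait_models()[intersect(q1_traits, names(table))]
  q1 <- do.call(run_question1, c(list(table = table, tree = tree,
                                      trait_models = tm,
                                      reference_levels = list(region = "a"),
                                      seed = seed), mcmc))

  # Question 2a: bootstrap phylogenetic signal per region
  C <- phylo_vcv(tree)
  signal_trait <- config$signal_trait %||% "body_pct_P"
  boot_iter <- config$boot_iter %||% 1000L
  regions <- sort(unique(as.character(table$region)))
  boots <- lapply(regions, function(r) {
    bootstrap_signal(table[table$region == r, ], signal_trait, C,
                     statistic = "lambda", n_iter = boot_iter, seed = seed,
                     group_label = r)
  })
  names(boots) <- regions
  boot_full <- bootstrap_signal(table, signal_trait, C, statistic = "lambda",
                                n_iter = boot_iter, seed = seed,
                                group_label = "full")
  signal_cmp <- compare_signal_groups(boots[[1]], boots[[2]])
  mpd <- vapply(regions, function(r) {
    mean_pairwise_distance(tree, unique(table$species[table$region == r]))
  }, numeric(1))

  # Question 2b: isotopic niche
  sizes <- config$community_sizes %||% c(250, 375, 450)
  n_by_region <- table(table$region[stats::complete.cases(table[, c("d13C", "d15N")])])
  sizes <- sizes[sizes <= min(n_by_region)]
  niche <- if (length(sizes)) {
    run_question2_niche(table, sizes = sizes,
                        n_iter = config$niche_iter %||% 500L, seed = seed)
  } else NULL

  # Question 3: family-by-region contrasts
  q3_traits <- config$q3_traits %||% intersect(names(default_trait_models()), names(table))
  q3 <- do.call(run_question3, c(list(table = table, tree = tree,
                                      traits = q3_traits, seed = seed), mcmc))

  manifest <- list(seed = seed, n_input_rows = n_input,
                   n_rejected_rows = n_rejected, n_modeled_rows = nrow(table),
                   n_species = length(unique(table$species)),
                   regions = as.list(table(table$region)),
                   signal_trait = signal_trait, boot_iter = boot_iter,
                   community_sizes = sizes,
                   mean_pairwise_distance = as.list(mpd),
                   questions_completed = c("q1", "q2_signal",
                                           if (!is.null(niche)) "q2_niche", "q3"),
                   package_version = as.character(utils::packageVersion("reefchem")))
  out <- list(q1 = q1, signal = list(bootstrap = c(boots, list(full = boot_full)),
                                     comparison = signal_cmp, mpd = mpd),
              niche = niche, q3 = q3, validation = validation,
              manifest = manifest, table = table, tree = tree)
  if (!is.null(outdir)) write_results(out, outdir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_results <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  wcsv(results$q1$comparison, "q1_model_comparison.csv")
  wcsv(results$q1$coefficients, "q1_coefficients.csv")
  draws <- do.call(rbind, lapply(results$signal$bootstrap, function(b) {
    data.frame(group = b$group_label, statistic = b$statistic,
               iteration = seq_along(b$draws), value = b$draws)
  }))
  wcsv(draws, "q2_signal_draws.csv")
  wcsv(results$signal$comparison, "q2_signal_summary.csv")
  if (!is.null(results$niche)) {
    wcsv(results$niche$summary, "q2_niche_summary.csv")
    wcsv(results$niche$iterations, "q2_niche_iterations.csv")
  }
  wcsv(results$q3$contrasts, "q3_contrasts.csv")
  wcsv(results$q3$residual_comparison, "q3_residual_comparison.csv")
  jsonlite::write_json(results$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
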
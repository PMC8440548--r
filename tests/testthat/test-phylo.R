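test_that("read_newick round-trips tips and branch lengths and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  tr <- read_newick(f)
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 1))

  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_equal(ape::Ntip(tr), 3L)
  d <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(d, rep(2, 3))

  writeLines("(A:1,B;", f)
  expect_error(read_newick(f), "malformed|parse")
  writeLines("(A,B);", f)
  expect_error(read_newick(f), "branch length")
})

test_that("force_ultrametric equalizes depths minimally and is idempotent", {
  # already ultrametric: untouched
  tr <- fixture_tree8()
  expect_identical(force_ultrametric(tr)$edge.length, tr$edge.length)

  # 2-tip case has the closed-form NNLS solution: split the difference
  tr2 <- ape::read.tree(text = "(A:1,B:2);")
  out <- force_ultrametric(tr2)
  expect_equal(sort(out$edge.length), c(1.5, 1.5), tolerance = 1e-9)

  # postcondition + idempotence on random non-ultrametric trees
  for (s in 1:10) {
    set.seed(s)
    tr <- ape::rtree(12)
    out <- force_ultrametric(tr)
    depths <- ape::node.depth.edgelength(out)[1:12]
    expect_lt(max(depths) - min(depths), 1e-9 * max(depths))
    expect_identical(out$edge.length, force_ultrametric(out)$edge.length)
    expect_true(all(out$edge.length >= 0))
    expect_identical(ape::Ntip(out), ape::Ntip(tr))
  }
})

test_that("phylo_vcv returns shared root-to-MRCA branch lengths", {
  C <- phylo_vcv(ape::read.tree(text = "(A:1,B:1);"))
  expect_equal(unname(C), diag(2))

  C <- phylo_vcv(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)

  C <- phylo_vcv(star_tree(6, depth = 3))
  expect_equal(unname(C), 3 * diag(6))
})

test_that("vcv is PSD and consistent with patristic distances on random trees", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(4:20, 1)
    tr <- ape::rphylo(n, birth = 1, death = 0)
    C <- suppressWarnings(phylo_vcv(tr))
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
    # d(i,j) = C[i,i] + C[j,j] - 2 C[i,j], against an independent path walk
    D <- stats::cophenetic(tr)[rownames(C), colnames(C)]
    D_from_C <- outer(diag(C), diag(C), "+") - 2 * C
    expect_equal(unname(D_from_C), unname(D), tolerance = 1e-9)
  }
})

test_that("lambda_transform scales off-diagonals only and validates lambda", {
  C <- phylo_vcv(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_identical(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C), nrow = 3), ignore_attr = TRUE)
  half <- lambda_transform(C, 0.5)
  expect_equal(half["A", "B"], 0.5)
  expect_equal(diag(half), diag(C))
  expect_error(lambda_transform(C, -0.1), "lambda")
  expect_error(lambda_transform(C, 1.5), "lambda")
})

test_that("prune_to_taxa preserves path lengths and commutes with vcv", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_identical(prune_to_taxa(tr, tr$tip.label), tr)

  pruned <- prune_to_taxa(tr, c("A", "C"))
  expect_setequal(pruned$tip.label, c("A", "C"))
  expect_equal(unname(stats::cophenetic(pruned)["A", "C"]), 4)

  expect_message(one <- prune_to_taxa(tr, c("A", "Z")), "Z")
  expect_identical(one$tip.label, "A")
  expect_error(prune_to_taxa(tr, c("X", "Y")), "none")

  for (s in 1:10) {
    set.seed(s)
    big <- ape::rphylo(10, 1, 0)
    keep <- sample(big$tip.label, 5)
    C_then_prune <- suppressWarnings(phylo_vcv(big))[keep, keep]
    prune_then_C <- suppressWarnings(phylo_vcv(prune_to_taxa(big, keep)))[keep, keep]
    expect_equal(prune_then_C, C_then_prune, tolerance = 1e-9)
  }
})

test_that("mean pairwise distance averages patristic distances over pairs", {
  expect_equal(mean_pairwise_distance(ape::read.tree(text = "(A:1,B:1);")), 2)
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(mean_pairwise_distance(tr), 10 / 3)
  expect_error(mean_pairwise_distance(tr, "A"), "two taxa")
  # ultrametric bound: all pairwise distances <= 2 * depth
  tr8 <- fixture_tree8()
  expect_lte(mean_pairwise_distance(tr8), 2 * 2)
})
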
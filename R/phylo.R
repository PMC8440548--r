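#' Read a rooted phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contract the rest
#' of the pipeline relies on: one tree per file, unique tip labels, and branch
#' lengths present on every edge.
#'
#' @param path Path to a newick file containing a single tree.
#' @return An object of class `"phylo"`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed newick in '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed newick in '", path, "': no tree could be parsed")
  if (inherits(tree, "multiPhylo")) stop("expected one tree per file, found ", length(tree))
  validate_phylo(tree)
  tree
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks unique tip labels, presence of branch lengths, and nonnegative edge
#' lengths. Called by every function that consumes a tree.
#'
#' @param tree A `"phylo"` object.
#' @return The tree, invisibly.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels: ",
    paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' Force a tree to be ultrametric by non-negative least squares
#'
#' Adjusts branch lengths so that all root-to-tip path lengths are equal,
#' minimising the sum of squared changes to the observed branch lengths
#' subject to all lengths remaining nonnegative; topology is unchanged.
#' Already-ultrametric trees are returned untouched.
#'
#' @param tree A rooted `"phylo"` object with branch lengths.
#' @param tol Relative tolerance on root-to-tip spread below which the tree
#'   counts as already ultrametric.
#' @return An ultrametric `"phylo"` object with the same topology.
#' @export
force_ultrametric <- function(tree, tol = 1e-9) {
  validate_phylo(tree)
  if (is_ultrametric(tree, tol)) return(tree)
  out <- phytools::force.ultrametric(tree, method = "nnls", message = FALSE)
  # nnls can return tiny negative lengths from rounding; clamp at zero
  out$edge.length[out$edge.length < 0 & out$edge.length > -1e-12] <- 0
  validate_phylo(out)
  out
}

#' @rdname force_ultrametric
#' @export
is_ultrametric <- function(tree, tol = 1e-9) {
  depths <- node_depths(tree)[seq_along(tree$tip.label)]
  (max(depths) - min(depths)) <= tol * max(max(depths), 1)
}

# root-to-node path lengths for all nodes, by edge traversal
node_depths <- function(tree) {
  n_node <- max(tree$edge)
  depth <- numeric(n_node)
  # edges in preorder: parent always visited before child when sorted by parent
  ord <- reorder(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    depth[ord$edge[k, 2]] <- depth[ord$edge[k, 1]] + ord$edge.length[k]
  }
  depth
}

#' Phylogenetic variance-covariance matrix
#'
#' Builds the species-by-species matrix C whose entry (i, j) is the shared
#' branch length from the root to the most recent common ancestor of tips i
#' and j; the diagonal holds root-to-tip distances. Under Brownian motion,
#' trait covariances are proportional to C. Row/column order follows the
#' tree's tip order.
#'
#' @param tree A rooted `"phylo"` object; non-ultrametric input triggers a
#'   warning (call [force_ultrametric()] first for time trees).
#' @return A symmetric positive-semidefinite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_phylo(tree)
  if (!is_ultrametric(tree, tol = 1e-6)) {
    warning("tree is not ultrametric; covariance diagonal will be unequal")
  }
  C <- ape::vcv(tree)
  # a root edge (e.g. the stem kept by prune_to_taxa) is shared by all tips
  if (!is.null(tree$root.edge) && tree$root.edge > 0) C <- C + tree$root.edge
  C
}

#' Pagel's lambda transformation of a phylogenetic covariance matrix
#'
#' Multiplies off-diagonal entries of C by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` returns the Brownian expectation, `lambda = 0` an
#' independence (star) structure.
#'
#' @param C Phylogenetic covariance matrix (see [phylo_vcv()]).
#' @param lambda Scalar in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]")
  }
  out <- C * lambda
  diag(out) <- diag(C)
  out
}

#' Prune a tree to a set of taxa
#'
#' Restricts the tree to `keep`, collapsing degree-2 internal nodes with
#' branch lengths summed so patristic distances among retained tips are
#' preserved. Requested taxa absent from the tree are reported via a message,
#' not an error.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain.
#' @return The pruned `"phylo"` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylo(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    message("dropping ", length(missing), " taxa absent from tree: ",
            paste(missing, collapse = ", "))
  }
  present <- intersect(keep, tree$tip.label)
  if (!length(present)) stop("none of the requested taxa are in the tree")
  if (length(present) == length(tree$tip.label)) return(tree)
  # retain the stem from the original root as a root edge so shared depth
  # (and hence the covariance) is measured from the same origin
  pruned <- ape::keep.tip(tree, present)
  if (length(present) >= 2L) {
    mrca <- ape::getMRCA(tree, present)
    stem <- node_depths(tree)[mrca] + if (is.null(tree$root.edge)) 0 else tree$root.edge
    if (stem > 0) pruned$root.edge <- stem
  }
  pruned
}

#' Mean pairwise patristic distance among taxa
#'
#' Average over all unordered pairs of the path-length (patristic) distance
#' between two tips. Used to compare how closely related two regional
#' assemblages are.
#'
#' @param tree A `"phylo"` object.
#' @param taxa Character vector of at least two tip labels; defaults to all.
#' @return A single numeric distance.
#' @export
mean_pairwise_distance <- function(tree, taxa = tree$tip.label) {
  validate_phylo(tree)
  taxa <- unique(as.character(taxa))
  if (!all(taxa %in% tree$tip.label)) {
    stop("taxa not in tree: ", paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  }
  if (length(taxa) < 2L) stop("need at least two taxa")
  d <- stats::cophenetic(prune_to_taxa(tree, taxa))
  mean(d[upper.tri(d)])
}
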
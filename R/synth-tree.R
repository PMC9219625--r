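# Host species trees for the simulator.  Trees are `ape` "phylo" objects
# throughout; branch lengths are expected substitutions/site for the host
# genes (the transposon can evolve at a scaled rate, see apply_ht_scenario).

#' Simulate an ultrametric Yule species tree
#'
#' Pure-birth tree on `n_leaves` species via [ape::rphylo()], optionally
#' rescaled so that the root-to-tip path length equals `depth` expected
#' substitutions per site.  Leaves are labelled `sp01`, `sp02`, ...
#'
#' @param n_leaves Number of species (>= 2).
#' @param birth_rate Speciation rate per unit time (> 0).
#' @param seed Optional integer seed; the tree is deterministic given
#'   `(n_leaves, birth_rate, seed)`.
#' @param depth Optional root-to-tip depth (substitutions/site) the tree is
#'   rescaled to.
#' @return An ultrametric `phylo` object.
#' @examples
#' tr <- simulate_yule_tree(8, 1, seed = 1)
#' @export
simulate_yule_tree <- function(n_leaves, birth_rate = 1, seed = NULL, depth = NULL) {
  if (n_leaves < 2) stop("n_leaves must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_leaves, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_leaves))
  if (!is.null(depth)) {
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * depth / h
  }
  tr
}

# Age (time before present) of every node of an ultrametric tree, in branch
# length units.  Vector indexed by node number.
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d) - d
}

# Most recent common ancestor age of two tips.
mrca_age <- function(tree, a, b) {
  n <- ape::getMRCA(tree, c(a, b))
  node_ages(tree)[n]
}
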
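# Sequence evolution along a tree under a reversible substitution model.
# Sites are i.i.d.; each branch applies the transition matrix P(t) to every
# site independently (no indels -- simulated sequence sets stay co-linear).

# Evolve an integer-coded sequence for duration t (expected subs/site,
# already including any rate scaling).
evolve_int <- function(v, t, model) {
  if (t <= 0) return(v)
  P <- transition_probs(model, t)
  out <- integer(length(v))
  for (b in 1:4) {
    idx <- which(v == b)
    if (length(idx)) out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
  }
  out
}

#' Evolve a sequence for a given divergence
#'
#' Applies the substitution model to a single sequence for `t` expected
#' substitutions per site.
#'
#' @param seq DNA string.
#' @param t Expected substitutions/site (>= 0).
#' @param model A [substitution_model()].
#' @param seed Optional integer seed.
#' @return The mutated DNA string, same length as the input.
#' @export
evolve_sequence <- function(seq, t, model = substitution_model("K2P"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  int_to_seq(evolve_int(seq_to_int(seq), t * model$rate, model))
}

#' Evolve a root sequence along a species tree
#'
#' Simulates one ungapped sequence per tree node, starting from `root_seq`,
#' with branch lengths interpreted as expected substitutions per site times
#' `model$rate`.
#'
#' @param root_seq DNA string at the root.
#' @param tree A `phylo` object.
#' @param model A [substitution_model()].
#' @param seed Optional integer seed.
#' @param keep_internal Keep internal-node sequences (attribute
#'   `"node_seqs"`, integer-coded) for lineage sampling.
#' @return Named character vector of leaf sequences (one per tip, all the
#'   same length as `root_seq`).
#' @examples
#' tr <- simulate_yule_tree(4, 1, seed = 1, depth = 0.1)
#' leaves <- evolve_along_tree(random_dna(200, seed = 2), tr,
#'                             substitution_model("K2P"), seed = 3)
#' @export
evolve_along_tree <- function(root_seq, tree, model = substitution_model("K2P"),
                              seed = NULL, keep_internal = FALSE) {
  if (!nzchar(root_seq)) stop("root_seq must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  v0 <- seq_to_int(root_seq)  # validates alphabet
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_seqs <- vector("list", ntip + tree$Nnode)
  node_seqs[[root]] <- v0
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]  # preorder
  lens <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1L]; child <- edges[k, 2L]
    node_seqs[[child]] <- evolve_int(node_seqs[[par]], lens[k] * model$rate, model)
  }
  leaves <- vapply(seq_len(ntip), function(i) int_to_seq(node_seqs[[i]]), character(1))
  names(leaves) <- tree$tip.label
  if (keep_internal) attr(leaves, "node_seqs") <- node_seqs
  leaves
}
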
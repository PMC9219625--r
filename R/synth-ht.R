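# Transposon histories along a species tree: vertical descent with optional
# horizontal transfer (HT) directives.  An HT directive (donor, recipient,
# time) replaces the recipient's element by the state of the donor lineage
# sampled `time` substitutions/site (host scale) before the present, then
# lets it diverge for the remaining time, so the donor/recipient element
# divergence reflects the transfer time rather than the species split.

#' Describe a transposon history
#'
#' @param element Ancestral element sequence (DNA string), e.g. from
#'   [make_te_element()].
#' @param te_rate Substitution rate of the element relative to the host genes
#'   (branch lengths are host substitutions/site; the element evolves at
#'   `te_rate` times that).
#' @param model Substitution model for the element.
#' @param ht List of HT directives, each a list with `donor` and `recipient`
#'   (leaf labels) and `time` (host substitutions/site before present).
#' @return An object of class `"te_history"`.
#' @export
te_history <- function(element, te_rate = 1, model = substitution_model("K2P", kappa = 2),
                       ht = list()) {
  stopifnot(te_rate > 0)
  structure(list(element = element, te_rate = te_rate, model = model, ht = ht),
            class = "te_history")
}

# State of the lineage ancestral to `tip` at age `t`, given per-node integer
# sequences from evolve_along_tree(keep_internal = TRUE).  The state is drawn
# from the Markov bridge conditioned on the two realized node states of the
# branch spanning `t`, so the sampled sequence shares the donor lineage's
# actual history up to the transfer time.  Times are host units; the element
# evolves at `te_rate` times the host rate.
lineage_state_at <- function(tree, node_seqs, ages, tip_idx, t, model, te_rate) {
  path <- tip_idx
  node <- tip_idx
  root <- length(tree$tip.label) + 1L
  parent <- function(n) tree$edge[tree$edge[, 2L] == n, 1L]
  while (node != root) {
    node <- parent(node)
    path <- c(path, node)
  }
  if (t > ages[root]) stop("HT time predates the root")
  k <- which(ages[path] >= t)[1L]           # youngest ancestor at least as old as t
  anc <- path[k]
  if (abs(ages[anc] - t) < 1e-12 || k == 1L) return(node_seqs[[anc]])
  child <- path[k - 1L]
  P1 <- transition_probs(model, (ages[anc] - t) * te_rate * model$rate)
  P2 <- transition_probs(model, (t - ages[child]) * te_rate * model$rate)
  va <- node_seqs[[anc]]; vc <- node_seqs[[child]]
  out <- integer(length(va))
  for (a in 1:4) for (b in 1:4) {
    idx <- which(va == a & vc == b)
    if (!length(idx)) next
    w <- P1[a, ] * P2[, b]
    out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = w)
  }
  out
}

#' Simulate element evolution with horizontal transfer
#'
#' Evolves the ancestral element of a [te_history()] along `tree` and applies
#' its HT directives.  Under a vertical-only history the expected element
#' divergence between two species equals their host-gene divergence scaled by
#' `te_rate`; each HT directive makes the donor/recipient element divergence
#' correspond to twice the transfer time instead.
#'
#' @param tree Ultrametric `phylo` object (branch lengths: host
#'   substitutions/site).
#' @param spec A [te_history()].
#' @param seed Optional integer seed.
#' @return A list with `te_seqs` (named character vector, one element
#'   sequence per species) and `truth`, a data frame of applied HT events
#'   (`donor`, `recipient`, `time`).
#' @export
apply_ht_scenario <- function(tree, spec, seed = NULL) {
  stopifnot(inherits(spec, "te_history"))
  if (!is.null(seed)) set.seed(seed)
  tips <- tree$tip.label
  for (d in spec$ht) {
    if (!all(c(d$donor, d$recipient) %in% tips))
      stop("HT directive references unknown species")
    if (d$time < 0) stop("HT time must be >= 0")
    if (d$time > mrca_age(tree, d$donor, d$recipient))
      stop("HT time older than the species' divergence")
  }
  tree_te <- tree
  tree_te$edge.length <- tree$edge.length * spec$te_rate
  leaves <- evolve_along_tree(spec$element, tree_te, spec$model, keep_internal = TRUE)
  node_seqs <- attr(leaves, "node_seqs")
  ages <- node_ages(tree)  # host units
  for (d in spec$ht) {
    tip_idx <- match(d$recipient, tips)
    donor_idx <- match(d$donor, tips)
    state <- lineage_state_at(tree, node_seqs, ages, donor_idx, d$time,
                              spec$model, spec$te_rate)
    leaves[[d$recipient]] <- int_to_seq(
      evolve_int(state, d$time * spec$te_rate * spec$model$rate, spec$model))
  }
  truth <- if (length(spec$ht)) {
    data.frame(donor = vapply(spec$ht, `[[`, "", "donor"),
               recipient = vapply(spec$ht, `[[`, "", "recipient"),
               time = vapply(spec$ht, `[[`, 0, "time"), stringsAsFactors = FALSE)
  } else {
    data.frame(donor = character(), recipient = character(), time = numeric())
  }
  attr(leaves, "node_seqs") <- NULL
  list(te_seqs = leaves, truth = truth)
}
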
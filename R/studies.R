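# Whole-study simulators: a species tree, neutrally evolving single-copy
# host genes (RPL3/RPL4 analogues plus a RAG1-like confirmation gene) and a
# transposon history, vertical or with one planted horizontal transfer.
# These define the validation conditions for the HT detector: 20 species,
# host genes and element evolving at equal rates, root-to-tip depth 0.25
# substitutions/site, 10 kb genes, a 2.5 kb element.

#' Choose donor/recipient for a transfer between the most divergent lineages
#'
#' On an ultrametric tree the maximally divergent leaf pairs are exactly the
#' cross-root pairs.  The donor is taken from the leaf-richer side of the
#' root (first leaf in label order; transfer out of the lineage-rich clade),
#' the recipient from the other side.
#'
#' @param tree Ultrametric `phylo`.
#' @return List with `donor` and `recipient` leaf labels.
#' @export
most_divergent_pair <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  side_tips <- lapply(kids, function(k) {
    if (k <= ntip) tree$tip.label[k] else
      ape::extract.clade(tree, k)$tip.label
  })
  sizes <- lengths(side_tips)
  big <- which.max(sizes)
  small <- if (big == 1L) 2L else 1L
  list(donor = sort(side_tips[[big]])[1L], recipient = sort(side_tips[[small]])[1L])
}

#' Simulate a complete HT study data set
#'
#' Generates one replicate of the study design used to validate the HT
#' detector: a Yule species tree, two primary host genes and a secondary
#' confirmation gene evolving neutrally along it, and a transposon history
#' that is either purely vertical (`ht_time = NULL`) or carries one recent
#' transfer between the two most divergent lineages.
#'
#' @param n_species Number of species (default 20).
#' @param depth Root-to-tip depth in host substitutions/site (default 0.25).
#' @param gene_length Host-gene length in bp (default 10000).
#' @param te_length Element length in bp (default 2500).
#' @param kappa Transition/transversion ratio for all markers (default 2).
#' @param te_rate Element rate relative to the host genes (default 1).
#' @param ht_time Transfer time before present (host substitutions/site), or
#'   `NULL` for a vertical-only history.  The default transfer time used by
#'   the validation studies is 0.04, i.e. a donor/recipient element identity
#'   of roughly 92%.
#' @param seed Integer seed; one global stream drives the whole replicate.
#' @return List: `tree`, `te_seqs`, `hosts` (named list RPL3/RPL4),
#'   `secondary` (named list RAG1), `vertebrate` flags, `truth` (planted HT
#'   events).
#' @export
simulate_ht_study <- function(n_species = 20, depth = 0.25, gene_length = 10000,
                              te_length = 2500, kappa = 2, te_rate = 1,
                              ht_time = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_yule_tree(n_species, 1, depth = depth)
  model <- substitution_model("K2P", kappa = kappa)
  gene <- function() evolve_along_tree(random_dna(gene_length), tree, model)
  hosts <- list(RPL3 = gene(), RPL4 = gene())
  secondary <- list(RAG1 = gene())
  element <- make_te_element(length = te_length)
  ht <- list()
  if (!is.null(ht_time)) {
    pick <- most_divergent_pair(tree)
    ht <- list(list(donor = pick$donor, recipient = pick$recipient, time = ht_time))
  }
  spec <- te_history(as.character(element), te_rate = te_rate, model = model, ht = ht)
  te <- apply_ht_scenario(tree, spec)
  list(tree = tree, te_seqs = te$te_seqs, hosts = hosts, secondary = secondary,
       vertebrate = setNames(rep(TRUE, n_species), tree$tip.label),
       truth = te$truth)
}

#' Run the HT detector on a simulated study replicate
#'
#' Computes the element identity matrix and composite-likelihood TN93
#' distance matrices for the element and every host gene, then applies
#' [detect_ht()] with the study thresholds.
#'
#' @param sim A [simulate_ht_study()] result.
#' @param ... Passed to [detect_ht()] (thresholds, ANOVA grouping, ...).
#' @return An `"ht_scan"` object.
#' @export
scan_ht_study <- function(sim, ...) {
  id_te <- identity_matrix(sim$te_seqs)
  d_te <- mcl_distance_matrix(sim$te_seqs)
  d_hosts <- lapply(sim$hosts, mcl_distance_matrix)
  d_sec <- lapply(sim$secondary, mcl_distance_matrix)
  detect_ht(id_te, d_te, d_hosts, secondary = d_sec,
            vertebrate = sim$vertebrate, ...)
}

#' Replicated HT simulation study
#'
#' Repeats [simulate_ht_study()] + [scan_ht_study()] over independent seeds
#' and summarises, per replicate, how many events were called and whether
#' the planted transfer (if any) was recovered and confirmed.
#'
#' @param n_reps Number of replicates.
#' @param scenario `"null"` (vertical only) or `"ht"` (one planted recent
#'   transfer).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param ht_time Transfer time for the `"ht"` scenario (default 0.04).
#' @param ... Passed to [simulate_ht_study()].
#' @return Data frame with one row per replicate: `rep`, `n_called`,
#'   `planted_recovered`, `planted_confirmed`.
#' @export
ht_simulation_study <- function(n_reps = 100, scenario = c("null", "ht"),
                                seed = 1, ht_time = 0.04, ...) {
  scenario <- match.arg(scenario)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_ht_study(ht_time = if (scenario == "ht") ht_time else NULL,
                             seed = seed + r, ...)
    scan <- scan_ht_study(sim)
    called <- Filter(function(e) isTRUE(e$called), scan$events)
    recovered <- FALSE; confirmed <- FALSE
    if (scenario == "ht" && nrow(sim$truth)) {
      planted <- c(sim$truth$donor[1L], sim$truth$recipient[1L])
      for (e in called) {
        if (all(planted %in% e$members)) {
          recovered <- TRUE
          confirmed <- isTRUE(e$confirmed)
        }
      }
    }
    rows[[r]] <- data.frame(rep = r, n_called = length(called),
                            planted_recovered = recovered,
                            planted_confirmed = confirmed)
  }
  do.call(rbind, rows)
}
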
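# Synthetic-data generator: trees, sequence evolution, element planting and
# transfer scenarios.

test_that("Yule trees have the forced shapes and are deterministic", {
  t2 <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(t2$Nnode, 1L)          # a root with two leaf children

  t8a <- simulate_yule_tree(8, 1, seed = 3)
  t8b <- simulate_yule_tree(8, 1, seed = 3)
  expect_identical(ape::write.tree(t8a), ape::write.tree(t8b))
  expect_equal(t8a$Nnode, 7L)         # binary-tree identity: n - 1 internal nodes

  t8c <- simulate_yule_tree(8, 1, seed = 4)
  expect_false(identical(ape::write.tree(t8a), ape::write.tree(t8c)))
  expect_error(simulate_yule_tree(1, 1), "n_leaves")

  # depth rescaling is exact and the tree ultrametric
  td <- simulate_yule_tree(6, 1, seed = 5, depth = 0.25)
  depths <- ape::node.depth.edgelength(td)[seq_len(6)]
  expect_equal(unname(depths), rep(0.25, 6), tolerance = 1e-12)
})

test_that("evolve_along_tree respects the zero-rate limit and rejects bad input", {
  tr <- simulate_yule_tree(4, 1, seed = 2, depth = 0.3)
  root <- random_dna(500, seed = 6)
  m0 <- substitution_model("K2P", kappa = 2, rate = 0)
  leaves <- evolve_along_tree(root, tr, m0, seed = 7)
  expect_true(all(leaves == root))
  expect_error(evolve_along_tree("ACGN", tr, m0), "A,C,G,T")
  expect_error(evolve_along_tree("", tr, m0), "non-empty")
})

test_that("K2P estimates recover the simulated divergence (calibration)", {
  set.seed(11)
  m <- substitution_model("K2P", kappa = 2)
  for (d in c(0.01, 0.1, 0.5)) {
    est <- vapply(1:50, function(i) {
      root <- random_dna(3000)
      a <- evolve_sequence(root, d / 2, m)
      b <- evolve_sequence(root, d / 2, m)
      k2p_distance(a, b)$distance
    }, numeric(1))
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - d), 3 * se + 1e-12)
  }
})

test_that("a huge transition/transversion ratio suppresses transversions", {
  set.seed(12)
  m <- substitution_model("K2P", kappa = 1e4)
  root <- random_dna(10000)
  x <- evolve_sequence(root, 0.1, m)
  va <- strsplit(root, "")[[1]]; vb <- strsplit(x, "")[[1]]
  purine <- function(z) z %in% c("A", "G")
  diffs <- which(va != vb)
  tv <- sum(purine(va[diffs]) != purine(vb[diffs]))
  expect_gt(length(diffs), 500)       # substitutions did happen
  expect_lte(tv, 3)                   # expected ~0.2 transversions at kappa 1e4
})

test_that("planted copies are faithful at age zero and truth is conserved", {
  e <- make_te_element(seed = 21)
  g <- random_dna(30000, seed = 22)
  res <- plant_te_copies(g, e, 6, ages = 0, seed = 23)
  expect_equal(nrow(res$truth), 6L)
  for (i in seq_len(6)) {
    s <- substr(res$genome, res$truth$start[i] + 1L, res$truth$end[i])
    expect_true(s == as.character(e) || s == revcomp(as.character(e)))
    expect_identical(res$truth$class[i], "intact")
    expect_identical(check_tsd(res$genome, c(res$truth$start[i], res$truth$end[i])), "TA")
  }
  # conservation: every planted copy retrievable by exact string search
  n_fwd <- length(gregexpr(as.character(e), res$genome, fixed = TRUE)[[1]])
  hits_fwd <- gregexpr(as.character(e), res$genome, fixed = TRUE)[[1]]
  hits_rev <- gregexpr(revcomp(as.character(e)), res$genome, fixed = TRUE)[[1]]
  found <- sum(hits_fwd > 0) + sum(hits_rev > 0)
  expect_equal(found, 6L)

  # n_copies = 0 leaves the genome untouched
  res0 <- plant_te_copies(g, e, 0)
  expect_identical(res0$genome, g)
  expect_equal(nrow(res0$truth), 0L)

  expect_error(plant_te_copies(random_dna(100, seed = 1), e, 1), "shorter")
})

test_that("truncation removes at least 10% of an end and relabels the copy", {
  e <- make_te_element(seed = 31)
  g <- random_dna(60000, seed = 32)
  res <- plant_te_copies(g, e, 12, ages = 0, truncation_prob = 1, seed = 33)
  expect_true(all(res$truth$class == "truncated"))
  expect_true(all(res$truth$length <= nchar(e) - 0.10 * nchar(e)))
  expect_true(all(res$truth$length >= 0.10 * nchar(e)))
})

test_that("HT at time zero makes donor and recipient elements identical", {
  tr <- simulate_yule_tree(6, 1, seed = 41, depth = 0.2)
  e <- make_te_element(seed = 42)
  spec <- te_history(as.character(e),
                     ht = list(list(donor = "sp01", recipient = "sp04", time = 0)))
  res <- apply_ht_scenario(tr, spec, seed = 43)
  expect_identical(res$te_seqs[["sp01"]], res$te_seqs[["sp04"]])
  expect_equal(percent_identity(res$te_seqs[["sp01"]], res$te_seqs[["sp04"]]), 1.0)
})

test_that("vertical-only element and host distances are strongly correlated", {
  set.seed(51)
  tr <- simulate_yule_tree(8, 1, depth = 0.2)
  m <- substitution_model("K2P", kappa = 2)
  host <- evolve_along_tree(random_dna(30000), tr, m)
  spec <- te_history(random_dna(30000), model = m)
  te <- apply_ht_scenario(tr, spec)$te_seqs
  Dh <- mcl_distance_matrix(host)
  Dt <- mcl_distance_matrix(te)
  lt <- lower.tri(Dh)
  expect_gt(cor(Dh[lt], Dt[lt]), 0.98)
})

test_that("a recent transfer inverts the element/host distance relation", {
  set.seed(61)
  tr <- simulate_yule_tree(6, 1, depth = 0.3)
  m <- substitution_model("K2P", kappa = 2)
  pick <- most_divergent_pair(tr)
  host <- evolve_along_tree(random_dna(8000), tr, m)
  spec <- te_history(random_dna(8000), model = m,
                     ht = list(list(donor = pick$donor, recipient = pick$recipient,
                                    time = 0.001)))
  te <- apply_ht_scenario(tr, spec)$te_seqs
  Dh <- mcl_distance_matrix(host); Dt <- mcl_distance_matrix(te)
  ij <- cbind(pick$donor, pick$recipient)
  off <- Dt[lower.tri(Dt)]
  expect_equal(Dt[ij][1], min(off))          # element distance: matrix minimum
  # host divergence of the pair is maximal on the tree (all cross-root pairs
  # tie on an ultrametric tree; the estimate itself carries sampling noise)
  coph <- ape::cophenetic.phylo(tr)
  expect_gte(coph[ij][1], max(coph) - 1e-9)
  expect_gt(Dh[ij][1], 0.9 * max(Dh[lower.tri(Dh)]))
})

test_that("HT directives are validated", {
  tr <- simulate_yule_tree(4, 1, seed = 71, depth = 0.2)
  e <- random_dna(200, seed = 72)
  expect_error(apply_ht_scenario(tr, te_history(e, ht = list(list(
    donor = "sp01", recipient = "nope", time = 0.01)))), "unknown species")
  # a transfer older than the pair's divergence is not a transfer
  a <- ape::node.depth.edgelength(tr)
  deep <- max(a)
  expect_error(apply_ht_scenario(tr, te_history(e, ht = list(list(
    donor = "sp01", recipient = "sp02", time = deep + 1)))), "older")
})

test_that("the generator is a pure function of (parameters, seed)", {
  e <- make_te_element(seed = 81)
  g <- random_dna(20000, seed = 82)
  r1 <- plant_te_copies(g, e, 4, ages = 0.02, truncation_prob = 0.5, seed = 83)
  r2 <- plant_te_copies(g, e, 4, ages = 0.02, truncation_prob = 0.5, seed = 83)
  expect_identical(r1, r2)
  s1 <- simulate_ht_study(n_species = 5, gene_length = 500, te_length = 1800,
                          seed = 84)
  s2 <- simulate_ht_study(n_species = 5, gene_length = 500, te_length = 1800,
                          seed = 84)
  expect_identical(s1$te_seqs, s2$te_seqs)
  expect_identical(s1$hosts, s2$hosts)
})
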
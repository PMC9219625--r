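# Boundary annotation: TIR pairs, TSDs, ORFs, classification, consensus.

test_that("exact planted TIRs are found with exact coordinates", {
  set.seed(201)
  region <- make_tir_region(23, interior = 500)
  tir <- find_tir_pair(region, max_mismatch = 0, end_window = 10)
  expect_s3_class(tir, "tir_pair")
  expect_equal(tir$left[1], 0)
  expect_equal(tir$right[2], nchar(region))
  expect_gte(tir$length, 23)           # chance complementary interior bases may extend it
  oracle <- brute_tir(region, max_mismatch = 0, end_window = 10)
  expect_equal(tir$length, unname(oracle["len"]))
  expect_equal(tir$mismatches, unname(oracle["mm"]))
})

test_that("random sequence without terminal repeats yields no TIR pair", {
  set.seed(202)
  misses <- 0L
  for (i in 1:20) {
    region <- random_dna(1000)
    got <- find_tir_pair(region, end_window = 10)
    oracle <- brute_tir(region, end_window = 10)
    if (is.null(oracle)) {
      misses <- misses + 1L
      expect_null(got)
    } else {
      expect_equal(got$length, unname(oracle["len"]))
    }
  }
  expect_gt(misses, 10)   # most random regions carry no acceptable repeat
})

test_that("mismatched TIRs agree with the exhaustive oracle", {
  set.seed(203)
  for (i in 1:30) {
    len <- sample(8:33, 1)
    region <- make_tir_region(len, interior = 300, mut = 1L)
    got <- find_tir_pair(region, max_mismatch = 1, end_window = 10)
    oracle <- brute_tir(region, max_mismatch = 1, end_window = 10)
    expect_false(is.null(got))
    expect_equal(got$length, unname(oracle["len"]))
    expect_equal(got$mismatches, unname(oracle["mm"]))
    expect_equal(got$left[1], unname(oracle["left0"]))
    expect_equal(got$right[2], unname(oracle["right_end0"]))
  }
  expect_error(find_tir_pair("ACGTACGTACGTACGTACGT", min_len = 20, max_len = 10),
               "min_len")
})

test_that("the seeded wide-window search locates offset TIRs", {
  set.seed(204)
  for (i in 1:5) {
    core <- make_tir_region(20, interior = 400)
    region <- paste0(random_dna(150), "TA", core, "TA", random_dna(150))
    # raw search: boundaries within the mismatch budget of the truth
    got <- find_tir_pair(region, end_window = 180)   # wide window: seed mode
    expect_false(is.null(got))
    expect_lte(abs(got$left[1] - 152), 8)
    expect_lte(abs(got$right[2] - (nchar(region) - 152)), 8)
    # the TSD-aware annotation pins the boundary exactly at the TA flanks
    ann <- annotate_region(region, end_window = 180)
    expect_equal(ann$element, c(152L, nchar(region) - 152L))
    expect_identical(ann$tsd, "TA")
  }
})

test_that("TSD checking distinguishes TA, none, and undetermined", {
  g <- paste0("CCTA", "GGGGCCCCGGGG", "TACC")
  expect_identical(check_tsd(g, c(4L, 16L)), "TA")
  g2 <- paste0("CCTG", "GGGGCCCCGGGG", "TACC")
  expect_identical(check_tsd(g2, c(4L, 16L)), "none")
  g3 <- paste0("GGGGCCCCGGGG", "TACC")
  expect_identical(check_tsd(g3, c(0L, 12L)), "undetermined")
})

test_that("the longest ORF matches the planted transposase and the enumeration oracle", {
  e <- make_te_element(seed = 211)
  orf <- find_longest_orf(as.character(e))
  expect_equal(orf$protein_aa, 492L)
  expect_identical(orf$strand, "+")
  expect_equal(orf$interval[1], attr(e, "orf_start"))
  expect_equal(orf$interval[2], attr(e, "orf_start") + attr(e, "orf_nt"))

  expect_null(find_longest_orf("CCCCCCGGGGGGCCCCCC"))

  set.seed(212)
  for (i in 1:20) {
    s <- random_dna(2000)
    got <- find_longest_orf(s)
    oracle <- longest_orf_oracle_aa(s)
    if (is.null(oracle)) expect_null(got) else expect_equal(got$protein_aa, oracle)
  }
})

test_that("two planted ORFs resolve to the longer one", {
  set.seed(213)
  mk_orf <- function(aa) paste0("ATG", paste(sample(NONSTOP <- setdiff(
    as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES, paste0)),
    c("TAA", "TAG", "TGA")), aa - 1, replace = TRUE), collapse = ""), "TAA")
  s <- paste0("TAA", mk_orf(300), "TAA", random_dna(30), "TAA", mk_orf(500), "TAA")
  got <- find_longest_orf(s)
  expect_equal(got$protein_aa, 500L)
  expect_equal(got$protein_aa, longest_orf_oracle_aa(s))
})

test_that("classification follows the full/intact census rules", {
  tir <- structure(list(left = c(0, 20), right = c(2480, 2500), length = 20,
                        mismatches = 0), class = "tir_pair")
  expect_identical(classify_copy(tir, 492), "intact")
  expect_identical(classify_copy(tir, 250), "full")
  expect_identical(classify_copy(tir, 300), "full")   # ">300 aa" is strict
  expect_identical(classify_copy(tir, 301), "intact")
  expect_identical(classify_copy(NULL, 492), "truncated")
  # intact implies the full criterion as well
  expect_true(classify_copy(tir, 492) %in% c("full", "intact"))
})

test_that("consensus building follows majority rule and the representative path", {
  copies6 <- rep("ACGTACGTAC", 6)
  c6 <- build_consensus(copies6)
  expect_true(c6$is_consensus)
  expect_identical(c6$seq, "ACGTACGTAC")

  col <- c("AAAA", "AAAA", "AAAA", "AAAA", "GAAA", "GAAA")
  expect_identical(substr(build_consensus(col)$seq, 1, 1), "A")

  # fewer than 6 copies: longest intact representative, flagged
  three <- c("ACGT", "ACGTACGT", "ACGTACGTACGT")
  rep3 <- build_consensus(three, classes = c("full", "intact", "truncated"))
  expect_false(rep3$is_consensus)
  expect_identical(rep3$seq, "ACGTACGT")
  expect_equal(rep3$representative, 2L)

  # gap-majority columns are dropped
  gappy <- c("A-GT", "A-GT", "A-GT", "ACGT", "A-GT", "A-GT")
  expect_identical(build_consensus(gappy)$seq, "AGT")

  expect_error(build_consensus(character(0)), "no copies")
})

test_that("consensus recovers the source from independently mutated copies", {
  set.seed(221)
  m <- substitution_model("K2P", kappa = 2)
  src <- random_dna(1500)
  copies <- vapply(1:10, function(i) evolve_sequence(src, runif(1, 0.02, 0.10), m),
                   character(1))
  cons <- build_consensus(copies)
  expect_true(cons$is_consensus)
  expect_gte(percent_identity(cons$seq, src), 0.99)
})

test_that("annotation of whole planted copies recovers structure and class", {
  e <- make_te_element(seed = 231)
  g <- random_dna(20000, seed = 232)
  res <- plant_te_copies(g, e, 3, ages = 0, seed = 233)
  for (i in 1:3) {
    a <- res$truth$start[i]; b <- res$truth$end[i]
    region <- substr(res$genome, a + 1L - 2L, b + 2L)   # 2 bp flanks for the TSD
    ann <- annotate_region(region, end_window = 6)
    expect_identical(ann$class, "intact")
    expect_identical(ann$tsd, "TA")
    expect_equal(ann$element, c(2L, 2L + (b - a)))
  }
})
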
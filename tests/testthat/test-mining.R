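# Homology mining: hit-table parsing, the built-in translated search, hit
# consolidation, flank extraction and the copy census.

test_that("hit tables parse with coordinate normalisation and strict errors", {
  expect_equal(nrow(parse_hit_table(character(0))), 0L)

  row <- paste(c("q", "chr1", "95.5", "100", "4", "0", "1", "100", "100", "1",
                 "1e-120", "250"), collapse = "\t")
  h <- parse_hit_table(row)
  expect_identical(h$strand, "-")
  expect_equal(h$start, 0L)
  expect_equal(h$end, 100L)

  fwd <- paste(c("q", "chr1", "90", "50", "5", "0", "1", "50", "201", "250",
                 "1e-30", "80"), collapse = "\t")
  hf <- parse_hit_table(fwd)
  expect_identical(hf$strand, "+")
  expect_equal(c(hf$start, hf$end), c(200L, 250L))

  bad_ident <- sub("95.5", "abc", row, fixed = TRUE)
  expect_error(parse_hit_table(bad_ident), "line 1")
  expect_error(parse_hit_table("a\tb\tc"), "line 1.*columns")
})

test_that("translated search finds an exact back-translated query once, on both strands", {
  set.seed(101)
  e <- make_te_element(seed = 102)
  orf <- substr(as.character(e), attr(e, "orf_start") + 1L,
                attr(e, "orf_start") + attr(e, "orf_nt") - 3L)
  query <- tehorizon:::translate_frame(orf, 0L)
  g <- paste0(random_dna(5000), orf, random_dna(5000))
  hits <- translated_search(query, g)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$strand, "+")
  expect_equal(hits$identity, 100)
  expect_equal(c(hits$start, hits$end), c(5000L, 5000L + nchar(orf)))

  hits_rc <- translated_search(query, revcomp(g))
  expect_equal(nrow(hits_rc), 1L)
  expect_identical(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score)   # strand symmetry
  expect_equal(c(hits_rc$start, hits_rc$end),
               c(nchar(g) - hits$end, nchar(g) - hits$start))
})

test_that("translated search stays silent on shuffled genomes", {
  set.seed(111)
  e <- make_te_element(seed = 112)
  orf <- substr(as.character(e), attr(e, "orf_start") + 1L,
                attr(e, "orf_start") + attr(e, "orf_nt") - 3L)
  query <- tehorizon:::translate_frame(orf, 0L)
  v <- tehorizon:::seq_to_int(random_dna(20000))
  n_hits <- vapply(1:30, function(i) {
    nrow(translated_search(query, tehorizon:::int_to_seq(sample(v))))
  }, integer(1))
  expect_true(all(n_hits == 0L))
  expect_error(translated_search("MKV", random_dna(1000)), "50 aa")
  # genome shorter than 3x the query: empty result, not an error
  expect_equal(nrow(translated_search(query, random_dna(90))), 0L)
})

test_that("top non-overlapping selection is greedy, tie-broken, order-free", {
  hits <- data.frame(query = "q", contig = "c",
                     start = c(0L, 50L, 200L, 300L),
                     end = c(100L, 150L, 280L, 380L),
                     strand = "+", identity = 90, aln_len = 50L,
                     score = c(50, 40, 30, 30), evalue = NA_real_)
  sel <- select_top_nonoverlapping(hits, 10)
  expect_equal(sort(sel$start), c(0L, 200L, 300L))   # the 40 overlaps the 50

  three <- hits[c(1, 3, 4), ]
  expect_equal(nrow(select_top_nonoverlapping(three, 10)), 3L)
  expect_equal(nrow(select_top_nonoverlapping(three, 2)), 2L)

  tie <- data.frame(query = "q", contig = "c", start = c(120L, 100L),
                    end = c(220L, 200L), strand = "+", identity = 90,
                    aln_len = 50L, score = c(60, 60), evalue = NA_real_)
  expect_equal(select_top_nonoverlapping(tie, 10)$start, 100L)  # smaller start wins

  # invariance to input order
  set.seed(121)
  big <- data.frame(query = "q", contig = "c",
                    start = as.integer(seq(0, 900, by = 60)),
                    end = as.integer(seq(0, 900, by = 60)) + sample(40:80, 16, TRUE),
                    strand = "+", identity = 90, aln_len = 50L,
                    score = sample(10:99, 16), evalue = NA_real_)
  a <- select_top_nonoverlapping(big, 5)
  b <- select_top_nonoverlapping(big[sample(16), ], 5)
  expect_equal(a$start, b$start)
})

test_that("flank extraction clips at contig ends and honours strand", {
  g <- random_dna(10000, seed = 131)
  hit <- data.frame(contig = "c", start = 4000L, end = 5000L, strand = "+")
  r <- extract_flanked(g, hit, flank = 2000L)
  expect_equal(nchar(r$seq), 5000L)
  expect_false(r$clipped)
  expect_identical(substr(r$seq, 2001, 3000), substr(g, 4001, 5000))

  edge <- data.frame(contig = "c", start = 0L, end = 500L, strand = "+")
  re <- extract_flanked(g, edge, flank = 2000L)
  expect_equal(re$left_flank, 0L)
  expect_true(re$clipped)

  r0 <- extract_flanked(g, hit, flank = 0L)
  expect_identical(r0$seq, substr(g, 4001, 5000))

  minus <- data.frame(contig = "c", start = 4000L, end = 5000L, strand = "-")
  rm_ <- extract_flanked(g, minus, flank = 100L)
  expect_identical(rm_$seq, revcomp(substr(g, 3901, 5100)))

  expect_error(extract_flanked(g, data.frame(start = 9000L, end = 11000L, strand = "+")),
               "outside")
})

test_that("the census applies its three thresholds strictly", {
  set.seed(141)
  ref <- random_dna(2500)
  m <- substitution_model("K2P", kappa = 2)
  # passing copy: 1200 bp, ~0.85 identity after heavy mutation
  copy_pass <- evolve_sequence(substr(ref, 1, 1200), 0.17, m)
  # identity just below 0.80 fails even though length and coverage pass
  copy_lowid <- evolve_sequence(substr(ref, 1, 1600), 0.35, m)
  copy_short <- substr(ref, 1, 900)
  cen <- count_copies(c(copy_pass, copy_lowid, copy_short), ref)
  expect_true(1L %in% cen$counted)
  expect_gt(cen$stats$identity[1], 0.80)
  expect_lt(cen$stats$identity[2], 0.80)
  expect_false(2L %in% cen$counted)
  expect_false(3L %in% cen$counted)

  empty <- count_copies(character(0), ref)
  expect_equal(empty$count, 0L)
  expect_error(count_copies("ACGT", ""), "non-empty")
})

test_that("relaxing any census threshold never decreases the count", {
  set.seed(151)
  ref <- random_dna(2000)
  m <- substitution_model("K2P", kappa = 2)
  copies <- vapply(1:12, function(i) {
    L <- sample(600:2000, 1)
    evolve_sequence(substr(ref, 1, L), runif(1, 0, 0.4), m)
  }, character(1))
  base <- count_copies(copies, ref)$count
  expect_gte(count_copies(copies, ref, min_len = 500L)$count, base)
  expect_gte(count_copies(copies, ref, min_cov = 0.20)$count, base)
  expect_gte(count_copies(copies, ref, min_id = 0.60)$count, base)
})

test_that("mining plus annotation re-locates age-zero plants exactly", {
  e <- make_te_element(seed = 161)
  g <- random_dna(25000, seed = 162)
  res <- plant_te_copies(g, e, 4, ages = 0, seed = 163)
  orf <- substr(as.character(e), attr(e, "orf_start") + 1L,
                attr(e, "orf_start") + attr(e, "orf_nt") - 3L)
  query <- tehorizon:::translate_frame(orf, 0L)
  hits <- select_top_nonoverlapping(translated_search(query, res$genome), 10)
  expect_equal(nrow(hits), 4L)
  got <- t(vapply(seq_len(nrow(hits)), function(i) {
    r <- extract_flanked(res$genome, hits[i, ], flank = 600L)
    ann <- annotate_region(r$seq, end_window = 700L)
    region_to_genomic(r$region[["start"]], nchar(r$seq), ann$element, hits$strand[i])
  }, numeric(2)))
  expect_equal(got[order(got[, 1]), 1], sort(res$truth$start))
  expect_equal(got[order(got[, 1]), 2], sort(res$truth$end))
})
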
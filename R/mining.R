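# Homology mining: ingesting tabular hit files from an external translated
# search, a desk-scale built-in translated search (six-frame translation +
# seeded ungapped extension under BLOSUM62), hit consolidation, flank
# extraction, and the copy-census thresholds (>1000 bp, >40% coverage,
# >80% identity; all strict).
# Subject coordinates are 0-based half-open with an explicit strand.

#' Parse a 12-column tabular homology hit file
#'
#' Reads the standard tab-separated 12-column hit format (query id, subject
#' id, percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, significance, score).  Subject coordinates
#' are normalised to 0-based half-open intervals; hits whose subject start
#' exceeds their end are placed on the minus strand.
#'
#' @param stream A file path, connection, or character vector of lines.
#' @param dialect Named integer vector mapping the fields `qid`, `sid`,
#'   `identity`, `length`, `sstart`, `send`, `evalue`, `score` to column
#'   indices; defaults to the standard 12-column layout.
#' @return A data frame of hits: `query`, `contig`, `start`, `end`, `strand`,
#'   `identity` (0-100), `aln_len`, `score`, `evalue`.
#' @export
parse_hit_table <- function(stream,
                            dialect = c(qid = 1L, sid = 2L, identity = 3L,
                                        length = 4L, sstart = 9L, send = 10L,
                                        evalue = 11L, score = 12L)) {
  lines <- if (is.character(stream) && length(stream) == 1L && file.exists(stream)) {
    readLines(stream)
  } else if (inherits(stream, "connection")) {
    readLines(stream)
  } else {
    as.character(stream)
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(query = character(), contig = character(), start = integer(),
                      end = integer(), strand = character(), identity = numeric(),
                      aln_len = integer(), score = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_needed <- max(dialect)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < ncol_needed)
      stop(sprintf("line %d: expected at least %d tab-separated columns, got %d",
                   i, ncol_needed, length(f)))
    num <- suppressWarnings(as.numeric(f[dialect[c("identity", "length", "sstart",
                                                   "send", "evalue", "score")]]))
    if (anyNA(num))
      stop(sprintf("line %d: non-numeric value in a numeric field", i))
    s <- num[3L]; e <- num[4L]
    strand <- if (s <= e) "+" else "-"
    rows[[i]] <- data.frame(query = f[dialect["qid"]], contig = f[dialect["sid"]],
                            start = as.integer(min(s, e)) - 1L,
                            end = as.integer(max(s, e)),
                            strand = strand, identity = num[1L],
                            aln_len = as.integer(num[2L]), score = num[6L],
                            evalue = num[5L], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Ungapped X-drop extension of a seed match between query and subject
# protein integer index vectors, under a scoring matrix.
extend_seed <- function(qv, sv, qpos, spos, smat, word = 4L, xdrop = 20) {
  # initial word score
  sc <- sum(smat[cbind(qv[qpos:(qpos + word - 1L)], sv[spos:(spos + word - 1L)])])
  best <- sc
  qr <- qpos + word - 1L; sr <- spos + word - 1L; best_qr <- qr; best_sr <- sr
  i <- qr; j <- sr
  while (i < length(qv) && j < length(sv)) {
    i <- i + 1L; j <- j + 1L
    sc <- sc + smat[qv[i], sv[j]]
    if (sc > best) { best <- sc; best_qr <- i; best_sr <- j }
    if (best - sc > xdrop) break
  }
  sc <- best
  ql <- qpos; sl <- spos; best_ql <- ql; best_sl <- sl
  i <- ql; j <- sl
  while (i > 1L && j > 1L) {
    i <- i - 1L; j <- j - 1L
    sc <- sc + smat[qv[i], sv[j]]
    if (sc > best) { best <- sc; best_ql <- i; best_sl <- j }
    if (best - sc > xdrop) break
  }
  list(score = best, q1 = best_ql, q2 = best_qr, s1 = best_sl, s2 = best_sr)
}

#' Desk-scale translated homology search
#'
#' Searches a protein query against all six translated frames of a genome by
#' exact word seeding followed by ungapped X-drop extension under BLOSUM62.
#' This is a deliberately small, deterministic stand-in for a full translated
#' search engine: scores are raw BLOSUM62 sums and the significance control
#' is a fixed raw-score threshold (see [calibrate_score_threshold()] for an
#' empirical shuffle-based calibration).
#'
#' @param query_protein Amino-acid string (>= 50 aa).
#' @param genome DNA string.
#' @param min_score Raw score threshold below which hits are suppressed.
#' @param word Seed word size (exact amino-acid match).
#' @param xdrop X-drop parameter for the ungapped extension.
#' @param contig Contig name used in the output.
#' @return A data frame of hits in the same layout as [parse_hit_table()]:
#'   genomic `start`/`end` are 0-based half-open on the forward strand,
#'   `strand` gives the frame orientation, `identity` is the percent of
#'   identical aligned residues.
#' @export
translated_search <- function(query_protein, genome, min_score = 100,
                              word = 4L, xdrop = 20, contig = "chr1") {
  if (nchar(query_protein) < 50L) stop("query must be >= 50 aa")
  empty <- data.frame(query = character(), contig = character(), start = integer(),
                      end = integer(), strand = character(), identity = numeric(),
                      aln_len = integer(), score = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (nchar(genome) < 3L * nchar(query_protein)) return(empty)
  smat <- blosum62
  aa <- rownames(smat)
  qv <- match(strsplit(query_protein, "")[[1L]], aa)
  if (anyNA(qv)) stop("query contains unknown amino-acid codes")
  qn <- length(qv)
  qwords <- vapply(seq_len(qn - word + 1L),
                   function(i) paste(aa[qv[i:(i + word - 1L)]], collapse = ""),
                   character(1))
  widx <- split(seq_along(qwords), qwords)
  glen <- nchar(genome)
  rows <- list()
  for (fr in six_frames(genome)) {
    prot <- fr$protein
    if (nchar(prot) < word) next
    sv <- match(strsplit(prot, "")[[1L]], aa)
    sv[is.na(sv)] <- match("*", aa)
    sn <- length(sv)
    starts <- seq_len(sn - word + 1L)
    swords <- substring(prot, starts, starts + word - 1L)
    hitlist <- widx[swords]
    seed_s <- rep.int(starts, lengths(hitlist))
    seed_q <- unlist(hitlist, use.names = FALSE)
    if (!length(seed_q)) next
    # one extension per diagonal cluster; seeds on an already-covered
    # diagonal interval are skipped
    diag_id <- seed_s - seed_q
    ord <- order(diag_id, seed_s)
    seed_s <- seed_s[ord]; seed_q <- seed_q[ord]; diag_id <- diag_id[ord]
    covered_hi <- -Inf; covered_diag <- NA
    for (k in seq_along(seed_s)) {
      if (!is.na(covered_diag) && diag_id[k] == covered_diag && seed_s[k] <= covered_hi) next
      ext <- extend_seed(qv, sv, seed_q[k], seed_s[k], smat, word, xdrop)
      covered_diag <- diag_id[k]; covered_hi <- ext$s2
      if (ext$score < min_score) next
      ident <- 100 * mean(qv[ext$q1:ext$q2] == sv[ext$s1:ext$s2])
      # protein -> genome coordinates (0-based half-open, forward strand)
      p1 <- ext$s1; p2 <- ext$s2
      if (fr$strand == "+") {
        g1 <- fr$offset + 3L * (p1 - 1L)
        g2 <- fr$offset + 3L * p2
      } else {
        g2 <- glen - (fr$offset + 3L * (p1 - 1L))
        g1 <- glen - (fr$offset + 3L * p2)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(query = "query", contig = contig, start = g1, end = g2,
                   strand = fr$strand, identity = ident,
                   aln_len = p2 - p1 + 1L, score = ext$score,
                   evalue = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  hits <- do.call(rbind, rows)
  # collapse duplicate extensions of the same region, keep best score
  hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) {
      later <- (i + 1L):nrow(hits)
      ov <- pmax(0L, pmin(hits$end[later], hits$end[i]) - pmax(hits$start[later], hits$start[i]))
      dup <- ov > 0.9 * (hits$end[later] - hits$start[later]) &
        hits$strand[later] == hits$strand[i]
      keep[later][dup] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Calibrate the translated-search score threshold on shuffled genomes
#'
#' Runs [translated_search()] with no threshold against `n` dinucleotide-
#' preserving shuffles of the genome and returns the highest score observed,
#' an empirical null for the raw-score cutoff.
#'
#' @inheritParams translated_search
#' @param n Number of shuffles.
#' @param seed Optional integer seed.
#' @return Numeric: the maximum null score (or `-Inf` when nothing aligns).
#' @export
calibrate_score_threshold <- function(query_protein, genome, n = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- seq_to_int(genome)
  best <- -Inf
  for (i in seq_len(n)) {
    g <- int_to_seq(sample(v))
    h <- translated_search(query_protein, g, min_score = -Inf)
    if (nrow(h)) best <- max(best, h$score)
  }
  best
}

#' Keep the top non-overlapping hits
#'
#' Greedy selection by descending score: a hit is kept only if it shares no
#' subject base with any previously kept hit on the same contig.  Score ties
#' are broken by smaller start, so the result is invariant to input order.
#'
#' @param hits Hit data frame (from [parse_hit_table()] or
#'   [translated_search()]).
#' @param k Maximum number of hits to keep (>= 1).
#' @return The selected subset, ordered by descending score.
#' @export
select_top_nonoverlapping <- function(hits, k = 10L) {
  if (k < 1L) stop("k must be >= 1")
  if (!nrow(hits)) return(hits)
  hits <- hits[order(-hits$score, hits$start, hits$end), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (length(kept) >= k) break
    ok <- TRUE
    for (j in kept) {
      if (hits$contig[i] == hits$contig[j] &&
          hits$start[i] < hits$end[j] && hits$end[i] > hits$start[j]) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- hits[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a hit region with flanking sequence
#'
#' Returns the genomic sequence of a hit extended by `flank` bp on each side,
#' clipped at the contig ends; minus-strand hits are reverse-complemented so
#' the query orientation is restored.
#'
#' @param genome DNA string (the hit's contig).
#' @param hit One-row hit data frame (0-based half-open `start`/`end`).
#' @param flank Flank size in bp (default 2000).
#' @return A list: `seq`, `left_flank`/`right_flank` (realised flank lengths,
#'   in extracted orientation), `clipped`, and `region` (0-based half-open
#'   genomic interval of the extracted sequence, forward strand).
#' @export
extract_flanked <- function(genome, hit, flank = 2000L) {
  n <- nchar(genome)
  if (hit$start < 0L || hit$end > n || hit$start >= hit$end)
    stop("hit interval outside the contig")
  a <- max(0L, hit$start - flank)
  b <- min(n, hit$end + flank)
  s <- substr(genome, a + 1L, b)
  left <- hit$start - a
  right <- b - hit$end
  if (identical(hit$strand, "-")) {
    s <- revcomp(s)
    tmp <- left; left <- right; right <- tmp
  }
  list(seq = s, left_flank = left, right_flank = right,
       clipped = (left < flank) || (right < flank),
       region = c(start = a, end = b))
}

#' Copy census under the mining thresholds
#'
#' Aligns each candidate copy to the reference element and counts the copies
#' that satisfy all three census thresholds: length > `min_len` bp, reference
#' coverage > `min_cov`, and identity > `min_id` (all strict inequalities).
#' Coverage is measured on the reference; identity is computed over aligned
#' non-gap columns.
#'
#' @param copies Character vector of copy sequences.
#' @param reference Reference/consensus element (DNA string).
#' @param min_len Minimum copy length in bp (exclusive).
#' @param min_cov Minimum reference coverage fraction (exclusive).
#' @param min_id Minimum identity fraction (exclusive).
#' @return An object of class `"copy_census"`: list with `count`, `counted`
#'   (indices), `stats` (per-copy length/coverage/identity), `thresholds`.
#' @export
count_copies <- function(copies, reference, min_len = 1000L, min_cov = 0.40,
                         min_id = 0.80) {
  if (!nzchar(reference)) stop("reference must be non-empty")
  n <- length(copies)
  stats <- data.frame(length = integer(n), coverage = numeric(n), identity = numeric(n))
  for (i in seq_len(n)) {
    aln <- align_pair(copies[i], reference)
    stats$length[i] <- nchar(copies[i])
    # reference bases inside aligned (both non-gap) columns
    p <- strsplit(aln$a, "")[[1L]]; r <- strsplit(aln$b, "")[[1L]]
    both <- p != "-" & r != "-"
    stats$coverage[i] <- sum(both) / nchar(reference)
    stats$identity[i] <- if (any(both)) mean(p[both] == r[both]) else 0
  }
  pass <- which(stats$length > min_len & stats$coverage > min_cov & stats$identity > min_id)
  structure(list(count = length(pass), counted = pass, stats = stats,
                 thresholds = c(min_len = min_len, min_cov = min_cov, min_id = min_id)),
            class = "copy_census")
}

#' @export
print.copy_census <- function(x, ...) {
  cat(sprintf("copy census: %d of %d copies counted (length > %d bp, coverage > %.0f%%, identity > %.0f%%)\n",
              x$count, nrow(x$stats), x$thresholds["min_len"],
              100 * x$thresholds["min_cov"], 100 * x$thresholds["min_id"]))
  invisible(x)
}
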
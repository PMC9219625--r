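# Element boundary annotation: terminal inverted repeats (TIR), TA
# target-site duplications (TSD), transposase ORFs, copy classification
# (truncated / full / intact) and consensus building.
# Intervals are 0-based half-open relative to the annotated region.

# Default mismatch tolerance for a TIR of length `len`: ceiling(10%), but
# short repeats (< 12 bp) must be exact -- at typical terminal-window sizes a
# random 8-11 bp inverted match with one mismatch is expected by chance, so
# tolerating mismatches there would flag spurious TIRs on truncated copies.
default_tir_tolerance <- function(len) ifelse(len < 12L, 0L, ceiling(len / 10))

# Enumerate acceptable TIR candidates.  v: integer-coded region;
# w = revcomp(region) so that a left TIR at v[i..] pairing a right TIR
# ending at region position n-m+1 is a direct (mismatch-counted) match of
# v[i+t] against w[m+t].
tir_candidates <- function(v, min_len, max_len, max_mismatch, end_window) {
  n <- length(v)
  w <- 5L - rev(v)
  W <- min(end_window, n)
  reach <- min(n, W + max_len)
  tol <- function(len) if (is.null(max_mismatch)) default_tir_tolerance(len) else
    rep_len(max_mismatch, length(len))
  cand <- list()
  push <- function(i, m, len, mm) {
    left0 <- i - 1L
    right_end0 <- n - m + 1L
    right_start0 <- right_end0 - len
    if (right_start0 < left0 + len) return()
    cand[[length(cand) + 1L]] <<- c(left0 = left0, left_end0 = left0 + len,
                                    right_start0 = right_start0,
                                    right_end0 = right_end0, len = len, mm = mm)
  }
  eval_diagonal <- function(i0, m0, span) {
    # scan offsets o = 0..span-1 from (i0, m0); report, per start, the best
    # (longest, then fewest-mismatch) acceptable candidate
    o <- seq_len(span) - 1L
    ok <- v[i0 + o] == w[m0 + o]
    cs <- c(0L, cumsum(!ok))
    for (len in seq(min(max_len, span), min_len)) {
      t_allowed <- tol(len)
      starts <- seq_len(span - len + 1L)
      mm <- cs[starts + len] - cs[starts]
      hit <- which(mm <= t_allowed & (i0 + starts - 1L) <= W & (m0 + starts - 1L) <= W)
      for (s in hit) push(i0 + s - 1L, m0 + s - 1L, len, mm[s])
    }
  }
  if (W <= 64L) {
    for (d in (-(W - 1L)):(W - 1L)) {
      i0 <- max(1L, 1L + d); m0 <- max(1L, 1L - d)
      span <- min(reach - i0 + 1L, reach - m0 + 1L)
      if (span >= min_len) eval_diagonal(i0, m0, span)
    }
  } else {
    # seed mode for wide terminal windows: exact 6-mer seeds, segment
    # evaluation around each seed cluster
    word <- 6L
    enc <- function(x, upto) {
      nn <- min(length(x), upto + max_len) - word + 1L
      if (nn < 1L) return(integer(0))
      code <- integer(nn)
      for (t in 0:(word - 1L)) code <- code + (x[seq_len(nn) + t] - 1L) * 4L^t
      code
    }
    cv <- enc(v, W); cw <- enc(w, W)
    mp <- match(cv, cw)
    seeds_i <- which(!is.na(mp))
    done <- new.env(parent = emptyenv())
    for (i in seeds_i) {
      # all w-positions sharing this code
      ms <- which(cw == cv[i])
      for (m in ms) {
        key <- paste0(i - m, ":", (i %/% max_len))
        if (!is.null(done[[key]])) next
        done[[key]] <- TRUE
        i0 <- max(1L, i - max_len + 1L); m0 <- m - (i - i0)
        if (m0 < 1L) { i0 <- i0 + (1L - m0); m0 <- 1L }
        span <- min(reach - i0 + 1L, reach - m0 + 1L, 2L * max_len + word)
        if (span >= min_len) eval_diagonal(i0, m0, span)
      }
    }
  }
  if (!length(cand)) return(NULL)
  out <- as.data.frame(do.call(rbind, cand))
  out[!duplicated(out), , drop = FALSE]
}

#' Find a terminal inverted repeat pair
#'
#' Searches a region for the highest-scoring pair of terminal inverted
#' repeats: the left copy must start within `end_window` of the region start
#' and the right copy must end within `end_window` of the region end.
#' Candidates are ranked longest first, then fewest mismatches, then smaller
#' left start, then larger right end.
#'
#' @param region DNA string.
#' @param min_len,max_len TIR length bounds in bp (defaults 8 and 40; family
#'   surveys report TIRs of 8-33 bp).
#' @param max_mismatch Mismatch tolerance.  `NULL` (default) uses the
#'   length-dependent rule `ceiling(len/10)`, with short (< 12 bp) repeats
#'   required to be exact.
#' @param end_window Terminal window in bp (default 50).
#' @return `NULL` if no acceptable pair exists, otherwise an object of class
#'   `"tir_pair"`: list with `left`/`right` 0-based half-open intervals,
#'   `length`, and `mismatches`.
#' @export
find_tir_pair <- function(region, min_len = 8L, max_len = 40L,
                          max_mismatch = NULL, end_window = 50L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  v <- seq_to_int(region)
  if (length(v) < 2L * min_len) stop("region shorter than two minimal TIRs")
  cand <- tir_candidates(v, min_len, max_len, max_mismatch, end_window)
  if (is.null(cand)) return(NULL)
  ord <- order(-cand$len, cand$mm, cand$left0, -cand$right_end0)
  b <- cand[ord[1L], ]
  structure(list(left = c(b$left0, b$left_end0),
                 right = c(b$right_start0, b$right_end0),
                 length = b$len, mismatches = b$mm),
            class = "tir_pair")
}

#' @export
print.tir_pair <- function(x, ...) {
  cat(sprintf("TIR pair: %d bp, %d mismatch(es); left [%d,%d), right [%d,%d)\n",
              x$length, x$mismatches, x$left[1], x$left[2], x$right[1], x$right[2]))
  invisible(x)
}

#' Check for a TA target-site duplication
#'
#' A cut-and-paste insertion at a TA dinucleotide duplicates the TA, so an
#' element interval has a TSD when the two bases immediately left and
#' immediately right of it are both `TA`.
#'
#' @param genome DNA string.
#' @param interval 0-based half-open element interval `c(start, end)`.
#' @return `"TA"` when both flanks read TA, `"none"` otherwise, or
#'   `"undetermined"` when a flank is clipped at the contig edge.
#' @export
check_tsd <- function(genome, interval) {
  start <- interval[1L]; end <- interval[2L]
  n <- nchar(genome)
  if (start < 0L || end > n || start >= end) stop("interval outside the genome")
  if (start < 2L || end + 2L > n) return("undetermined")
  left <- substr(genome, start - 1L, start)
  right <- substr(genome, end + 1L, end + 2L)
  if (left == "TA" && right == "TA") "TA" else "none"
}

#' Find the longest open reading frame in six frames
#'
#' Scans all six reading frames for `ATG ... stop` spans and returns the
#' longest; ties prefer the plus strand, then the 5'-most start.
#'
#' @param seq DNA string.
#' @return `NULL` if no complete ORF exists, else a list with `interval`
#'   (0-based half-open on the forward strand, stop codon included),
#'   `strand`, and `protein_aa` (start codon counted, stop excluded).
#' @export
find_longest_orf <- function(seq) {
  v <- seq_to_int(seq)
  n <- length(v)
  if (n < 6L) return(NULL)
  vr <- revcomp_int(v)
  best <- NULL
  consider <- function(aa, start0, end0, strand) {
    if (is.null(best) || aa > best$protein_aa ||
        (aa == best$protein_aa && best$strand == "-" && strand == "+") ||
        (aa == best$protein_aa && best$strand == strand && start0 < best$interval[1L])) {
      best <<- list(interval = c(start0, end0), strand = strand, protein_aa = aa)
    }
  }
  for (strand in c("+", "-")) {
    x <- if (strand == "+") v else vr
    for (off in 0:2) {
      starts <- seq.int(off + 1L, n - 2L, by = 3L)
      if (!length(starts)) next
      cod <- paste0(DNA_BASES[x[starts]], DNA_BASES[x[starts + 1L]], DNA_BASES[x[starts + 2L]])
      open <- NA_integer_
      for (i in seq_along(cod)) {
        if (is.na(open) && cod[i] == "ATG") open <- i
        if (!is.na(open) && cod[i] %in% c("TAA", "TAG", "TGA")) {
          aa <- i - open
          a0 <- starts[open] - 1L; b0 <- starts[i] + 2L
          if (strand == "-") { tmp <- a0; a0 <- n - b0; b0 <- n - tmp }
          consider(aa, a0, b0, strand)
          open <- NA_integer_
        }
      }
    }
  }
  best
}

#' Classify an element copy
#'
#' Applies the census classification: a copy flanked by a TIR pair is a
#' *full* element; a full element whose transposase ORF exceeds 300 aa is
#' *intact*; anything without a TIR pair is *truncated*.
#'
#' @param tir A [find_tir_pair()] result or `NULL`.
#' @param orf_aa Transposase length in aa (0 or `NULL` when absent).
#' @return `"truncated"`, `"full"`, or `"intact"`.
#' @export
classify_copy <- function(tir, orf_aa = 0) {
  if (is.null(tir)) return("truncated")
  if (!is.null(orf_aa) && length(orf_aa) && !is.na(orf_aa) && orf_aa > 300) "intact" else "full"
}

#' Annotate one element region
#'
#' Runs the full boundary annotation on a candidate region: TIR pair search,
#' TSD check (using `left_flank`/`right_flank` bases of non-element context
#' included in the region), ORF scan, and classification.  When several TIR
#' candidates are acceptable, candidates whose implied element interval is
#' flanked by a TA on both sides are preferred, which suppresses chance
#' inverted repeats in wide search windows.
#'
#' @param region DNA string (element candidate plus any flanking context).
#' @param end_window Terminal window passed to the TIR search.
#' @param min_len,max_len,max_mismatch TIR search parameters.
#' @param prefer_tsd Prefer TA-flanked TIR candidates (default `TRUE`).
#' @return A list: `tir` (or `NULL`), `tsd`, `orf` (or `NULL`), `class`,
#'   `element` (0-based half-open interval of the inferred element within the
#'   region; the whole region when no TIR pair is found).
#' @export
annotate_region <- function(region, end_window = 50L, min_len = 8L,
                            max_len = 40L, max_mismatch = NULL,
                            prefer_tsd = TRUE) {
  v <- seq_to_int(region)
  n <- length(v)
  cand <- if (n >= 2L * min_len)
    tir_candidates(v, min_len, max_len, max_mismatch, end_window) else NULL
  tir <- NULL
  if (!is.null(cand)) {
    if (prefer_tsd) {
      has_tsd <- vapply(seq_len(nrow(cand)), function(i) {
        identical(check_tsd(region, c(cand$left0[i], cand$right_end0[i])), "TA")
      }, logical(1))
      if (any(has_tsd)) cand <- cand[has_tsd, , drop = FALSE]
    }
    ord <- order(-cand$len, cand$mm, cand$left0, -cand$right_end0)
    b <- cand[ord[1L], ]
    tir <- structure(list(left = c(b$left0, b$left_end0),
                          right = c(b$right_start0, b$right_end0),
                          length = b$len, mismatches = b$mm),
                     class = "tir_pair")
  }
  element <- if (!is.null(tir)) c(tir$left[1L], tir$right[2L]) else c(0L, n)
  tsd <- check_tsd(region, element)
  elem_seq <- substr(region, element[1L] + 1L, element[2L])
  orf <- find_longest_orf(elem_seq)
  cls <- classify_copy(tir, if (is.null(orf)) 0 else orf$protein_aa)
  list(tir = tir, tsd = tsd, orf = orf, class = cls, element = element,
       element_seq = elem_seq)
}

#' Build a consensus (or pick a representative) from aligned copies
#'
#' With at least `min_copies` aligned copies (the census rule: "many copies",
#' i.e. more than 5) a majority-rule consensus is built: per column the most
#' frequent non-gap base wins (ties resolved alphabetically), and a column is
#' emitted only when at least half of the rows are non-gap.  With fewer
#' copies the longest copy (preferring intact ones when classes are given) is
#' returned as a representative.
#'
#' @param copies Character vector of gapped sequences on a common column
#'   space (equal widths), `-` for gaps.
#' @param min_copies Minimum number of copies for a consensus (default 6).
#' @param classes Optional per-copy class labels used to prefer intact
#'   representatives.
#' @return A list: `seq`, `is_consensus`, `n`, and (for representatives)
#'   `representative` (the index of the chosen copy).
#' @export
build_consensus <- function(copies, min_copies = 6L, classes = NULL) {
  if (!length(copies)) stop("no copies supplied")
  if (length(copies) < min_copies) {
    pool <- seq_along(copies)
    if (!is.null(classes) && any(classes == "intact")) pool <- which(classes == "intact")
    lens <- nchar(gsub("-", "", copies[pool], fixed = TRUE))
    idx <- pool[which.max(lens)]
    return(list(seq = gsub("-", "", copies[idx], fixed = TRUE),
                is_consensus = FALSE, n = length(copies), representative = idx))
  }
  widths <- unique(nchar(copies))
  if (length(widths) != 1L) stop("aligned copies must have equal widths")
  m <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  nongap <- colSums(m != "-")
  keep <- nongap >= length(copies) / 2
  cons <- vapply(which(keep), function(j) {
    col <- m[, j]; col <- col[col != "-"]
    tab <- table(factor(col, levels = DNA_BASES))
    DNA_BASES[which.max(tab)]
  }, character(1))
  list(seq = paste(cons, collapse = ""), is_consensus = TRUE, n = length(copies))
}
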
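# Construction and planting of synthetic cut-and-paste DNA transposon
# copies.  Elements carry terminal inverted repeats (TIRs) and an internal
# transposase ORF; insertion happens only at TA dinucleotides and duplicates
# the TA, so target-site-duplication (TSD) semantics are exact and testable.
# All truth coordinates are 0-based half-open.

NONSTOP_CODONS <- local({
  codons <- as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                            DNA_BASES, paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
})

#' Build a synthetic transposon element
#'
#' Constructs an element with the canonical pogo/Tigger-like layout: a left
#' TIR, a spacer, a single transposase ORF (`ATG ... stop`), a spacer, and
#' the reverse complement of the left TIR.  The three codons immediately
#' upstream of the ORF are a stop codon in the ORF frame, so the planted ORF
#' cannot be extended by chance upstream starts.
#'
#' @param length Total element length in bp (default 2500, the typical size
#'   of an intact family member).
#' @param tir_len TIR length in bp (default 20).
#' @param orf_aa Transposase length in amino acids, start codon included
#'   (default 492); the ORF occupies `3 * (orf_aa + 1)` bp.
#' @param disrupt_orf If `TRUE`, two in-frame stop codons are written at 1/3
#'   and 2/3 of the ORF, producing a structurally full element that no longer
#'   encodes an intact (>300 aa) transposase.
#' @param seed Optional integer seed.
#' @return A DNA string with attributes `tir_len`, `orf_start` (0-based) and
#'   `orf_nt` (ORF length in nt including the stop codon).
#' @examples
#' e <- make_te_element(seed = 1)
#' @export
make_te_element <- function(length = 2500, tir_len = 20, orf_aa = 492,
                            disrupt_orf = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  orf_nt <- 3L * (orf_aa + 1L)
  pad <- length - 2L * tir_len - orf_nt - 3L
  if (pad < 20L) stop("element length too small for the requested TIR and ORF")
  pad_left <- pad %/% 2L
  pad_right <- pad - pad_left
  tir <- random_dna(tir_len)
  codons <- c("ATG", sample(NONSTOP_CODONS, orf_aa - 1L, replace = TRUE), "TAA")
  if (disrupt_orf) {
    codons[orf_aa %/% 3L] <- "TAA"
    codons[2L * (orf_aa %/% 3L)] <- "TAA"
  }
  elem <- paste0(tir, random_dna(pad_left), "TAA", paste(codons, collapse = ""),
                 random_dna(pad_right), revcomp(tir))
  structure(elem, tir_len = tir_len, orf_start = tir_len + pad_left + 3L,
            orf_nt = orf_nt)
}

# Longest ATG..stop ORF restricted to one forward frame of an integer-coded
# sequence; used to derive truth labels independently of the 6-frame
# annotation scan.  Returns protein length in aa (start codon counted).
frame_longest_orf_aa <- function(v, frame_offset) {
  n <- length(v)
  starts <- seq.int(frame_offset + 1L, n - 2L, by = 3L)
  if (length(starts) == 0L) return(0L)
  cod <- paste0(DNA_BASES[v[starts]], DNA_BASES[v[starts + 1L]], DNA_BASES[v[starts + 2L]])
  best <- 0L; open <- NA_integer_
  for (i in seq_along(cod)) {
    if (is.na(open) && cod[i] == "ATG") open <- i
    if (!is.na(open) && cod[i] %in% c("TAA", "TAG", "TGA")) {
      best <- max(best, i - open)
      open <- NA_integer_
    }
  }
  best
}

#' Disrupt the transposase ORF of an element
#'
#' Writes two in-frame stop codons at 1/3 and 2/3 of the ORF of a
#' [make_te_element()] element, producing a same-family variant that is
#' structurally full (TIRs intact) but no longer encodes an intact (>300 aa)
#' transposase.
#'
#' @param element An element with `orf_start`/`orf_nt` attributes.
#' @return The disrupted element, attributes preserved.
#' @export
disrupt_element_orf <- function(element) {
  os <- attr(element, "orf_start"); on <- attr(element, "orf_nt")
  if (is.null(os) || is.null(on)) stop("element lacks ORF attributes")
  s <- as.character(element)
  n_cod <- on %/% 3L
  for (ci in c(n_cod %/% 3L, 2L * (n_cod %/% 3L))) {
    p <- os + 3L * (ci - 1L)          # 0-based codon start
    substr(s, p + 1L, p + 3L) <- "TAA"
  }
  structure(s, tir_len = attr(element, "tir_len"), orf_start = os, orf_nt = on)
}

# Truth class of a realized (mutated, untruncated) element copy, using only
# construction knowledge: the planted ORF frame.
realized_class <- function(copy_seq, orf_start) {
  v <- seq_to_int(copy_seq)
  aa <- frame_longest_orf_aa(v, orf_start %% 3L)
  if (aa > 300L) "intact" else "full"
}

#' Plant transposon copies into a genome at TA sites
#'
#' Inserts `n_copies` mutated copies of `element` at randomly chosen TA
#' dinucleotides, duplicating the TA on insertion so that every copy is
#' flanked by a TA target-site duplication.  Each copy is first aged by its
#' divergence (expected substitutions/site) under `model`; truncated copies
#' then lose a uniformly drawn prefix and/or suffix of at least 10% of the
#' element length.  Copies are inserted on either strand.
#'
#' @param genome DNA string (one contig).
#' @param element Element DNA string (ideally from [make_te_element()]), or a
#'   character vector recycled across copies for mixed-variant planting.
#' @param n_copies Number of copies to insert.
#' @param ages Per-copy divergence from the element, substitutions/site
#'   (recycled).
#' @param truncation_prob Probability that a copy is truncated.
#' @param truncate Optional logical vector overriding the random truncation
#'   draw (recycled).
#' @param model Substitution model used to age copies.
#' @param strands Candidate insertion strands, sampled per copy.
#' @param contig Contig name recorded in the truth table.
#' @param seed Optional integer seed.
#' @return A list with `genome` (the new contig) and `truth`, a data frame
#'   with one row per planted copy: `contig`, `start`, `end` (0-based
#'   half-open, TSD excluded), `strand`, `age`, `class`
#'   (truncated/full/intact), `tsd`, `length`, and `census` (whether the copy
#'   satisfies the >1000 bp census length rule).
#' @export
plant_te_copies <- function(genome, element, n_copies, ages = 0,
                            truncation_prob = 0, truncate = NULL,
                            model = substitution_model("K2P", kappa = 2),
                            strands = c("+", "-"), contig = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (truncation_prob < 0 || truncation_prob > 1) stop("truncation_prob must be in [0,1]")
  elem_attrs <- if (is.list(element)) element else as.list(element)
  if (length(elem_attrs) == 1L && !is.list(element)) elem_attrs <- list(element)
  elem_chr <- vapply(elem_attrs, function(e) as.character(e), character(1))
  if (any(nchar(genome) < nchar(elem_chr))) stop("genome shorter than element")
  truth0 <- data.frame(contig = character(), start = integer(), end = integer(),
                       strand = character(), age = numeric(), class = character(),
                       tsd = logical(), length = integer(), census = logical(),
                       stringsAsFactors = FALSE)
  if (n_copies == 0L) return(list(genome = genome, truth = truth0))

  variant_of <- rep_len(seq_along(elem_attrs), n_copies)
  ages <- rep_len(ages, n_copies)
  if (is.null(truncate)) truncate <- runif(n_copies) < truncation_prob
  truncate <- rep_len(truncate, n_copies)
  strand <- sample(rep_len(strands, max(2L, n_copies)), n_copies, replace = TRUE)

  ta <- gregexpr("TA", genome, fixed = TRUE)[[1L]]
  ta <- ta[ta > 2L & ta < nchar(genome) - 2L]
  if (length(ta) < n_copies) stop("not enough TA insertion sites in genome")
  sites <- sort(sample(ta, n_copies))

  parts <- character(0)
  prev <- 0L          # last consumed 1-based position of the original genome
  offset <- 0L        # accumulated length added before current site
  rows <- vector("list", n_copies)
  for (i in seq_len(n_copies)) {
    ev <- elem_attrs[[variant_of[i]]]
    elem <- as.character(ev)
    L0 <- nchar(elem)
    copy <- if (ages[i] > 0) {
      int_to_seq(evolve_int(seq_to_int(elem), ages[i] * model$rate, model))
    } else elem
    cls <- NA_character_
    if (truncate[i]) {
      cut_mode <- sample(c("left", "right", "both"), 1L)
      fl <- if (cut_mode %in% c("left", "both")) floor(runif(1, 0.10, 0.45) * L0) else 0L
      fr <- if (cut_mode %in% c("right", "both")) floor(runif(1, 0.10, 0.45) * L0) else 0L
      copy <- substr(copy, fl + 1L, L0 - fr)
      cls <- "truncated"
    } else {
      os <- attr(ev, "orf_start")
      cls <- if (is.null(os)) "full" else realized_class(copy, os)
    }
    L <- nchar(copy)
    ins <- if (strand[i] == "-") revcomp(copy) else copy
    p <- sites[i]
    # original genome up to and including the TA, then copy, then duplicated TA
    parts <- c(parts, substr(genome, prev + 1L, p + 1L), ins, "TA")
    start0 <- offset + p + 1L                    # 0-based start of the copy
    rows[[i]] <- data.frame(contig = contig, start = start0, end = start0 + L,
                            strand = strand[i], age = ages[i], class = cls,
                            tsd = TRUE, length = L, census = L > 1000L,
                            stringsAsFactors = FALSE)
    prev <- p + 1L
    offset <- offset + L + 2L
  }
  parts <- c(parts, substr(genome, prev + 1L, nchar(genome)))
  list(genome = paste(parts, collapse = ""), truth = do.call(rbind, rows))
}

#' Plant a class-structured census of transposon copies
#'
#' Convenience wrapper around [plant_te_copies()] planting a fixed number of
#' truncated, full-but-not-intact, and intact copies at a common divergence,
#' as used for census and classification validation.
#'
#' @param genome DNA string.
#' @param n_truncated,n_full,n_intact Copy counts per class.
#' @param age Divergence applied to every copy (substitutions/site).
#' @param element Intact element; default [make_te_element()] defaults.
#' @param element_full A full-length, ORF-disrupted variant; by default the
#'   same element with its ORF broken by [disrupt_element_orf()], so that
#'   full-only copies stay members of the same family.
#' @param seed Optional integer seed.
#' @inheritParams plant_te_copies
#' @return As [plant_te_copies()].  Note that class labels in the truth
#'   table describe the realized copies: an aged "intact" plant whose ORF
#'   acquired a premature stop is recorded as `full`.
#' @export
plant_te_census <- function(genome, n_truncated = 30, n_full = 12, n_intact = 8,
                            age = 0, element = NULL, element_full = NULL,
                            model = substitution_model("K2P", kappa = 2),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(element)) element <- make_te_element()
  if (is.null(element_full)) element_full <- disrupt_element_orf(element)
  n <- n_truncated + n_full + n_intact
  variants <- c(rep(list(element), n_truncated), rep(list(element_full), n_full),
                rep(list(element), n_intact))
  truncate <- c(rep(TRUE, n_truncated), rep(FALSE, n_full + n_intact))
  ord <- sample.int(n)  # interleave classes along the genome
  res <- plant_te_copies(genome, variants[ord], n, ages = age,
                         truncate = truncate[ord], model = model)
  res$element <- element
  res$element_full <- element_full
  res
}
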
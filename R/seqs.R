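# Low-level sequence utilities.  Sequences cross the package API as plain
# upper-case character strings over {A,C,G,T}; internally most numeric work
# happens on integer vectors with the encoding A=1, C=2, G=3, T=4.

DNA_BASES <- c("A", "C", "G", "T")

seq_to_int <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], DNA_BASES)
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T}")
  v
}

int_to_seq <- function(v) paste(DNA_BASES[v], collapse = "")

#' Generate a random DNA sequence
#'
#' Draws an i.i.d. nucleotide sequence, optionally with non-uniform base
#' frequencies.  Used throughout the synthetic-data generator for genome
#' backbones and neutral host-gene ancestors.
#'
#' @param length Number of bases.
#' @param freqs Base frequencies in A, C, G, T order; recycled to sum 1.
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return A character string of `length` bases.
#' @export
random_dna <- function(length, freqs = rep(0.25, 4), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- freqs / sum(freqs)
  int_to_seq(sample.int(4L, length, replace = TRUE, prob = freqs))
}

#' Reverse complement of a DNA string
#'
#' @param x Character string over A/C/G/T.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

revcomp_int <- function(v) rev(5L - v)

#' Read a FASTA file as named character strings
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' character vectors, the representation the rest of the package works with.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Translate one reading frame (1-based offset 0..2) of a nucleotide string.
translate_frame <- function(x, offset) {
  n <- nchar(x)
  len <- n - offset
  len <- len - (len %% 3L)
  if (len < 3L) return("")
  sub <- substr(x, offset + 1L, offset + len)
  as.character(Biostrings::translate(Biostrings::DNAString(sub)))
}

# All six translated frames: list with frame id (+1,+2,+3,-1,-2,-3),
# protein string, and strand.
six_frames <- function(x) {
  rc <- revcomp(x)
  frames <- list()
  for (o in 0:2) {
    frames[[length(frames) + 1L]] <- list(frame = o + 1L, strand = "+", offset = o,
                                          protein = translate_frame(x, o))
    frames[[length(frames) + 1L]] <- list(frame = -(o + 1L), strand = "-", offset = o,
                                          protein = translate_frame(rc, o))
  }
  frames
}
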
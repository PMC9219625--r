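# Kimura divergence landscapes: per-family histograms of copy coverage (kb)
# against copy-to-consensus K2P divergence (%), and the derived activity
# assessment (recent activity below 2% divergence; fossil-dominated when
# most mass lies above 10%).

#' Divergence profile of element copies against a consensus
#'
#' Computes, for every copy, its K2P divergence from the consensus (pairwise
#' deletion) and its aligned length, and accumulates aligned kb into
#' contiguous divergence bins starting at 0%.  Copies with undefined
#' (saturated) distances are excluded and reported.
#'
#' @param copies Character vector of copy sequences.
#' @param consensus Consensus (or representative) sequence.
#' @param bin_width Bin width in percent divergence (default 1).
#' @param aligned If `TRUE` the copies are already gapped strings on the
#'   consensus column space (equal widths); otherwise each copy is globally
#'   aligned to the consensus first.
#' @param element,species Optional identifiers stored in the profile.
#' @return An object of class `"divergence_profile"`: list with `copies`
#'   (per-copy divergence % and kb), `histogram` (bin lower edge % ->
#'   coverage kb, contiguous from 0), `bin_width`, `total_kb`, `excluded`.
#' @export
divergence_profile <- function(copies, consensus, bin_width = 1, aligned = FALSE,
                               element = "element", species = "species") {
  if (bin_width <= 0) stop("bin_width must be positive")
  div <- numeric(0); kb <- numeric(0); excluded <- integer(0)
  for (i in seq_along(copies)) {
    if (aligned) {
      g <- gapped_pair_ints(copies[i], consensus)
      k <- tryCatch(k2p_distance(copies[i], consensus), error = function(e) NULL)
      ncols <- sum(g$both)
    } else {
      aln <- align_pair(copies[i], consensus)
      k <- tryCatch(k2p_distance(aln), error = function(e) NULL)
      ncols <- aln$aligned_cols
    }
    if (is.null(k) || isTRUE(k$saturated)) {
      excluded <- c(excluded, i)
      next
    }
    div <- c(div, 100 * k$distance)
    kb <- c(kb, ncols / 1000)
  }
  nbins <- if (length(div)) floor(max(div) / bin_width) + 1L else 0L
  hist <- if (nbins) {
    edges <- (seq_len(nbins) - 1L) * bin_width
    idx <- pmin(floor(div / bin_width) + 1L, nbins)
    setNames(vapply(seq_len(nbins), function(b) sum(kb[idx == b]), numeric(1)),
             edges)
  } else numeric(0)
  structure(list(element = element, species = species,
                 copies = data.frame(divergence = div, kb = kb),
                 histogram = hist, bin_width = bin_width,
                 total_kb = sum(kb), excluded = excluded),
            class = "divergence_profile")
}

#' Activity assessment from a divergence profile
#'
#' Flags recent activity when any coverage mass lies below `recent_cut`
#' percent divergence, and a fossil-dominated landscape when more than half
#' of the mass lies above `old_cut` percent.
#'
#' @param profile A [divergence_profile()].
#' @param recent_cut Recent-activity divergence cut in percent (default 2).
#' @param old_cut Old-copy divergence cut in percent (default 10).
#' @return List with `recent_activity`, `fossil_dominated`,
#'   `mass_below_recent`, `mass_above_old` (fractions of total kb).
#' @export
activity_assessment <- function(profile, recent_cut = 2, old_cut = 10) {
  stopifnot(inherits(profile, "divergence_profile"))
  cp <- profile$copies
  if (!nrow(cp) || profile$total_kb <= 0) stop("assessment undefined: empty profile")
  below <- sum(cp$kb[cp$divergence < recent_cut]) / profile$total_kb
  above <- sum(cp$kb[cp$divergence > old_cut]) / profile$total_kb
  list(recent_activity = below > 0, fossil_dominated = above > 0.5,
       mass_below_recent = below, mass_above_old = above)
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat(sprintf("divergence profile: %s / %s, %d copies, %.1f kb total, bin %g%%\n",
              x$species, x$element, nrow(x$copies), x$total_kb, x$bin_width))
  invisible(x)
}

#' @method plot divergence_profile
#' @export
plot.divergence_profile <- function(x, ...) {
  barplot(x$histogram, names.arg = names(x$histogram), space = 0,
          xlab = "Kimura divergence (%)", ylab = "coverage (kb)",
          main = sprintf("%s / %s", x$species, x$element), ...)
  invisible(x)
}
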
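# Pairwise alignment, identity and genetic distances.
#
# Distances follow the two estimators the HT analysis needs: the Kimura
# two-parameter (K2P) closed form, and a composite-likelihood Tamura-Nei
# (TN93) matrix in which the substitution parameters (two transition rates,
# one transversion rate, base frequencies) are estimated once from counts
# pooled over all sequence pairs, and each pair's distance is then the
# maximum-likelihood branch length under that shared model.  Columns are
# deleted pairwise: a column is used for a pair iff both members are
# non-gap, regardless of other rows.

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, delegated to
#' [Biostrings::pairwiseAlignment()].  A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return An object of class `"pair_alignment"`: list with gapped sequences
#'   `a` and `b` (equal widths), `score`, `aligned_cols` (columns with both
#'   sequences non-gap) and `gap_cols`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap_open = 4, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a), Biostrings::DNAString(b),
                                      type = "global", substitutionMatrix = sm,
                                      gapOpening = gap_open, gapExtension = gap_extend)
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  va <- strsplit(ga, "")[[1L]]; vb <- strsplit(gb, "")[[1L]]
  both <- va != "-" & vb != "-"
  structure(list(a = ga, b = gb, score = Biostrings::score(pa),
                 aligned_cols = sum(both), gap_cols = sum(!both)),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: score %.1f, %d aligned columns, %d gap columns\n",
              x$score, x$aligned_cols, x$gap_cols))
  invisible(x)
}

# Resolve (alignment | two gapped strings) into two integer vectors with NA
# at gaps, restricted to pairwise-complete columns on request.
gapped_pair_ints <- function(a, b = NULL) {
  if (inherits(a, "pair_alignment")) { b <- a$b; a <- a$a }
  va <- strsplit(toupper(a), "")[[1L]]; vb <- strsplit(toupper(b), "")[[1L]]
  if (length(va) != length(vb)) stop("gapped sequences must have equal widths")
  ia <- match(va, DNA_BASES); ib <- match(vb, DNA_BASES)
  list(a = ia, b = ib, both = !is.na(ia) & !is.na(ib))
}

#' Percent identity of an alignment
#'
#' Fraction of identical bases over the pairwise-complete (both non-gap)
#' columns.
#'
#' @param aln A [align_pair()] result, or a gapped string (then `b` must be
#'   the matching gapped partner).
#' @param b Optional gapped partner sequence.
#' @return Identity fraction in \[0, 1\].
#' @export
percent_identity <- function(aln, b = NULL) {
  g <- gapped_pair_ints(aln, b)
  if (!any(g$both)) stop("identity undefined: no pairwise-complete columns")
  mean(g$a[g$both] == g$b[g$both])
}

# 4x4 substitution count matrix over pairwise-complete columns.
pair_count_matrix <- function(ia, ib) {
  keep <- !is.na(ia) & !is.na(ib)
  m <- matrix(tabulate((ia[keep] - 1L) * 4L + ib[keep], nbins = 16L), 4L, 4L,
              byrow = TRUE, dimnames = list(DNA_BASES, DNA_BASES))
  m
}

# Transition (P) and transversion (Q) proportions from a count matrix.
count_props <- function(cm) {
  n <- sum(cm)
  ts1 <- cm["A", "G"] + cm["G", "A"]          # purine transitions
  ts2 <- cm["C", "T"] + cm["T", "C"]          # pyrimidine transitions
  tv <- n - sum(diag(cm)) - ts1 - ts2
  list(n = n, P1 = ts1 / n, P2 = ts2 / n, P = (ts1 + ts2) / n, Q = tv / n)
}

#' Kimura two-parameter distance
#'
#' K2P closed form with pairwise deletion:
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, with `P` and `Q` the
#' transition and transversion fractions over pairwise-complete columns.
#'
#' @inheritParams percent_identity
#' @return A list: `distance`, `P`, `Q`, `n_sites`, `variance` (the standard
#'   closed-form sampling variance) and `saturated` (`TRUE` with `distance =
#'   NA` when a logarithm argument is non-positive).
#' @export
k2p_distance <- function(aln, b = NULL) {
  g <- gapped_pair_ints(aln, b)
  cm <- pair_count_matrix(g$a, g$b)
  pr <- count_props(cm)
  if (pr$n == 0L) stop("distance undefined: no pairwise-complete columns")
  w1 <- 1 - 2 * pr$P - pr$Q
  w2 <- 1 - 2 * pr$Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(distance = NA_real_, P = pr$P, Q = pr$Q, n_sites = pr$n,
                variance = NA_real_, saturated = TRUE))
  }
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  c1 <- 1 / w1; c2 <- 1 / w2; c3 <- (c1 + c2) / 2
  v <- (c1^2 * pr$P + c3^2 * pr$Q - (c1 * pr$P + c3 * pr$Q)^2) / pr$n
  list(distance = d, P = pr$P, Q = pr$Q, n_sites = pr$n, variance = v,
       saturated = FALSE)
}

#' Uncorrected p-distance
#'
#' @inheritParams percent_identity
#' @return Fraction of differing pairwise-complete columns.
#' @export
p_distance <- function(aln, b = NULL) {
  1 - percent_identity(aln, b)
}

# Maximum-likelihood branch length for one pair under a fixed (shared)
# substitution model.  The likelihood is over the four substitution
# categories (identical, purine transition, pyrimidine transition,
# transversion); with the shared rates taken from the same pair's moment
# estimates this maximum coincides exactly with the TN93 closed form.
# Returns NA when the pair is saturated (the likelihood keeps increasing
# with t).
ml_pair_distance <- function(cm, model, t_max = 15) {
  n <- sum(cm)
  if (n == 0L) stop("distance undefined: no pairwise-complete columns")
  pr <- count_props(cm)
  obs <- c(same = n - (pr$P1 + pr$P2 + pr$Q) * n,
           ts1 = pr$P1 * n, ts2 = pr$P2 * n, tv = pr$Q * n)
  if (obs["ts1"] + obs["ts2"] + obs["tv"] == 0) return(0)
  pi_ <- model$freqs
  cat_probs <- function(P) {
    f <- pi_ * P                              # rows scaled by freqs
    ts1 <- f["A", "G"] + f["G", "A"]
    ts2 <- f["C", "T"] + f["T", "C"]
    same <- sum(diag(f))
    c(same = same, ts1 = ts1, ts2 = ts2, tv = 1 - same - ts1 - ts2)
  }
  score <- function(t) {
    P <- transition_probs(model, t)
    dP <- model$Q %*% P
    p <- cat_probs(P)
    dp <- cat_probs_deriv(dP, pi_)
    sum(obs * dp / pmax(p, 1e-300))
  }
  cat_probs_deriv <- function(dP, pi_) {
    f <- pi_ * dP
    ts1 <- f["A", "G"] + f["G", "A"]
    ts2 <- f["C", "T"] + f["T", "C"]
    same <- sum(diag(f))
    c(same = same, ts1 = ts1, ts2 = ts2, tv = -same - ts1 - ts2)
  }
  lo <- 1e-11
  if (score(lo) <= 0) return(0)
  if (score(t_max) >= 0) return(NA_real_)   # saturated
  uniroot(score, c(lo, t_max), tol = 1e-13)$root
}

#' Composite-likelihood TN93 distance matrix
#'
#' Estimates TN93 substitution parameters once from substitution counts
#' pooled over all sequence pairs (pairwise deletion), then computes each
#' pair's maximum-likelihood distance under that shared model.  This is the
#' shared-parameter construction behind "maximum composite likelihood"
#' distance tables; saturated pairs are flagged (`NA` entries plus a
#' `saturated` attribute), never silently dropped.
#'
#' @param seqs Named character vector of sequences.  With `aligned = TRUE`
#'   (default) they must be on a common column space (equal widths, `-` for
#'   gaps); otherwise every pair is globally aligned first with
#'   [align_pair()].
#' @param aligned Are the input sequences already aligned?
#' @return A symmetric numeric matrix with zero diagonal and attributes
#'   `method` (`"MCL-TN93"`), `saturated` (logical matrix) and `model` (the
#'   fitted shared [substitution_model()]).
#' @export
mcl_distance_matrix <- function(seqs, aligned = TRUE) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  labs <- names(seqs)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  ints <- lapply(seqs, function(s) match(strsplit(toupper(s), "")[[1L]], DNA_BASES))
  if (aligned) {
    if (length(unique(lengths(ints))) != 1L)
      stop("aligned sequences must have equal widths")
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cms <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (aligned) {
      cms[[k]] <- pair_count_matrix(ints[[i]], ints[[j]])
    } else {
      aln <- align_pair(seqs[[i]], seqs[[j]])
      g <- gapped_pair_ints(aln)
      cms[[k]] <- pair_count_matrix(g$a, g$b)
    }
  }
  pooled <- Reduce(`+`, cms)
  # base frequencies from all sequences (each counted once)
  base_counts <- rowSums(vapply(ints, function(v) tabulate(v, 4L), numeric(4)))
  freqs <- base_counts / sum(base_counts)
  pr <- count_props(pooled)
  piA <- freqs[1L]; piC <- freqs[2L]; piG <- freqs[3L]; piT <- freqs[4L]
  piR <- piA + piG; piY <- piC + piT
  wb <- 1 - pr$Q / (2 * piR * piY)
  w1 <- 1 - piR * pr$P1 / (2 * piA * piG) - pr$Q / (2 * piR)
  w2 <- 1 - piY * pr$P2 / (2 * piC * piT) - pr$Q / (2 * piY)
  if (wb <= 0 || w1 <= 0 || w2 <= 0)
    stop("pooled substitution counts are saturated; cannot estimate shared TN93 parameters")
  b <- -log(wb); a1 <- -log(w1); a2 <- -log(w2)
  kappa1 <- if (b > 0) max((a1 - piY * b) / (piR * b), 1e-6) else 1
  kappa2 <- if (b > 0) max((a2 - piR * b) / (piY * b), 1e-6) else 1
  model <- substitution_model("TN93", kappa1 = kappa1, kappa2 = kappa2, freqs = freqs)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  sat <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    d <- ml_pair_distance(cms[[k]], model)
    if (is.na(d)) sat[i, j] <- sat[j, i] <- TRUE
    D[i, j] <- D[j, i] <- d
  }
  structure(D, method = "MCL-TN93", saturated = sat, model = model)
}

#' Pairwise identity matrix
#'
#' @inheritParams mcl_distance_matrix
#' @return Symmetric matrix of identity fractions (diagonal 1).
#' @export
identity_matrix <- function(seqs, aligned = TRUE) {
  n <- length(seqs)
  labs <- names(seqs)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  M <- diag(1, n)
  dimnames(M) <- list(labs, labs)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    M[i, j] <- M[j, i] <- if (aligned) percent_identity(seqs[[i]], seqs[[j]]) else
      percent_identity(align_pair(seqs[[i]], seqs[[j]]))
  }
  M
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration.  Ties in the Q criterion are
#' broken by the lexicographically smallest index pair, so the output is
#' deterministic.  Negative branch lengths are clamped to zero with the
#' deficit moved to the sister branch (path lengths through the joined node
#' are preserved).
#'
#' @param dm Symmetric numeric matrix with labelled rows/columns (>= 3).
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 labels")
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix must be symmetric")
  labs <- rownames(dm)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(dm)))
  nodes <- as.list(labs)      # newick fragments
  D <- unname(dm)
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (length(nodes) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Qm <- (r - 2) * D - outer(R, R, `+`)
    diag(Qm) <- Inf
    # lexicographically smallest (i, j) among minima
    idx <- which(Qm == min(Qm), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0; vi <- max(vi, 0) }
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[[i]], fmt(vi), nodes[[j]], fmt(vj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    D <- D2
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[[1]], fmt(v1), nodes[[2]], fmt(v2),
                 nodes[[3]], fmt(v3))
  ape::read.tree(text = nwk)
}
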
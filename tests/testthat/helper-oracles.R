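# Independent oracles used across the suite.  Each re-implements the checked
# computation by brute force or closed form, sharing no code with the
# package internals.

BASES <- c("A", "C", "G", "T")

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# --- exhaustive affine-gap global alignment score (Gotoh, full DP) --------
dp_align_score <- function(a, b, match = 1, mismatch = -1, gap_open = 4,
                           gap_extend = 1) {
  va <- chars(a); vb <- chars(b)
  n <- length(va); m <- length(vb)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)   # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1L, m + 1L)   # gap in a (consumes b)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) Ix[i + 1L, 1L] <- -(gap_open + i * gap_extend)
  for (j in seq_len(m)) Iy[1L, j + 1L] <- -(gap_open + j * gap_extend)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (va[i] == vb[j]) match else mismatch
    M[i + 1L, j + 1L] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
    Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                              Ix[i, j + 1L] - gap_extend)
    Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                              Iy[i + 1L, j] - gap_extend)
  }
  max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
}

# --- brute-force terminal-inverted-repeat search --------------------------
# Enumerates every (left start, right end, length) triple and applies the
# same acceptance rule and ranking as the package contract.
brute_tir <- function(region, min_len = 8L, max_len = 40L, max_mismatch = NULL,
                      end_window = 50L) {
  v <- match(chars(region), BASES)
  comp <- c(4L, 3L, 2L, 1L)
  n <- length(v)
  tol <- function(len) if (is.null(max_mismatch)) {
    if (len < 12L) 0L else ceiling(len / 10)
  } else max_mismatch
  best <- NULL
  for (i0 in 0:(min(end_window, n) - 1L)) {
    for (re in seq(n, by = -1L, length.out = min(end_window, n))) {
      for (len in min_len:max_len) {
        if (i0 + len > n || re - len < i0 + len) next
        left <- v[(i0 + 1L):(i0 + len)]
        right <- v[(re - len + 1L):re]
        mm <- sum(left != comp[rev(right)])
        if (mm > tol(len)) next
        cand <- c(len = len, mm = mm, left0 = i0, right_end0 = re)
        if (is.null(best) ||
            cand["len"] > best["len"] ||
            (cand["len"] == best["len"] && cand["mm"] < best["mm"]) ||
            (cand["len"] == best["len"] && cand["mm"] == best["mm"] &&
             cand["left0"] < best["left0"]) ||
            (cand["len"] == best["len"] && cand["mm"] == best["mm"] &&
             cand["left0"] == best["left0"] && cand["right_end0"] > best["right_end0"])) {
          best <- cand
        }
      }
    }
  }
  best
}

# --- exhaustive ORF enumeration ------------------------------------------
enumerate_orfs <- function(seq) {
  rc <- paste(rev(c(A = "T", C = "G", G = "C", T = "A")[chars(seq)]), collapse = "")
  out <- list()
  n <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (off in 0:2) {
      starts <- seq.int(off + 1L, n - 2L, by = 3L)
      cods <- substring(s, starts, starts + 2L)
      atg <- which(cods == "ATG")
      stp <- which(cods %in% c("TAA", "TAG", "TGA"))
      for (a in atg) {
        nxt <- stp[stp > a]
        if (!length(nxt)) next
        out[[length(out) + 1L]] <- list(aa = nxt[1L] - a, strand = strand,
                                        start_codon = starts[a])
      }
    }
  }
  out
}

longest_orf_oracle_aa <- function(seq) {
  orfs <- enumerate_orfs(seq)
  if (!length(orfs)) return(NULL)
  max(vapply(orfs, `[[`, 0L, "aa"))
}

# --- direct-formula one-factor ANOVA -------------------------------------
direct_anova <- function(groups) {
  k <- length(groups)
  vals <- unlist(groups)
  N <- length(vals)
  gm <- mean(vals)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, p = pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

permutation_anova_p <- function(groups, B = 2000L) {
  vals <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  Fobs <- direct_anova(groups)$F
  cnt <- 0L
  for (b in seq_len(B)) {
    gp <- sample(g)
    Fb <- direct_anova(split(vals, gp))$F
    if (Fb >= Fobs) cnt <- cnt + 1L
  }
  (1 + cnt) / (B + 1)
}

# --- TN93 closed-form distance -------------------------------------------
tn93_closed <- function(a, b) {
  ia <- match(chars(a), BASES); ib <- match(chars(b), BASES)
  keep <- !is.na(ia) & !is.na(ib); ia <- ia[keep]; ib <- ib[keep]
  n <- length(ia)
  f <- (tabulate(ia, 4L) + tabulate(ib, 4L)) / (2 * n)
  piA <- f[1]; piC <- f[2]; piG <- f[3]; piT <- f[4]
  piR <- piA + piG; piY <- piC + piT
  P1 <- sum((ia == 1 & ib == 3) | (ia == 3 & ib == 1)) / n
  P2 <- sum((ia == 2 & ib == 4) | (ia == 4 & ib == 2)) / n
  Q <- sum(ia != ib) / n - P1 - P2
  a1 <- -log(1 - piR * P1 / (2 * piA * piG) - Q / (2 * piR))
  a2 <- -log(1 - piY * P2 / (2 * piC * piT) - Q / (2 * piY))
  bb <- -log(1 - Q / (2 * piR * piY))
  (2 * piA * piG / piR) * a1 + (2 * piC * piT / piY) * a2 +
    2 * (piR * piY - piA * piG * piY / piR - piC * piT * piR / piY) * bb
}

# --- K2P closed form recomputed from raw strings --------------------------
k2p_closed <- function(a, b) {
  ia <- match(chars(a), BASES); ib <- match(chars(b), BASES)
  keep <- !is.na(ia) & !is.na(ib); ia <- ia[keep]; ib <- ib[keep]
  n <- length(ia)
  ts <- sum((ia == 1 & ib == 3) | (ia == 3 & ib == 1) |
            (ia == 2 & ib == 4) | (ia == 4 & ib == 2))
  tv <- sum(ia != ib) - ts
  P <- ts / n; Q <- tv / n
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# --- fixtures -------------------------------------------------------------
# A region with an exact planted TIR of length `len` at both ends (TA flanks
# optional), interior random; `mut` positions of the left TIR mutated.
make_tir_region <- function(len, interior = 400L, mut = 0L) {
  tir <- random_dna(len)
  if (mut > 0L) {
    v <- chars(tir)
    pos <- sample(seq_len(len), mut)
    for (p in pos) v[p] <- sample(setdiff(BASES, v[p]), 1L)
    left <- paste(v, collapse = "")
  } else left <- tir
  paste0(left, random_dna(interior), revcomp(tir))
}

# Map an annotated element interval (within an extracted, possibly
# reverse-complemented region) back to forward genomic coordinates.
region_to_genomic <- function(region_start, region_len, element, strand) {
  if (strand == "+") {
    c(region_start + element[1L], region_start + element[2L])
  } else {
    c(region_start + region_len - element[2L], region_start + region_len - element[1L])
  }
}
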
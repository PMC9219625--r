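# Nucleotide substitution models used by the simulator and the distance
# estimators.  Both K2P and TN93 are parameterised through the TN93 rate
# matrix; K2P is the equal-frequency, single-transition-rate special case.

#' Construct a nucleotide substitution model
#'
#' Builds a reversible substitution model of the Tamura-Nei (TN93) family.
#' The rate matrix is scaled so that one unit of branch length corresponds to
#' one expected substitution per site, which lets simulated divergence be read
#' directly in substitutions/site.
#'
#' @param model `"K2P"` or `"TN93"`.
#' @param kappa Transition/transversion rate ratio (used for K2P, and as the
#'   default for both transition classes under TN93).  Must be positive.
#' @param kappa1,kappa2 Purine (A/G) and pyrimidine (C/T) transition rate
#'   ratios relative to the transversion rate (TN93 only); default `kappa`.
#' @param freqs Equilibrium base frequencies in A, C, G, T order.  Forced to
#'   1/4 each under K2P.
#' @param rate Overall rate multiplier (expected substitutions/site per unit
#'   branch length); default 1.
#' @return An object of class `"subst_model"`: a list with the (scaled) rate
#'   matrix `Q`, its eigendecomposition, `freqs`, and the rate parameters.
#' @examples
#' m <- substitution_model("K2P", kappa = 2)
#' @export
substitution_model <- function(model = c("K2P", "TN93"), kappa = 2,
                               kappa1 = kappa, kappa2 = kappa,
                               freqs = rep(0.25, 4), rate = 1) {
  model <- match.arg(model)
  if (kappa1 <= 0 || kappa2 <= 0) stop("kappa must be > 0")
  if (rate < 0) stop("rate must be >= 0")
  if (model == "K2P") {
    freqs <- rep(0.25, 4)
    kappa2 <- kappa1
  }
  if (length(freqs) != 4L || any(freqs <= 0)) stop("freqs must be 4 positive values")
  freqs <- freqs / sum(freqs)
  Q <- tn93_rate_matrix(kappa1, kappa2, freqs)
  eig <- eigen(Q)
  structure(list(model = model, kappa1 = kappa1, kappa2 = kappa2,
                 freqs = freqs, rate = rate, Q = Q,
                 evec = eig$vectors, eval = Re(eig$values),
                 evec_inv = solve(eig$vectors)),
            class = "subst_model")
}

# Unnormalised TN93 generator, then scaled to mean rate 1 at equilibrium.
# beta = 1 is the transversion rate; alpha1 = kappa1 (A<->G), alpha2 = kappa2
# (C<->T).
tn93_rate_matrix <- function(kappa1, kappa2, freqs) {
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    pur_i <- i %in% c(1L, 3L)
    pur_j <- j %in% c(1L, 3L)
    r <- if (pur_i && pur_j) kappa1 else if (!pur_i && !pur_j) kappa2 else 1
    Q[i, j] <- r * freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# Transition probability matrix P(t) = exp(Qt) via the cached
# eigendecomposition; t in expected substitutions/site.
transition_probs <- function(model, t) {
  if (t <= 0) return(matrix(diag(4), 4, 4, dimnames = list(DNA_BASES, DNA_BASES)))
  P <- model$evec %*% diag(exp(model$eval * t)) %*% model$evec_inv
  P <- Re(P)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  P
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model (kappa1 = %.3g, kappa2 = %.3g, rate = %.3g)\n",
              x$model, x$kappa1, x$kappa2, x$rate))
  cat("base frequencies:", paste(sprintf("%s=%.3f", DNA_BASES, x$freqs), collapse = " "), "\n")
  invisible(x)
}
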
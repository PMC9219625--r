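# Horizontal-transfer inference from distance matrices.
#
# Three filters, applied per species pair and then per candidate event:
#   1. element identity  > 0.70 (strict),
#   2. element distance at most the host-gene distance divided by 1.2
#      (d_te * 1.2 <= d_host, for every primary host gene),
#   3. a one-factor ANOVA across markers (element vs each host gene) over
#      the distances of the event's passing pairs, significant at p < 0.01
#      with the element group mean smallest.
# Events are connected components of the pass graph; secondary conserved
# genes (RAG1 for vertebrate pairs, tub3 for pairs involving an
# invertebrate) re-run filters 2-3 for confirmation.

upper_pairs <- function(labs) {
  n <- length(labs)
  if (n < 2L) return(data.frame(a = character(), b = character()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(a = labs[idx[, 1L]], b = labs[idx[, 2L]], stringsAsFactors = FALSE)
}

#' Identity filter for HT candidates
#'
#' Selects species pairs whose element identity is strictly greater than the
#' threshold (by default 70%).
#'
#' @param id_matrix Symmetric identity matrix (fractions).
#' @param threshold Identity threshold, exclusive (default 0.70).
#' @return Data frame of candidate pairs `a`, `b` with their `identity`.
#' @export
identity_filter <- function(id_matrix, threshold = 0.70) {
  labs <- rownames(id_matrix)
  pr <- upper_pairs(labs)
  if (!nrow(pr)) return(cbind(pr, identity = numeric(0)))
  pr$identity <- id_matrix[cbind(pr$a, pr$b)]
  pr[pr$identity > threshold, , drop = FALSE]
}

#' Distance-ratio filter
#'
#' A pair passes when its element distance, inflated by `factor`, does not
#' exceed the host-gene distance — by default for *every* primary host gene
#' (`mode = "all"`); `mode = "any"` requires only one gene.  Saturated or
#' missing distances fail the filter.
#'
#' @param d_te Element distance (scalar or vector).
#' @param d_hosts Host-gene distances: a numeric vector (one gene per
#'   element) or a list/matrix of per-gene values aligned with `d_te`.
#' @param factor Ratio factor (default 1.2).
#' @param mode `"all"` (default) or `"any"`.
#' @return Logical vector of pass flags.
#' @export
distance_ratio_filter <- function(d_te, d_hosts, factor = 1.2, mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (is.numeric(d_hosts)) d_hosts <- list(d_hosts)
  if (is.list(d_hosts)) d_hosts <- do.call(cbind, d_hosts)
  d_hosts <- matrix(d_hosts, nrow = length(d_te))
  ok <- !is.na(d_te) & apply(d_hosts, 1L, function(h) !anyNA(h))
  cmp <- d_te * factor <= d_hosts
  pass <- if (mode == "all") apply(cmp, 1L, all) else apply(cmp, 1L, any)
  pass & ok
}

#' One-factor ANOVA across marker distance groups
#'
#' Compares the element distances of an implicated set of pairs against the
#' corresponding host-gene distances with a one-factor ANOVA (delegated to
#' [stats::aov()]).  When all values are identical across groups the test is
#' degenerate and reported as `F = 0`, `p = 1`; with fewer than two values
#' per group the test is untestable (`NA`).
#'
#' @param te_dists Numeric vector of element distances (one group).
#' @param host_dist_groups List of numeric vectors, one per host gene.
#' @return List with `F`, `p`, `group_means`, `te_smallest`, `testable`.
#' @export
anova_significance <- function(te_dists, host_dist_groups) {
  groups <- c(list(te = te_dists), as.list(host_dist_groups))
  if (is.null(names(groups)) || any(names(groups)[-1] == ""))
    names(groups)[-1] <- paste0("host", seq_along(groups[-1]))
  values <- unlist(groups, use.names = FALSE)
  gf <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  means <- vapply(groups, mean, numeric(1))
  te_smallest <- which.min(means) == 1L && all(means[1L] < means[-1L])
  if (any(lengths(groups) < 2L)) {
    return(list(F = NA_real_, p = NA_real_, group_means = means,
                te_smallest = te_smallest, testable = FALSE))
  }
  if (var(values) == 0) {
    return(list(F = 0, p = 1, group_means = means, te_smallest = FALSE,
                testable = TRUE))
  }
  fit <- aov(values ~ gf)
  tab <- anova(fit)
  Fv <- tab$`F value`[1L]
  pv <- tab$`Pr(>F)`[1L]
  if (is.nan(Fv) || is.na(Fv)) { Fv <- 0; pv <- 1 }
  if (is.infinite(Fv) || (is.na(pv) && Fv > 0)) pv <- 0
  list(F = Fv, p = pv, group_means = means, te_smallest = te_smallest,
       testable = TRUE)
}

#' Group passing pairs into candidate HT events
#'
#' Events are the connected components of the graph whose edges are the
#' pairs passing the identity and distance-ratio filters.  Events are
#' ordered by their smallest member label.
#'
#' @param pairs Data frame with columns `a` and `b` (species labels).
#' @return List of events; each is a list with `members` (sorted labels) and
#'   `pairs` (the rows of `pairs` within the event).
#' @export
call_ht_events <- function(pairs) {
  if (!nrow(pairs)) return(list())
  g <- igraph::graph_from_data_frame(pairs[, c("a", "b")], directed = FALSE)
  comp <- igraph::components(g)
  events <- lapply(seq_len(comp$no), function(k) {
    members <- sort(names(comp$membership)[comp$membership == k])
    inside <- pairs$a %in% members & pairs$b %in% members
    list(members = members, pairs = pairs[inside, , drop = FALSE])
  })
  events[order(vapply(events, function(e) e$members[1L], character(1)))]
}

# ANOVA groups for one event: distances of the event's passing pairs
# (default), or of all pairs among the implicated species ("component").
event_groups <- function(event, d_te, d_host_list, groups = c("passing", "component")) {
  groups <- match.arg(groups)
  pr <- if (groups == "passing") event$pairs[, c("a", "b")] else
    upper_pairs(event$members)
  idx <- cbind(pr$a, pr$b)
  list(te = d_te[idx], hosts = lapply(d_host_list, function(m) m[idx]))
}

#' Detect horizontal-transfer events
#'
#' Runs the full three-filter HT inference on an element identity matrix, an
#' element distance matrix, and one distance matrix per primary host gene,
#' with optional secondary-gene confirmation.
#'
#' @param id_te Element identity matrix (fractions, symmetric).
#' @param d_te Element distance matrix.
#' @param d_hosts Named list of primary host-gene distance matrices
#'   (typically RPL3 and RPL4 analogues), all with the same labels.
#' @param identity_threshold Identity cut-off, exclusive (default 0.70).
#' @param ratio_factor Distance-ratio factor (default 1.2).
#' @param alpha ANOVA significance level (default 0.01).
#' @param ratio_mode `"all"` or `"any"` host gene for the ratio filter.
#' @param anova_groups `"passing"` (default): ANOVA groups are the distances
#'   of the event's passing pairs; `"component"`: all pairwise distances
#'   among implicated species.
#' @param secondary Optional named list of secondary-gene distance matrices
#'   (`RAG1`, `tub3`) for [confirm_events()].
#' @param vertebrate Named logical vector (per species) used to pick the
#'   secondary gene; required when `secondary` is given.
#' @param bonferroni Apply a Bonferroni correction of `alpha` across
#'   candidate events (off by default).
#' @return An object of class `"ht_scan"`: list with `candidates` (per-pair
#'   filter table), `events` (all candidate events with ANOVA evidence and
#'   `called` flags), and the thresholds used.
#' @export
detect_ht <- function(id_te, d_te, d_hosts, identity_threshold = 0.70,
                      ratio_factor = 1.2, alpha = 0.01,
                      ratio_mode = c("all", "any"),
                      anova_groups = c("passing", "component"),
                      secondary = NULL, vertebrate = NULL, bonferroni = FALSE) {
  ratio_mode <- match.arg(ratio_mode)
  anova_groups <- match.arg(anova_groups)
  labs <- rownames(d_te)
  cand <- upper_pairs(labs)
  cand$identity <- id_te[cbind(cand$a, cand$b)]
  cand$d_te <- d_te[cbind(cand$a, cand$b)]
  for (g in names(d_hosts)) cand[[paste0("d_", g)]] <- d_hosts[[g]][cbind(cand$a, cand$b)]
  cand$identity_pass <- cand$identity > identity_threshold
  host_cols <- lapply(d_hosts, function(m) m[cbind(cand$a, cand$b)])
  cand$ratio_pass <- distance_ratio_filter(cand$d_te, host_cols, ratio_factor, ratio_mode)
  cand$pass <- cand$identity_pass & cand$ratio_pass
  events <- call_ht_events(cand[cand$pass, , drop = FALSE])
  a_eff <- if (bonferroni && length(events)) alpha / length(events) else alpha
  for (k in seq_along(events)) {
    gr <- event_groups(events[[k]], d_te, d_hosts, anova_groups)
    an <- anova_significance(gr$te, gr$hosts)
    events[[k]]$anova <- an
    events[[k]]$called <- isTRUE(an$testable) && !is.na(an$p) &&
      an$p < a_eff && an$te_smallest
  }
  res <- structure(list(candidates = cand, events = events,
                        thresholds = list(identity = identity_threshold,
                                          ratio_factor = ratio_factor,
                                          alpha = alpha, ratio_mode = ratio_mode,
                                          anova_groups = anova_groups)),
                   class = "ht_scan")
  if (!is.null(secondary)) {
    res$events <- confirm_events(res$events, secondary, vertebrate, d_te,
                                 d_hosts = d_hosts, ratio_factor = ratio_factor,
                                 alpha = alpha)
  }
  res
}

#' Confirm HT events with secondary conserved genes
#'
#' Re-runs the distance-ratio and ANOVA filters on each called event using a
#' secondary gene: RAG1 for pairs of vertebrates, tub3 for pairs involving
#' an invertebrate.  An event is `confirmed` when every pair passes the
#' ratio filter under its secondary gene and the event still passes the
#' marker ANOVA with the secondary gene included among the host-gene groups
#' (significant with the element mean smallest); pairs whose secondary
#' distance is missing are unconfirmable and mark the event `partial`.
#'
#' @param events Event list from [detect_ht()]/[call_ht_events()].
#' @param secondary Named list of secondary distance matrices (`RAG1`,
#'   `tub3`).
#' @param vertebrate Named logical vector per species.
#' @param d_te Element distance matrix.
#' @param d_hosts Optional named list of primary host-gene distance
#'   matrices; when supplied their groups join the confirmation ANOVA.
#' @param ratio_factor Ratio factor (default 1.2).
#' @param alpha Significance level (default 0.01).
#' @return The event list with `confirmed` and `partial` flags added.
#' @export
confirm_events <- function(events, secondary, vertebrate, d_te, d_hosts = NULL,
                           ratio_factor = 1.2, alpha = 0.01) {
  if (is.null(vertebrate)) stop("vertebrate flags are required for confirmation")
  for (k in seq_along(events)) {
    ev <- events[[k]]
    pr <- ev$pairs[, c("a", "b")]
    d_sec <- rep(NA_real_, nrow(pr))
    for (i in seq_len(nrow(pr))) {
      gene <- if (isTRUE(vertebrate[[pr$a[i]]]) && isTRUE(vertebrate[[pr$b[i]]]))
        "RAG1" else "tub3"
      m <- secondary[[gene]]
      if (!is.null(m) && all(c(pr$a[i], pr$b[i]) %in% rownames(m)))
        d_sec[i] <- m[pr$a[i], pr$b[i]]
    }
    dte <- d_te[cbind(pr$a, pr$b)]
    events[[k]]$partial <- anyNA(d_sec)
    # re-run the ratio filter under the secondary gene: pairs that fail (or
    # lack data) drop out, and the event is confirmed when the surviving
    # pairs still support it
    sec_pass <- !is.na(d_sec) & distance_ratio_filter(dte, list(d_sec), ratio_factor)
    an <- NULL
    if (any(sec_pass)) {
      keep <- which(sec_pass)
      groups <- list(secondary = d_sec[keep])
      if (!is.null(d_hosts)) {
        idx <- cbind(pr$a[keep], pr$b[keep])
        groups <- c(lapply(d_hosts, function(m) m[idx]), groups)
      }
      an <- anova_significance(dte[keep], groups)
    }
    events[[k]]$secondary_pairs <- sum(sec_pass)
    events[[k]]$confirmed <- !is.null(an) && isTRUE(an$testable) &&
      !is.na(an$p) && an$p < alpha && an$te_smallest
    events[[k]]$anova_secondary <- an
  }
  events
}

#' @export
print.ht_scan <- function(x, ...) {
  called <- vapply(x$events, function(e) isTRUE(e$called), logical(1))
  cat(sprintf("HT scan: %d candidate pair(s), %d candidate event(s), %d called\n",
              sum(x$candidates$pass), length(x$events), sum(called)))
  for (k in which(called)) {
    e <- x$events[[k]]
    conf <- if (!is.null(e$confirmed)) {
      if (e$confirmed) ", confirmed" else ", unconfirmed"
    } else ""
    cat(sprintf("  event %d: {%s}, p = %.3g%s\n", k,
                paste(e$members, collapse = ", "), e$anova$p, conf))
  }
  invisible(x)
}
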
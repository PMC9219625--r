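# End-to-end pipeline: simulate -> mine -> annotate -> census/consensus ->
# distances -> HT detection -> divergence landscapes, driven by a single
# config (R list or YAML file).  Every output is a plain-text table keyed in
# a checksum manifest, and the whole run is a pure function of
# (config, seed): re-running a config reproduces the manifest byte for byte.

#' Build a pipeline configuration
#'
#' Returns the default configuration, updated with any supplied fields, and
#' validates it.  The thresholds collect every constant of the analysis:
#' mining (top-k 10, 2 kb flanks, census > 1000 bp / > 40% coverage / > 80%
#' identity), annotation (TIR 8-40 bp, intact > 300 aa), HT filters
#' (identity > 0.70, ratio factor 1.2, alpha 0.01) and landscape cuts
#' (2% / 10%).
#'
#' @param ... Fields overriding the defaults (see the function body; nested
#'   lists such as `thresholds` are merged field-wise).
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    output_dir = "tehorizon-run",
    tree = "((spA:0.025,spC:0.025):0.225,spB:0.25);",
    genome_length = 50000L,
    gene_length = 4000L,
    te = list(element_length = 2500L, tir_len = 20L, te_rate = 1, kappa = 2),
    copies_per_species = 8L,
    copy_age = 0.01,
    truncation_prob = 0.25,
    ht = list(list(donor = "spA", recipient = "spB", time = 0.01)),
    thresholds = list(
      min_score = 100, top_k = 10L, flank = 2000L,
      census_min_len = 1000L, census_min_cov = 0.40, census_min_id = 0.80,
      consensus_min_copies = 6L,
      tir_min_len = 8L, tir_max_len = 40L, tir_end_window = 50L,
      intact_aa = 300L,
      identity = 0.70, ratio_factor = 1.2, alpha = 0.01,
      recent_cut = 2, old_cut = 10
    )
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) && !is.null(names(over[[nm]]))) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; fields override the [pipeline_config()] defaults.
#' @return A validated `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

validate_pipeline_config <- function(cfg) {
  th <- cfg$thresholds
  if (is.null(cfg$seed)) stop("config: seed is mandatory")
  if (th$identity <= 0 || th$identity > 1)
    stop("config: identity threshold must be in (0, 1]")
  if (th$ratio_factor < 1) stop("config: ratio_factor must be >= 1")
  if (th$alpha <= 0 || th$alpha >= 1) stop("config: alpha must be in (0, 1)")
  if (th$census_min_cov < 0 || th$census_min_cov > 1 ||
      th$census_min_id < 0 || th$census_min_id > 1)
    stop("config: census fractions must be in [0, 1]")
  if (th$tir_min_len > th$tir_max_len) stop("config: tir_min_len > tir_max_len")
  if (cfg$copy_age < 0) stop("config: copy_age must be >= 0")
  if (cfg$truncation_prob < 0 || cfg$truncation_prob > 1)
    stop("config: truncation_prob must be in [0, 1]")
  invisible(cfg)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), round(m, 10), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Project copies onto the reference column space: one gapped string per copy
# with exactly nchar(reference) columns (copy insertions dropped).
project_to_reference <- function(copies, reference) {
  vapply(copies, function(cp) {
    aln <- align_pair(cp, reference)
    a <- strsplit(aln$a, "")[[1L]]; r <- strsplit(aln$b, "")[[1L]]
    paste(a[r != "-"], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Run the full pipeline
#'
#' Executes simulate -> mine -> annotate -> census/consensus -> distances ->
#' HT detection -> landscapes for a configuration, writing all stage outputs
#' and a checksum manifest under `config$output_dir`.
#'
#' @param config A `"pipeline_config"`, a YAML path, or a list of overrides.
#' @return A run report (invisible): list with `config`, `outputs` (paths),
#'   `n_called_events`, `called_members`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  th <- config$thresholds
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  set.seed(config$seed)

  ## --- synth ------------------------------------------------------------
  tree <- ape::read.tree(text = config$tree)
  species <- tree$tip.label
  model <- substitution_model("K2P", kappa = config$te$kappa)
  element <- make_te_element(length = config$te$element_length,
                             tir_len = config$te$tir_len)
  spec <- te_history(as.character(element), te_rate = config$te$te_rate,
                     model = model, ht = config$ht)
  te <- apply_ht_scenario(tree, spec)
  hosts <- list(RPL3 = evolve_along_tree(random_dna(config$gene_length), tree, model),
                RPL4 = evolve_along_tree(random_dna(config$gene_length), tree, model))
  secondary <- list(RAG1 = evolve_along_tree(random_dna(config$gene_length), tree, model))

  genomes <- list(); truth <- list()
  for (sp in species) {
    sp_elem <- structure(te$te_seqs[[sp]],
                         tir_len = attr(element, "tir_len"),
                         orf_start = attr(element, "orf_start"),
                         orf_nt = attr(element, "orf_nt"))
    res <- plant_te_copies(random_dna(config$genome_length), sp_elem,
                           config$copies_per_species, ages = config$copy_age,
                           truncation_prob = config$truncation_prob,
                           model = model, contig = sp)
    genomes[[sp]] <- res$genome
    tr <- res$truth; tr$species <- sp
    truth[[sp]] <- tr[, c("species", setdiff(names(tr), "species"))]
  }
  outputs <- character(0)
  outputs <- c(outputs, write_fasta(unlist(genomes), out("genomes.fa")))
  for (g in names(hosts)) outputs <- c(outputs, write_fasta(hosts[[g]], out(sprintf("host_%s.fa", g))))
  outputs <- c(outputs, write_fasta(secondary$RAG1, out("host_RAG1.fa")))
  outputs <- c(outputs, write_tsv(do.call(rbind, truth), out("truth.tsv")))
  if (nrow(te$truth))
    outputs <- c(outputs, write_tsv(te$truth, out("truth_ht.tsv")))

  ## --- mining -----------------------------------------------------------
  orf0 <- attr(element, "orf_start")
  query <- translate_frame(substr(as.character(element), orf0 + 1L,
                                  orf0 + attr(element, "orf_nt") - 3L), 0L)
  hit_rows <- list(); regions <- list()
  for (sp in species) {
    hits <- translated_search(query, genomes[[sp]], min_score = th$min_score,
                              contig = sp)
    hits <- select_top_nonoverlapping(hits, k = th$top_k)
    if (!nrow(hits)) next
    hit_rows[[sp]] <- hits
    for (i in seq_len(nrow(hits))) {
      regions[[length(regions) + 1L]] <-
        c(list(species = sp, hit = hits[i, , drop = FALSE]),
          extract_flanked(genomes[[sp]], hits[i, ], flank = th$flank))
    }
  }
  hits_all <- do.call(rbind, hit_rows)
  outputs <- c(outputs, write_tsv(hits_all, out("hits.tsv")))

  ## --- annotate ---------------------------------------------------------
  ann_rows <- list()
  copies_by_sp <- setNames(vector("list", length(species)), species)
  classes_by_sp <- setNames(vector("list", length(species)), species)
  for (rg in regions) {
    ann <- annotate_region(rg$seq, end_window = th$flank + 500L,
                           min_len = th$tir_min_len, max_len = th$tir_max_len)
    sp <- rg$species
    copies_by_sp[[sp]] <- c(copies_by_sp[[sp]], ann$element_seq)
    classes_by_sp[[sp]] <- c(classes_by_sp[[sp]], ann$class)
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      species = sp, contig = rg$hit$contig,
      start = rg$region[["start"]] + if (rg$hit$strand == "+") ann$element[1L] else
        (nchar(rg$seq) - ann$element[2L]),
      end = rg$region[["start"]] + if (rg$hit$strand == "+") ann$element[2L] else
        (nchar(rg$seq) - ann$element[1L]),
      strand = rg$hit$strand, class = ann$class,
      tir_len = if (is.null(ann$tir)) NA_integer_ else ann$tir$length,
      tir_mismatches = if (is.null(ann$tir)) NA_integer_ else ann$tir$mismatches,
      tsd = ann$tsd,
      orf_aa = if (is.null(ann$orf)) NA_integer_ else ann$orf$protein_aa,
      stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, ann_rows)
  outputs <- c(outputs, write_tsv(annotation, out("annotation.tsv")))

  ## --- census + consensus ------------------------------------------------
  census_rows <- list(); consensus <- character(0)
  for (sp in species) {
    cp <- copies_by_sp[[sp]]
    if (is.null(cp) || !length(cp)) next
    cen <- count_copies(cp, as.character(element),
                        min_len = th$census_min_len, min_cov = th$census_min_cov,
                        min_id = th$census_min_id)
    cls <- classes_by_sp[[sp]]
    census_rows[[sp]] <- data.frame(
      species = sp, copies = length(cp), counted = cen$count,
      full = sum(cls %in% c("full", "intact")), intact = sum(cls == "intact"),
      stringsAsFactors = FALSE)
    proj <- project_to_reference(cp, as.character(element))
    cons <- build_consensus(proj, min_copies = th$consensus_min_copies, classes = cls)
    consensus[[sp]] <- gsub("-", "", cons$seq, fixed = TRUE)
  }
  outputs <- c(outputs, write_tsv(do.call(rbind, census_rows), out("census.tsv")))
  outputs <- c(outputs, write_fasta(consensus, out("consensus.fa")))

  ## --- distances ---------------------------------------------------------
  id_te <- identity_matrix(consensus, aligned = FALSE)
  d_te <- mcl_distance_matrix(consensus, aligned = FALSE)
  d_hosts <- lapply(hosts, mcl_distance_matrix)
  d_sec <- lapply(secondary, mcl_distance_matrix)
  outputs <- c(outputs, write_matrix_tsv(id_te, out("identity_te.tsv")))
  outputs <- c(outputs, write_matrix_tsv(d_te, out("dist_te.tsv")))
  for (g in names(d_hosts))
    outputs <- c(outputs, write_matrix_tsv(d_hosts[[g]], out(sprintf("dist_%s.tsv", g))))

  ## --- HT detection ------------------------------------------------------
  scan <- detect_ht(id_te, d_te, d_hosts,
                    identity_threshold = th$identity,
                    ratio_factor = th$ratio_factor, alpha = th$alpha,
                    secondary = d_sec,
                    vertebrate = setNames(rep(TRUE, length(species)), species))
  cand <- scan$candidates
  cand[vapply(cand, is.numeric, logical(1))] <-
    lapply(cand[vapply(cand, is.numeric, logical(1))], round, 10)
  outputs <- c(outputs, write_tsv(cand, out("ht_candidates.tsv")))
  ev_rows <- lapply(seq_along(scan$events), function(k) {
    e <- scan$events[[k]]
    data.frame(event = k, members = paste(e$members, collapse = ","),
               n_pairs = nrow(e$pairs),
               p = if (is.na(e$anova$p)) NA_real_ else signif(e$anova$p, 6),
               called = e$called,
               confirmed = isTRUE(e$confirmed), stringsAsFactors = FALSE)
  })
  ev_df <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(event = integer(), members = character(), n_pairs = integer(),
               p = numeric(), called = logical(), confirmed = logical())
  outputs <- c(outputs, write_tsv(ev_df, out("ht_events.tsv")))

  ## --- landscapes --------------------------------------------------------
  activity <- list()
  for (sp in species) {
    cp <- copies_by_sp[[sp]]
    if (is.null(cp) || !length(cp)) next
    prof <- divergence_profile(cp, consensus[[sp]], species = sp)
    hist_df <- data.frame(bin_lower_pct = as.numeric(names(prof$histogram)),
                          coverage_kb = round(unname(prof$histogram), 6))
    outputs <- c(outputs, write_tsv(hist_df, out(sprintf("landscape_%s.tsv", sp))))
    act <- activity_assessment(prof, recent_cut = th$recent_cut, old_cut = th$old_cut)
    activity[[sp]] <- lapply(act, function(x) if (is.numeric(x)) round(x, 8) else x)
  }
  jsonlite::write_json(activity, out("activity.json"), auto_unbox = TRUE, pretty = TRUE)
  outputs <- c(outputs, out("activity.json"))

  ## --- manifest ----------------------------------------------------------
  rel <- sort(unique(basename(outputs)))
  sums <- tools::md5sum(file.path(config$output_dir, rel))
  manifest <- data.frame(file = rel, md5 = unname(sums), stringsAsFactors = FALSE)
  write_tsv(manifest, out("manifest.tsv"))

  called <- Filter(function(e) isTRUE(e$called), scan$events)
  invisible(list(config = config, outputs = c(outputs, out("manifest.tsv")),
                 n_called_events = length(called),
                 called_members = lapply(called, `[[`, "members"),
                 manifest = manifest))
}
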
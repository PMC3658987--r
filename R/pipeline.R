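# End-to-end orchestration: simulate/load inputs -> RBM orthologs ->
# triangulation -> CDS/UTR delimitation -> codon alignments -> quality
# filters -> substitution rates -> divergence dating -> GO enrichment ->
# SSR/marker mining -> single-copy candidates, with per-stage record counts
# and file digests collected into a manifest.

#' Run the full comparative pipeline
#'
#' Inputs are either file paths (`species_a`, `species_b` FASTA nucleotide;
#' `outgroup` FASTA amino-acid; optional `go_map` two-column text) or a
#' simulation request (`sim = list(n_genes = ..., ...)` passed to
#' [simulate_species_pair()]). All reports are written under `out_dir`;
#' reruns with the same inputs, config and seed are byte-identical.
#'
#' @param config an [orthodiv_config()]
#' @param out_dir output directory (created)
#' @param species_a,species_b,outgroup,go_map,single_copy input file paths
#' @param gene_models optional data.frame for [mine_single_copy()]
#' @param sim optional list of [simulate_species_pair()] arguments; when
#'   given, inputs are simulated (seed defaults to `config$seed`)
#' @return a `pipeline_manifest`
#' @export
run_pipeline <- function(config = orthodiv_config(), out_dir,
                         species_a = NULL, species_b = NULL, outgroup = NULL,
                         go_map = NULL, single_copy = NULL,
                         gene_models = NULL, sim = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages <- list()
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  note <- function(name, ...) {
    stages[[name]] <<- list(counts = list(...))
  }

  # ---- inputs ------------------------------------------------------------
  if (!is.null(sim)) {
    simres <- stage("simulate", {
      sim$seed <- sim$seed %||% config$seed
      do.call(simulate_species_pair, sim)
    })
    set_a <- simres$contigs_a; set_b <- simres$contigs_b
    proteins <- simres$outgroup
    gomap <- simres$go_map
    note("simulate", genes = nrow(simres$truth),
         contigs_a = length(set_a), contigs_b = length(set_b))
  } else {
    if (is.null(species_a) || is.null(species_b)) {
      stop("stage load failed: species contig FASTA paths are required",
           call. = FALSE)
    }
    set_a <- stage("load", read_fasta(species_a, "nucleotide"))
    set_b <- stage("load", read_fasta(species_b, "nucleotide"))
    gomap <- if (!is.null(go_map)) read_go_map(go_map) else NULL
    proteins <- NULL
    if (!is.null(outgroup)) proteins <- read_fasta(outgroup, "amino-acid")
    note("load", contigs_a = length(set_a), contigs_b = length(set_b))
  }
  write_config(config, file.path(out_dir, "config.yaml"))
  files <- c(files, file.path(out_dir, "config.yaml"))

  # ---- orthologs ---------------------------------------------------------
  rbm <- stage("orthologs", reciprocal_best_matches(set_a, set_b, config))
  note("orthologs", rbm_pairs = nrow(rbm))

  tri <- stage("triangulate", {
    if (is.null(proteins)) stop("outgroup proteome is required")
    triangulate(rbm, set_a, set_b, proteins, config)
  })
  pairs <- tri$pairs
  f <- file.path(out_dir, "ortholog_pairs.tsv")
  write_table(pairs[, c("contig_a", "contig_b", "anchor_protein",
                        "score", "identity")], f)
  files <- c(files, f)
  note("triangulate", pairs = nrow(pairs))

  # ---- CDS/UTR delimitation and codon alignment --------------------------
  coding <- stage("extract-cds", {
    hits <- tri$anchor_hits
    annots <- list(); alns <- list()
    for (r in seq_len(nrow(pairs))) {
      ha <- hits[hits$query_id == pairs$contig_a[r], , drop = FALSE][1, ]
      hb <- hits[hits$query_id == pairs$contig_b[r], , drop = FALSE][1, ]
      prot <- proteins[[pairs$anchor_protein[r]]]
      ca <- set_a[[pairs$contig_a[r]]]; cb <- set_b[[pairs$contig_b[r]]]
      an_a <- delimit_cds_utr(ca, prot, ha)
      an_b <- delimit_cds_utr(cb, prot, hb)
      if (isTRUE(an_a$rejected) || isTRUE(an_b$rejected)) next
      annots[[length(annots) + 1L]] <- an_a
      annots[[length(annots) + 1L]] <- an_b
      alns[[length(alns) + 1L]] <- build_codon_alignment(
        an_a, an_b, ca, cb, pair_id = pairs$pair_id[r],
        gap_open = config$prot_gap_open, gap_extend = config$prot_gap_extend)
    }
    list(annots = annots, alns = alns)
  })
  f <- file.path(out_dir, "annotations.gff3")
  write_gff3(coding$annots, f)
  files <- c(files, f)
  note("extract-cds", annotated_pairs = length(coding$alns))

  # ---- filters -----------------------------------------------------------
  filt <- stage("filter", filter_alignments(
    coding$alns, rates_fn = function(al) yn_rates(al)$Ks,
    min_len = config$min_cds_aln_len, ks_max = config$ks_max))
  f <- file.path(out_dir, "discarded_alignments.tsv")
  write_table(filt$discarded, f)
  files <- c(files, f)
  note("filter", kept = length(filt$kept), discarded = nrow(filt$discarded))

  # ---- rates, divergence -------------------------------------------------
  rates <- stage("rates", estimate_rates(filt$kept, method = "YN",
                                         omega_threshold = config$omega_threshold))
  f <- file.path(out_dir, "rates.tsv")
  write_table(rates, f)
  files <- c(files, f)
  utr_div <- stage("rates", utr_divergence(filt$kept))
  note("rates", pairs = nrow(rates),
       identical = sum(rates$selection_class == "identical"),
       single_type = sum(rates$selection_class == "single-type"),
       candidate = sum(rates$selection_class == "candidate"),
       positive = sum(rates$selection_class == "positive"))

  dating <- stage("date", {
    ks <- ks_summary(rates$Ks, bin_width = config$ks_bin_width)
    list(ks = ks, t = divergence_time(ks$mean_ks, ks$sd_ks, config$subst_rate))
  })
  f <- file.path(out_dir, "divergence.tsv")
  write_table(data.frame(mean_ks = dating$ks$mean_ks, sd_ks = dating$ks$sd_ks,
                         n_pairs = dating$ks$n, r = config$subst_rate,
                         T_mya = dating$t$T_mya, T_sd_mya = dating$t$T_sd_mya,
                         mean_k2p_cds = utr_div$cds, mean_k2p_utr5 = utr_div$utr5,
                         mean_k2p_utr3 = utr_div$utr3), f)
  files <- c(files, f)
  note("date", T_mya = dating$t$T_mya)

  # ---- enrichment --------------------------------------------------------
  enr <- NULL
  if (!is.null(gomap) && length(gomap)) {
    enr <- stage("enrich", {
      part <- partition_by_omega(rates, config$omega_threshold)
      enrichment_scan(gomap, part$test_ids, part$reference_ids,
                      min_hits = config$go_min_hits, alpha = config$go_alpha)
    })
    f <- file.path(out_dir, "enrichment.tsv")
    write_table(enr, f)
    files <- c(files, f)
    note("enrich", significant_terms = nrow(enr))
  }

  # ---- SSRs and markers --------------------------------------------------
  loci_a <- stage("ssr", detect_ssrs_set(set_a, config$ssr_min_repeats))
  loci_b <- stage("ssr", detect_ssrs_set(set_b, config$ssr_min_repeats))
  loci_a$species <- rep("a", nrow(loci_a))
  loci_b$species <- rep("b", nrow(loci_b))
  f <- file.path(out_dir, "ssr_loci.tsv")
  write_table(rbind(loci_a, loci_b), f)
  files <- c(files, f)
  cand <- stage("markers", match_orthologous_ssrs(pairs, loci_a, loci_b,
                                                  set_a, set_b, config))
  mk <- stage("markers", filter_marker_candidates(
    cand, tract_min = config$ssr_tract_min, flank_min = config$flank_min,
    flank_identity_min = config$flank_identity_min))
  f <- file.path(out_dir, "marker_candidates.tsv")
  write_table(cand, f)
  files <- c(files, f)
  f <- file.path(out_dir, "markers_kept.tsv")
  write_table(mk$kept, f)
  files <- c(files, f)
  note("markers", ssr_a = nrow(loci_a), ssr_b = nrow(loci_b),
       candidates = nrow(cand), kept = nrow(mk$kept))

  # ---- single-copy mining ------------------------------------------------
  sc_prot <- NULL
  if (!is.null(single_copy)) sc_prot <- read_fasta(single_copy, "amino-acid")
  else if (!is.null(proteins)) sc_prot <- proteins
  if (!is.null(sc_prot)) {
    sc <- stage("singlecopy", mine_single_copy(
      pairs, set_a, set_b, sc_prot, gene_models,
      span_min = config$sc_span_min, identity_min = config$sc_identity_min,
      intron_min = config$sc_intron_min, config = config))
    f <- file.path(out_dir, "single_copy_candidates.tsv")
    write_table(sc, f)
    files <- c(files, f)
    note("singlecopy", candidates = nrow(sc))
  }

  manifest <- structure(list(
    config = unclass(config),
    stages = stages,
    files = as.list(tools::md5sum(files)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    class = "pipeline_manifest")
  yaml::write_yaml(list(config = manifest$config,
                        stages = manifest$stages,
                        files = manifest$files),
                   file.path(out_dir, "manifest.yaml"))
  manifest
}

# mean K2P divergence of CDS and UTR partitions over kept alignments
utr_divergence <- function(alignments) {
  get <- function(a, b) {
    vapply(alignments, function(al) {
      if (is.null(al[[a]]) || is.null(al[[b]])) return(NA_real_)
      d <- tryCatch(k2p_distance(al[[a]], al[[b]]), error = function(e) NULL)
      if (is.null(d) || !d$defined) NA_real_ else d$d
    }, 0)
  }
  cds <- get("aligned_cds_a", "aligned_cds_b")
  u5 <- get("aligned_utr5_a", "aligned_utr5_b")
  u3 <- get("aligned_utr3_a", "aligned_utr3_b")
  list(cds = mean(cds, na.rm = TRUE),
       utr5 = if (all(is.na(u5))) NA_real_ else mean(u5, na.rm = TRUE),
       utr3 = if (all(is.na(u3))) NA_real_ else mean(u3, na.rm = TRUE))
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("orthodiv pipeline manifest\n")
  for (nm in names(x$stages)) {
    cnt <- x$stages[[nm]]$counts
    cat(sprintf("  %-12s %s\n", nm,
                paste(names(cnt), unlist(cnt), sep = "=", collapse = "  ")))
  }
  invisible(x)
}
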
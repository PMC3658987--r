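# Synthetic species-pair generator. An ancestral gene set (CDS + UTRs at a
# target GC) is evolved along two lineages with a codon-aware Bernoulli
# substitution process (transition bias kappa, nonsynonymous changes
# accepted with probability omega, stop-creating changes rejected; UTRs
# neutral at a configurable multiple of the synonymous rate), fragmented
# into contigs with a transcriptome-like length distribution, optionally
# confounded with paralogs and orphans, decorated with planted SSRs and GO
# annotations, and accompanied by a truth table so every downstream stage
# can be validated closed-loop.

#' Generate an ancestral gene set
#'
#' CDSs start with ATG, end with a stop codon, contain no internal stop,
#' and draw codons from a base composition tuned to `gc_target`; UTR lengths
#' are uniform in their ranges with the same composition. Deterministic for
#' a fixed seed.
#'
#' @param n_genes number of genes (>= 1)
#' @param length_range CDS length range in nt (rounded to codons); lower
#'   bound must be >= 150 (shorter genes would be filtered downstream)
#' @param gc_target target GC fraction (realised set-wide GC within ~0.02)
#' @param utr5_range,utr3_range UTR length ranges (nt)
#' @param seed integer seed
#' @return list of genes: id, cds, utr5, utr3
#' @export
generate_ancestor_set <- function(n_genes, length_range = c(300, 2400),
                                  gc_target = 0.413,
                                  utr5_range = c(30, 150),
                                  utr3_range = c(50, 250), seed = 1) {
  stopifnot(n_genes >= 1, gc_target > 0, gc_target < 1)
  if (length_range[1] < 150) {
    stop("length-range lower bound must be >= 150 (downstream filter)")
  }
  set.seed(seed)
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  gc <- genetic_code()
  sense_codons <- names(gc)[gc != "*"]
  stop_codons <- names(gc)[gc == "*"]
  codon_p <- function(cods) {
    w <- vapply(cods, function(cd) prod(p[chars(cd)]), 0)
    w / sum(w)
  }
  p_sense <- codon_p(sense_codons)
  p_stop <- codon_p(stop_codons)
  rand_nt <- function(n) {
    if (n == 0L) return("")
    paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
  }
  lapply(seq_len(n_genes), function(i) {
    L <- sample(seq(length_range[1], length_range[2]), 1)
    m <- max(3L, L %/% 3L)       # codons incl. start and stop
    body <- sample(sense_codons, m - 2L, replace = TRUE, prob = p_sense)
    cds <- paste0("ATG", paste(body, collapse = ""),
                  sample(stop_codons, 1, prob = p_stop))
    list(id = sprintf("g%05d", i), cds = cds,
         utr5 = rand_nt(sample(seq(utr5_range[1], utr5_range[2]), 1)),
         utr3 = rand_nt(sample(seq(utr3_range[1], utr3_range[2]), 1)))
  })
}

# substitute one base under transition bias kappa
mutate_base <- function(b, kappa) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")[[b]]
  if (runif(1) < kappa / (kappa + 2)) ts
  else sample(setdiff(BASES, c(b, ts)), 1)
}

# neutral per-site substitution (UTRs, outgroup-style divergence)
mutate_neutral <- function(seq, p_sub, kappa) {
  if (nchar(seq) == 0L || p_sub <= 0) return(seq)
  s <- chars(seq)
  hit <- which(runif(length(s)) < p_sub & s %in% BASES)
  for (i in hit) s[i] <- mutate_base(s[i], kappa)
  paste(s, collapse = "")
}

# codon-aware selection-filtered substitution: per-site attempts at prob mu,
# stop-creating changes rejected, nonsynonymous accepted with prob omega.
# First and last codons (start/stop) are held fixed.
mutate_cds <- function(cds, mu, omega, kappa) {
  gc <- genetic_code()
  s <- chars(cds)
  n <- length(s)
  sites <- which(runif(n) < mu)
  sites <- sites[sites > 3L & sites <= n - 3L]
  for (i in sites) {
    ci <- (i - 1L) %/% 3L
    cod_idx <- (3L * ci + 1L):(3L * ci + 3L)
    old <- paste(s[cod_idx], collapse = "")
    new_s <- s
    new_s[i] <- mutate_base(s[i], kappa)
    new <- paste(new_s[cod_idx], collapse = "")
    if (gc[[new]] == "*") next
    if (gc[[new]] != gc[[old]] && runif(1) >= omega) next
    s <- new_s
  }
  paste(s, collapse = "")
}

#' Default omega mixture
#'
#' 87% of genes draw omega from a Gamma distribution centred on 0.25
#' (purifying selection of varying strength), 13% sit at omega = 0.8
#' (relaxed/positive candidates), giving a mean omega of ~0.32 and ~13% of
#' genes above 0.5.
#' @param shape Gamma shape of the purifying component
#' @return list of components: weight, omega, optional shape
#' @export
default_omega_mixture <- function(shape = 6) {
  list(list(weight = 0.87, omega = 0.25, shape = shape),
       list(weight = 0.13, omega = 0.8))
}

#' Evolve an ancestral gene set into two diverged species
#'
#' Each gene draws a true pairwise synonymous divergence Ks from a Gamma
#' with mean `ks_mean` and sd `ks_sd`, and a true omega from
#' `omega_mixture`; each lineage then accumulates substitutions with
#' per-site attempt probability Ks/2, transition bias `kappa`, rejection of
#' stop-creating changes, and acceptance of nonsynonymous changes with
#' probability omega. UTRs evolve neutrally at `utr_rate_multiplier` times
#' the synonymous per-site rate.
#'
#' @param ancestors from [generate_ancestor_set()]
#' @param ks_mean,ks_sd mean/sd of true pairwise Ks across genes
#' @param omega_mixture list of components `list(weight, omega[, shape])`;
#'   weights must sum to 1, omegas must be >= 0; with `shape` present the
#'   gene's omega is Gamma(shape, mean = omega)
#' @param utr_rate_multiplier UTR per-site substitution rate relative to the
#'   synonymous per-site rate. The default 0.8 makes UTRs diverge at roughly
#'   1.6-1.8 times the CDS-average rate (UTR K2P ~ 0.019 vs CDS ~ 0.012 at
#'   the default mixture), the pattern typical of plant species pairs:
#'   UTRs are under relaxed but not absent constraint, so they evolve
#'   faster than the CDS average yet slower than synonymous sites
#' @param kappa transition/transversion rate ratio
#' @param seed integer seed
#' @return list: `genes_a`, `genes_b` (lists of id/cds/utr5/utr3) and
#'   `truth` (data.frame gene_id, omega_true, ks_true, component)
#' @export
evolve_species_pair <- function(ancestors, ks_mean = 0.027, ks_sd = 0.017,
                                omega_mixture = default_omega_mixture(),
                                utr_rate_multiplier = 0.8, kappa = 2,
                                seed = 1) {
  stopifnot(ks_mean > 0)
  w <- vapply(omega_mixture, function(cmp) cmp$weight, 0)
  if (abs(sum(w) - 1) > 1e-8) stop("omega mixture weights must sum to 1")
  if (any(vapply(omega_mixture, function(cmp) cmp$omega, 0) < 0)) {
    stop("omega must be >= 0")
  }
  set.seed(seed)
  n <- length(ancestors)
  comp <- sample(seq_along(omega_mixture), n, replace = TRUE, prob = w)
  omega_true <- vapply(seq_len(n), function(i) {
    cmp <- omega_mixture[[comp[i]]]
    if (!is.null(cmp$shape) && cmp$omega > 0) {
      rgamma(1, shape = cmp$shape, rate = cmp$shape / cmp$omega)
    } else cmp$omega
  }, 0)
  ks_true <- if (ks_sd > 0) {
    sh <- (ks_mean / ks_sd)^2
    rgamma(n, shape = sh, rate = sh / ks_mean)
  } else rep(ks_mean, n)
  evolve_one <- function(g, mu, omega) {
    list(id = g$id,
         cds = mutate_cds(g$cds, mu, omega, kappa),
         utr5 = mutate_neutral(g$utr5, min(0.75, utr_rate_multiplier * mu), kappa),
         utr3 = mutate_neutral(g$utr3, min(0.75, utr_rate_multiplier * mu), kappa))
  }
  genes_a <- vector("list", n); genes_b <- vector("list", n)
  for (i in seq_len(n)) {
    mu <- ks_true[i] / 2  # per-lineage per-site attempt probability
    genes_a[[i]] <- evolve_one(ancestors[[i]], mu, omega_true[i])
    genes_b[[i]] <- evolve_one(ancestors[[i]], mu, omega_true[i])
  }
  truth <- data.frame(gene_id = vapply(ancestors, `[[`, "", "id"),
                      omega_true = omega_true, ks_true = ks_true,
                      component = comp, stringsAsFactors = FALSE)
  list(genes_a = genes_a, genes_b = genes_b, truth = truth)
}

#' Outgroup proteome from the ancestor set
#'
#' The translated ancestral CDSs with additional amino-acid divergence
#' (default 15% of residues substituted uniformly) stand in for a distant
#' reference proteome: triangulation only needs a common best-hit anchor.
#'
#' @param ancestors from [generate_ancestor_set()]
#' @param aa_divergence fraction of residues substituted
#' @param seed integer seed
#' @return named character vector of proteins (`vvNNNNN`), one per gene
#' @export
make_outgroup_proteome <- function(ancestors, aa_divergence = 0.15, seed = 1) {
  set.seed(seed)
  aas <- chars("ACDEFGHIKLMNPQRSTVWY")
  out <- vapply(ancestors, function(g) {
    p <- chars(sub("\\*$", "", translate_cds(g$cds)))
    hit <- which(runif(length(p)) < aa_divergence)
    for (i in hit) p[i] <- sample(setdiff(aas, p[i]), 1)
    paste(p, collapse = "")
  }, "")
  setNames(out, sub("^g", "vv", vapply(ancestors, `[[`, "", "id")))
}

#' Fragment evolved gene sets into contig sets
#'
#' Contigs are windows of each gene's transcript (utr5+cds+utr3): with
#' probability `1 - full_prob` a window length is drawn from a two-block
#' distribution placing `short_frac` of the mass on `short_range` (the
#' 200-500 bp excess typical of short-read assemblies) and the rest on
#' `long_range`, capped by the transcript. Contigs are reverse-complemented
#' with probability `strand_flip_prob`; with `paralog_prob` a gene gains an
#' extra, strongly diverged copy in one species (pairwise Ks forced beyond
#' the paralog filter); with `orphan_prob` a gene is emitted in only one
#' species. Set `truncate = FALSE` for full-transcript contigs.
#'
#' @param evolved from [evolve_species_pair()]
#' @param short_frac,short_range,long_range window length distribution
#' @param strand_flip_prob,paralog_prob,orphan_prob confounder probabilities
#' @param paralog_extra_div extra per-site divergence of paralog copies
#' @param truncate draw windows (TRUE) or emit full transcripts (FALSE)
#' @param seed integer seed
#' @return list: `contigs_a`, `contigs_b` (named character vectors),
#'   `truth` (per-gene table with contig ids, window offsets, strands,
#'   orphan flags), `paralogs` (extra contig table)
#' @export
fragment_to_contigs <- function(evolved, short_frac = 0.56,
                                short_range = c(200, 500),
                                long_range = c(500, 1200),
                                strand_flip_prob = 0.25, paralog_prob = 0.05,
                                orphan_prob = 0.05, paralog_extra_div = 0.1,
                                truncate = TRUE, seed = 1) {
  stopifnot(short_frac >= 0, short_frac <= 1,
            strand_flip_prob >= 0, strand_flip_prob <= 1,
            paralog_prob >= 0, paralog_prob <= 1,
            orphan_prob >= 0, orphan_prob <= 1)
  set.seed(seed)
  n <- length(evolved$genes_a)
  truth <- evolved$truth
  truth$contig_a <- NA_character_; truth$contig_b <- NA_character_
  truth$off_a <- NA_integer_; truth$off_b <- NA_integer_
  truth$len_a <- NA_integer_; truth$len_b <- NA_integer_
  truth$strand_a <- NA_character_; truth$strand_b <- NA_character_
  truth$orphan <- "none"
  contigs_a <- character(0); contigs_b <- character(0)
  paralogs <- list()
  ka <- 0L; kb <- 0L
  window <- function(tlen) {
    if (!truncate) return(c(0L, tlen))
    if (runif(1) < short_frac) {
      w <- sample(seq(short_range[1], short_range[2]), 1)
    } else {
      w <- sample(seq(long_range[1], long_range[2]), 1)
    }
    w <- min(w, tlen)
    off <- sample(0:(tlen - w), 1)
    c(off, off + w)
  }
  for (i in seq_len(n)) {
    orphan <- if (runif(1) < orphan_prob) sample(c("a", "b"), 1) else "none"
    truth$orphan[i] <- orphan
    for (sp in c("a", "b")) {
      if (orphan != "none" && orphan != sp) next
      g <- if (sp == "a") evolved$genes_a[[i]] else evolved$genes_b[[i]]
      tx <- paste0(g$utr5, g$cds, g$utr3)
      wd <- window(nchar(tx))
      seq <- substr(tx, wd[1] + 1L, wd[2])
      strand <- if (runif(1) < strand_flip_prob) "-" else "+"
      if (strand == "-") seq <- revcomp(seq)
      if (sp == "a") {
        ka <- ka + 1L; id <- sprintf("pa%05d", ka)
        contigs_a[id] <- seq
        truth$contig_a[i] <- id; truth$off_a[i] <- wd[1]
        truth$len_a[i] <- wd[2] - wd[1]; truth$strand_a[i] <- strand
      } else {
        kb <- kb + 1L; id <- sprintf("pb%05d", kb)
        contigs_b[id] <- seq
        truth$contig_b[i] <- id; truth$off_b[i] <- wd[1]
        truth$len_b[i] <- wd[2] - wd[1]; truth$strand_b[i] <- strand
      }
    }
    if (runif(1) < paralog_prob) {
      sp <- sample(c("a", "b"), 1)
      g <- if (sp == "a") evolved$genes_a[[i]] else evolved$genes_b[[i]]
      tx <- mutate_neutral(paste0(g$utr5, g$cds, g$utr3), paralog_extra_div, 2)
      wd <- window(nchar(tx))
      seq <- substr(tx, wd[1] + 1L, wd[2])
      if (runif(1) < strand_flip_prob) seq <- revcomp(seq)
      if (sp == "a") {
        ka <- ka + 1L; id <- sprintf("pa%05d", ka); contigs_a[id] <- seq
      } else {
        kb <- kb + 1L; id <- sprintf("pb%05d", kb); contigs_b[id] <- seq
      }
      paralogs[[length(paralogs) + 1L]] <- data.frame(
        contig_id = id, species = sp, source_gene = truth$gene_id[i],
        stringsAsFactors = FALSE)
    }
  }
  list(contigs_a = contigs_a, contigs_b = contigs_b, truth = truth,
       paralogs = if (length(paralogs)) do.call(rbind, paralogs)
                  else data.frame(contig_id = character(0), species = character(0),
                                  source_gene = character(0), stringsAsFactors = FALSE))
}

#' Default SSR motif frequencies
#'
#' Dominated by AG, AT and AC dinucleotides followed by AAG trinucleotides,
#' the composition typical of plant EST microsatellites (~82% dinucleotide,
#' ~14% trinucleotide, the remainder tetra- to hexanucleotide).
#' @return named numeric vector (motif -> probability, sums to 1)
#' @export
default_ssr_motifs <- function() {
  c(AG = 0.38, AT = 0.25, AC = 0.19, AAG = 0.07, AAT = 0.03, AGG = 0.02,
    ATC = 0.02, AAAT = 0.015, AAAG = 0.01, AGAT = 0.005, AAAAT = 0.004,
    AACTC = 0.002, AAGGAG = 0.002, AACGTC = 0.002)
}

#' Plant SSR tracts into orthologous contig pairs
#'
#' For a fraction of ortholog pairs a motif is drawn from
#' `motif_freq`, a repeat count from `count_range`, and the tract (with
#' one guard base on each side so the planted repeat cannot extend into its
#' flanks) is inserted at a homologous 3'UTR position of both contigs; with
#' probability `per_species_mutation` the second species gains 1-2 extra
#' units (length polymorphism). Flanks are unmodified. Insertions land only
#' where both contig windows cover the transcript's 3'UTR, so planting
#' never disrupts a coding region.
#'
#' @param frag from [fragment_to_contigs()]
#' @param evolved the [evolve_species_pair()] output the fragments came from
#' @param motif_freq named probability vector of motifs (2-6 nt, no N)
#' @param pair_fraction fraction of eligible pairs receiving an SSR
#' @param count_range repeat-count range (minimum >= 5 to be detectable)
#' @param per_species_mutation probability of a cross-species length change
#' @param seed integer seed
#' @return `frag` with modified contigs plus `ssr_truth` (data.frame:
#'   gene_id, contig_a, contig_b, motif, motif_class, count_a, count_b,
#'   start_a, start_b in stored-contig coordinates)
#' @export
plant_ssrs <- function(frag, evolved, motif_freq = default_ssr_motifs(),
                       pair_fraction = 0.16, count_range = 5:10,
                       per_species_mutation = 0.3, seed = 1) {
  if (length(motif_freq)) {
    ml <- nchar(names(motif_freq))
    if (any(ml < 2 | ml > 6)) stop("motifs must be 2-6 nt")
    if (any(grepl("N", names(motif_freq)))) stop("motif contains N")
  }
  set.seed(seed)
  truth <- frag$truth
  ssr_rows <- list()
  if (length(motif_freq) == 0L) {
    frag$ssr_truth <- data.frame(gene_id = character(0), contig_a = character(0),
      contig_b = character(0), motif = character(0), motif_class = character(0),
      count_a = integer(0), count_b = integer(0), start_a = integer(0),
      start_b = integer(0), stringsAsFactors = FALSE)
    return(frag)
  }
  gene_ids <- vapply(evolved$genes_a, `[[`, "", "id")
  for (i in seq_len(nrow(truth))) {
    if (is.na(truth$contig_a[i]) || is.na(truth$contig_b[i])) next
    if (runif(1) >= pair_fraction) next
    gi <- match(truth$gene_id[i], gene_ids)
    ga <- evolved$genes_a[[gi]]; gb <- evolved$genes_b[[gi]]
    # homologous UTR span covered by both windows (transcript coordinates;
    # the two transcripts have equal part lengths since evolution is
    # substitution-only); planting is restricted to UTRs so the coding
    # frame is never disrupted
    u3_start <- nchar(ga$utr5) + nchar(ga$cds)
    win_lo <- max(truth$off_a[i], truth$off_b[i]) + 5L
    win_hi <- min(truth$off_a[i] + truth$len_a[i],
                  truth$off_b[i] + truth$len_b[i]) - 5L
    spans <- list(c(win_lo, min(nchar(ga$utr5), win_hi)),
                  c(max(u3_start, win_lo), min(u3_start + nchar(ga$utr3), win_hi)))
    pos_pool <- unlist(lapply(spans, function(sp)
      if (sp[2] > sp[1]) sp[1]:sp[2] else integer(0)))
    if (length(pos_pool) == 0L) next
    t_pos <- if (length(pos_pool) == 1L) pos_pool else sample(pos_pool, 1)
    motif <- sample(names(motif_freq), 1, prob = motif_freq)
    k_a <- sample(count_range, 1)
    k_b <- if (runif(1) < per_species_mutation) k_a + sample(1:2, 1) else k_a
    m <- nchar(motif)
    g_left <- setdiff(BASES, substr(motif, m, m))[1]
    g_right <- setdiff(BASES, substr(motif, 1, 1))[1]
    insert_one <- function(contig, off, strand, k) {
      ins <- paste0(g_left, paste(rep(motif, k), collapse = ""), g_right)
      p <- t_pos - off  # 0-based: insert before stored position p (forward)
      L <- nchar(contig)
      if (strand == "-") {
        ins <- revcomp(ins)
        p <- L - p
        tract_start <- p + 1L
      } else {
        tract_start <- p + 1L
      }
      list(seq = paste0(substr(contig, 1, p), ins, substr(contig, p + 1L, L)),
           start = tract_start)
    }
    ca <- truth$contig_a[i]; cb <- truth$contig_b[i]
    ra <- insert_one(frag$contigs_a[[ca]], truth$off_a[i], truth$strand_a[i], k_a)
    rb <- insert_one(frag$contigs_b[[cb]], truth$off_b[i], truth$strand_b[i], k_b)
    frag$contigs_a[[ca]] <- ra$seq
    frag$contigs_b[[cb]] <- rb$seq
    stored_motif_a <- if (truth$strand_a[i] == "-") revcomp(motif) else motif
    stored_motif_b <- if (truth$strand_b[i] == "-") revcomp(motif) else motif
    ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
      gene_id = truth$gene_id[i], contig_a = ca, contig_b = cb,
      motif = motif, motif_class = motif_class(motif),
      count_a = k_a, count_b = k_b,
      start_a = ra$start, start_b = rb$start,
      motif_stored_a = stored_motif_a, motif_stored_b = stored_motif_b,
      stringsAsFactors = FALSE)
  }
  frag$ssr_truth <- if (length(ssr_rows)) do.call(rbind, ssr_rows)
    else data.frame(gene_id = character(0), contig_a = character(0),
      contig_b = character(0), motif = character(0), motif_class = character(0),
      count_a = integer(0), count_b = integer(0), start_a = integer(0),
      start_b = integer(0), motif_stored_a = character(0),
      motif_stored_b = character(0), stringsAsFactors = FALSE)
  frag
}

#' Emit GO annotations with optional planted enrichment
#'
#' Every gene draws each background term independently with probability
#' `p_background`; genes whose true omega exceeds 0.5 carry each enriched
#' term with the odds multiplied by `enrichment_strength` (strength 1 means
#' no enrichment anywhere). Both contigs of a gene inherit its terms.
#'
#' @param frag from [fragment_to_contigs()] (uses truth contig ids)
#' @param background_terms,enriched_terms character vectors of GO ids
#'   (disjoint)
#' @param enrichment_strength odds multiplier (>= 1)
#' @param p_background per-term baseline probability
#' @param seed integer seed
#' @return list: `go_map` (contig id -> terms) and `enriched_terms`
#' @export
emit_go_annotations <- function(frag,
                                background_terms = sprintf("GO:%07d", 1:40),
                                enriched_terms = sprintf("GO:%07d", 9001:9003),
                                enrichment_strength = 1, p_background = 0.08,
                                seed = 1) {
  if (length(intersect(background_terms, enriched_terms))) {
    stop("enriched terms must be disjoint from background terms")
  }
  set.seed(seed)
  truth <- frag$truth
  p0 <- p_background
  p_enr <- p0 * enrichment_strength / (1 - p0 + p0 * enrichment_strength)
  go_map <- list()
  all_terms <- c(background_terms, enriched_terms)
  if (length(all_terms) == 0L) {
    return(list(go_map = structure(list(), names = character(0)),
                enriched_terms = character(0)))
  }
  for (i in seq_len(nrow(truth))) {
    fast <- truth$omega_true[i] > 0.5
    terms <- c(
      background_terms[runif(length(background_terms)) < p0],
      enriched_terms[runif(length(enriched_terms)) < if (fast) p_enr else p0])
    for (cid in c(truth$contig_a[i], truth$contig_b[i])) {
      if (!is.na(cid)) go_map[[cid]] <- terms
    }
  }
  list(go_map = go_map, enriched_terms = enriched_terms)
}

#' Simulate a complete synthetic species pair
#'
#' Convenience wrapper chaining [generate_ancestor_set()],
#' [evolve_species_pair()], [make_outgroup_proteome()],
#' [fragment_to_contigs()], [plant_ssrs()] and [emit_go_annotations()],
#' with child seeds derived per stage from one master seed. When `out_dir`
#' is given, contig FASTAs, the outgroup proteome, GO map and truth table
#' are written there.
#'
#' @param n_genes number of ancestral genes
#' @param seed master seed
#' @param out_dir optional output directory
#' @param ancestor,evolve,fragment,ssr,go lists of stage parameter overrides
#' @return list with contigs_a, contigs_b, outgroup, go_map, truth,
#'   ssr_truth, paralogs, enriched_terms, evolved (gene-level sets)
#' @export
simulate_species_pair <- function(n_genes = 300, seed = 1, out_dir = NULL,
                                  ancestor = list(), evolve = list(),
                                  fragment = list(), ssr = list(),
                                  go = list()) {
  anc <- do.call(generate_ancestor_set,
                 c(list(n_genes = n_genes, seed = derive_seed(seed, "ancestor")),
                   ancestor))
  ev <- do.call(evolve_species_pair,
                c(list(ancestors = anc, seed = derive_seed(seed, "evolve")),
                  evolve))
  outgroup <- make_outgroup_proteome(anc, seed = derive_seed(seed, "outgroup"))
  fr <- do.call(fragment_to_contigs,
                c(list(evolved = ev, seed = derive_seed(seed, "fragment")),
                  fragment))
  fr <- do.call(plant_ssrs,
                c(list(frag = fr, evolved = ev, seed = derive_seed(seed, "ssr")),
                  ssr))
  goa <- do.call(emit_go_annotations,
                 c(list(frag = fr, seed = derive_seed(seed, "go")), go))
  sim <- list(contigs_a = fr$contigs_a, contigs_b = fr$contigs_b,
              outgroup = outgroup, go_map = goa$go_map,
              enriched_terms = goa$enriched_terms, truth = fr$truth,
              ssr_truth = fr$ssr_truth, paralogs = fr$paralogs,
              evolved = ev, ancestors = anc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(sim$contigs_a, file.path(out_dir, "species_a.fa"))
    write_fasta(sim$contigs_b, file.path(out_dir, "species_b.fa"))
    write_fasta(sim$outgroup, file.path(out_dir, "outgroup.faa"))
    write_go_map(sim$go_map, file.path(out_dir, "go_map.tsv"))
    write_table(sim$truth, file.path(out_dir, "truth.tsv"))
  }
  sim
}
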
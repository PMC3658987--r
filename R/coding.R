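# Protein-guided delimitation of CDS and UTRs on a contig, codon-preserving
# pairwise alignment of ortholog CDSs (global protein alignment
# back-translated so gaps stay on codon boundaries), and the alignment
# quality filters (internal stops, < 150 bp, Ks > 0.1).

#' Delimit CDS and UTRs on a contig from its anchor-protein hit
#'
#' The CDS is the contig span aligned to the outgroup protein, extended
#' outward codon by codon: downstream to the first in-frame stop (retained in
#' the CDS) when the alignment reaches the protein's last residue, and
#' upstream to the furthest ATG before an in-frame stop when it reaches the
#' first residue. A 5'UTR is called only when the resulting CDS start is
#' internal to the contig and the alignment covers the protein's first
#' residue; symmetrically for the 3'UTR. All coordinates are 0-based
#' half-open on the sense strand (after strand resolution), so a
#' reverse-complemented contig yields the identical annotation with
#' `strand = "-"`.
#'
#' @param contig nucleotide string
#' @param anchor_protein amino-acid string of the anchoring protein
#' @param hit one-row data.frame from [translated_search()] /
#'   [contig_best_anchor()] with the contig as query
#' @return object of class `coding_annotation`: contig_id, strand,
#'   cds_range, utr5_range, utr3_range (NULL when absent), anchor_protein,
#'   covered_protein_fraction, contig_length; or a rejected annotation
#'   (`rejected = TRUE`, `reason`)
#' @export
delimit_cds_utr <- function(contig, anchor_protein, hit) {
  L <- nchar(contig)
  reject <- function(reason) {
    structure(list(contig_id = hit$query_id, rejected = TRUE, reason = reason),
              class = "coding_annotation")
  }
  if (hit$q_end - hit$q_start < 3L) return(reject("aligned span shorter than one codon"))
  sense <- if (hit$strand == "-") revcomp(contig) else contig
  # hit coords are on the forward strand; flip onto the sense strand
  if (hit$strand == "-") {
    cs <- L - hit$q_end; ce <- L - hit$q_start
  } else {
    cs <- hit$q_start; ce <- hit$q_end
  }
  if ((ce - cs) %% 3L != 0L) return(reject("aligned span not a codon multiple"))
  plen <- nchar(anchor_protein)
  # local alignment may trim a few diverged terminal residues; treat the
  # protein terminus as reached within this residue tolerance
  tol <- 3L
  covers_start <- hit$s_start <= tol
  covers_end <- hit$s_end >= plen - tol
  codon_at <- function(j) substr(sense, j + 1L, j + 3L)
  is_stop <- function(cod) cod %in% c("TAA", "TAG", "TGA")

  cds_start <- cs; cds_end <- ce
  utr3 <- NULL
  if (covers_end) {
    j <- ce
    while (j + 3L <= L) {
      if (is_stop(codon_at(j))) { cds_end <- j + 3L; break }
      cds_end <- j + 3L
      j <- j + 3L
    }
    if (cds_end < L && is_stop(codon_at(cds_end - 3L))) {
      utr3 <- c(cds_end, L)
    }
  }
  utr5 <- NULL
  if (covers_start) {
    # expected start from the number of unaligned leading protein residues;
    # prefer it when it is an ATG with no in-frame stop down to the aligned
    # span, otherwise take the furthest upstream ATG before an in-frame stop
    expected <- cs - 3L * hit$s_start
    atgs <- integer(0)
    j <- cs - 3L
    if (codon_at(cs) == "ATG") atgs <- cs
    while (j >= 0L) {
      cod <- codon_at(j)
      if (is_stop(cod)) break
      if (cod == "ATG") atgs <- c(atgs, j)
      j <- j - 3L
    }
    if (expected %in% atgs) cds_start <- expected
    else if (length(atgs)) cds_start <- min(atgs)
    if (length(atgs) && cds_start > 0L) utr5 <- c(0L, cds_start)
  }
  if (cds_end - cds_start < 3L) return(reject("no open reading frame consistent with hit"))
  structure(list(
    contig_id = hit$query_id, strand = hit$strand,
    cds_range = c(cds_start, cds_end),
    utr5_range = utr5, utr3_range = utr3,
    anchor_protein = hit$subject_id,
    covered_protein_fraction = (hit$s_end - hit$s_start) / plen,
    contig_length = L, rejected = FALSE, reason = NA_character_),
    class = "coding_annotation")
}

#' Extract the annotated CDS/UTR sequences from a contig
#'
#' @param annot a `coding_annotation`
#' @param contig the contig the annotation refers to (original orientation)
#' @return list with `cds`, `utr5`, `utr3` (NULL when absent), on the sense
#'   strand
#' @export
annotation_seqs <- function(annot, contig) {
  stopifnot(!isTRUE(annot$rejected))
  sense <- if (annot$strand == "-") revcomp(contig) else contig
  cut <- function(rg) if (is.null(rg)) NULL else substr(sense, rg[1] + 1L, rg[2])
  list(cds = cut(annot$cds_range), utr5 = cut(annot$utr5_range),
       utr3 = cut(annot$utr3_range))
}

strip_terminal_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3L && substr(cds, n - 2L, n) %in% c("TAA", "TAG", "TGA")) {
    substr(cds, 1L, n - 3L)
  } else cds
}

# align two nucleotide strings globally with linear gap cost
global_nuc_align <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = nuc_submat(match, mismatch),
    gapOpening = 0, gapExtension = gap)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Codon-preserving alignment of two anchored CDS annotations
#'
#' The two CDSs (terminal stops removed) are translated and globally aligned
#' under BLOSUM62 with affine gaps; the protein alignment is back-translated
#' so every residue gap becomes a 3-nt gap on a codon boundary. UTR pairs
#' present on both annotations are aligned separately by global nucleotide
#' alignment (match +1 / mismatch -1 / gap -2).
#'
#' @param annot_a,annot_b `coding_annotation` objects anchored to the same
#'   protein
#' @param contig_a,contig_b the corresponding contig sequences
#' @param pair_id label for the pair
#' @param gap_open,gap_extend protein alignment gap penalties
#' @return object of class `codon_alignment`
#' @export
build_codon_alignment <- function(annot_a, annot_b, contig_a, contig_b,
                                  pair_id = NULL, gap_open = 11, gap_extend = 1) {
  if (!identical(annot_a$anchor_protein, annot_b$anchor_protein)) {
    stop("annotations anchored to different proteins")
  }
  sa <- annotation_seqs(annot_a, contig_a)
  sb <- annotation_seqs(annot_b, contig_b)
  cds_a <- strip_terminal_stop(sa$cds)
  cds_b <- strip_terminal_stop(sb$cds)
  aa_a <- translate_cds(cds_a)
  aa_b <- translate_cds(cds_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b), type = "global",
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_extend)
  gapped_a <- chars(as.character(Biostrings::alignedPattern(aln)))
  gapped_b <- chars(as.character(Biostrings::alignedSubject(aln)))
  back <- function(gapped_aa, cds) {
    cods <- codon_split(cds)
    out <- character(length(gapped_aa))
    k <- 0L
    for (i in seq_along(gapped_aa)) {
      if (gapped_aa[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- cods[k] }
    }
    if (k != length(cods)) stop("back-translation does not match stored CDS")
    paste(out, collapse = "")
  }
  acd_a <- back(gapped_a, cds_a)
  acd_b <- back(gapped_b, cds_b)
  utr5 <- utr3 <- NULL
  if (!is.null(sa$utr5) && !is.null(sb$utr5) && nchar(sa$utr5) && nchar(sb$utr5)) {
    utr5 <- global_nuc_align(sa$utr5, sb$utr5)
  }
  if (!is.null(sa$utr3) && !is.null(sb$utr3) && nchar(sa$utr3) && nchar(sb$utr3)) {
    utr3 <- global_nuc_align(sa$utr3, sb$utr3)
  }
  cods_a <- codon_split(acd_a); cods_b <- codon_split(acd_b)
  structure(list(
    pair_id = pair_id %||% paste0(annot_a$contig_id, "|", annot_b$contig_id),
    aligned_cds_a = acd_a, aligned_cds_b = acd_b,
    aligned_utr5_a = utr5$a, aligned_utr5_b = utr5$b,
    aligned_utr3_a = utr3$a, aligned_utr3_b = utr3$b,
    n_codons_ungapped = sum(cods_a != "---" & cods_b != "---")),
    class = "codon_alignment")
}

#' Quality-filter codon alignments
#'
#' Discards an alignment if (i) either ungapped CDS contains an internal
#' stop codon, (ii) the ungapped aligned CDS length (columns where both
#' sequences are non-gap, in nucleotides) is below `min_len`, or (iii) its
#' Ks exceeds `ks_max` (paralog guard). All applicable reasons are recorded;
#' the filter is idempotent and order-independent.
#'
#' @param alignments list of `codon_alignment` objects
#' @param rates_fn function mapping a `codon_alignment` to its Ks (default
#'   kappa-corrected counting, [yn_rates()])
#' @param min_len minimum ungapped aligned CDS nucleotides
#' @param ks_max maximum allowed Ks
#' @return list with `kept` (alignments) and `discarded` (data.frame:
#'   pair_id, reason)
#' @export
filter_alignments <- function(alignments,
                              rates_fn = function(al) yn_rates(al)$Ks,
                              min_len = 150, ks_max = 0.1) {
  kept <- list()
  disc <- list()
  for (al in alignments) {
    reasons <- character(0)
    dg_a <- gsub("-", "", al$aligned_cds_a, fixed = TRUE)
    dg_b <- gsub("-", "", al$aligned_cds_b, fixed = TRUE)
    if (grepl("*", translate_cds(dg_a), fixed = TRUE) ||
        grepl("*", translate_cds(dg_b), fixed = TRUE)) {
      reasons <- c(reasons, "stop")
    }
    ca <- chars(al$aligned_cds_a); cb <- chars(al$aligned_cds_b)
    shared <- sum(ca != "-" & cb != "-")
    if (shared < min_len) reasons <- c(reasons, paste0("length<", min_len))
    ks <- tryCatch(rates_fn(al), error = function(e) NA_real_)
    if (!is.na(ks) && ks > ks_max) reasons <- c(reasons, paste0("Ks>", ks_max))
    if (length(reasons)) {
      disc[[length(disc) + 1L]] <- data.frame(
        pair_id = al$pair_id, reason = paste(reasons, collapse = ";"),
        stringsAsFactors = FALSE)
    } else kept[[length(kept) + 1L]] <- al
  }
  list(kept = kept,
       discarded = if (length(disc)) do.call(rbind, disc)
                   else data.frame(pair_id = character(0), reason = character(0),
                                   stringsAsFactors = FALSE))
}
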
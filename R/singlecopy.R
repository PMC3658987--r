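# Single-copy nuclear gene candidate mining: a reference single-copy
# protein set (e.g. genes single-copy across several model plants) is
# searched against per-pair consensus sequences; hits spanning >= 600 bp at
# >= 75% identity seed candidates, and reference gene models supply the
# count of introns >= 300 bp within the hit span (for intron-spanning
# primer design downstream).

#' Consensus sequence of an ortholog contig pair
#'
#' The two contigs are locally aligned (strand resolved); at agreeing
#' columns the shared base is taken, at disagreements the species-A base
#' (the number of such columns is reported), and at gaps the base present.
#'
#' @param a,b contig sequences
#' @param config an [orthodiv_config()]
#' @return list with `consensus` (string) and `n_disagreements`
#' @export
pair_consensus <- function(a, b, config = orthodiv_config()) {
  aln <- contig_pair_alignment(a, b, config)
  ga <- aln$ga; gb <- aln$gb
  take_b <- ga == "-"
  cons <- ifelse(take_b, gb, ga)
  n_dis <- sum(ga != "-" & gb != "-" & ga != gb)
  list(consensus = paste(cons[cons != "-"], collapse = ""),
       n_disagreements = n_dis)
}

#' Mine single-copy nuclear gene candidates
#'
#' Each reference protein is searched (six-frame translated alignment)
#' against the consensus sequence of every ortholog pair; the protein's
#' best hit yields a candidate iff it spans at least `span_min` nucleotides
#' at identity at least `identity_min`. `introns_ge_300` counts reference
#' gene-model introns of at least `intron_min` nt falling inside the hit's
#' protein span; proteins without a gene model get NA there.
#'
#' @param pairs data.frame with contig_a, contig_b (and optionally pair_id)
#' @param contigs_a,contigs_b contig sets
#' @param single_copy_proteins named character vector of reference proteins
#' @param gene_models optional data.frame: protein_id, intron_after_residue
#'   (1-based residue preceding the intron), intron_length (nt)
#' @param span_min,identity_min,intron_min selection thresholds
#' @param config an [orthodiv_config()]
#' @return data.frame: reference_gene_id, pair_id, hit_span_nt, identity,
#'   introns_ge_300
#' @export
mine_single_copy <- function(pairs, contigs_a, contigs_b, single_copy_proteins,
                             gene_models = NULL, span_min = 600,
                             identity_min = 0.75, intron_min = 300,
                             config = orthodiv_config()) {
  empty <- data.frame(reference_gene_id = character(0), pair_id = character(0),
                      hit_span_nt = integer(0), identity = numeric(0),
                      introns_ge_300 = integer(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L || length(single_copy_proteins) == 0L) return(empty)
  pid <- pairs$pair_id %||% paste0(pairs$contig_a, "|", pairs$contig_b)
  consensi <- setNames(vapply(seq_len(nrow(pairs)), function(r) {
    pair_consensus(contigs_a[[pairs$contig_a[r]]],
                   contigs_b[[pairs$contig_b[r]]], config)$consensus
  }, ""), pid)
  # prefilter: shared protein k-mers against six-frame translations
  frames <- lapply(consensi, six_frame_translations)
  frame_seq <- setNames(vapply(frames, function(f) paste(f$aa, collapse = "|"), ""),
                        names(consensi))
  idx <- if (isTRUE(config$kmer_prefilter)) kmer_index(frame_seq, config$prot_kmer)
  rows <- list()
  for (p_id in names(single_copy_proteins)) {
    cand <- if (is.null(idx)) names(consensi)
            else kmer_candidates(single_copy_proteins[[p_id]], idx,
                                 config$prot_kmer, both_strands = FALSE)
    if (length(cand) == 0L) next
    hits <- translated_search(setNames(single_copy_proteins[p_id], p_id),
                              consensi[cand],
                              gap_open = config$prot_gap_open,
                              gap_extend = config$prot_gap_extend,
                              .frames = frames)
    if (nrow(hits) == 0L) next
    best <- hits[1, ]
    span <- best$q_end - best$q_start
    if (span < span_min || best$identity < identity_min) next
    n_intron <- NA_integer_
    if (!is.null(gene_models) && p_id %in% gene_models$protein_id) {
      gm <- gene_models[gene_models$protein_id == p_id, , drop = FALSE]
      n_intron <- sum(gm$intron_length >= intron_min &
                        gm$intron_after_residue > best$s_start &
                        gm$intron_after_residue <= best$s_end)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      reference_gene_id = p_id, pair_id = best$query_id,
      hit_span_nt = span, identity = best$identity,
      introns_ge_300 = n_intron, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
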
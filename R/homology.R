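# Orthology assignment: reciprocal best match (RBM) between the two species'
# contig sets, then triangulation through an outgroup proteome — a pair is
# kept only when both contigs have the same best outgroup protein, which
# guards against lineage-specific genes and recent paralogs.

#' Best hit per query from a hit table
#'
#' Ties are broken deterministically: higher score, then longer alignment,
#' then lexicographically smaller subject id.
#'
#' @param hits data.frame with columns query_id, subject_id, score, aln_length
#' @return named character vector query_id -> subject_id (queries without
#'   hits absent)
#' @export
best_hit_table <- function(hits) {
  if (nrow(hits) == 0L) return(setNames(character(0), character(0)))
  o <- order(hits$query_id, -hits$score, -hits$aln_length, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  setNames(h$subject_id, h$query_id)
}

#' Reciprocal best matches between two contig sets
#'
#' All-vs-all local alignment (both strands); pair (a, b) is reported iff b
#' is a's top-scoring hit and a is b's. Scores are computed once per
#' unordered pair, so the result is symmetric in the two species. With
#' `prefilter = TRUE` only pairs sharing at least one exact k-mer (either
#' strand) are aligned.
#'
#' @param set_a,set_b named character vectors of nucleotide contigs
#' @param config an [orthodiv_config()] (scoring + thresholds)
#' @return data.frame: contig_a, contig_b, score, identity, aln_length
#' @export
reciprocal_best_matches <- function(set_a, set_b, config = orthodiv_config()) {
  stopifnot(length(set_a) > 0, length(set_b) > 0)
  hits <- all_vs_all_nuc(set_a, set_b, config)
  if (nrow(hits) == 0L) {
    return(data.frame(contig_a = character(0), contig_b = character(0),
                      score = numeric(0), identity = numeric(0),
                      aln_length = integer(0), stringsAsFactors = FALSE))
  }
  best_ab <- best_hit_table(hits[, c("query_id", "subject_id", "score", "aln_length")])
  # b -> a direction from the same scores (local alignment is symmetric)
  best_ba <- best_hit_table(data.frame(
    query_id = hits$subject_id, subject_id = hits$query_id,
    score = hits$score, aln_length = hits$aln_length,
    stringsAsFactors = FALSE))
  a_ids <- names(best_ab)
  mutual <- best_ba[best_ab[a_ids]] == a_ids
  mutual[is.na(mutual)] <- FALSE
  keep <- a_ids[mutual]
  idx <- match(paste(keep, best_ab[keep]), paste(hits$query_id, hits$subject_id))
  out <- data.frame(contig_a = keep, contig_b = unname(best_ab[keep]),
                    score = hits$score[idx], identity = hits$identity[idx],
                    aln_length = hits$aln_length[idx], stringsAsFactors = FALSE)
  out <- out[order(out$contig_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all-vs-all (prefiltered) nucleotide local alignment; query = set_a ids
all_vs_all_nuc <- function(set_a, set_b, config) {
  cand <- if (isTRUE(config$kmer_prefilter)) {
    idx <- kmer_index(set_a, config$nuc_kmer)
    lapply(set_b, function(s) kmer_candidates(s, idx, config$nuc_kmer))
  } else {
    lapply(set_b, function(s) names(set_a))
  }
  rows <- list()
  for (b_id in names(set_b)) {
    qa <- cand[[b_id]]
    if (length(qa) == 0L) next
    h <- sw_nuc_batch(set_a[qa], set_b[[b_id]], b_id,
                      match = config$nuc_match, mismatch = config$nuc_mismatch,
                      gap_open = config$nuc_gap_open,
                      gap_extend = config$nuc_gap_extend)
    rows[[b_id]] <- h[h$score >= config$min_nuc_score &
                        h$aln_length >= config$min_nuc_aln_len, , drop = FALSE]
  }
  if (length(rows) == 0L) return(empty_hits())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Best outgroup protein per contig (translated search)
#'
#' Runs each outgroup protein against the contigs in six frames and reports
#' each contig's best protein hit (ties broken as in [best_hit_table()]).
#'
#' @param contigs named character vector of contigs
#' @param proteins named character vector of outgroup proteins
#' @param config an [orthodiv_config()]
#' @return data.frame of best hits, one row per contig with a hit; columns
#'   as [translated_search()]
#' @export
contig_best_anchor <- function(contigs, proteins, config = orthodiv_config()) {
  if (length(contigs) == 0L || length(proteins) == 0L) return(empty_hits())
  frames <- lapply(contigs, six_frame_translations)
  frame_seq <- setNames(vapply(frames, function(f) paste(f$aa, collapse = "|"), ""),
                        names(contigs))
  idx <- if (isTRUE(config$kmer_prefilter)) kmer_index(frame_seq, config$prot_kmer)
  rows <- list()
  for (p_id in names(proteins)) {
    cids <- if (is.null(idx)) names(contigs)
            else kmer_candidates(proteins[[p_id]], idx, config$prot_kmer,
                                 both_strands = FALSE)
    if (length(cids) == 0L) next
    h <- translated_search(setNames(proteins[p_id], p_id), contigs[cids],
                           gap_open = config$prot_gap_open,
                           gap_extend = config$prot_gap_extend,
                           min_score = config$min_prot_score,
                           min_len = config$min_prot_aln_len,
                           .frames = frames)
    rows[[p_id]] <- h
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (nrow(hits) == 0L) return(empty_hits())
  o <- order(hits$query_id, -hits$score, -hits$aln_length, hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Triangulate RBM pairs through an outgroup proteome
#'
#' A reciprocal-best-match pair is retained iff both contigs' best outgroup
#' protein is the same; that protein is recorded as the pair's anchor. Pairs
#' where either contig has no outgroup hit are dropped. The output is always
#' a subset of the input pairs.
#'
#' @param rbm_pairs data.frame from [reciprocal_best_matches()]
#' @param set_a,set_b contig sets
#' @param outgroup_proteins named character vector of outgroup proteins
#' @param config an [orthodiv_config()]
#' @return list with `pairs` (rbm_pairs rows + `anchor_protein`, `pair_id`)
#'   and `anchor_hits` (best-protein hit rows per contig, used downstream
#'   for CDS delimitation)
#' @export
triangulate <- function(rbm_pairs, set_a, set_b, outgroup_proteins,
                        config = orthodiv_config()) {
  contigs <- c(set_a[rbm_pairs$contig_a], set_b[rbm_pairs$contig_b])
  anchors <- contig_best_anchor(contigs, outgroup_proteins, config)
  best <- setNames(anchors$subject_id, anchors$query_id)
  aa <- best[rbm_pairs$contig_a]
  ab <- best[rbm_pairs$contig_b]
  keep <- !is.na(aa) & !is.na(ab) & aa == ab
  pairs <- rbm_pairs[keep, , drop = FALSE]
  pairs$anchor_protein <- unname(aa[keep])
  if (nrow(pairs)) {
    pairs$pair_id <- paste0(pairs$contig_a, "|", pairs$contig_b)
  } else pairs$pair_id <- character(0)
  rownames(pairs) <- NULL
  list(pairs = pairs,
       anchor_hits = anchors[anchors$query_id %in%
                               c(pairs$contig_a, pairs$contig_b), , drop = FALSE])
}
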
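# Pairwise similarity search used by orthology assignment: exact local
# alignment (Smith-Waterman, via Biostrings' C implementation) for
# nucleotide-nucleotide comparisons, and protein vs six-frame translated
# contig search with BLOSUM62. An optional exact k-mer prefilter (shared
# >= 1 word) keeps all-vs-all searches tractable; it only prunes candidate
# pairs, scoring is unchanged.

nuc_submat <- function(match = 1, mismatch = -2) {
  key <- paste0("nucmat_", match, "_", mismatch)
  if (is.null(.orthodiv_cache[[key]])) {
    .orthodiv_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE)
  }
  .orthodiv_cache[[key]]
}

blosum62 <- function() {
  if (is.null(.orthodiv_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .orthodiv_cache$blosum62 <- e$BLOSUM62
  }
  .orthodiv_cache$blosum62
}

# one row per alignment of patterns (XStringSet) vs a single subject
.hit_rows <- function(aln, query_ids, subject_id) {
  n <- length(aln)
  pr <- aln@pattern@range
  sr <- aln@subject@range
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  data.frame(
    query_id = query_ids, subject_id = subject_id,
    score = BiocGenerics::score(aln),
    identity = ifelse(len > 0, Biostrings::nmatch(aln) / len, 0),
    aln_length = len,
    q_start = BiocGenerics::start(pr) - 1L, q_end = BiocGenerics::end(pr),
    s_start = rep(BiocGenerics::start(sr) - 1L, length.out = n),
    s_end = rep(BiocGenerics::end(sr), length.out = n),
    stringsAsFactors = FALSE)
}

#' Best local nucleotide alignment between two sequences
#'
#' Optimal Smith-Waterman local alignment under match/mismatch scoring with
#' affine gaps, searching both strands of the query. Coordinates are 0-based
#' half-open; for a minus-strand hit the query range is reported on the
#' original (forward) query coordinates.
#'
#' @param query,subject nucleotide strings
#' @param match,mismatch,gap_open,gap_extend scoring (penalties positive)
#' @param min_score,min_len hits below either are discarded (NULL returned)
#' @param query_id,subject_id labels carried into the hit
#' @return one-row data.frame hit (query_id, subject_id, score, identity,
#'   aln_length, q_start, q_end, s_start, s_end, strand, frame) or NULL
#' @export
local_align_nuc <- function(query, subject, match = 1, mismatch = -2,
                            gap_open = 5, gap_extend = 2,
                            min_score = -Inf, min_len = 1,
                            query_id = "query", subject_id = "subject") {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  hits <- sw_nuc_batch(setNames(query, query_id), subject, subject_id,
                       match, mismatch, gap_open, gap_extend)
  best <- hits[order(-hits$score, -hits$aln_length, hits$strand), , drop = FALSE][1, ]
  if (best$score < min_score || best$aln_length < min_len) return(NULL)
  rownames(best) <- NULL
  best
}

# align each of `queries` (named character) against one subject, both
# strands; returns the better strand per query
sw_nuc_batch <- function(queries, subject, subject_id,
                         match = 1, mismatch = -2, gap_open = 5, gap_extend = 2) {
  mat <- nuc_submat(match, mismatch)
  subj <- Biostrings::DNAString(subject)
  fwd <- Biostrings::DNAStringSet(unname(queries))
  rev <- Biostrings::reverseComplement(fwd)
  a_f <- Biostrings::pairwiseAlignment(fwd, subj, type = "local",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  a_r <- Biostrings::pairwiseAlignment(rev, subj, type = "local",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  hf <- .hit_rows(a_f, names(queries), subject_id)
  hf$strand <- "+"
  hr <- .hit_rows(a_r, names(queries), subject_id)
  hr$strand <- "-"
  # minus-strand query range back to forward coordinates
  qlen <- nchar(queries)
  tmp <- qlen - hr$q_end
  hr$q_end <- qlen - hr$q_start
  hr$q_start <- tmp
  use_rev <- hr$score > hf$score
  out <- hf
  out[use_rev, ] <- hr[use_rev, ]
  out$frame <- NA_integer_
  out
}

# six reading-frame translations of a contig; returns data.frame
# (frame, aa, offset) where offset is the 0-based nt offset of the frame
# start on the strand read
six_frame_translations <- function(contig) {
  L <- nchar(contig)
  rc <- revcomp(contig)
  rows <- list()
  for (f in 1:3) {
    for (s in c(1L, -1L)) {
      src <- if (s > 0) contig else rc
      n_cod <- (L - (f - 1L)) %/% 3L
      if (n_cod < 1L) next
      sub <- substr(src, f, f - 1L + 3L * n_cod)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = s * f, aa = translate_cds(sub), offset = f - 1L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# nt range (0-based half-open, forward strand) of aa positions [as, ae]
# (1-based inclusive) in a given frame of a contig of length L
frame_aa_to_nt <- function(frame, offset, as, ae, L) {
  s <- offset + 3L * (as - 1L)
  e <- offset + 3L * ae
  if (frame > 0) c(s, e) else c(L - e, L - s)
}

#' Search a protein against contigs in all six reading frames
#'
#' Each contig is translated in six frames and locally aligned to the
#' protein under BLOSUM62; the best frame per contig is reported, BLASTX
#' orientation: `query_id` is the contig, `subject_id` the protein,
#' `q_start/q_end` the nucleotide span on the contig's forward strand and
#' `s_start/s_end` the residue span on the protein (both 0-based half-open).
#' Hits are sorted by score descending.
#'
#' @param protein amino-acid string
#' @param contigs named character vector of nucleotide contigs
#' @param gap_open,gap_extend affine gap penalties
#' @param min_score,min_len hit acceptance thresholds (aa columns)
#' @return data.frame of hits (possibly 0 rows)
#' @export
translated_search <- function(protein, contigs, gap_open = 11, gap_extend = 1,
                              min_score = -Inf, min_len = 1, .frames = NULL) {
  stopifnot(nchar(protein) > 0)
  if (length(contigs) == 0L) return(empty_hits())
  prot_id <- names(protein) %||% "protein"
  if (is.null(names(contigs))) names(contigs) <- paste0("contig", seq_along(contigs))
  frames <- if (is.null(.frames)) lapply(contigs, six_frame_translations)
            else .frames[names(contigs)]
  all_aa <- unlist(lapply(frames, function(f) f$aa), use.names = FALSE)
  n_per <- vapply(frames, nrow, 0L)
  contig_of <- rep(names(contigs), n_per)
  frame_df <- do.call(rbind, frames)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(all_aa), Biostrings::AAString(protein),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
  hits <- .hit_rows(aln, contig_of, prot_id)
  hits$frame <- frame_df$frame
  # aa frame coordinates -> nt contig coordinates
  L <- nchar(contigs)[contig_of]
  nt <- t(mapply(frame_aa_to_nt, frame_df$frame, frame_df$offset,
                 hits$q_start + 1L, hits$q_end, L))
  hits$aa_q_start <- hits$q_start
  hits$aa_q_end <- hits$q_end
  hits$q_start <- as.integer(nt[, 1]); hits$q_end <- as.integer(nt[, 2])
  hits$strand <- ifelse(hits$frame > 0, "+", "-")
  # best frame per contig
  hits <- hits[order(-hits$score, -hits$aln_length, hits$frame), , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  hits <- hits[hits$score >= min_score & hits$aln_length >= min_len, , drop = FALSE]
  rownames(hits) <- NULL
  hits[order(-hits$score, -hits$aln_length, hits$query_id), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             score = numeric(0), identity = numeric(0), aln_length = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), frame = integer(0),
             stringsAsFactors = FALSE)
}

# ---- k-mer prefilter ------------------------------------------------------

unique_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# hash: kmer -> character vector of sequence ids containing it
kmer_index <- function(seqs, k) {
  env <- new.env(parent = emptyenv())
  for (id in names(seqs)) {
    for (km in unique_kmers(seqs[[id]], k)) {
      env[[km]] <- c(env[[km]], id)
    }
  }
  env
}

# ids in the index sharing >= 1 k-mer with s (both strands if nucleotide)
kmer_candidates <- function(s, index, k, both_strands = TRUE) {
  kms <- unique_kmers(s, k)
  if (both_strands) kms <- unique(c(kms, unique_kmers(revcomp(s), k)))
  hits <- unlist(lapply(kms, function(km) index[[km]]), use.names = FALSE)
  unique(hits)
}
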
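# MISA-style SSR detection (perfect microsatellites, motif lengths 2-6,
# >= 5 repeat units), canonical motif classes collapsing strand and phase,
# SSR location statistics, and cross-species orthologous SSR marker
# candidates with flank conservation filters.

rotations <- function(x) {
  m <- nchar(x)
  vapply(0:(m - 1L), function(i) paste0(substr(x, i + 1L, m), substr(x, 1L, i)), "")
}

is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  for (p in seq_len(m - 1L)) {
    if (m %% p == 0L &&
        motif == paste(rep(substr(motif, 1L, p), m %/% p), collapse = "")) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical motif and motif class of a microsatellite
#'
#' The canonical motif is the lexicographically smallest string among all
#' rotations of the motif and of its reverse complement; the class pairs it
#' with the smallest rotation of its reverse complement, e.g. `AG -> AG/CT`,
#' `AT -> AT/TA`, `AAG -> AAG/CTT`.
#'
#' @param motif nucleotide motif (2-6 nt)
#' @return canonical motif / class string
#' @export
canonical_motif <- function(motif) {
  min(c(rotations(motif), rotations(revcomp(motif))))
}

#' @rdname canonical_motif
#' @export
motif_class <- function(motif) {
  cm <- canonical_motif(motif)
  partner <- setdiff(rotations(revcomp(cm)), cm)
  paste(cm, if (length(partner)) min(partner) else cm, sep = "/")
}

#' Detect perfect SSRs in a contig
#'
#' All maximal perfect tracts of primitive motifs of lengths
#' `motif_lengths` with at least `min_repeats` full units. A tract is
#' reported at the leftmost start of its periodic run; tracts whose motif is
#' itself a repetition of a shorter motif appear at the shorter motif only
#' (mononucleotide runs are therefore never reported). Motifs containing N
#' are skipped. Coordinates 0-based half-open.
#'
#' @param contig nucleotide string
#' @param contig_id id recorded in the output
#' @param min_repeats minimum number of full repeat units
#' @param motif_lengths motif sizes to scan
#' @return data.frame: contig_id, motif, motif_class, repeat_count, start,
#'   end, tract_length, location_ratio (start / contig length)
#' @export
detect_ssrs <- function(contig, contig_id = "contig", min_repeats = 5,
                        motif_lengths = 2:6) {
  s <- chars(contig)
  n <- length(s)
  rows <- list()
  for (m in motif_lengths) {
    if (n < m * min_repeats) next
    eq <- s[seq_len(n - m)] == s[(m + 1L):n]
    i <- 1L
    while (i <= length(eq)) {
      if (!eq[i]) { i <- i + 1L; next }
      j <- i
      while (j < length(eq) && eq[j + 1L]) j <- j + 1L
      # periodic run of period m covers positions i .. j+m (1-based)
      k <- (j - i + 1L + m) %/% m        # full units from the run start
      if (k >= min_repeats) {
        motif <- paste(s[i:(i + m - 1L)], collapse = "")
        if (!grepl("[^ACGT]", motif) && is_primitive_motif(motif)) {
          rows[[length(rows) + 1L]] <- data.frame(
            contig_id = contig_id, motif = motif,
            motif_class = motif_class(motif), repeat_count = k,
            start = i - 1L, end = i - 1L + k * m,
            tract_length = k * m,
            location_ratio = (i - 1L) / n, stringsAsFactors = FALSE)
        }
      }
      i <- j + 2L  # eq[j + 1] is FALSE (or past the end): next run is beyond it
    }
  }
  if (length(rows) == 0L) return(empty_ssr_loci())
  out <- do.call(rbind, rows)
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_ssr_loci <- function() {
  data.frame(contig_id = character(0), motif = character(0),
             motif_class = character(0), repeat_count = integer(0),
             start = integer(0), end = integer(0), tract_length = integer(0),
             location_ratio = numeric(0), stringsAsFactors = FALSE)
}

#' Detect SSRs across a whole contig set
#' @param contigs named character vector
#' @inheritParams detect_ssrs
#' @return data.frame as [detect_ssrs()], all contigs combined
#' @export
detect_ssrs_set <- function(contigs, min_repeats = 5, motif_lengths = 2:6) {
  out <- lapply(names(contigs), function(id) {
    detect_ssrs(contigs[[id]], id, min_repeats, motif_lengths)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Histogram of SSR start location ratios
#'
#' Location of a tract is its start position divided by the contig length;
#' counts are binned over [0, 1).
#'
#' @param loci data.frame from [detect_ssrs()] (uses `location_ratio`)
#' @param bins number of equal-width bins
#' @return data.frame: bin_start, bin_end, count
#' @export
ssr_location_histogram <- function(loci, bins = 10) {
  breaks <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(findInterval(loci$location_ratio, breaks), bins)
  data.frame(bin_start = breaks[-(bins + 1L)], bin_end = breaks[-1L],
             count = tabulate(idx, nbins = bins))
}

# local alignment of two contigs with strand resolution; returns gapped
# strings plus 0-based half-open ranges on each contig (a-range in original
# a coordinates even when the minus strand aligns) and the strand used
contig_pair_alignment <- function(a, b, config = orthodiv_config()) {
  mat <- nuc_submat(config$nuc_match, config$nuc_mismatch)
  one <- function(qa) {
    Biostrings::pairwiseAlignment(Biostrings::DNAString(qa),
      Biostrings::DNAString(b), type = "local", substitutionMatrix = mat,
      gapOpening = config$nuc_gap_open, gapExtension = config$nuc_gap_extend)
  }
  f <- one(a)
  r <- one(revcomp(a))
  use_rev <- Biostrings::score(r) > Biostrings::score(f)
  aln <- if (use_rev) r else f
  pr <- aln@pattern@range; sr <- aln@subject@range
  a_start <- BiocGenerics::start(pr) - 1L; a_end <- BiocGenerics::end(pr)
  if (use_rev) {
    La <- nchar(a)
    tmp <- La - a_end; a_end <- La - a_start; a_start <- tmp
  }
  list(ga = chars(as.character(Biostrings::alignedPattern(aln))),
       gb = chars(as.character(Biostrings::alignedSubject(aln))),
       a_range = c(a_start, a_end),
       b_range = c(BiocGenerics::start(sr) - 1L, BiocGenerics::end(sr)),
       strand = if (use_rev) "-" else "+")
}

#' Match orthologous SSR loci into cross-species marker candidates
#'
#' For each ortholog pair the two contigs are locally aligned (strand
#' resolved); loci of the same canonical motif class whose tracts overlap
#' when projected through the alignment become one candidate. Flank length
#' and identity are measured on the alignment columns outside the merged
#' tract.
#'
#' @param pairs data.frame with columns contig_a, contig_b (and optionally
#'   pair_id), e.g. from [triangulate()]
#' @param loci_a,loci_b data.frames from [detect_ssrs_set()]
#' @param contigs_a,contigs_b the contig sets
#' @param config an [orthodiv_config()]
#' @return data.frame of candidates: pair_id, motif_class, counts, tract
#'   lengths, starts, flank lengths and identities
#' @export
match_orthologous_ssrs <- function(pairs, loci_a, loci_b, contigs_a, contigs_b,
                                   config = orthodiv_config()) {
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    ca_id <- pairs$contig_a[r]; cb_id <- pairs$contig_b[r]
    la <- loci_a[loci_a$contig_id == ca_id, , drop = FALSE]
    lb <- loci_b[loci_b$contig_id == cb_id, , drop = FALSE]
    if (nrow(la) == 0L || nrow(lb) == 0L) next
    a <- contigs_a[[ca_id]]; b <- contigs_b[[cb_id]]
    aln <- contig_pair_alignment(a, b, config)
    if (aln$strand == "-") {  # mirror a's loci onto the reverse strand
      La <- nchar(a)
      new_start <- La - la$end
      la$end <- La - la$start
      la$start <- new_start
    }
    # per-column positions (0-based, position of the base at that column)
    apos <- cumsum(aln$ga != "-") - 1L + aln$a_range[1]
    bpos <- cumsum(aln$gb != "-") - 1L + aln$b_range[1]
    for (i in seq_len(nrow(la))) {
      cols_a <- which(aln$ga != "-" & apos >= la$start[i] & apos < la$end[i])
      if (length(cols_a) == 0L) next
      for (j in seq_len(nrow(lb))) {
        if (la$motif_class[i] != lb$motif_class[j]) next
        cols_b <- which(aln$gb != "-" & bpos >= lb$start[j] & bpos < lb$end[j])
        if (length(cols_b) == 0L) next
        if (max(cols_a) < min(cols_b) || max(cols_b) < min(cols_a)) next
        tract_cols <- range(c(cols_a, cols_b))
        left <- seq_len(tract_cols[1] - 1L)
        right <- if (tract_cols[2] < length(apos)) (tract_cols[2] + 1L):length(apos) else integer(0)
        fid <- function(cols) {
          if (length(cols) == 0L) return(c(0L, NA_real_))
          idn <- mean(aln$ga[cols] == aln$gb[cols] & aln$ga[cols] != "-")
          c(length(cols), idn)
        }
        fl <- fid(left); fr <- fid(right)
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = pairs$pair_id[r] %||% paste0(ca_id, "|", cb_id),
          contig_a = ca_id, contig_b = cb_id,
          motif_class = la$motif_class[i],
          count_a = la$repeat_count[i], count_b = lb$repeat_count[j],
          tract_length_a = la$tract_length[i], tract_length_b = lb$tract_length[j],
          start_a = la$start[i], start_b = lb$start[j],
          flank_left_len = as.integer(fl[1]), flank_left_identity = fl[2],
          flank_right_len = as.integer(fr[1]), flank_right_identity = fr[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(pair_id = character(0), contig_a = character(0),
                      contig_b = character(0), motif_class = character(0),
                      count_a = integer(0), count_b = integer(0),
                      tract_length_a = integer(0), tract_length_b = integer(0),
                      start_a = integer(0), start_b = integer(0),
                      flank_left_len = integer(0), flank_left_identity = numeric(0),
                      flank_right_len = integer(0), flank_right_identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Filter marker candidates on tract length and flank conservation
#'
#' A candidate is kept iff the longer of its two tracts is at least
#' `tract_min` nucleotides AND both flanks are at least `flank_min` aligned
#' columns with identity at least `flank_identity_min`. Rejection reasons
#' (`"tract<…"`, `"flank"`) partition the rejected set.
#'
#' @param candidates data.frame from [match_orthologous_ssrs()]
#' @param tract_min minimum tract length (nt) in at least one species
#' @param flank_min minimum flank length (aligned columns), both sides
#' @param flank_identity_min minimum flank identity, both sides
#' @return list with `kept` and `rejected` (with a `reason` column)
#' @export
filter_marker_candidates <- function(candidates, tract_min = 16,
                                     flank_min = 50, flank_identity_min = 0.9) {
  if (nrow(candidates) == 0L) {
    return(list(kept = candidates,
                rejected = cbind(candidates, reason = character(0))))
  }
  tract_ok <- pmax(candidates$tract_length_a, candidates$tract_length_b) >= tract_min
  flank_ok <- candidates$flank_left_len >= flank_min &
    candidates$flank_right_len >= flank_min &
    !is.na(candidates$flank_left_identity) &
    !is.na(candidates$flank_right_identity) &
    candidates$flank_left_identity >= flank_identity_min &
    candidates$flank_right_identity >= flank_identity_min
  reason <- ifelse(!tract_ok & !flank_ok, paste0("tract<", tract_min, ";flank"),
            ifelse(!tract_ok, paste0("tract<", tract_min),
            ifelse(!flank_ok, "flank", "")))
  keep <- tract_ok & flank_ok
  rej <- candidates[!keep, , drop = FALSE]
  rej$reason <- reason[!keep]
  rownames(rej) <- NULL
  kept <- candidates[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, rejected = rej)
}

#' Tally SSR loci by motif class size
#'
#' Mirrors the di- through hexa-nucleotide tally rows of a microsatellite
#' summary: counts partition the total.
#' @param loci data.frame from [detect_ssrs_set()]
#' @return named integer vector (di, tri, tetra, penta, hexa, total)
#' @export
ssr_class_tally <- function(loci) {
  m <- nchar(loci$motif)
  c(di = sum(m == 2), tri = sum(m == 3), tetra = sum(m == 4),
    penta = sum(m == 5), hexa = sum(m == 6), total = length(m))
}
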
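#' Read a FASTA file into a named character vector
#'
#' One element per record, in file order, names taken from the first
#' whitespace-delimited token of the header. Sequences are uppercased.
#' Nucleotide sequences may contain only ACGTN; amino-acid sequences the
#' twenty residue letters plus `*` and `X`.
#'
#' @param path path to a FASTA file
#' @param alphabet `"nucleotide"` or `"amino-acid"`
#' @return named character vector (empty for an empty file)
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  if (any(!nzchar(seqs))) stop("zero-length sequence: ", ids[!nzchar(seqs)][1])
  legal <- if (alphabet == "nucleotide") "[^ACGTN]" else "[^ACDEFGHIKLMNPQRSTVWY*X]"
  bad <- regexpr(legal, seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal character '%s' at position %d of '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line wrap width
#' @return the path, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a data frame as a tab-separated report
#'
#' Tab-separated with a header line; double columns rendered with six fixed
#' decimals so reports are byte-reproducible. If `schema` is given (a named
#' character vector column -> one of "character", "integer", "double"), the
#' frame is checked against it and an error names the offending column.
#'
#' @param rows data.frame
#' @param path output path
#' @param schema optional named character vector of column types
#' @return the path, invisibly
#' @export
write_table <- function(rows, path, schema = NULL) {
  stopifnot(is.data.frame(rows))
  if (!is.null(schema)) {
    if (!identical(names(rows), names(schema))) {
      stop("columns do not match schema: got [",
           paste(names(rows), collapse = ", "), "], expected [",
           paste(names(schema), collapse = ", "), "]")
    }
    for (cn in names(schema)) {
      ok <- switch(schema[[cn]],
        character = is.character(rows[[cn]]),
        integer   = is.integer(rows[[cn]]) || (is.numeric(rows[[cn]]) && all(rows[[cn]] == round(rows[[cn]]), na.rm = TRUE)),
        double    = is.numeric(rows[[cn]]),
        stop("unknown schema type for column ", cn))
      if (!ok) stop("column does not match schema type: ", cn)
    }
  }
  out <- rows
  for (cn in names(out)) {
    if (is.double(out[[cn]]) && !all(out[[cn]] == round(out[[cn]]), na.rm = TRUE)) {
      out[[cn]] <- ifelse(is.na(out[[cn]]), NA, sprintf("%.6f", out[[cn]]))
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a tab-separated report written by [write_table()]
#' @param path file path
#' @return data.frame
#' @export
read_table_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write CDS/UTR annotations as GFF3
#'
#' Internal coordinates are 0-based half-open; this writer converts to the
#' 1-based inclusive convention of GFF3. Features emitted: `CDS`,
#' `five_prime_UTR`, `three_prime_UTR`.
#'
#' @param annotations list of `coding_annotation` objects
#'   (see [delimit_cds_utr()])
#' @param path output path
#' @return the path, invisibly
#' @export
write_gff3 <- function(annotations, path) {
  lines <- "##gff-version 3"
  for (a in annotations) {
    feats <- list(CDS = a$cds_range,
                  five_prime_UTR = a$utr5_range,
                  three_prime_UTR = a$utr3_range)
    for (ft in names(feats)) {
      rg <- feats[[ft]]
      if (is.null(rg)) next
      if (rg[2] <= rg[1]) stop("empty or inverted range for ", ft, " on ", a$contig_id)
      lines <- c(lines, paste(
        a$contig_id, "orthodiv", ft,
        rg[1] + 1L, rg[2],                       # 0-based half-open -> 1-based inclusive
        ".", a$strand, if (ft == "CDS") "0" else ".",
        paste0("ID=", a$contig_id, ".", ft),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a contig-to-GO annotation map
#'
#' Plain-text two-column format: `contig_id<TAB>GO:NNNNNNN[;GO:...]`.
#'
#' @param path file path
#' @return named list mapping contig id to a character vector of GO ids
#' @export
read_go_map <- function(path) {
  if (file.size(path) == 0L) return(structure(list(), names = character(0)))
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  terms <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2])) character(0)
    else strsplit(p[2], ";", fixed = TRUE)[[1]]
  })
  setNames(terms, ids)
}

#' @rdname read_go_map
#' @param go_map named list of GO id vectors
#' @export
write_go_map <- function(go_map, path) {
  lines <- vapply(seq_along(go_map), function(i) {
    paste0(names(go_map)[i], "\t", paste(go_map[[i]], collapse = ";"))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
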
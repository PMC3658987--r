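# GO-term over-representation between fast-evolving (omega > 0.5) and
# conservatively evolving ortholog pairs, by one-sided Fisher's exact test.

#' Partition ortholog pairs by Ka/Ks
#'
#' Pairs with omega strictly above the threshold form the test set, all
#' others with defined omega the reference set (the boundary value goes to
#' the reference set). Pairs with undefined omega are excluded.
#'
#' @param rates data.frame with columns `pair_id` and `omega`
#'   (as from [estimate_rates()])
#' @param threshold omega cutoff
#' @return list with `test_ids` and `reference_ids`
#' @export
partition_by_omega <- function(rates, threshold = 0.5) {
  ok <- !is.na(rates$omega)
  list(test_ids = rates$pair_id[ok & rates$omega > threshold],
       reference_ids = rates$pair_id[ok & rates$omega <= threshold])
}

#' One-sided Fisher's exact test for over-representation
#'
#' Exact hypergeometric upper-tail probability of observing at least `a`
#' term-bearing pairs in the test set given fixed margins; the 2x2 table is
#' (a, b) term/non-term in the test set, (c, d) in the reference set.
#'
#' @param a,b,c,d non-negative counts
#' @return p-value
#' @examples
#' fisher_exact_one_sided(5, 0, 0, 5)  # 1/choose(10, 5)
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n_test <- a + b; n_ref <- c + d
  if (n_test == 0 || n_ref == 0) stop("degenerate margin: empty test or reference set")
  k <- a + c
  x <- a:min(k, n_test)
  sum(dhyper(x, m = k, n = n_test + n_ref - k, k = n_test))
}

#' Scan GO terms for over-representation in the test set
#'
#' Each pair carries the union of its two contigs' GO terms. Terms with
#' pooled frequency (test + reference) below `min_hits` are skipped; for
#' the rest a one-sided Fisher test of over-representation in the test set
#' is run and terms with `p < alpha` are reported, sorted by p ascending.
#' A Benjamini-Hochberg FDR column is included for reference but is not
#' used for the filter.
#'
#' @param go_map named list contig_id -> character vector of GO ids (see
#'   [read_go_map()])
#' @param test_ids,reference_ids pair ids (`"contigA|contigB"`) from
#'   [partition_by_omega()]
#' @param min_hits minimum pooled term frequency
#' @param alpha reporting threshold on the raw p-value
#' @return data.frame: go_id, p_value, fdr, freq_test, freq_reference,
#'   direction (always "over"; the scan tests over-representation)
#' @export
enrichment_scan <- function(go_map, test_ids, reference_ids,
                            min_hits = 5, alpha = 0.05) {
  pair_terms <- function(pid) {
    cc <- strsplit(pid, "|", fixed = TRUE)[[1]]
    unique(unlist(go_map[cc], use.names = FALSE))
  }
  tt <- lapply(test_ids, pair_terms)
  rt <- lapply(reference_ids, pair_terms)
  n_test <- length(test_ids); n_ref <- length(reference_ids)
  counts_t <- table(unlist(tt, use.names = FALSE))
  counts_r <- table(unlist(rt, use.names = FALSE))
  terms <- sort(unique(c(names(counts_t), names(counts_r))))
  if (length(terms) == 0L) {
    return(data.frame(go_id = character(0), p_value = numeric(0),
                      fdr = numeric(0), freq_test = integer(0),
                      freq_reference = integer(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  a <- as.integer(ifelse(terms %in% names(counts_t), counts_t[terms], 0L))
  c_ <- as.integer(ifelse(terms %in% names(counts_r), counts_r[terms], 0L))
  keep <- (a + c_) >= min_hits
  terms <- terms[keep]; a <- a[keep]; c_ <- c_[keep]
  p <- vapply(seq_along(terms), function(i) {
    fisher_exact_one_sided(a[i], n_test - a[i], c_[i], n_ref - c_[i])
  }, 0)
  out <- data.frame(go_id = terms, p_value = p,
                    fdr = p.adjust(p, method = "BH"),
                    freq_test = a, freq_reference = c_,
                    direction = rep("over", length(terms)),
                    stringsAsFactors = FALSE)
  out <- out[out$p_value < alpha, , drop = FALSE]
  out <- out[order(out$p_value, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
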
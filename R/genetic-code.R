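# Standard genetic code tables and codon-pair difference counting.
#
# Conventions used throughout (documented in the methods vignette):
#  * per-position synonymous site fractions use denominator 3 (changes that
#    create a stop codon count as nonsynonymous), so S + N = 3 x codons
#    exactly under equal weighting;
#  * codons differing at k positions are scored by averaging over all k!
#    minimal substitution pathways with equal weights; pathway steps are
#    classified by translation with '*' treated as an ordinary state.

.orthodiv_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(.orthodiv_cache$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .orthodiv_cache$gc <- setNames(unname(gc), names(gc))
  }
  .orthodiv_cache$gc
}

all_codons <- function() names(genetic_code())

#' Translate a CDS to amino acids (standard code)
#'
#' Codons containing N translate to `X`; stops to `*`.
#' @param cds nucleotide string, length divisible by 3
#' @return amino-acid string
#' @export
translate_cds <- function(cds) {
  cod <- codon_split(cds)
  gc <- genetic_code()
  aa <- ifelse(cod %in% names(gc), gc[cod], "X")
  paste(aa, collapse = "")
}

# Per-codon synonymous site count (summed over the 3 positions) with
# transition changes weighted kappa and transversions 1. kappa = 1 gives the
# unweighted NG86 fractions. Returns a named numeric vector over 64 codons.
syn_site_counts <- function(kappa = 1) {
  key <- paste0("syn_sites_", format(kappa, digits = 12))
  if (!is.null(.orthodiv_cache[[key]])) return(.orthodiv_cache[[key]])
  gc <- genetic_code()
  out <- setNames(numeric(64), names(gc))
  for (cod in names(gc)) {
    p <- chars(cod)
    s <- 0
    for (pos in 1:3) {
      w_syn <- 0; w_tot <- 0
      for (b in setdiff(BASES, p[pos])) {
        q <- p; q[pos] <- b
        w <- if (is_transition(p[pos], b)) kappa else 1
        w_tot <- w_tot + w
        if (gc[[paste(q, collapse = "")]] == gc[[cod]]) w_syn <- w_syn + w
      }
      s <- s + 3 * w_syn / (w_tot * 3) # 1 site per position, weighted fraction
    }
    out[cod] <- s
  }
  .orthodiv_cache[[key]] <- out
  out
}

# permutations of a small integer vector (k <= 3 here)
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# 64 x 64 x 4 array of pathway-averaged difference counts between codon
# pairs: slices syn_ts, syn_tv, nsyn_ts, nsyn_tv.
codon_diff_array <- function() {
  if (!is.null(.orthodiv_cache$diff_arr)) return(.orthodiv_cache$diff_arr)
  gc <- genetic_code()
  cods <- names(gc)
  arr <- array(0, dim = c(64, 64, 4),
               dimnames = list(cods, cods, c("syn_ts", "syn_tv", "nsyn_ts", "nsyn_tv")))
  for (i in 1:64) {
    p1 <- chars(cods[i])
    for (j in 1:64) {
      if (i == j) next
      p2 <- chars(cods[j])
      d <- which(p1 != p2)
      acc <- numeric(4)
      paths <- .perms(d)
      for (ord in paths) {
        cur <- p1
        for (pos in ord) {
          nxt <- cur; nxt[pos] <- p2[pos]
          syn <- gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]]
          ts <- is_transition(cur[pos], nxt[pos])
          k <- if (syn && ts) 1L else if (syn) 2L else if (ts) 3L else 4L
          acc[k] <- acc[k] + 1
          cur <- nxt
        }
      }
      arr[i, j, ] <- acc / length(paths)
    }
  }
  .orthodiv_cache$diff_arr <- arr
  arr
}
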
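# Independent brute-force oracles used to validate the package's optimised
# implementations. These are deliberately written as plain, slow,
# definition-level code paths.

# ---- Smith-Waterman (Gotoh affine) oracle, forward strand ----------------
# gap of length L costs gap_open + L * gap_extend (Biostrings convention)
sw_oracle_fwd <- function(q, s, match = 1, mismatch = -2,
                          gap_open = 5, gap_extend = 2) {
  a <- strsplit(q, "")[[1]]; b <- strsplit(s, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in pattern (consuming subject)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_extend,
                     H[i, j - 1] - gap_open - gap_extend)
      F[i, j] <- max(F[i - 1, j] - gap_extend,
                     H[i - 1, j] - gap_open - gap_extend)
      sc <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

sw_oracle_best <- function(q, s, ...) {
  max(sw_oracle_fwd(q, s, ...), sw_oracle_fwd(revcomp(q), s, ...))
}

# ---- NG86 counting oracle ------------------------------------------------
# Direct definition-level enumeration: per-position synonymous fractions
# with denominator 3 (stop-creating changes nonsynonymous), all minimal
# pathways with equal weights, '*' an ordinary state for step
# classification.
.oracle_orders <- list(
  `1` = matrix(1, 1, 1),
  `2` = rbind(c(1, 2), c(2, 1)),
  `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))

ng86_oracle <- function(aligned_a, aligned_b) {
  GC <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  ts_pair <- c("AG", "GA", "CT", "TC")
  ca <- substring(aligned_a, seq(1, nchar(aligned_a), 3), seq(3, nchar(aligned_a), 3))
  cb <- substring(aligned_b, seq(1, nchar(aligned_b), 3), seq(3, nchar(aligned_b), 3))
  keep <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[keep]; cb <- cb[keep]
  syn_sites_one <- function(cod) {
    p <- strsplit(cod, "")[[1]]
    tot <- 0
    for (pos in 1:3) {
      for (nb in setdiff(bases, p[pos])) {
        q <- p; q[pos] <- nb
        if (GC[[paste(q, collapse = "")]] == GC[[cod]]) tot <- tot + 1 / 3
      }
    }
    tot
  }
  S <- (sum(vapply(ca, syn_sites_one, 0)) + sum(vapply(cb, syn_sites_one, 0))) / 2
  N <- 3 * length(ca) - S
  Sd <- 0; Nd <- 0
  for (k in seq_along(ca)) {
    p1 <- strsplit(ca[k], "")[[1]]; p2 <- strsplit(cb[k], "")[[1]]
    d <- which(p1 != p2)
    if (length(d) == 0L) next
    orders <- .oracle_orders[[as.character(length(d))]]
    sd_k <- 0; nd_k <- 0
    for (r in seq_len(nrow(orders))) {
      cur <- p1
      for (pos in d[orders[r, ]]) {
        nxt <- cur; nxt[pos] <- p2[pos]
        if (GC[[paste(cur, collapse = "")]] == GC[[paste(nxt, collapse = "")]]) {
          sd_k <- sd_k + 1
        } else nd_k <- nd_k + 1
        cur <- nxt
      }
    }
    Sd <- Sd + sd_k / nrow(orders)
    Nd <- Nd + nd_k / nrow(orders)
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

# ---- one-sided Fisher oracle (binomial-coefficient enumeration) ----------
fisher_oracle <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c; N <- n1 + n2
  xs <- max(0, k - n2):min(k, n1)
  probs <- choose(n1, xs) * choose(n2, k - xs) / choose(N, k)
  sum(probs[xs >= a])
}

# ---- exhaustive SSR scanner oracle ---------------------------------------
ssr_oracle <- function(contig, min_repeats = 5, motif_lengths = 2:6) {
  s <- strsplit(contig, "")[[1]]; n <- length(s)
  prim <- function(motif) {
    m <- nchar(motif)
    for (p in seq_len(m - 1)) {
      if (m %% p == 0 &&
          motif == paste(rep(substr(motif, 1, p), m / p), collapse = "")) {
        return(FALSE)
      }
    }
    TRUE
  }
  rows <- list()
  for (m in motif_lengths) {
    if (n < m * min_repeats) next
    for (i in seq_len(n - m * min_repeats + 1)) {
      motif <- paste(s[i:(i + m - 1)], collapse = "")
      if (grepl("[^ACGT]", motif)) next
      if (!prim(motif)) next
      # leftmost start of the periodic run
      if (i > 1 && s[i - 1] == s[i + m - 1]) next
      k <- 1
      while (i + (k + 1) * m - 1 <= n &&
             all(s[(i + k * m):(i + (k + 1) * m - 1)] == s[i:(i + m - 1)])) {
        k <- k + 1
      }
      if (k >= min_repeats) {
        rows[[length(rows) + 1]] <- data.frame(
          motif = motif, repeat_count = k, start = i - 1, end = i - 1 + k * m,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(motif = character(0), repeat_count = integer(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, nchar(out$motif)), , drop = FALSE]
}

# ---- misc helpers --------------------------------------------------------
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# random stop-free CDS of n_codons (incl. ATG start, excl. stop)
rand_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 1, TRUE), collapse = ""))
}

# simple neutral mutator used as a test fixture generator (avoids creating
# stop codons so CDS fixtures stay translatable)
mutate_neutral_test <- function(cds, p) {
  s <- strsplit(cds, "")[[1]]
  gc <- Biostrings::GENETIC_CODE
  for (i in which(runif(length(s)) < p)) {
    old <- s
    s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
    ci <- (i - 1) %/% 3
    cod <- paste(s[(3 * ci + 1):(3 * ci + 3)], collapse = "")
    if (gc[[cod]] == "*") s <- old
  }
  paste(s, collapse = "")
}

# strip a terminal stop codon if present
strip_stop_test <- function(cds) {
  n <- nchar(cds)
  if (substr(cds, n - 2, n) %in% c("TAA", "TAG", "TGA")) substr(cds, 1, n - 3)
  else cds
}
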
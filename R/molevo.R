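# Substitution-rate estimation: Kimura two-parameter distance, Nei-Gojobori
# (1986) counting with Jukes-Cantor correction, and a kappa-corrected
# counting variant in the spirit of yn00, plus selection classification,
# Ks-distribution summary and T = K/2r divergence dating.

#' Kimura two-parameter distance between two aligned nucleotide strings
#'
#' Transitions (P) and transversions (Q) are counted over shared sites: both
#' characters must be one of ACGT (gaps and N are skipped, pairwise
#' deletion). `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))`. When a log argument
#' is non-positive the distance is saturated and flagged undefined.
#'
#' @param seq_a,seq_b equal-length (gapped) nucleotide strings
#' @return list with `P`, `Q`, `d`, `n_sites`, `defined`
#' @examples
#' k2p_distance("ACGT", "ACGT")$d  # 0
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must be equal length")
  a <- chars(toupper(seq_a)); b <- chars(toupper(seq_b))
  keep <- a %in% BASES & b %in% BASES
  n <- sum(keep)
  if (n == 0L) stop("no shared ungapped, unambiguous sites")
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  P <- sum(diff & is_transition(a, b)) / n
  Q <- sum(diff & !is_transition(a, b)) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    return(list(P = P, Q = Q, d = NA_real_, n_sites = n, defined = FALSE))
  }
  d <- -0.5 * log(arg1) - 0.25 * log(arg2)
  list(P = P, Q = Q, d = d, n_sites = n, defined = TRUE)
}

# Shared machinery: extract ungapped, N-free codon pairs from a codon
# alignment's gapped strings and return their indices into the codon tables.
aligned_codon_pairs <- function(aligned_a, aligned_b) {
  ca <- codon_split(aligned_a); cb <- codon_split(aligned_b)
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  list(a = ca[ok], b = cb[ok])
}

rates_from_counts <- function(S, N, diffs, method, correction) {
  Sd <- diffs[["syn_ts"]] + diffs[["syn_tv"]]
  Nd <- diffs[["nsyn_ts"]] + diffs[["nsyn_tv"]]
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (correction == "JC") {
    Ks <- if (pS < 0.75) -0.75 * log(1 - 4 / 3 * pS) else NA_real_
    Ka <- if (pN < 0.75) -0.75 * log(1 - 4 / 3 * pN) else NA_real_
  } else { # K2P-style on the transition/transversion split
    k2 <- function(ts, tv, sites) {
      P <- ts / sites; Q <- tv / sites
      a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
      if (a1 <= 0 || a2 <= 0) return(NA_real_)
      -0.5 * log(a1) - 0.25 * log(a2)
    }
    Ks <- if (S > 0) k2(diffs[["syn_ts"]], diffs[["syn_tv"]], S) else NA_real_
    Ka <- if (N > 0) k2(diffs[["nsyn_ts"]], diffs[["nsyn_tv"]], N) else NA_real_
  }
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ka = Ka, Ks = Ks, omega = omega, method = method,
       saturated = is.na(Ka) || is.na(Ks))
}

#' Nei-Gojobori (1986) Ka/Ks from a codon alignment
#'
#' Synonymous site fractions per codon position are the fraction of the three
#' possible single-nucleotide changes that are synonymous (changes creating a
#' stop count as nonsynonymous), so `S + N = 3 * n_codons` exactly. Codons
#' differing at several positions are scored by averaging over all minimal
#' substitution pathways with equal weights. Distances are Jukes-Cantor
#' corrected proportions; `pS` or `pN >= 0.75` flags saturation.
#'
#' Codon columns containing a gap or N in either sequence are skipped.
#'
#' @param aligned_a,aligned_b equal-length gapped CDS strings with gaps in
#'   multiples of 3 on codon boundaries, or a `codon_alignment` object as
#'   `aligned_a`
#' @return list of counts and rates: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ka`,
#'   `Ks`, `omega`, `n_codons`, `kappa`, `method`, `selection_class`
#' @export
ng86_rates <- function(aligned_a, aligned_b = NULL) {
  if (inherits(aligned_a, "codon_alignment")) {
    aligned_b <- aligned_a$aligned_cds_b; aligned_a <- aligned_a$aligned_cds_a
  }
  cp <- aligned_codon_pairs(aligned_a, aligned_b)
  if (length(cp$a) == 0L) stop("no ungapped codon pairs")
  sites <- syn_site_counts(kappa = 1)
  S <- (sum(sites[cp$a]) + sum(sites[cp$b])) / 2
  N <- 3 * length(cp$a) - S
  arr <- codon_diff_array()
  idx <- cbind(match(cp$a, all_codons()), match(cp$b, all_codons()))
  diffs <- vapply(dimnames(arr)[[3]], function(k) sum(arr[, , k][idx]), 0)
  r <- rates_from_counts(S, N, diffs, "NG86", "JC")
  r$n_codons <- length(cp$a)
  r$kappa <- 1
  r$selection_class <- classify_selection(r)
  r
}

#' Kappa-corrected counting Ka/Ks (yn00-style)
#'
#' As [ng86_rates()] but: the transition/transversion ratio kappa is first
#' estimated from third codon positions by K2P (falling back to `kappa = 2`
#' when undefined); site counting weights transition changes by kappa; and
#' the proportions are corrected with the K2P formula applied separately to
#' the transition and transversion components of `pS` and `pN`.
#'
#' @inheritParams ng86_rates
#' @param kappa_fallback kappa used when the third-position estimate is
#'   undefined
#' @return as [ng86_rates()]
#' @export
yn_rates <- function(aligned_a, aligned_b = NULL, kappa_fallback = 2) {
  if (inherits(aligned_a, "codon_alignment")) {
    aligned_b <- aligned_a$aligned_cds_b; aligned_a <- aligned_a$aligned_cds_a
  }
  cp <- aligned_codon_pairs(aligned_a, aligned_b)
  if (length(cp$a) == 0L) stop("no ungapped codon pairs")
  kappa <- estimate_kappa_4fold(cp$a, cp$b, kappa_fallback)
  sites <- syn_site_counts(kappa = kappa)
  S <- (sum(sites[cp$a]) + sum(sites[cp$b])) / 2
  N <- 3 * length(cp$a) - S
  arr <- codon_diff_array()
  idx <- cbind(match(cp$a, all_codons()), match(cp$b, all_codons()))
  diffs <- vapply(dimnames(arr)[[3]], function(k) sum(arr[, , k][idx]), 0)
  r <- rates_from_counts(S, N, diffs, "YN", "K2P")
  r$n_codons <- length(cp$a)
  r$kappa <- kappa
  r$selection_class <- classify_selection(r)
  r
}

# kappa estimated at four-fold degenerate third positions (both codons in
# the same four-fold family), where every change is synonymous, so the
# transition/transversion ratio reflects the mutation process rather than
# selection filtering; raw third-position counts overestimate kappa because
# transversions are more often nonsynonymous and purged
estimate_kappa_4fold <- function(cod_a, cod_b, fallback = 2) {
  fourfold <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  pre_a <- substr(cod_a, 1, 2)
  keep <- pre_a == substr(cod_b, 1, 2) & pre_a %in% fourfold
  estimate_kappa(substr(cod_a[keep], 3, 3), substr(cod_b[keep], 3, 3), fallback)
}

# kappa = alpha/beta from K2P on paired aligned bases
estimate_kappa <- function(third_a, third_b, fallback = 2) {
  n <- length(third_a)
  if (n == 0L) return(fallback)
  diff <- third_a != third_b
  P <- sum(diff & is_transition(third_a, third_b)) / n
  Q <- sum(diff & !is_transition(third_a, third_b)) / n
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0 || Q == 0) return(fallback)
  kappa <- (-2 * log(a1) + log(a2)) / (-log(a2))
  if (!is.finite(kappa) || kappa <= 0) fallback else kappa
}

#' Classify an ortholog pair's selection regime from its rates
#'
#' `identical`: no substitutions at all; `single-type`: only synonymous or
#' only nonsynonymous differences (omega undefined or degenerate); otherwise
#' the omega classes `reference` (omega < threshold), `candidate`
#' (threshold <= omega <= 1) and `positive` (omega > 1).
#'
#' @param rates list with `Sd`, `Nd`, `omega` (as from [ng86_rates()])
#' @param omega_threshold lower omega bound of the candidate class
#' @return character class label
#' @examples
#' classify_selection(list(Sd = 3, Nd = 6, omega = 1.902))  # "positive"
#' @export
classify_selection <- function(rates, omega_threshold = 0.5) {
  if (rates$Sd + rates$Nd == 0) return("identical")
  if (rates$Sd == 0 || rates$Nd == 0) return("single-type")
  if (is.na(rates$omega)) return("single-type")
  if (rates$omega < omega_threshold) "reference"
  else if (rates$omega <= 1) "candidate"
  else "positive"
}

#' Summarise a set of Ks values
#'
#' Mean and standard deviation over pairs with defined Ks, a histogram at a
#' configurable bin width, and the mode bin (diagnostic for the divergence
#' peak). A single value reports sd 0.
#'
#' @param ks numeric vector of Ks values (NAs dropped)
#' @param bin_width histogram bin width
#' @return list with `mean_ks`, `sd_ks`, `n`, `histogram` (data.frame:
#'   bin_start, bin_end, count), `mode_bin` (c(start, end))
#' @export
ks_summary <- function(ks, bin_width = 0.005) {
  ks <- ks[!is.na(ks)]
  if (length(ks) == 0L) stop("no defined Ks values")
  m <- mean(ks)
  s <- if (length(ks) > 1L) sd(ks) else 0
  breaks <- seq(0, max(ks) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(ks, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  hist <- data.frame(bin_start = breaks[-length(breaks)],
                     bin_end = breaks[-1L], count = counts)
  mb <- which.max(counts)
  list(mean_ks = m, sd_ks = s, n = length(ks), histogram = hist,
       mode_bin = c(hist$bin_start[mb], hist$bin_end[mb]))
}

#' Divergence time from mean synonymous divergence: T = K / 2r
#'
#' @param K mean synonymous substitutions per synonymous site between
#'   orthologs
#' @param sd_K standard deviation of K over pairs (propagated linearly)
#' @param r synonymous substitution rate, substitutions/site/year
#' @return object of class `divergence_estimate` with `T_years`, `T_sd_years`,
#'   `T_mya`, `T_sd_mya` and the inputs
#' @examples
#' divergence_time(0.027, 0.017, 1.5e-8)  # ~0.90 +/- 0.57 Mya
#' @export
divergence_time <- function(K, sd_K = 0, r) {
  if (r <= 0) stop("substitution rate r must be > 0")
  if (K < 0) stop("K must be >= 0")
  T_years <- K / (2 * r)
  T_sd <- sd_K / (2 * r)
  structure(list(K = K, sd_K = sd_K, r = r,
                 T_years = T_years, T_sd_years = T_sd,
                 T_mya = T_years / 1e6, T_sd_mya = T_sd / 1e6),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("Divergence time T = K/2r: %.2f +/- %.2f Mya (K = %.3f +/- %.3f, r = %.3g)\n",
              x$T_mya, x$T_sd_mya, x$K, x$sd_K, x$r))
  invisible(x)
}

#' Estimate rates for a list of codon alignments
#'
#' @param alignments list of `codon_alignment` objects
#' @param method `"YN"` (kappa-corrected counting) or `"NG86"`
#' @param omega_threshold threshold for [classify_selection()]
#' @return data.frame: pair_id, method, Ka, Ks, omega, selection_class,
#'   n_codons, S, N, Sd, Nd, kappa
#' @export
estimate_rates <- function(alignments, method = c("YN", "NG86"),
                           omega_threshold = 0.5) {
  method <- match.arg(method)
  f <- if (method == "YN") yn_rates else ng86_rates
  rows <- lapply(alignments, function(al) {
    r <- f(al)
    r$selection_class <- classify_selection(r, omega_threshold)
    data.frame(pair_id = al$pair_id %||% NA_character_, method = method,
               Ka = r$Ka, Ks = r$Ks, omega = r$omega,
               selection_class = r$selection_class, n_codons = r$n_codons,
               S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd, kappa = r$kappa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
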
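#' @noRd
BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' Vectorised over `x`. Accepts ACGTN.
#' @param x character vector of nucleotide strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# TRUE where the unordered base pair is a transition (A<->G or C<->T)
is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Derive a reproducible child seed from a master seed and a label
#'
#' Submodules of the simulator and pipeline draw their own seeds from the one
#' master seed so that stages are independently reproducible.
#' @param master integer master seed
#' @param label character stage label
#' @return integer in [0, 2^31 - 2]
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- as.double(master) %% 2147483647
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# split an ungapped or gapped sequence string into codon triplets
codon_split <- function(s) {
  n <- nchar(s)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
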
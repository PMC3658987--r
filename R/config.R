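#' Default run configuration
#'
#' All tunable thresholds of the pipeline in one flat list. Values mirror the
#' analysis defaults: minimum raw alignment score and length standing in for
#' a database E-value cutoff, the Ks ceiling used to purge paralogs, the
#' 150-bp minimum aligned CDS, the omega = 0.5 selection threshold, MISA-style
#' SSR settings (>= 5 repeat units, >= 16 bp tract), single-copy mining
#' criteria (>= 600 bp span, >= 75% identity, introns >= 300 bp) and the
#' dicot synonymous substitution rate r = 1.5e-8 /site/year used for dating.
#'
#' @param ... name = value overrides of any default
#' @return named list of class `orthodiv_config`
#' @examples
#' cfg <- orthodiv_config(ks_max = 0.2)
#' cfg$ks_max
#' @export
orthodiv_config <- function(...) {
  cfg <- list(
    # homology / alignment
    nuc_match = 1, nuc_mismatch = -2, nuc_gap_open = 5, nuc_gap_extend = 2,
    prot_gap_open = 11, prot_gap_extend = 1,
    min_nuc_score = 40, min_nuc_aln_len = 60,
    min_prot_score = 40, min_prot_aln_len = 20,
    kmer_prefilter = TRUE, nuc_kmer = 16, prot_kmer = 6,
    # coding filters
    min_cds_aln_len = 150, ks_max = 0.1,
    # selection / enrichment
    omega_threshold = 0.5, go_min_hits = 5, go_alpha = 0.05,
    # SSR / markers
    ssr_min_repeats = 5, ssr_tract_min = 16,
    flank_min = 50, flank_identity_min = 0.9,
    # single-copy mining
    sc_span_min = 600, sc_identity_min = 0.75, sc_intron_min = 300,
    # dating
    subst_rate = 1.5e-8,
    # Ks histogram
    ks_bin_width = 0.005,
    # randomness
    seed = 1
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "orthodiv_config")
}

validate_config <- function(cfg) {
  num <- vapply(cfg, is.numeric, logical(1))
  vals <- unlist(cfg[num & !names(cfg) %in%
    c("nuc_mismatch", "seed")]) # mismatch penalty is negative by design
  if (any(vals <= 0)) {
    stop("config thresholds must be strictly positive: ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  }
  invisible(cfg)
}

#' Write / read a run configuration as flat key-value YAML
#'
#' Round-trips exactly: `read_config(write_config(cfg, f))` equals `cfg`.
#' @param cfg an `orthodiv_config`
#' @param path file path
#' @return `write_config` the path, invisibly; `read_config` the config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(orthodiv_config, vals)
}
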
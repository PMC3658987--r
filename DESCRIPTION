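Package: orthodiv
Title: Comparative Transcriptome Divergence and Marker Mining for Close Species Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative evolutionary analysis of two closely related
    species from assembled transcriptome contigs: ortholog identification by
    reciprocal best match with outgroup triangulation, protein-guided CDS and
    UTR delimitation, codon-preserving pairwise alignment, Ka/Ks estimation
    (Nei-Gojobori counting and a kappa-corrected variant), Kimura
    two-parameter divergence for coding and untranslated regions,
    synonymous-peak divergence dating (T = K/2r), selection-stratified Gene
    Ontology over-representation by Fisher's exact test, EST-SSR detection
    with cross-species marker candidate filtering, and single-copy nuclear
    gene candidate mining. Includes a synthetic species-pair generator so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
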
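test_that("ancestor generation is deterministic, GC-targeted and validates inputs", {
  a1 <- generate_ancestor_set(5, seed = 1)
  a2 <- generate_ancestor_set(5, seed = 1)
  expect_identical(a1, a2)
  expect_length(generate_ancestor_set(1, seed = 2), 1)
  expect_error(generate_ancestor_set(5, length_range = c(100, 500)), "150")

  anc <- generate_ancestor_set(200, gc_target = 0.41, seed = 3)
  allseq <- paste(vapply(anc, function(g) paste0(g$utr5, g$cds, g$utr3), ""),
                  collapse = "")
  gc <- sum(strsplit(allseq, "")[[1]] %in% c("G", "C")) / nchar(allseq)
  expect_lt(abs(gc - 0.41), 0.02)

  # structural invariants of every gene
  for (g in anc[1:20]) {
    expect_equal(substr(g$cds, 1, 3), "ATG")
    aa <- translate_cds(g$cds)
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*.", aa))  # single, terminal stop
  }
})

test_that("evolution respects the omega mixture and is codon-safe", {
  anc <- generate_ancestor_set(30, seed = 4, length_range = c(300, 900))
  # omega = 0: purely synonymous evolution, proteins unchanged
  ev0 <- evolve_species_pair(anc, ks_mean = 0.05,
                             omega_mixture = list(list(weight = 1, omega = 0)),
                             seed = 5)
  for (i in seq_along(anc)) {
    expect_identical(translate_cds(ev0$genes_a[[i]]$cds),
                     translate_cds(anc[[i]]$cds))
    expect_identical(translate_cds(ev0$genes_b[[i]]$cds),
                     translate_cds(anc[[i]]$cds))
  }
  expect_error(evolve_species_pair(anc,
    omega_mixture = list(list(weight = 1, omega = -0.1))), "omega")
  expect_error(evolve_species_pair(anc,
    omega_mixture = list(list(weight = 0.5, omega = 0.2))), "sum")

  # determinism
  ev1 <- evolve_species_pair(anc, seed = 6)
  ev2 <- evolve_species_pair(anc, seed = 6)
  expect_identical(ev1, ev2)
})

test_that("UTRs diverge faster than coding sequence at the configured multiplier", {
  anc <- generate_ancestor_set(120, seed = 7,
                               utr5_range = c(60, 150), utr3_range = c(80, 250))
  divs <- function(ev) {
    cds_d <- utr_d <- numeric(0)
    for (i in seq_along(anc)) {
      cds_d <- c(cds_d, k2p_distance(ev$genes_a[[i]]$cds, ev$genes_b[[i]]$cds)$d)
      utr_d <- c(utr_d, k2p_distance(ev$genes_a[[i]]$utr3, ev$genes_b[[i]]$utr3)$d)
    }
    c(cds = mean(cds_d, na.rm = TRUE), utr = mean(utr_d, na.rm = TRUE))
  }
  d17 <- divs(evolve_species_pair(anc, ks_mean = 0.03,
                                  utr_rate_multiplier = 1.7, seed = 8))
  expect_gt(d17[["utr"]], d17[["cds"]])

  # at defaults the UTR/CDS divergence ratio lands in the relaxed-constraint
  # band typical of close plant species pairs
  d_def <- divs(evolve_species_pair(anc, seed = 8))
  expect_gt(d_def[["utr"]], d_def[["cds"]])
  expect_lt(d_def[["utr"]] / d_def[["cds"]], 2.6)
})

test_that("fragmentation emulates the contig length mix and closes the loop", {
  anc <- generate_ancestor_set(150, seed = 9)
  ev <- evolve_species_pair(anc, seed = 10)
  fr <- fragment_to_contigs(ev, strand_flip_prob = 0, paralog_prob = 0,
                            orphan_prob = 0, seed = 11)
  expect_true(all(fr$truth$strand_a == "+"))
  lens <- nchar(fr$contigs_a)
  short <- mean(lens >= 200 & lens <= 500)
  expect_lt(abs(short - 0.56), 0.12)  # short-heavy mass as configured

  # full transcripts: contig equals the evolved transcript
  fr2 <- fragment_to_contigs(ev, truncate = FALSE, strand_flip_prob = 0,
                             paralog_prob = 0, orphan_prob = 0, seed = 12)
  i <- 1
  tx <- paste0(ev$genes_a[[i]]$utr5, ev$genes_a[[i]]$cds, ev$genes_a[[i]]$utr3)
  expect_identical(unname(fr2$contigs_a[fr2$truth$contig_a[i]]), tx)
  expect_equal(nrow(fr2$truth), length(fr2$contigs_a))

  # orphans appear in exactly one species; paralogs add extra contigs
  fr3 <- fragment_to_contigs(ev, paralog_prob = 0.3, orphan_prob = 0.3, seed = 13)
  orp <- fr3$truth[fr3$truth$orphan != "none", ]
  expect_gt(nrow(orp), 0)
  expect_true(all(is.na(orp$contig_b[orp$orphan == "a"])))
  expect_gt(nrow(fr3$paralogs), 0)
})

test_that("planted SSRs are recovered by the detector at recorded positions", {
  sim <- simulate_species_pair(
    n_genes = 50, seed = 14,
    fragment = list(truncate = FALSE, paralog_prob = 0, orphan_prob = 0,
                    strand_flip_prob = 0.5),
    ssr = list(pair_fraction = 0.6, per_species_mutation = 0.5))
  st <- sim$ssr_truth
  expect_gt(nrow(st), 10)
  for (i in seq_len(nrow(st))) {
    for (side in c("a", "b")) {
      cid <- st[[paste0("contig_", side)]][i]
      contigs <- if (side == "a") sim$contigs_a else sim$contigs_b
      loci <- detect_ssrs(contigs[[cid]], cid)
      hit <- loci[loci$start == st[[paste0("start_", side)]][i], ]
      expect_equal(nrow(hit), 1)
      expect_equal(hit$repeat_count, st[[paste0("count_", side)]][i])
      expect_equal(hit$motif_class, st$motif_class[i])
    }
  }
  # length polymorphism planted: some pairs differ in repeat count
  expect_gt(sum(st$count_a != st$count_b), 0)

  # empty motif table leaves contigs untouched
  sim0 <- simulate_species_pair(n_genes = 5, seed = 15,
                                ssr = list(motif_freq = numeric(0)))
  expect_equal(nrow(sim0$ssr_truth), 0)
})

test_that("GO emission plants enrichment only above the omega threshold", {
  anc <- generate_ancestor_set(400, seed = 16, length_range = c(300, 600))
  ev <- evolve_species_pair(anc, seed = 17)
  fr <- fragment_to_contigs(ev, paralog_prob = 0, orphan_prob = 0, seed = 18)
  goa <- emit_go_annotations(fr, background_terms = sprintf("GO:%07d", 1:10),
                             enriched_terms = "GO:9999999",
                             enrichment_strength = 8, p_background = 0.1,
                             seed = 19)
  fast <- fr$truth$omega_true > 0.5
  freq_fast <- mean(vapply(fr$truth$contig_a[fast], function(cid)
    "GO:9999999" %in% goa$go_map[[cid]], TRUE))
  freq_slow <- mean(vapply(fr$truth$contig_a[!fast], function(cid)
    "GO:9999999" %in% goa$go_map[[cid]], TRUE))
  expect_gt(freq_fast, freq_slow + 0.2)

  expect_error(emit_go_annotations(fr, background_terms = "GO:1",
                                   enriched_terms = "GO:1"), "disjoint")
  empty <- emit_go_annotations(fr, background_terms = character(0),
                               enriched_terms = character(0))
  expect_length(empty$go_map, 0)
})

test_that("the full simulation is byte-identical under a fixed seed", {
  s1 <- simulate_species_pair(n_genes = 15, seed = 20)
  s2 <- simulate_species_pair(n_genes = 15, seed = 20)
  expect_identical(s1$contigs_a, s2$contigs_a)
  expect_identical(s1$contigs_b, s2$contigs_b)
  expect_identical(s1$outgroup, s2$outgroup)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$go_map, s2$go_map)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_species_pair(n_genes = 10, seed = 21, out_dir = d1)
  simulate_species_pair(n_genes = 10, seed = 21, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
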
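test_that("SSR detection finds tracts at the repeat threshold with canonical classes", {
  l <- detect_ssrs(paste0("GGC", strrep("AT", 6), "CGGT"), "c1")
  expect_equal(nrow(l), 1)
  expect_equal(l$motif_class, "AT/TA")
  expect_equal(l$repeat_count, 6)
  expect_equal(c(l$start, l$end), c(3L, 15L))

  expect_equal(nrow(detect_ssrs(paste0("GGC", strrep("AT", 4), "CGGT"))), 0)
  # mononucleotide runs never reported (non-primitive dinucleotide motif)
  expect_equal(nrow(detect_ssrs(strrep("A", 30))), 0)
})

test_that("motif classes collapse rotations and reverse complements", {
  expect_equal(motif_class("AG"), "AG/CT")
  expect_equal(motif_class("GA"), "AG/CT")
  expect_equal(motif_class("CT"), "AG/CT")
  expect_equal(motif_class("TC"), "AG/CT")
  expect_equal(motif_class("AT"), "AT/TA")
  expect_equal(motif_class("AC"), "AC/GT")
  expect_equal(motif_class("AAG"), "AAG/CTT")
  expect_equal(motif_class("CTT"), "AAG/CTT")
})

test_that("SSR detection equals the exhaustive scanner oracle on random contigs", {
  set.seed(41)
  for (case in 1:100) {
    # low-complexity-biased contigs so repeats actually occur
    n <- sample(80:300, 1)
    contig <- paste(sample(c("A", "C", "G", "T", "A", "T"), n, TRUE), collapse = "")
    if (runif(1) < 0.5) {
      # splice in a planted repeat to exercise the scanner
      m <- sample(c("AT", "AG", "AAG", "AGAT"), 1)
      k <- sample(5:9, 1)
      at <- sample(0:(nchar(contig)), 1)
      contig <- paste0(substr(contig, 1, at), strrep(m, k),
                       substr(contig, at + 1, nchar(contig)))
    }
    got <- detect_ssrs(contig, "c")
    want <- ssr_oracle(contig)
    expect_equal(got$motif, want$motif, info = paste("case", case))
    expect_equal(got$start, want$start, info = paste("case", case))
    expect_equal(got$repeat_count, want$repeat_count, info = paste("case", case))
  }
})

test_that("location ratios and their histogram follow the start/length definition", {
  set.seed(44)
  contig <- paste0(rand_dna(99), "C", strrep("AG", 8), "T", rand_dna(283))
  l <- detect_ssrs(contig, "c1")
  l <- l[l$motif_class == "AG/CT", ]
  expect_equal(l$location_ratio, 100 / 400)

  loci <- data.frame(location_ratio = c(0, 0.05, 0.25, 0.95))
  h <- ssr_location_histogram(loci, bins = 10)
  expect_equal(h$count[1], 2)   # 0 and 0.05 in the first bin
  expect_equal(h$count[3], 1)
  expect_equal(h$count[10], 1)
  expect_equal(sum(h$count), 4)
})

test_that("orthologous SSRs are matched through the pair alignment", {
  set.seed(42)
  left <- rand_dna(120); right <- rand_dna(130)
  a <- paste0(left, "C", strrep("AG", 8), "T", right)
  b_flank_l <- mutate_neutral_test(left, 0.02)
  b_flank_r <- mutate_neutral_test(right, 0.02)
  b <- paste0(b_flank_l, "C", strrep("AG", 10), "T", b_flank_r)
  pairs <- data.frame(contig_a = "a1", contig_b = "b1", stringsAsFactors = FALSE)
  la <- detect_ssrs_set(c(a1 = a)); lb <- detect_ssrs_set(c(b1 = b))
  mc <- match_orthologous_ssrs(pairs, la, lb, c(a1 = a), c(b1 = b))
  expect_equal(nrow(mc), 1)
  expect_equal(mc$motif_class, "AG/CT")
  expect_equal(c(mc$count_a, mc$count_b), c(8L, 10L))
  expect_gt(mc$flank_left_identity, 0.9)

  # SSR in only one species -> no candidate
  b_no <- paste0(b_flank_l, "C", "AGAG", "T", b_flank_r)
  mc2 <- match_orthologous_ssrs(pairs, la, detect_ssrs_set(c(b1 = b_no)),
                                c(a1 = a), c(b1 = b_no))
  expect_equal(nrow(mc2), 0)

  # two same-class loci far apart match only their overlapping partners
  a2 <- paste0(left, strrep("AG", 6), rand_dna(150), strrep("AG", 7), right)
  b2 <- paste0(b_flank_l, strrep("AG", 6), substr(a2, 133, 282),
               strrep("AG", 7), b_flank_r)
  mc3 <- match_orthologous_ssrs(pairs, detect_ssrs_set(c(a1 = a2)),
                                detect_ssrs_set(c(b1 = b2)),
                                c(a1 = a2), c(b1 = b2))
  expect_equal(nrow(mc3), 2)
  expect_false(any(abs(mc3$start_a - mc3$start_b) > 20))
})

test_that("marker filters enforce tract and flank criteria with reasons", {
  cand <- data.frame(
    pair_id = c("p1", "p2", "p3"),
    contig_a = "a", contig_b = "b", motif_class = c("AAG/CTT", "AG/CT", "AG/CT"),
    count_a = c(5L, 8L, 10L), count_b = c(5L, 8L, 10L),
    tract_length_a = c(15L, 16L, 20L), tract_length_b = c(15L, 16L, 20L),
    start_a = 0L, start_b = 0L,
    flank_left_len = c(60L, 60L, 10L), flank_left_identity = c(0.98, 0.98, 0.98),
    flank_right_len = c(60L, 60L, 60L), flank_right_identity = c(0.98, 0.98, 0.98),
    stringsAsFactors = FALSE)
  res <- filter_marker_candidates(cand, tract_min = 16, flank_min = 50,
                                  flank_identity_min = 0.9)
  expect_equal(res$kept$pair_id, "p2")        # (AG)8 = 16 nt kept
  reasons <- setNames(res$rejected$reason, res$rejected$pair_id)
  expect_match(reasons[["p1"]], "tract<16")   # (AAG)5 = 15 nt
  expect_match(reasons[["p3"]], "flank")
  # reasons partition the rejected set
  expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(cand))
})

test_that("motif-class tallies partition the total SSR count", {
  loci <- data.frame(motif = c("AG", "AT", "AAG", "AGAT", "AACTC", "AAGGAG"))
  tly <- ssr_class_tally(loci)
  expect_equal(unname(tly["total"]), 6L)
  expect_equal(sum(tly[c("di", "tri", "tetra", "penta", "hexa")]),
               unname(tly["total"]))
})

test_that("single-copy mining applies span, identity and intron criteria", {
  set.seed(43)
  cds_long <- rand_cds(260)      # 780 nt
  cds_short <- rand_cds(130)     # 390 nt
  prot_long <- sub("\\*$", "", translate_cds(cds_long))
  prot_short <- sub("\\*$", "", translate_cds(cds_short))
  contigs_a <- c(a1 = cds_long, a2 = cds_short)
  contigs_b <- c(b1 = mutate_neutral_test(cds_long, 0.01),
                 b2 = mutate_neutral_test(cds_short, 0.01))
  pairs <- data.frame(contig_a = c("a1", "a2"), contig_b = c("b1", "b2"),
                      pair_id = c("P1", "P2"), stringsAsFactors = FALSE)
  models <- data.frame(protein_id = "sc1",
                       intron_after_residue = c(100L, 200L),
                       intron_length = c(350L, 120L), stringsAsFactors = FALSE)
  res <- mine_single_copy(pairs, contigs_a, contigs_b,
                          c(sc1 = prot_long, sc2 = prot_short),
                          gene_models = models)
  expect_equal(res$reference_gene_id, "sc1")   # short hit (<600 nt) rejected
  expect_equal(res$pair_id, "P1")
  expect_gte(res$hit_span_nt, 600)
  expect_gte(res$identity, 0.75)
  expect_equal(res$introns_ge_300, 1L)         # only the 350-nt intron counts

  # no gene model -> intron count unknown
  res2 <- mine_single_copy(pairs, contigs_a, contigs_b, c(sc1 = prot_long))
  expect_true(is.na(res2$introns_ge_300))
})

test_that("pair consensus takes agreement, species A at conflicts", {
  a <- "ACGTACGTAC"
  b <- "ACGTTCGTAC"
  cons <- pair_consensus(a, b)
  expect_equal(cons$consensus, a)
  expect_equal(cons$n_disagreements, 1)
})
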
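test_that("local nucleotide alignment scores identical and reverse-complement queries", {
  set.seed(2)
  q <- rand_dna(100)
  h <- local_align_nuc(q, q)
  expect_equal(h$score, 100)
  expect_equal(h$identity, 1)
  expect_equal(h$strand, "+")
  expect_equal(c(h$q_start, h$q_end), c(0L, 100L))

  h2 <- local_align_nuc(revcomp(q), q)
  expect_equal(h2$score, 100)
  expect_equal(h2$strand, "-")
  expect_equal(c(h2$q_start, h2$q_end), c(0L, 100L))
})

test_that("local alignment equals the quadratic DP oracle on random sequences", {
  set.seed(3)
  for (case in 1:100) {
    q <- rand_dna(60); s <- rand_dna(60)
    h <- local_align_nuc(q, s)
    expect_equal(h$score, sw_oracle_best(q, s), info = paste("case", case))
  }
})

test_that("translated search finds the right frame on both strands", {
  set.seed(5)
  prot <- "MKLVNNWEDPRA"
  bt <- "ATGAAACTTGTTAATAATTGGGAGGATCCTCGTGCT"  # back-translation
  contig <- paste0("GC", bt, "TTACC")
  h <- translated_search(setNames(prot, "p"), c(c1 = contig))
  expect_equal(h$frame, 3L)
  expect_equal(h$identity, 1)
  expect_equal(substr(contig, h$q_start + 1, h$q_end), bt)

  h2 <- translated_search(setNames(prot, "p"), c(c1 = revcomp(contig)))
  expect_equal(h2$score, h$score)
  expect_lt(h2$frame, 0)
  expect_equal(h2$strand, "-")
})

test_that("best-hit tables break ties by score, length, then subject id", {
  hits <- data.frame(
    query_id = c("q1", "q1", "q2", "q2", "q3"),
    subject_id = c("s1", "s2", "s2", "s1", "s9"),
    score = c(50, 40, 50, 50, 10),
    aln_length = c(60L, 60L, 60L, 60L, 20L), stringsAsFactors = FALSE)
  bh <- best_hit_table(hits)
  expect_equal(unname(bh["q1"]), "s1")   # higher score
  expect_equal(unname(bh["q2"]), "s1")   # tie -> lexicographic
  expect_equal(unname(bh["q3"]), "s9")
  expect_length(best_hit_table(hits[0, ]), 0)
})

test_that("reciprocal best matches pair orthologs, drop orphans, and are symmetric", {
  set.seed(6)
  g1 <- rand_dna(300); g2 <- rand_dna(300)
  mut <- function(s) mutate_neutral_test(s, 0.02)
  set_a <- c(a1 = mut(g1), a2 = mut(g2), a3 = rand_dna(250))  # a3 is an orphan
  set_b <- c(b1 = mut(g1), b2 = mut(g2))
  cfg <- orthodiv_config(min_nuc_score = 30)
  rbm <- reciprocal_best_matches(set_a, set_b, cfg)
  expect_setequal(paste(rbm$contig_a, rbm$contig_b), c("a1 b1", "a2 b2"))
  expect_false("a3" %in% rbm$contig_a)

  # symmetry under species swap
  rbm_swap <- reciprocal_best_matches(set_b, set_a, cfg)
  expect_setequal(paste(rbm_swap$contig_b, rbm_swap$contig_a),
                  paste(rbm$contig_a, rbm$contig_b))

  # each contig appears at most once
  expect_false(anyDuplicated(rbm$contig_a) > 0)
  expect_false(anyDuplicated(rbm$contig_b) > 0)
})

test_that("recent paralogs: only the mutual best copy pairs", {
  set.seed(7)
  g <- rand_dna(400)
  b1 <- mutate_neutral_test(g, 0.01)
  a_close <- mutate_neutral_test(g, 0.01)
  a_far <- mutate_neutral_test(g, 0.12)   # diverged paralog
  set_a <- c(a1 = a_close, a2 = a_far)
  set_b <- c(b1 = b1)
  rbm <- reciprocal_best_matches(set_a, set_b, orthodiv_config(min_nuc_score = 30))
  expect_equal(nrow(rbm), 1)
  expect_equal(rbm$contig_a, "a1")
  # verify against exhaustive scoring
  s_close <- sw_oracle_best(a_close, b1)
  s_far <- sw_oracle_best(a_far, b1)
  expect_gt(s_close, s_far)
})

test_that("prefiltered search equals exact all-vs-all on seeded cases", {
  set.seed(8)
  genes <- replicate(6, rand_dna(300))
  set_a <- setNames(vapply(genes, mutate_neutral_test, "", p = 0.02),
                    paste0("a", 1:6))
  set_b <- setNames(vapply(genes, mutate_neutral_test, "", p = 0.02),
                    paste0("b", 1:6))
  r1 <- reciprocal_best_matches(set_a, set_b, orthodiv_config(kmer_prefilter = TRUE))
  r2 <- reciprocal_best_matches(set_a, set_b, orthodiv_config(kmer_prefilter = FALSE))
  expect_equal(r1, r2)
  expect_equal(nrow(r1), 6)
})

test_that("triangulation keeps same-anchor pairs, drops split anchors, never adds pairs", {
  set.seed(9)
  cds1 <- rand_cds(120); cds2 <- rand_cds(120)
  p1 <- sub("\\*$", "", translate_cds(cds1))
  p2 <- sub("\\*$", "", translate_cds(cds2))
  mut <- function(s) mutate_neutral_test(s, 0.02)
  set_a <- c(a1 = mut(cds1), a2 = mut(cds2))
  set_b <- c(b1 = mut(cds1), b2 = mut(cds2))
  prot <- c(v1 = p1, v2 = p2)
  cfg <- orthodiv_config(min_nuc_score = 30)
  rbm <- reciprocal_best_matches(set_a, set_b, cfg)
  tri <- triangulate(rbm, set_a, set_b, prot, cfg)
  expect_setequal(paste(tri$pairs$contig_a, tri$pairs$contig_b), c("a1 b1", "a2 b2"))
  expect_setequal(tri$pairs$anchor_protein[order(tri$pairs$contig_a)], c("v1", "v2"))
  # output is a subset of input pairs
  expect_true(all(paste(tri$pairs$contig_a, tri$pairs$contig_b) %in%
                    paste(rbm$contig_a, rbm$contig_b)))

  # force an anchor split: a fake RBM pair between unrelated genes
  fake <- data.frame(contig_a = "a1", contig_b = "b2",
                     score = 1, identity = 0.5, aln_length = 100,
                     stringsAsFactors = FALSE)
  tri2 <- triangulate(fake, set_a, set_b, prot, cfg)
  expect_equal(nrow(tri2$pairs), 0)
})
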
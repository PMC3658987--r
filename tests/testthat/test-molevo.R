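test_that("K2P distance matches the closed form and is symmetric", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT")$d, 0)

  a <- strrep("A", 100)
  b <- paste0(strrep("G", 3), strrep("A", 97))  # 3 transitions
  d <- k2p_distance(a, b)
  expect_equal(d$P, 0.03)
  expect_equal(d$Q, 0)
  expect_equal(d$d, -0.5 * log(1 - 2 * 0.03), tolerance = 1e-12)

  set.seed(4)
  x <- rand_dna(300); y <- rand_dna(300)
  expect_equal(k2p_distance(x, y), k2p_distance(y, x))
})

test_that("K2P skips gaps and N, flags saturation, cross-checks against ape", {
  d <- k2p_distance("AC-GTN", "ATCGTA")
  expect_equal(d$n_sites, 4)  # positions 1,2,4,5 (gap and N dropped)
  expect_equal(d$P, 0.25)     # C->T transition at position 2

  sat <- k2p_distance(strrep("A", 10), strrep("G", 10))
  expect_false(sat$defined)
  expect_true(is.na(sat$d))

  skip_if_not_installed("ape")
  set.seed(9)
  x <- rand_dna(500)
  y <- vapply(strsplit(x, "")[[1]], function(b) {
    if (runif(1) < 0.1) sample(c("A", "C", "G", "T"), 1) else b
  }, "")
  y <- paste(y, collapse = "")
  m <- ape::as.DNAbin(rbind(strsplit(tolower(x), "")[[1]],
                            strsplit(tolower(y), "")[[1]]))
  expect_equal(k2p_distance(x, y)$d, as.numeric(ape::dist.dna(m, model = "K80")),
               tolerance = 1e-9)
})

test_that("NG86 handles degenerate pairs and enforces S+N = 3 x codons", {
  cds <- "ATGGCTAAACCC"
  r <- ng86_rates(cds, cds)
  expect_equal(r$Ka, 0); expect_equal(r$Ks, 0)
  expect_equal(r$selection_class, "identical")
  expect_equal(r$S + r$N, 3 * r$n_codons)

  # third-position synonymous change only (GGT -> GGC, both Gly)
  base <- paste0("ATG", strrep("GGT", 8))
  alt <- sub("GGT$", "GGC", base)
  r2 <- ng86_rates(base, alt)
  expect_equal(r2$Nd, 0)
  expect_equal(r2$Ka, 0)
  expect_gt(r2$Ks, 0)
  expect_equal(r2$selection_class, "single-type")
})

test_that("NG86 counts equal the enumeration oracle on random codon pairs", {
  set.seed(11)
  for (case in 1:30) {
    a <- rand_cds(100)
    b <- mutate_neutral_test(a, 0.05)
    r <- ng86_rates(a, b)
    o <- ng86_oracle(a, b)
    expect_equal(r$S, o$S, tolerance = 1e-9)
    expect_equal(r$N, o$N, tolerance = 1e-9)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-9)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-9)
  }
})

test_that("rate methods are symmetric in their two sequences", {
  set.seed(12)
  a <- rand_cds(150)
  b <- mutate_neutral_test(a, 0.04)
  for (f in list(ng86_rates, yn_rates)) {
    r1 <- f(a, b); r2 <- f(b, a)
    expect_equal(r1$Ka, r2$Ka)
    expect_equal(r1$Ks, r2$Ks)
    expect_equal(r1$S, r2$S)
  }
})

test_that("adding a synonymous difference never decreases Ks", {
  # GGA codons: third position fully synonymous
  base <- paste(rep("GGA", 60), collapse = "")
  prev <- ng86_rates(base, base)$Ks
  s <- base
  for (i in 1:5) {
    substr(s, i * 9, i * 9) <- "G"  # GGA -> GGG at codon 3i
    ks <- ng86_rates(base, s)$Ks
    expect_gte(ks, prev)
    prev <- ks
  }
})

test_that("selection classes follow the omega thresholds", {
  expect_equal(classify_selection(list(Sd = 4, Nd = 9, omega = 1.902)),
               "positive")
  expect_equal(classify_selection(list(Sd = 4, Nd = 5, omega = 0.777)),
               "candidate")
  expect_equal(classify_selection(list(Sd = 5, Nd = 2, omega = 0.3)),
               "reference")
  expect_equal(classify_selection(list(Sd = 0, Nd = 0, omega = NA)),
               "identical")
  expect_equal(classify_selection(list(Sd = 0, Nd = 3, omega = NA)),
               "single-type")
})

test_that("Ks summaries report mean, sd, histogram and mode bin", {
  s <- ks_summary(c(0.01, 0.02, 0.03))
  expect_equal(s$mean_ks, 0.02)
  expect_equal(s$n, 3)
  s1 <- ks_summary(0.05)
  expect_equal(s1$sd_ks, 0)
  expect_error(ks_summary(numeric(0)), "Ks")
  s2 <- ks_summary(c(0.026, 0.0261, 0.0262, 0.9), bin_width = 0.005)
  expect_equal(s2$mode_bin[1], 0.025)
})

test_that("divergence dating implements T = K/2r and is linear in K and 1/r", {
  t <- divergence_time(0.027, 0.017, 1.5e-8)
  expect_equal(t$T_years, 0.027 / (2 * 1.5e-8))
  expect_equal(round(t$T_mya, 2), 0.90)
  expect_equal(round(t$T_sd_mya, 2), 0.57)
  expect_equal(divergence_time(0, 0, 1.5e-8)$T_mya, 0)
  expect_equal(divergence_time(0.03, 0, 1.5e-8)$T_mya, 1.0)
  for (K in c(0.01, 0.02, 0.04)) {
    for (r in c(5e-9, 1.5e-8, 3e-8)) {
      expect_equal(divergence_time(K, 0, r)$T_years, K / (2 * r))
      expect_equal(divergence_time(2 * K, 0, r)$T_years,
                   2 * divergence_time(K, 0, r)$T_years)
      expect_equal(divergence_time(K, 0, 2 * r)$T_years,
                   divergence_time(K, 0, r)$T_years / 2)
    }
  }
  expect_error(divergence_time(0.02, 0.01, 0), "r")
})

test_that("K2P agrees with Jukes-Cantor behaviour when P:Q is 1:2 at low divergence", {
  # 300 sites, 3 transitions + 6 transversions -> P = 0.01, Q = 0.02
  a <- strrep("A", 300)
  b <- paste0(strrep("G", 3), strrep("C", 3), strrep("T", 3), strrep("A", 291))
  d <- k2p_distance(a, b)
  p <- 0.03
  jc <- -0.75 * log(1 - 4 / 3 * p)
  expect_lt(abs(d$d - jc), 1e-4)
})
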
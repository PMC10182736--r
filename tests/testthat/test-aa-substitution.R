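test_that("pair counts skip gaps, ambiguity and identical columns", {
  pc <- extractPairCounts("KR", "ER")
  expect_identical(pc$counts, c("E/K" = 1L))
  expect_identical(extractPairCounts("K-R", "KDR")$total_changes, 0L)
  expect_identical(extractPairCounts("KXR", "KDR")$total_changes, 0L)
  expect_identical(extractPairCounts("KDR", "KDR")$total_changes, 0L)
  expect_error(extractPairCounts("KK", "K"), "length")
  ## several alignments are summed
  pc2 <- extractPairCounts(c("KR", "KE"), c("ER", "KD"))
  expect_equal(pc2$total_changes, 2L)
  expect_identical(sort(names(pc2$counts)), c("D/E", "E/K"))
})

test_that("codon routes between K and E are the two A->G changes", {
  p <- singleNtPaths("K", "E")
  expect_setequal(paste(p$codon1, p$codon2), c("AAA GAA", "AAG GAG"))
  expect_identical(unique(p$from), "A")
  expect_identical(unique(p$to), "G")
  expect_equal(nrow(singleNtPaths("W", "K")), 0)
  expect_error(singleNtPaths("K", "K"), "differ")
})

test_that("reachable pair set equals the brute-force codon-pair oracle", {
  expect_identical(reachablePairs(), bruteReachablePairs())
  ## symmetry of the route finder
  for (pair in c("K/E", "W/K", "D/E", "A/V")) {
    aa <- strsplit(pair, "/")[[1]]
    expect_identical(nrow(singleNtPaths(aa[1], aa[2])) > 0,
                     nrow(singleNtPaths(aa[2], aa[1])) > 0)
  }
})

test_that("expected change table: forced mass, exact conservation", {
  ## only AAA codons and only A->G mutations: all weight on K/E
  freqs <- setNames(rep(0, 61), senseCodons())
  freqs["AAA"] <- 1
  m <- mutationMatrix(c("A>G" = 1), normalize = TRUE)
  obs <- c("E/K" = 50L, "A/V" = 50L)
  tab <- expectedChangeTable(freqs, m, obs)
  ## all expectation mass lands on K/E; A/V stays in the comparison set
  ## with expected 0, and the totals are conserved
  expect_equal(tab$expected[tab$pair == "E/K"], 100)
  expect_equal(tab$expected[tab$pair == "A/V"], 0)
  expect_equal(sum(tab$expected), sum(obs))
  ## normalization: expected totals equal observed totals over kept pairs
  set.seed(4)
  freqs2 <- runif(61); freqs2 <- setNames(freqs2 / sum(freqs2), senseCodons())
  obs2 <- setNames(rpois(20, 30) + 1L,
                   sample(reachablePairs(), 20))
  tab2 <- expectedChangeTable(freqs2, transitionBiasedMatrix(2), obs2)
  expect_equal(sum(tab2$expected), sum(obs2[tab2$pair]), tolerance = 1e-9)
})

test_that("expected weights match direct route enumeration", {
  ## uniform codon frequencies and uniform matrix: expected raw weight of
  ## a pair is (number of ordered single-nt routes) x (1/61) x (1/12)
  freqs <- setNames(rep(1 / 61, 61), senseCodons())
  u <- uniformMutationMatrix()
  obs <- setNames(rep(1L, length(reachablePairs())), reachablePairs())
  tab <- expectedChangeTable(freqs, u, obs)
  for (pair in c("E/K", "D/E", "A/V")) {
    aa <- strsplit(pair, "/")[[1]]
    nRoutes <- nrow(singleNtPaths(aa[1], aa[2])) +
      nrow(singleNtPaths(aa[2], aa[1]))
    expect_equal(tab$expected_raw[tab$pair == pair],
                 nRoutes / (61 * 12), tolerance = 1e-12)
  }
})

test_that("log2 O/E per pair and per aggregated class pair", {
  ct <- data.frame(pair = c("E/K", "D/E", "A/V"),
                   observed = c(20, 10, 40),
                   expected_raw = c(1, 1, 2),
                   expected = c(10, 10, 50))
  oe <- log2OE(ct)
  expect_equal(oe$pairs$log2_oe[oe$pairs$pair == "E/K"], 1)
  expect_equal(oe$pairs$log2_oe[oe$pairs$pair == "D/E"], 0)
  ## classes aggregate counts before the ratio
  ba <- oe$classes[oe$classes$class_pair == "acidic/basic", ]
  expect_equal(ba$log2_oe, log2(20 / 10))
  aa <- oe$classes[oe$classes$class_pair == "acidic/acidic", ]
  expect_equal(aa$log2_oe, 0)
  ## minCases filter
  oe5 <- log2OE(ct, minCases = 15)
  expect_setequal(oe5$pairs$pair, c("E/K", "A/V"))
})

test_that("direction inference follows the shared-residue rule", {
  d <- inferDirection("K", "K", "E")
  expect_identical(d$ancestral, "K")
  expect_identical(d$derived, "E")
  expect_identical(d$branch, "sister2")
  ## reference is the odd one out: excluded
  expect_equal(nrow(inferDirection("E", "K", "K")), 0)
  ## all three distinct: excluded
  expect_equal(nrow(inferDirection("K", "E", "R")), 0)
  ## gap in any species excludes the column
  expect_equal(nrow(inferDirection("K", "-", "E")), 0)
  ## multi-column with labels
  d2 <- inferDirection("KAD", "EAD", "KAD", labels = c("sec", "sim"))
  expect_identical(d2$branch, "sec")
  expect_identical(d2$derived, "E")
  expect_error(inferDirection("KK", "K", "K"), "length")
})

test_that("gain/loss tallies move residue classes in opposite directions", {
  ch <- data.frame(column = 1:2, ancestral = c("K", "K"),
                   derived = c("E", "E"), branch = "sister1")
  t1 <- tallyGainLoss(ch)
  expect_equal(t1$classes$gains[t1$classes$class == "acidic"], 2)
  expect_equal(t1$classes$losses[t1$classes$class == "basic"], 2)
  expect_equal(t1$classes$gains[t1$classes$class == "basic"], 0)
  ## hand-built list reproducing published-style tallies:
  ## 11 acidic gains / 4 acidic losses, 7 basic gains / 14 basic losses
  mk <- function(anc, der, n) if (n > 0)
    data.frame(column = seq_len(n), ancestral = anc, derived = der,
               branch = "s") else NULL
  ch2 <- rbind(mk("K", "E", 8), mk("G", "D", 3),   # acidic gains: 11
               mk("E", "G", 4),                    # acidic losses: 4
               mk("A", "K", 7),                    # basic gains: 7
               mk("K", "E", 0), mk("R", "T", 6))   # basic losses: 8+6=14
  t2 <- tallyGainLoss(ch2)
  cls <- setNames(seq_len(nrow(t2$classes)), t2$classes$class)
  expect_equal(t2$classes$gains[cls["acidic"]], 11)
  expect_equal(t2$classes$losses[cls["acidic"]], 4)
  expect_equal(t2$classes$gains[cls["basic"]], 7)
  expect_equal(t2$classes$losses[cls["basic"]], 14)
  ## per-class gains + losses never exceed total changes
  expect_true(all(t2$classes$gains + t2$classes$losses <= 2 * nrow(ch2)))
  ## empty input: all zeros
  t0 <- tallyGainLoss(ch[0, ])
  expect_true(all(t0$classes$gains == 0) && all(t0$classes$losses == 0))
})

test_that("per-pair Fisher enrichment with BH correction", {
  ## identical proportions: p = 1
  res <- pairEnrichmentTest(c("E/K" = 10L, "A/V" = 90L),
                            c("E/K" = 20L, "A/V" = 180L))
  expect_equal(res$p_two_sided[res$pair == "E/K"], 1)
  ## single tested pair: corrected equals raw
  res1 <- pairEnrichmentTest(c("E/K" = 10L, "A/V" = 90L),
                             c("E/K" = 20L, "A/V" = 180L), pairs = "E/K")
  expect_equal(res1$p_adj_two_sided, res1$p_two_sided)
  ## planted 3x enrichment at n = 500 is detected after correction
  set.seed(9)
  bg <- setNames(rep(100L, 10), paste0(LETTERS[1:10], "/Z"))
  focal <- setNames(as.integer(rmultinom(1, 500, c(3, rep(1, 9)))[, 1]),
                    names(bg))
  resP <- pairEnrichmentTest(focal, bg)
  expect_lt(resP$p_adj_two_sided[resP$pair == "A/Z"], 0.05)
  expect_error(pairEnrichmentTest(integer(0), bg), "zero-total")
})

test_that("neutral families leave almost all pair-level O/E ratios flat", {
  cfg <- simConfig(seed = 31, nGenes = 240L, codonsPerGene = 300L,
                   divergence = 0.1, chargeShift = 1,
                   mutationMatrix = uniformMutationMatrix())
  fam <- simulateProteinFamily(cfg)
  pc <- extractPairCounts(fam$alignments$ref, fam$alignments$derived)
  expect_gt(pc$total_changes, 4000)
  tab <- expectedChangeTable(codonFrequencies(fam$ancestralCds),
                             fam$matrix, pc)
  oe <- log2OE(tab)
  lg <- oe$pairs$log2_oe[is.finite(oe$pairs$log2_oe)]
  expect_lte(mean(abs(lg) > 0.5), 0.05)
})
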
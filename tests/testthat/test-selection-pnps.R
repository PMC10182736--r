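test_that("mutation matrix estimation from intronic SNP counts", {
  bases <- c("A", "C", "G", "T")
  types <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  types <- types[types$ref != types$alt, ]
  snps <- data.frame(ref = types$ref, alt = types$alt, context = "intron")
  m <- buildMutationMatrix(snps)
  expect_equal(unname(mutationFreq(m, types$ref, types$alt)),
               rep(1 / 12, 12))
  expect_equal(nSourceSnps(m), 12L)
  ## one extra A->G
  m2 <- buildMutationMatrix(rbind(snps, data.frame(ref = "A", alt = "G",
                                                   context = "intron")))
  expect_equal(unname(mutationFreq(m2, "A", "G")), 2 / 13)
  expect_error(buildMutationMatrix(snps[0, ]), "no intronic SNPs")
})

test_that("mutation matrix round-trips and symmetrizes", {
  set.seed(3)
  v <- runif(12)
  nm <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T")), 1,
              paste, collapse = ">")
  nm <- nm[substr(nm, 1, 1) != substr(nm, 3, 3)]
  m <- mutationMatrix(setNames(v, nm), nSourceSnps = 100L, normalize = TRUE)
  f <- tempfile(fileext = ".tsv")
  writeMutationMatrix(m, f)
  m2 <- readMutationMatrix(f)
  expect_equal(m2@mat, m@mat)
  expect_equal(nSourceSnps(m2), 100L)
  ms <- symmetrizeMatrix(m)
  expect_equal(unname(mutationFreq(ms, "A", "G")),
               unname((mutationFreq(m, "A", "G") + mutationFreq(m, "T", "C")) / 2))
})

test_that("expected PN/PS equals brute-force mutant enumeration", {
  u <- uniformMutationMatrix()
  expect_equal(expectedPnPs("TTT", u)$ratio, 8)
  expect_equal(expectedPnPs("GGG", u)$ratio, 2)
  atg <- expectedPnPs("ATG", u)
  expect_false(atg$defined)
  expect_true(is.na(atg$ratio))
  ## against the enumeration oracle, per codon, uniform matrix
  for (codon in senseCodons()) {
    o <- bruteExpectedPnPs(codon, function(f, t) 1 / 12)
    mine <- expectedPnPs(codon, u)
    expect_equal(mine$EN, o[["EN"]], tolerance = 1e-12)
    expect_equal(mine$ES, o[["ES"]], tolerance = 1e-12)
  }
})

test_that("expected ratio is composition-invariant under duplication", {
  set.seed(11)
  cds <- vapply(1:5, function(i)
    paste(sample(senseCodons(), 50, replace = TRUE), collapse = ""),
    character(1))
  m <- transitionBiasedMatrix(2)
  once <- expectedPnPs(cds, m)
  twice <- expectedPnPs(rep(cds, 2), m)
  expect_equal(twice$ratio, once$ratio, tolerance = 1e-12)
  expect_equal(twice$EN, 2 * once$EN, tolerance = 1e-12)
})

test_that("observed SNPs are scored per codon against the reference", {
  genes <- data.frame(gene_id = "g1", species = "ref", contig = "g1",
                      start = 0L, end = 9L, strand = "+",
                      cds = "AAAAAAGGG")
  snps <- data.frame(contig = "g1", pos = c(2L, 3L), ref = c("A", "A"),
                     alt = c("G", "G"), maf = c(0.3, 0.03),
                     context = "cds", gene_id = "g1")
  ## AAA -> AAG synonymous (pos 3); AAA -> GAA K->E nonsynonymous (pos 1)
  obs <- observedPnPs(snps, genes)
  expect_equal(obs$PS, 1L)
  expect_equal(obs$PN, 1L)
  ## MAF filter at 5% drops the second SNP
  obs5 <- observedPnPs(snps, genes, mafMin = 0.05)
  expect_equal(obs5$PS, 1L)
  expect_equal(obs5$PN, 0L)
  ## disagreeing reference allele errors
  bad <- snps; bad$ref[1] <- "C"
  expect_error(observedPnPs(bad, genes), "disagrees")
})

test_that("minus-strand genes are complemented before codon scoring", {
  ## CDS AAA GGG on the minus strand of a 6-bp contig
  cdsSeq <- "AAAGGG"
  genomic <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cdsSeq)))  # CCCTTT on the + strand
  genes <- data.frame(gene_id = "g1", species = "ref", contig = "c1",
                      start = 0L, end = 6L, strand = "-", cds = cdsSeq)
  ## genomic position 5 (0-based) = CDS position 0; + allele T == A on cds
  snps <- data.frame(contig = "c1", pos = 5L, ref = "T", alt = "C",
                     maf = 0.2, context = "cds", gene_id = "g1")
  obs <- observedPnPs(snps, genes)  # AAA -> GAA: K->E
  expect_equal(obs$PN, 1L)
  expect_equal(obs$PS, 0L)
})

test_that("normalized PN/PS is 1 when observed equals expected", {
  ## all-TTT gene: 8 nonsyn and 1 syn neighbour under the uniform matrix;
  ## 8 nonsyn + 1 syn observed SNPs give exactly the expected ratio
  genes <- data.frame(gene_id = "g1", species = "ref", contig = "g1",
                      start = 0L, end = 9L, strand = "+", cds = "TTTTTTTTT")
  mk <- function(pos, ref, alt) data.frame(contig = "g1", pos = pos,
                                           ref = ref, alt = alt, maf = 0.25,
                                           context = "cds", gene_id = "g1")
  snps <- rbind(mk(0L, "T", "A"), mk(0L, "T", "C"), mk(0L, "T", "G"),
                mk(1L, "T", "A"), mk(1L, "T", "C"), mk(1L, "T", "G"),
                mk(2L, "T", "A"),                   mk(2L, "T", "G"),
                mk(2L, "T", "C"))  # TTC synonymous
  r <- normalizedPnPs(genes, snps, uniformMutationMatrix())
  expect_equal(r$normalized, 1, tolerance = 1e-12)
  expect_true(r$defined)
  ## PS = 0 flags the result as undefined
  r0 <- normalizedPnPs(genes, snps[1:3, ], uniformMutationMatrix())
  expect_false(r0$defined)
  expect_true(is.na(r0$normalized))
})

test_that("subsampling sd is zero for homogeneous groups, seeded otherwise", {
  genes <- do.call(rbind, lapply(1:9, function(i)
    data.frame(gene_id = paste0("g", i), species = "ref",
               contig = paste0("g", i), start = 0L, end = 9L,
               strand = "+", cds = "TTTTTTAAA")))
  snps <- do.call(rbind, lapply(1:9, function(i)
    data.frame(contig = paste0("g", i), pos = c(0L, 2L), ref = "T",
               alt = c("A", "C"), maf = 0.25, context = "cds",
               gene_id = paste0("g", i))))
  sdHom <- subsampleSd(genes, snps, uniformMutationMatrix(), reps = 50,
                       seed = 1)
  expect_equal(sdHom, 0)
  ## heterogeneous: make three genes different
  genes2 <- genes
  genes2$cds[1:3] <- "GGGGGGAAA"
  snps2 <- snps
  snps2$ref[snps2$gene_id %in% c("g1", "g2", "g3") & snps2$pos == 0] <- "G"
  snps2$pos[snps2$gene_id %in% c("g1", "g2", "g3") & snps2$pos == 2] <- 5L
  snps2$ref[snps2$gene_id %in% c("g1", "g2", "g3") & snps2$pos == 5] <- "G"
  sdHet1 <- subsampleSd(genes2, snps2, uniformMutationMatrix(), reps = 50,
                        seed = 1)
  sdHet2 <- subsampleSd(genes2, snps2, uniformMutationMatrix(), reps = 50,
                        seed = 1)
  expect_gt(sdHet1, 0)
  expect_identical(sdHet1, sdHet2)
  expect_error(subsampleSd(genes, snps, uniformMutationMatrix(), reps = 1),
               "at least 2")
  expect_error(subsampleSd(genes[1:2, ], snps, uniformMutationMatrix()),
               "at least 3")
})

test_that("branch pooling follows the yeast and flies schemes", {
  cl <- data.frame(gene_id = paste0("g", 1:4), og_id = "OG",
                   klass = c("putative_de_novo", "putative_de_novo",
                             "conserved", "putative_de_novo"),
                   birth_branch = c("N3", "N0", NA, "N5"))
  pooled <- groupPool(cl, "yeast")
  expect_identical(pooled$group, c("N1-N4", "N0", "conserved", "N5"))
  clF <- data.frame(gene_id = "g1", og_id = "OG", klass = "putative_de_novo",
                    birth_branch = "N6")
  expect_identical(groupPool(clF, "flies")$group, "N6")
  expect_error(groupPool(clF, "yeast"), "not covered")
  ## passthrough
  expect_identical(groupPool(cl, "none")$group,
                   c("N3", "N0", "conserved", "N5"))
  ## custom scheme
  expect_identical(
    groupPool(cl, list(young = c("N0", "N3"), old = "N5"))$group,
    c("young", "young", "conserved", "old"))
})
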
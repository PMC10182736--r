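ogText <- paste(
  "Orthogroup\tspA\tspB",
  "OG1\tg1, g2\tg3",
  "OG2\tg4\t",
  sep = "\n")

test_that("orthogroups parse to long form, empty cells omitted", {
  og <- parseOrthogroups(ogText)
  expect_identical(og$gene_id[og$og_id == "OG1" & og$species == "spA"],
                   c("g1", "g2"))
  expect_identical(og$gene_id[og$og_id == "OG1" & og$species == "spB"], "g3")
  expect_false("spB" %in% og$species[og$og_id == "OG2"])
  ## duplicate gene across rows
  bad <- paste("Orthogroup\tspA", "OG1\tg1", "OG2\tg1", sep = "\n")
  expect_error(parseOrthogroups(bad), "more than one orthogroup")
})

test_that("orthogroups round-trip through write/parse", {
  og <- parseOrthogroups(ogText)
  f <- tempfile(fileext = ".tsv")
  writeOrthogroups(og, f)
  expect_identical(parseOrthogroups(f), og)
})

dupText <- paste(
  "Orthogroup\tSpecies Tree Node\tSupport\tGenes 1\tGenes 2",
  "OG1\tN1\t0.9\tg1\tg2, g3",
  "OG2\tN0\t1.0\tg4\tg5",
  sep = "\n")

test_that("duplications parse with fractional support", {
  dup <- parseDuplications(dupText)
  expect_equal(dup$support, c(0.9, 1.0))
  expect_identical(dup$genes2[[1]], c("g2", "g3"))
  bad <- paste("Orthogroup\tSpecies Tree Node\tSupport\tGenes 1\tGenes 2",
               "OG1\tN1\t0.9\tg1\t", sep = "\n")
  expect_error(parseDuplications(bad), "empty descendant")
  f <- tempfile(fileext = ".tsv")
  writeDuplications(dup, f)
  expect_identical(parseDuplications(f)$genes2, dup$genes2)
})

test_that("homology hits: 12-column tabular with E-value in column 11", {
  txt <- "g1\tOutg1|h1\t90\t50\t5\t0\t1\t50\t1\t50\t1e-05\t100"
  hits <- parseHomologyHits(txt)
  expect_identical(hits$subject_species, "Outg1")
  expect_identical(hits$subject_gene, "h1")
  expect_equal(hits$e_value, 1e-5)
  f <- tempfile()
  writeHomologyHits(hits, f)
  expect_identical(parseHomologyHits(f), hits)
})

mkIso <- function(gene, tx, start, nCodons, strand = "+", contig = "chr1",
                  body = "GCT") {
  cds <- paste0("ATG", paste(rep(body, nCodons - 2L), collapse = ""), "TAA")
  data.frame(gene_id = gene, transcript_id = tx, species = "ref",
             contig = contig, start = start, end = start + 3L * nCodons,
             strand = strand, cds = cds)
}

test_that("proteome preparation keeps the longest valid isoform", {
  iso <- rbind(mkIso("gA", "t1", 0L, 102),    # 300-bp protein part
               mkIso("gA", "t2", 0L, 42))
  prep <- prepareProteome(iso)
  expect_identical(prep$transcript_id, "t1")
  expect_equal(nchar(prep$protein), 101)
  ## internal stop codon discarded
  bad <- mkIso("gB", "t3", 2000L, 10)
  bad$cds <- "ATGTAAAAATGA"
  bad$end <- bad$start + nchar(bad$cds)
  prep2 <- prepareProteome(rbind(mkIso("gA", "t1", 0L, 102), bad))
  expect_false("gB" %in% prep2$gene_id)
  ## equal-length tie: smallest transcript id, flagged
  tie <- rbind(mkIso("gC", "tB", 0L, 30), mkIso("gC", "tA", 5000L, 30))
  prepTie <- prepareProteome(tie)
  expect_identical(prepTie$transcript_id, "tA")
  expect_true(prepTie$length_tie)
})

test_that("overlap removal is asymmetric: own-length denominator", {
  ## P spans 99 bp, Q spans 999 bp, overlap 21 bp on the same strand:
  ## 21/99 > 10% removes P; 21/999 <= 10% keeps Q
  p <- mkIso("gP", "tP", 1000L, 33)
  q <- mkIso("gQ", "tQ", 1078L, 333)
  prep <- prepareProteome(rbind(p, q))
  expect_identical(prep$gene_id, "gQ")
  ## opposite strands: both kept
  q2 <- q; q2$strand <- "-"
  expect_setequal(prepareProteome(rbind(p, q2))$gene_id, c("gP", "gQ"))
})

test_that("proteome preparation is idempotent", {
  set.seed(42)
  iso <- do.call(rbind, lapply(1:20, function(i)
    mkIso(sprintf("g%02d", i), sprintf("t%02d", i),
          as.integer(sample.int(3000, 1)), sample(20:60, 1))))
  once <- prepareProteome(iso)
  twice <- prepareProteome(once)
  rownames(once) <- rownames(twice) <- NULL
  expect_identical(twice, once)
})

test_that("SNP parsing assigns context and splits multi-allelics", {
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  S4Vectors::mcols(cds)$gene_id <- "g1"
  introns <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 400))
  snpTxt <- paste("contig\tpos\tref\talt\tmaf",
                  "chr1\t150\tA\tG,T\t0.2",   # cds, multi-allelic
                  "chr1\t350\tC\tT\t0.1",     # intron
                  "chr1\t500\tG\tA\t0.3",     # neither: dropped
                  sep = "\n")
  snps <- parseSnps(snpTxt, cds, introns)
  expect_equal(nrow(snps), 3)
  expect_identical(snps$context, c("cds", "cds", "intron"))
  expect_identical(snps$alt[1:2], c("G", "T"))
  expect_identical(snps$gene_id[1], "g1")
  expect_equal(snps$pos[1], 149)  # 0-based internally

  ## intron position overlapping an exon of another gene is excluded
  cds2 <- c(cds, GenomicRanges::GRanges("chr1", IRanges::IRanges(340, 360),
                                        gene_id = "g2"))
  ## the CDS hit wins the context; make the overlap exon-only instead
  exonOnly <- GenomicRanges::GRanges("chr1", IRanges::IRanges(340, 360))
  S4Vectors::mcols(exonOnly)$gene_id <- "g2"
  snps2 <- parseSnps("contig\tpos\tref\talt\tmaf\nchr1\t350\tC\tT\t0.1",
                     exonOnly, introns)
  expect_identical(snps2$context, "cds")  # assigned to the exon, not intron

  expect_error(parseSnps("contig\tpos\tref\talt\tmaf\nchr1\t10\tAC\tA\t0.1",
                         cds, introns), "indel")
  expect_error(parseSnps("contig\tpos\tref\talt\tmaf\nchr1\t10\tA\tA\t0.1",
                         cds, introns), "identical")
})

test_that("SNP tables round-trip through write/parse", {
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
                                gene_id = "g1")
  introns <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 400))
  snps <- parseSnps(paste("contig\tpos\tref\talt\tmaf",
                          "chr1\t150\tA\tG\t0.2",
                          "chr1\t350\tC\tT\t0.1", sep = "\n"),
                    cds, introns)
  f <- tempfile(fileext = ".tsv")
  writeSnps(snps, f)
  expect_identical(parseSnps(f, cds, introns), snps)
})

test_that("TPM conversion always totals one million", {
  expect_equal(unname(countsToTpm(c(g1 = 5, g2 = 5),
                                  c(g1 = 100, g2 = 100))),
               c(5e5, 5e5))
  expect_equal(unname(countsToTpm(c(g1 = 7), c(g1 = 123))), 1e6)
  tpm <- countsToTpm(c(g1 = 10, g2 = 10), c(g1 = 100, g2 = 200))
  expect_equal(unname(tpm[["g1"]]), 2e6 / 3, tolerance = 1e-9)
  set.seed(1)
  rnd <- countsToTpm(setNames(rpois(50, 100), paste0("g", 1:50)),
                     setNames(sample(200:2000, 50), paste0("g", 1:50)))
  expect_equal(sum(rnd), 1e6, tolerance = 1e-6)
  expect_error(countsToTpm(c(g1 = 1), c(g1 = 0)), "zero")
})

test_that("ORF extraction: NTG starts, in-frame stop required", {
  body <- paste(rep("GCT", 30), collapse = "")
  expect_identical(extractOrfs(paste0("ATG", body, "TAA")),
                   paste0("M", paste(rep("A", 30), collapse = "")))
  ## no in-frame stop: nothing emitted
  expect_length(extractOrfs(paste0("ATG", body)), 0)
  ## CTG start accepted, translated literally
  expect_identical(substr(extractOrfs(paste0("CTG", body, "TAA")), 1, 1), "L")
  ## nested ORFs sharing a stop: only the longest kept
  nested <- paste0("ATG", "GCT", "ATG", body, "TGA")
  orfs <- extractOrfs(nested)
  expect_length(orfs, 1)
  expect_equal(nchar(orfs), 33)  # from the upstream start
  ## minimum length
  expect_length(extractOrfs("ATGGCTGCTTAA"), 0)        # 3 aa < 10
  expect_length(extractOrfs("ATGGCTGCTTAA", minAa = 3), 1)
})

test_that("VCF input: context, MAF from INFO AF, 0-based conversion", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t150\t.\tA\tG\t.\t.\tAF=0.2",
               "chr1\t350\t.\tC\tT\t.\t.\tAF=0.9"), f)
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
                                gene_id = "g1")
  introns <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 400))
  snps <- parseSnps(f, cds, introns)
  expect_equal(nrow(snps), 2)
  expect_identical(snps$context, c("cds", "intron"))
  expect_equal(snps$maf, c(0.2, 0.1))  # minor allele side of AF
  expect_equal(snps$pos, c(149L, 349L))
})
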
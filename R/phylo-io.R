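## Readers/writers for the tabular dialects around orthology inference,
## annotation-preparation filters and small plumbing conversions.

.splitGeneList <- function(x) {
  x <- trimws(unlist(strsplit(x, ",", fixed = TRUE)))
  x[nzchar(x)]
}

#' Parse an orthogroups table
#'
#' Reads the wide tab-separated orthogroups dialect (first column
#' `Orthogroup`, one column per species holding comma-separated gene
#' lists) into a long data.frame. Empty cells mean the species has no
#' member. A gene appearing in two orthogroups is an error.
#'
#' @param x file path or literal TSV text.
#' @return data.frame with columns `og_id`, `species`, `gene_id`.
#' @export
parseOrthogroups <- function(x) {
  df <- read.delim(text = paste(.readLinesMaybe(x), collapse = "\n"),
                   check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("orthogroups table needs a header of species names")
  species <- names(df)[-1]
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    rows <- lapply(species, function(sp) {
      g <- .splitGeneList(df[i, sp])
      if (length(g) == 0L) return(NULL)
      data.frame(og_id = df[i, 1], species = sp, gene_id = g)
    })
    do.call(rbind, rows)
  }))
  if (is.null(out)) out <- data.frame(og_id = character(), species = character(),
                                      gene_id = character())
  dup <- duplicated(out$gene_id)
  if (any(dup))
    stop("gene(s) listed in more than one orthogroup/cell: ",
         paste(unique(out$gene_id[dup]), collapse = ", "))
  rownames(out) <- NULL
  out
}

#' @rdname parseOrthogroups
#' @param og long data.frame as returned by `parseOrthogroups`.
#' @param path output file.
#' @param species optional column order; defaults to order of appearance.
#' @export
writeOrthogroups <- function(og, path, species = NULL) {
  if (is.null(species)) species <- unique(og$species)
  ogs <- unique(og$og_id)
  wide <- data.frame(Orthogroup = ogs, check.names = FALSE)
  for (sp in species) {
    wide[[sp]] <- vapply(ogs, function(o)
      paste(og$gene_id[og$og_id == o & og$species == sp], collapse = ", "),
      character(1))
  }
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a per-branch duplications table
#'
#' Reads the tab-separated duplications dialect with columns
#' `Orthogroup`, `Species Tree Node`, `Support`, `Genes 1`, `Genes 2`.
#' Support values are fractions in [0, 1]; both descendant gene lists
#' must be nonempty.
#'
#' @param x file path or literal TSV text.
#' @return data.frame with columns `og_id`, `node`, `support` and list
#'   columns `genes1`, `genes2`.
#' @export
parseDuplications <- function(x) {
  df <- read.delim(text = paste(.readLinesMaybe(x), collapse = "\n"),
                   check.names = FALSE, colClasses = "character")
  need <- c("Orthogroup", "Species Tree Node", "Support", "Genes 1", "Genes 2")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  support <- as.numeric(df$Support)
  if (anyNA(support) || any(support < 0 | support > 1))
    stop("support must be a fraction in [0, 1]")
  g1 <- lapply(df[["Genes 1"]], .splitGeneList)
  g2 <- lapply(df[["Genes 2"]], .splitGeneList)
  if (any(lengths(g1) == 0L) || any(lengths(g2) == 0L))
    stop("duplication record with empty descendant gene list")
  out <- data.frame(og_id = df$Orthogroup, node = df[["Species Tree Node"]],
                    support = support)
  out$genes1 <- g1
  out$genes2 <- g2
  out
}

#' @rdname parseDuplications
#' @param dup data.frame as returned by `parseDuplications`.
#' @param path output file.
#' @export
writeDuplications <- function(dup, path) {
  wide <- data.frame(
    Orthogroup = dup$og_id,
    `Species Tree Node` = dup$node,
    Support = dup$support,
    `Genes 1` = vapply(dup$genes1, paste, character(1), collapse = ", "),
    `Genes 2` = vapply(dup$genes2, paste, character(1), collapse = ", "),
    check.names = FALSE)
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse homology hits (12-column blast tabular dialect)
#'
#' Column 11 is the E-value. The subject species is recovered from the
#' subject id, by default the part before a `|` separator
#' (`species|gene`).
#'
#' @param x file path or literal text (no header).
#' @param subjectSpeciesOf function mapping subject ids to species names.
#' @return data.frame with columns `query_gene`, `subject_species`,
#'   `subject_gene`, `e_value`.
#' @export
parseHomologyHits <- function(x, subjectSpeciesOf = function(id)
                                sub("\\|.*$", "", id)) {
  df <- read.delim(text = paste(.readLinesMaybe(x), collapse = "\n"),
                   header = FALSE, colClasses = "character")
  if (ncol(df) != 12L) stop("expected 12 tab-separated columns, got ", ncol(df))
  ev <- as.numeric(df[[11]])
  if (anyNA(ev) || any(ev < 0)) stop("invalid E-value")
  data.frame(query_gene = df[[1]],
             subject_species = vapply(df[[2]], subjectSpeciesOf, character(1),
                                      USE.NAMES = FALSE),
             subject_gene = sub("^[^|]*\\|", "", df[[2]]),
             e_value = ev)
}

#' @rdname parseHomologyHits
#' @param hits data.frame as returned by `parseHomologyHits`.
#' @param path output file.
#' @export
writeHomologyHits <- function(hits, path) {
  n <- nrow(hits)
  out <- data.frame(hits$query_gene,
                    paste(hits$subject_species, hits$subject_gene, sep = "|"),
                    rep(100, n), rep(50, n), rep(0, n), rep(0, n),
                    rep(1, n), rep(50, n), rep(1, n), rep(50, n),
                    hits$e_value, rep(100, n))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.parseSnpTable <- function(x) {
  if (length(x) == 1L && grepl("\\.vcf$", x, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(x, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                         stringsAsFactors = FALSE)
    info <- fix$INFO
    af <- suppressWarnings(as.numeric(sub("^.*AF=([0-9.eE+-]+).*$", "\\1",
                                          ifelse(grepl("AF=", info), info, NA))))
    data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT,
               maf = pmin(af, 1 - af))
  } else {
    df <- read.delim(text = paste(.readLinesMaybe(x), collapse = "\n"),
                     colClasses = "character")
    names(df)[1:4] <- c("contig", "pos", "ref", "alt")
    if (!"maf" %in% names(df)) df$maf <- NA
    data.frame(contig = df$contig, pos = as.integer(df$pos),
               ref = df$ref, alt = df$alt, maf = as.numeric(df$maf))
  }
}

#' Parse SNPs and assign CDS/intron context
#'
#' Accepts a VCF (SNP subset) or a 5-column TSV (contig, pos, ref, alt,
#' maf) with 1-based positions; positions are stored 0-based internally.
#' Multi-allelic records are split into one record per alternate allele.
#' Indels are rejected. A SNP overlapping a CDS interval gets context
#' `"cds"` (with the gene id); a SNP inside an intron interval that does
#' not overlap any exonic interval gets context `"intron"`; intronic
#' positions overlapping an exon of any gene are dropped, as are SNPs in
#' neither set.
#'
#' @param x VCF/TSV path or literal TSV text.
#' @param cdsRanges [GenomicRanges::GRanges] of CDS/exon intervals with a
#'   `gene_id` metadata column.
#' @param intronRanges [GenomicRanges::GRanges] of intron intervals.
#' @return data.frame with columns `contig`, `pos` (0-based), `ref`,
#'   `alt`, `maf`, `context`, `gene_id`.
#' @export
parseSnps <- function(x, cdsRanges, intronRanges) {
  df <- .parseSnpTable(x)
  ## multi-allelic split
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  df <- df[rep(seq_len(nrow(df)), lengths(alts)), , drop = FALSE]
  df$alt <- unlist(alts)
  if (any(nchar(df$ref) != 1L | nchar(df$alt) != 1L))
    stop("indels are not supported")
  bad <- !(df$ref %in% DNA_BASES) | !(df$alt %in% DNA_BASES)
  if (any(bad)) stop("non-ACGT allele")
  if (any(df$ref == df$alt)) stop("ref and alt alleles are identical")
  if (any(!is.na(df$maf) & (df$maf < 0 | df$maf > 0.5)))
    stop("minor allele frequency outside [0, 0.5]")
  gr <- GenomicRanges::GRanges(df$contig,
          IRanges::IRanges(start = df$pos, width = 1L))
  inCds <- GenomicRanges::findOverlaps(gr, cdsRanges, select = "first")
  inIntron <- !is.na(GenomicRanges::findOverlaps(gr, intronRanges,
                                                 select = "first"))
  df$pos <- df$pos - 1L  # 0-based internal
  df$context <- NA_character_
  df$gene_id <- NA_character_
  cds <- !is.na(inCds)
  df$context[cds] <- "cds"
  df$gene_id[cds] <- S4Vectors::mcols(cdsRanges)$gene_id[inCds[cds]]
  df$context[!cds & inIntron] <- "intron"
  df <- df[!is.na(df$context), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname parseSnps
#' @param snps SNP data.frame (internal 0-based positions).
#' @param path output TSV (written back with 1-based positions).
#' @export
writeSnps <- function(snps, path) {
  out <- snps
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-model intervals from a GFF3 subset
#'
#' Imports a GFF3 file (via rtracklayer) and returns the `GRanges` of the
#' requested feature type with a `gene_id` column. Only CDS/exon/intron
#' features are supported.
#' @param path GFF3 file.
#' @param feature one of `"CDS"`, `"exon"`, `"intron"`.
#' @export
readFeatureRanges <- function(path, feature = "CDS") {
  stopifnot(feature %in% c("CDS", "exon", "intron"))
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) == feature]
  id <- if (!is.null(gr$gene_id)) gr$gene_id else
    if (!is.null(gr$Parent)) as.character(gr$Parent) else gr$ID
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = as.character(id))
  gr
}

.validCds <- function(cds) {
  ok <- nchar(cds) %% 3L == 0L & nchar(cds) >= 6L & startsWith(cds, "ATG")
  for (i in which(ok)) {
    codons <- .splitCodons(cds[i])
    last <- codons[length(codons)]
    internal <- codons[-length(codons)]
    ok[i] <- (last %in% STOP_CODONS) && !any(internal %in% STOP_CODONS) &&
      all(strsplit(cds[i], "")[[1]] %in% DNA_BASES)
  }
  ok
}

#' Prepare an annotated proteome
#'
#' Applies the annotation-preparation filters: discard isoforms whose CDS
#' does not start with ATG, does not end with a stop codon, or contains
#' an internal stop; keep the longest protein per gene (ties broken by
#' lexicographically smallest transcript id and flagged); remove any
#' protein whose genomic span overlaps another same-strand protein by
#' more than 10% of its own length (the rule is per protein and
#' asymmetric, so of an unequal pair only the small one may go, and both
#' can go if both exceed the threshold).
#'
#' @param isoforms data.frame with columns `gene_id`, `transcript_id`,
#'   `species`, `contig`, `start`, `end` (0-based half-open), `strand`,
#'   `cds`.
#' @param maxOverlap overlap fraction above which a protein is removed.
#' @return one-row-per-gene data.frame with the translated `protein`
#'   column and a `length_tie` flag.
#' @export
prepareProteome <- function(isoforms, maxOverlap = 0.10) {
  iso <- isoforms[.validCds(isoforms$cds), , drop = FALSE]
  if (nrow(iso) == 0L)
    return(cbind(isoforms[0, , drop = FALSE],
                 protein = character(), length_tie = logical()))
  iso$protein <- translateCds(iso$cds)
  ## longest isoform per gene; ties -> smallest transcript_id, flagged
  iso <- iso[order(iso$gene_id, -nchar(iso$protein), iso$transcript_id), ]
  firstIdx <- which(!duplicated(iso$gene_id))
  tie <- vapply(firstIdx, function(i) {
    i < nrow(iso) && iso$gene_id[i + 1L] == iso$gene_id[i] &&
      nchar(iso$protein[i + 1L]) == nchar(iso$protein[i])
  }, logical(1))
  genes <- iso[firstIdx, , drop = FALSE]
  genes$length_tie <- tie
  ## same-strand genomic overlap filter, per protein's own span
  gr <- GenomicRanges::GRanges(genes$contig,
          IRanges::IRanges(start = genes$start + 1L, end = genes$end),
          strand = genes$strand)
  ov <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
  ov <- ov[S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)]
  drop <- rep(FALSE, nrow(genes))
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr)[S4Vectors::queryHits(ov)],
      IRanges::ranges(gr)[S4Vectors::subjectHits(ov)]))
    frac <- w / IRanges::width(gr)[S4Vectors::queryHits(ov)]
    drop[unique(S4Vectors::queryHits(ov)[frac > maxOverlap])] <- TRUE
  }
  out <- genes[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert read counts to TPM
#'
#' Transcripts per million: per-gene count/length rates rescaled so the
#' total is 1e6.
#' @param counts named numeric vector of read counts.
#' @param lengths named numeric vector of transcript lengths (nt), names
#'   matching `counts`.
#' @return named numeric vector of TPM values summing to 1e6.
#' @export
countsToTpm <- function(counts, lengths) {
  lengths <- lengths[names(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) stop("missing or zero gene length")
  rate <- counts / lengths
  rate / sum(rate) * 1e6
}

#' Extract ORFs from a transcript
#'
#' Scans the three forward frames for open reading frames running from an
#' NTG start codon to the first in-frame stop. ORFs without an in-frame
#' stop are not emitted; nested ORFs sharing a stop keep only the longest
#' (the most upstream start). Start codons are translated literally.
#'
#' @param transcript nucleotide sequence.
#' @param startCodons allowed start codons.
#' @param minAa minimum peptide length (start codon included).
#' @return character vector of peptides.
#' @export
extractOrfs <- function(transcript,
                        startCodons = c("ATG", "CTG", "TTG", "GTG"),
                        minAa = 10L) {
  peptides <- character(0)
  n <- nchar(transcript)
  for (off in 0:2) {
    len <- ((n - off) %/% 3L) * 3L
    if (len < 3L) next
    codons <- .splitCodons(substr(transcript, off + 1L, off + len))
    known <- codons %in% names(geneticCode())
    isStop <- known & codons %in% STOP_CODONS
    prevStop <- 0L
    for (s in which(isStop)) {
      seg <- (prevStop + 1L):(s - 1L)
      prevStop <- s
      if (length(seg) == 0L || seg[1] > seg[length(seg)]) next
      starts <- seg[codons[seg] %in% startCodons]
      if (length(starts) == 0L) next
      orf <- codons[starts[1]:(s - 1L)]
      if (length(orf) >= minAa && all(orf %in% names(geneticCode())))
        peptides <- c(peptides, paste(.translateCodons(orf), collapse = ""))
    }
  }
  peptides
}
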
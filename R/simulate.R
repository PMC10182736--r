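## Seeded generators producing inputs with the statistical structure the
## downstream stages assume, together with ground-truth tables for
## recovery tests. One top-level seed; each generator derives its own
## child seed so modules can be regenerated independently.

#' Simulation configuration
#'
#' Collects the parameters of the four generators. Defaults describe a
#' small but realistic study: a yeast-like 11-species tree, two expected
#' birth events per branch and mechanism, composition-controlled CDS of
#' 300 codons, a transition-biased mutational spectrum (kappa = 2) and a
#' deep SNP panel (10,000 coding + 20,000 intronic SNPs).
#'
#' @param seed top-level integer seed.
#' @param tree `"yeast11-like"`, `"flies16-like"` or a
#'   [SpeciesTree-class].
#' @param denovoRate,dupRate expected birth events per branch (Poisson).
#' @param lossProb per-lineage per-family loss probability for de novo
#'   families (the reference copy is never lost: the analysis is
#'   reference-centric).
#' @param nConserved conserved (outgroup-supported, full-depth) families.
#' @param nContaminants clade-restricted families with outgroup homology
#'   planted to exercise the outgroup filter.
#' @param nWgd conserved reference genes listed as WGD-derived.
#' @param denovoDupFrac fraction of de novo families that subsequently
#'   duplicate.
#' @param codonFreqs frequency vector over the 61 sense codons
#'   (uniform by default).
#' @param mutationMatrix a [MutationMatrix-class];
#'   [transitionBiasedMatrix()] by default.
#' @param purifyingFactor f, the acceptance probability of a
#'   nonsynonymous SNP relative to a synonymous one (1 = neutral).
#' @param nGenes,codonsPerGene,nSnps,nIntronSnps,intronLength CDS/SNP
#'   panel dimensions.
#' @param divergence per-codon substitution probability for protein
#'   families (low-divergence regime: at most one change per codon).
#' @param chargeShift s, multiplier on the acceptance of basic->acidic
#'   amino-acid changes (1 = neutral).
#' @param genomeLength,nInsertions,insertionLength,pointMutationRate
#'   genome-pair generator: length of genome A, number/length of
#'   unrelated insertions in B, per-base mutation rate inside conserved
#'   segments.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      tree = "yeast11-like",
                      denovoRate = 2, dupRate = 2, lossProb = 0,
                      nConserved = 20L, nContaminants = 2L, nWgd = 2L,
                      denovoDupFrac = 0.1,
                      codonFreqs = NULL,
                      mutationMatrix = transitionBiasedMatrix(2),
                      purifyingFactor = 1,
                      nGenes = 500L, codonsPerGene = 300L,
                      nSnps = 10000L, nIntronSnps = 20000L,
                      intronLength = 100000L,
                      divergence = 0.05, chargeShift = 1,
                      genomeLength = 6000L, nInsertions = 3L,
                      insertionLength = 400L, pointMutationRate = 0) {
  if (is.null(codonFreqs))
    codonFreqs <- setNames(rep(1 / 61, 61), senseCodons())
  stopifnot(abs(sum(codonFreqs) - 1) < 1e-9,
            all(codonFreqs >= 0),
            denovoRate >= 0, dupRate >= 0,
            lossProb >= 0, lossProb <= 1,
            purifyingFactor > 0, divergence >= 0, divergence <= 1,
            chargeShift > 0)
  cfg <- list(seed = as.integer(seed), tree = tree,
              denovoRate = denovoRate, dupRate = dupRate,
              lossProb = lossProb, nConserved = as.integer(nConserved),
              nContaminants = as.integer(nContaminants),
              nWgd = as.integer(nWgd), denovoDupFrac = denovoDupFrac,
              codonFreqs = codonFreqs, mutationMatrix = mutationMatrix,
              purifyingFactor = purifyingFactor,
              nGenes = as.integer(nGenes),
              codonsPerGene = as.integer(codonsPerGene),
              nSnps = as.integer(nSnps),
              nIntronSnps = as.integer(nIntronSnps),
              intronLength = as.integer(intronLength),
              divergence = divergence, chargeShift = chargeShift,
              genomeLength = as.integer(genomeLength),
              nInsertions = as.integer(nInsertions),
              insertionLength = as.integer(insertionLength),
              pointMutationRate = pointMutationRate)
  class(cfg) <- "SimConfig"
  cfg
}

.simTree <- function(cfg) {
  if (inherits(cfg$tree, "SpeciesTree")) return(cfg$tree)
  switch(cfg$tree,
         "yeast11-like" = yeastTree(),
         "flies16-like" = fliesTree(),
         stop("unknown tree preset: ", cfg$tree))
}

.randomSeq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Simulate gene family histories on the species tree
#'
#' Generates orthogroups, duplication records, outgroup homology hits, a
#' WGD exclusion list and a ground-truth table. A gene born de novo on
#' branch B is present, absent losses, in exactly the species of B's
#' clade; duplication events emit records at their true branch with
#' support 1.0; conserved and contaminant families carry hits in two
#' outgroup species at E = 1e-10 so the outgroup filter is exercised.
#'
#' @param cfg a [simConfig()].
#' @return list: `orthogroups`, `duplications`, `hits`, `wgdGenes`,
#'   `truth` (one row per reference gene: gene_id, og_id, mechanism,
#'   birth_branch, n_losses), `tree`.
#' @export
simulateGeneHistories <- function(cfg) {
  tree <- .simTree(cfg)
  if (length(allSpecies(tree)) == 0L) stop("empty species tree")
  set.seed(.childSeed(cfg$seed, 1L))
  labs <- branchLabels(tree)
  refSp <- cladeSpecies(tree, "N0")[1]
  ogRows <- list(); dupRows <- list(); hitRows <- list(); truthRows <- list()
  wgdGenes <- character(0)
  gCount <- 0L
  newGene <- function(sp) {
    gCount <<- gCount + 1L
    sprintf("%s_g%04d", sp, gCount)
  }
  ogCount <- 0L
  newOg <- function() {
    ogCount <<- ogCount + 1L
    sprintf("OG%04d", ogCount)
  }
  addFamily <- function(species, nRefCopies = 1L) {
    og <- newOg()
    species <- unique(species)
    rows <- data.frame(og_id = og, species = species,
                       gene_id = vapply(species, newGene, character(1)))
    if (nRefCopies > 1L)
      rows <- rbind(rows, data.frame(
        og_id = og, species = rep(refSp, nRefCopies - 1L),
        gene_id = vapply(rep(refSp, nRefCopies - 1L), newGene, character(1))))
    ogRows[[length(ogRows) + 1L]] <<- rows
    rows
  }
  addHits <- function(geneIds) {
    hitRows[[length(hitRows) + 1L]] <<- data.frame(
      query_gene = rep(geneIds, each = 2L),
      subject_species = rep(c("Outg1", "Outg2"), length(geneIds)),
      subject_gene = paste0("og_hit_", seq_len(2L * length(geneIds))),
      e_value = 1e-10)
  }
  refGenesOf <- function(rows) rows$gene_id[rows$species == refSp]

  ## conserved families (some listed as WGD-derived)
  for (i in seq_len(cfg$nConserved)) {
    rows <- addFamily(allSpecies(tree))
    addHits(refGenesOf(rows))
    mech <- if (i <= cfg$nWgd) "excluded_wgd" else "conserved"
    if (mech == "excluded_wgd") wgdGenes <- c(wgdGenes, refGenesOf(rows))
    truthRows[[length(truthRows) + 1L]] <- data.frame(
      gene_id = refGenesOf(rows), og_id = rows$og_id[1], mechanism = mech,
      birth_branch = NA_character_, n_losses = 0L)
  }
  ## contaminant families: clade-restricted but with outgroup homology
  for (i in seq_len(cfg$nContaminants)) {
    lab <- labs[sample.int(length(labs) - 1L, 1L)]  # strictly inside clade
    rows <- addFamily(cladeSpecies(tree, lab))
    addHits(refGenesOf(rows))
    truthRows[[length(truthRows) + 1L]] <- data.frame(
      gene_id = refGenesOf(rows), og_id = rows$og_id[1],
      mechanism = "removed_outgroup_homology",
      birth_branch = NA_character_, n_losses = 0L)
  }
  ## per-branch birth events
  for (li in seq_along(labs)) {
    lab <- labs[li]
    clade <- cladeSpecies(tree, lab)
    ## de novo births
    for (e in seq_len(rpois(1L, cfg$denovoRate))) {
      keep <- clade == refSp | runif(length(clade)) >= cfg$lossProb
      species <- clade[keep]
      dupped <- runif(1) < cfg$denovoDupFrac
      rows <- addFamily(species, nRefCopies = if (dupped) 2L else 1L)
      refGenes <- refGenesOf(rows)
      if (dupped) {
        dupLab <- labs[sample.int(li, 1L)]
        dupRows[[length(dupRows) + 1L]] <- data.frame(
          og_id = rows$og_id[1], node = dupLab, support = 1.0,
          genes1 = I(list(refGenes[1])), genes2 = I(list(refGenes[2])))
      }
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        gene_id = refGenes, og_id = rows$og_id[1],
        mechanism = if (dupped) "de_novo_plus_duplicated"
                    else "putative_de_novo",
        birth_branch = lab, n_losses = sum(!keep))
    }
    ## duplications inside conserved-style families
    for (e in seq_len(rpois(1L, cfg$dupRate))) {
      rows <- addFamily(allSpecies(tree), nRefCopies = 2L)
      addHits(refGenesOf(rows)[1])
      refGenes <- refGenesOf(rows)
      dupRows[[length(dupRows) + 1L]] <- data.frame(
        og_id = rows$og_id[1], node = lab, support = 1.0,
        genes1 = I(list(refGenes[1])), genes2 = I(list(refGenes[2])))
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        gene_id = refGenes, og_id = rows$og_id[1], mechanism = "duplicated",
        birth_branch = lab, n_losses = 0L)
    }
  }
  duplications <- if (length(dupRows)) do.call(rbind, dupRows)
    else data.frame(og_id = character(), node = character(),
                    support = numeric(), genes1 = I(list()),
                    genes2 = I(list()))
  list(orthogroups = do.call(rbind, ogRows),
       duplications = duplications,
       hits = do.call(rbind, hitRows),
       wgdGenes = wgdGenes,
       truth = do.call(rbind, truthRows),
       tree = tree)
}

## per-codon 9-mutant bookkeeping reused by the SNP and protein-family
## generators: weights m(ref->alt) and the consequence of each mutant
.mutantArrays <- function(matrix) {
  mt <- .codonMutantTable()
  mt <- mt[order(mt$codon, mt$pos, mt$to), ]
  codons <- senseCodons()
  idx <- split(seq_len(nrow(mt)), mt$codon)[codons]
  list(
    w = do.call(rbind, lapply(idx, function(i)
      mutationFreq(matrix, mt$from[i], mt$to[i]))),
    type = do.call(rbind, lapply(idx, function(i) mt$type[i])),
    mutant = do.call(rbind, lapply(idx, function(i) mt$mutant[i])),
    pos = do.call(rbind, lapply(idx, function(i) mt$pos[i])),
    from = do.call(rbind, lapply(idx, function(i) mt$from[i])),
    to = do.call(rbind, lapply(idx, function(i) mt$to[i])),
    codons = codons)
}

#' Simulate composition-controlled CDS and a SNP panel
#'
#' CDS are drawn codon-wise from `codonFreqs`. Coding SNPs are drawn by
#' sampling a (codon occurrence, single-nucleotide mutant) pair with
#' probability proportional to the mutation-matrix frequency of the
#' change, then accepting synonymous proposals with probability 1 and
#' nonsynonymous ones with probability f (`purifyingFactor`);
#' stop-gaining proposals are rejected, matching the default nonsense
#' exclusion of [expectedPnPs()]. Under this scheme the normalized PN/PS
#' of the panel estimates f. Intronic SNPs are drawn from the mutation
#' matrix on a separate neutral contig. Minor allele frequencies are
#' uniform on (0, 0.5).
#'
#' @param cfg a [simConfig()].
#' @return list: `genes` (gene table with `cds`), `snps` (coding +
#'   intronic records), `intronSeq`, `truth` (per coding SNP syn/nonsyn
#'   label), `matrix` (the generating matrix).
#' @export
simulateCdsSnps <- function(cfg) {
  set.seed(.childSeed(cfg$seed, 2L))
  arr <- .mutantArrays(cfg$mutationMatrix)
  f <- cfg$purifyingFactor
  accW <- arr$w * ifelse(arr$type == "syn", 1,
                         ifelse(arr$type == "nonsyn", f, 0))
  rownames(accW) <- arr$codons
  siteW <- rowSums(accW)

  nCodons <- cfg$nGenes * cfg$codonsPerGene
  codons <- sample(names(cfg$codonFreqs), nCodons, replace = TRUE,
                   prob = cfg$codonFreqs)
  geneOf <- rep(seq_len(cfg$nGenes), each = cfg$codonsPerGene)
  codonIdx <- rep(seq_len(cfg$codonsPerGene), cfg$nGenes) - 1L
  geneIds <- sprintf("gene_%04d", seq_len(cfg$nGenes))
  cds <- vapply(split(codons, geneOf), paste, character(1), collapse = "")
  genes <- data.frame(gene_id = geneIds, species = "ref",
                      contig = geneIds, start = 0L,
                      end = 3L * cfg$codonsPerGene, strand = "+",
                      cds = unname(cds))

  snps <- NULL; truth <- NULL
  if (cfg$nSnps > 0L) {
    occW <- siteW[codons]
    ## with replacement: recurrent sites are possible, as in real panels
    pick <- sample.int(nCodons, cfg$nSnps, replace = TRUE, prob = occW)
    ci <- match(codons[pick], arr$codons)
    j <- vapply(ci, function(i)
      sample.int(9L, 1L, prob = accW[i, ]), integer(1))
    sel <- cbind(ci, j)
    pos <- codonIdx[pick] * 3L + arr$pos[sel] - 1L
    type <- arr$type[sel]
    snps <- data.frame(contig = geneIds[geneOf[pick]], pos = pos,
                       ref = arr$from[sel], alt = arr$to[sel],
                       maf = runif(cfg$nSnps, 0, 0.5),
                       context = "cds", gene_id = geneIds[geneOf[pick]])
    truth <- data.frame(contig = snps$contig, pos = pos, type = type)
  }
  ## neutral intron contig + SNPs
  intronSeq <- .randomSeq(cfg$intronLength)
  if (cfg$nIntronSnps > 0L) {
    bases <- strsplit(intronSeq, "")[[1]]
    m <- cfg$mutationMatrix@mat
    diag(m) <- 0
    bw <- rowSums(m)[bases]
    ipick <- sample.int(cfg$intronLength, cfg$nIntronSnps, replace = TRUE,
                        prob = bw)
    iref <- bases[ipick]
    ialt <- vapply(iref, function(b)
      sample(DNA_BASES, 1L, prob = m[b, ]), character(1), USE.NAMES = FALSE)
    snps <- rbind(snps, data.frame(
      contig = "intron_1", pos = ipick - 1L, ref = iref, alt = ialt,
      maf = runif(cfg$nIntronSnps, 0, 0.5),
      context = "intron", gene_id = NA_character_))
  }
  list(genes = genes, snps = snps, intronSeq = intronSeq, truth = truth,
       matrix = cfg$mutationMatrix)
}

.basicToAcidic <- function(fromAa, toAa, scheme = defaultClassScheme()) {
  scheme[fromAa] == "basic" & scheme[toAa] == "acidic"
}

#' Simulate a diverged protein family (pair or triple)
#'
#' An ancestral CDS is drawn from `codonFreqs`; each descendant lineage
#' mutates every codon independently with probability `divergence`
#' (single change per codon: the low-divergence regime where observed
#' amino-acid pairs match the single-nucleotide expectation). Mutants
#' are proposed from the mutation matrix; stop-creating proposals leave
#' the codon unchanged and an optional charge-shift bias multiplies the
#' acceptance of basic->acidic changes by `chargeShift`. For pairs the
#' first sequence is the unmutated ancestor; for triples the reference
#' stays ancestral and two sisters evolve independently.
#'
#' @param cfg a [simConfig()].
#' @param nSpecies 2 or 3.
#' @return list: `alignments` (data.frame of aligned amino-acid
#'   sequences per gene), `ancestralCds`, `truth` (one row per accepted
#'   change), `matrix`.
#' @export
simulateProteinFamily <- function(cfg, nSpecies = 2L) {
  stopifnot(nSpecies %in% c(2L, 3L), cfg$divergence >= 0)
  set.seed(.childSeed(cfg$seed, 3L))
  arr <- .mutantArrays(cfg$mutationMatrix)
  s <- cfg$chargeShift
  gc <- geneticCode()
  nCodons <- cfg$nGenes * cfg$codonsPerGene
  anc <- sample(names(cfg$codonFreqs), nCodons, replace = TRUE,
                prob = cfg$codonFreqs)
  geneOf <- rep(seq_len(cfg$nGenes), each = cfg$codonsPerGene)

  evolve <- function(codons, branch) {
    out <- codons
    hit <- which(runif(length(codons)) < cfg$divergence)
    changes <- NULL
    if (length(hit)) {
      ci <- match(codons[hit], arr$codons)
      j <- vapply(ci, function(i)
        sample.int(9L, 1L, prob = arr$w[i, ]), integer(1))
      sel <- cbind(ci, j)
      mutant <- arr$mutant[sel]
      type <- arr$type[sel]
      fromAa <- gc[codons[hit]]
      toAa <- gc[mutant]
      accProb <- ifelse(type == "stop", 0,
                        ifelse(.basicToAcidic(fromAa, toAa), s, 1) / max(s, 1))
      acc <- runif(length(hit)) < accProb
      out[hit[acc]] <- mutant[acc]
      if (any(acc))
        changes <- data.frame(gene = geneOf[hit[acc]],
                              codon_index = hit[acc],
                              from_codon = codons[hit[acc]],
                              to_codon = mutant[acc],
                              from_aa = unname(fromAa[acc]),
                              to_aa = unname(toAa[acc]),
                              synonymous = type[acc] == "syn",
                              branch = branch)
    }
    list(codons = out, changes = changes)
  }
  toAa <- function(codons) vapply(split(unname(gc[codons]), geneOf),
                                  paste, character(1), collapse = "")
  ancAa <- toAa(anc)
  if (nSpecies == 2L) {
    d1 <- evolve(anc, "derived")
    aln <- data.frame(gene_id = sprintf("fam_%04d", seq_len(cfg$nGenes)),
                      ref = ancAa, derived = toAa(d1$codons))
    truth <- d1$changes
  } else {
    s1 <- evolve(anc, "sister1")
    s2 <- evolve(anc, "sister2")
    aln <- data.frame(gene_id = sprintf("fam_%04d", seq_len(cfg$nGenes)),
                      ref = ancAa, sister1 = toAa(s1$codons),
                      sister2 = toAa(s2$codons))
    truth <- rbind(s1$changes, s2$changes)
  }
  if (is.null(truth))
    truth <- data.frame(gene = integer(), codon_index = integer(),
                        from_codon = character(), to_codon = character(),
                        from_aa = character(), to_aa = character(),
                        synonymous = logical(), branch = character())
  list(alignments = aln,
       ancestralCds = vapply(split(anc, geneOf), paste, character(1),
                             collapse = ""),
       truth = truth, matrix = cfg$mutationMatrix)
}

#' Simulate a genome pair with planted synteny blocks
#'
#' Genome B is genome A with unrelated insertions planted between
#' conserved segments and point mutations applied inside the segments at
#' `pointMutationRate`. The truth table records each conserved segment's
#' interval on both genomes.
#'
#' @param cfg a [simConfig()].
#' @return list: `a`, `b` (sequences), `truth` (segment intervals,
#'   0-based half-open), `insertions` (intervals on B).
#' @export
simulateGenomePair <- function(cfg) {
  if (cfg$genomeLength <= 0L) stop("empty genome")
  set.seed(.childSeed(cfg$seed, 4L))
  L <- cfg$genomeLength
  a <- .randomSeq(L)
  k <- cfg$nInsertions
  jit <- min(50L, max(1L, L %/% (4L * (k + 1L))))
  cuts <- if (k > 0L)
    sort(round(L * seq_len(k) / (k + 1L)) +
           sample(seq(-jit, jit), k, replace = TRUE))
  else integer(0)
  bounds <- c(0L, cuts, L)
  segs <- character(0); truth <- NULL; insertions <- NULL
  bPos <- 0L; bParts <- character(0)
  for (i in seq_len(length(bounds) - 1L)) {
    seg <- substr(a, bounds[i] + 1L, bounds[i + 1L])
    if (cfg$pointMutationRate > 0) {
      bases <- strsplit(seg, "")[[1]]
      mut <- which(runif(length(bases)) < cfg$pointMutationRate)
      for (mi in mut)
        bases[mi] <- sample(setdiff(DNA_BASES, bases[mi]), 1L)
      seg <- paste(bases, collapse = "")
    }
    bParts <- c(bParts, seg)
    truth <- rbind(truth, data.frame(
      segment = i, start_a = bounds[i], end_a = bounds[i + 1L],
      start_b = bPos, end_b = bPos + nchar(seg)))
    bPos <- bPos + nchar(seg)
    if (i < length(bounds) - 1L) {
      ins <- .randomSeq(cfg$insertionLength)
      bParts <- c(bParts, ins)
      insertions <- rbind(insertions, data.frame(
        start_b = bPos, end_b = bPos + nchar(ins)))
      bPos <- bPos + nchar(ins)
    }
  }
  list(a = a, b = paste(bParts, collapse = ""), truth = truth,
       insertions = insertions)
}
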
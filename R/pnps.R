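## Normalized PN/PS: observed nonsynonymous/synonymous SNP ratio over the
## neutral expectation from codon composition and a mutation matrix.

## All 9 single-nucleotide mutants of every sense codon, with the
## functional consequence of each mutation. Built once and cached.
.codonMutantTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- geneticCode()
    rows <- list()
    for (codon in senseCodons()) {
      aa <- gc[[codon]]
      for (pos in 1:3) {
        ref <- substr(codon, pos, pos)
        for (alt in setdiff(DNA_BASES, ref)) {
          mut <- codon
          substr(mut, pos, pos) <- alt
          maa <- gc[[mut]]
          type <- if (maa == "*") "stop" else if (maa == aa) "syn" else "nonsyn"
          rows[[length(rows) + 1L]] <- data.frame(
            codon = codon, pos = pos, from = ref, to = alt,
            mutant = mut, aa = aa, mutant_aa = maa, type = type)
        }
      }
    }
    tab <<- do.call(rbind, rows)
    tab
  }
})

#' Codon occurrence counts / relative frequencies of a CDS set
#'
#' @param cds character vector of in-frame coding sequences.
#' @param relative return relative frequencies over the 61 sense codons.
#' @return named numeric vector over the sense codons.
#' @export
codonFrequencies <- function(cds, relative = TRUE) {
  codons <- unlist(lapply(cds, .splitCodons), use.names = FALSE)
  counts <- table(factor(codons, senseCodons()))
  out <- as.numeric(counts)
  names(out) <- senseCodons()
  if (relative) {
    if (sum(out) == 0) stop("no sense codons in input")
    out <- out / sum(out)
  }
  out
}

#' Expected PN/PS from codon composition and a mutation matrix
#'
#' For every codon occurrence in the CDS set, the 9 single-nucleotide
#' mutants are enumerated; the mutation frequency m(ref->alt) is added to
#' the expected nonsynonymous weight EN when the amino acid changes and
#' to the expected synonymous weight ES when it is silent. Mutations
#' creating a stop codon are excluded from both by default (nonsense
#' changes are not missense; set `countNonsenseAsNonsyn` to fold them
#' into EN).
#'
#' @param cds character vector of in-frame CDS (terminal stops allowed).
#' @param matrix a [MutationMatrix-class].
#' @param countNonsenseAsNonsyn count stop-gaining mutations as
#'   nonsynonymous.
#' @return list with `EN`, `ES`, `ratio` (EN/ES) and `defined` (`FALSE`
#'   when ES is 0, e.g. a lone ATG codon).
#' @export
expectedPnPs <- function(cds, matrix, countNonsenseAsNonsyn = FALSE) {
  counts <- codonFrequencies(cds, relative = FALSE)
  tab <- .codonMutantTable()
  w <- counts[tab$codon] * mutationFreq(matrix, tab$from, tab$to)
  nonsynTypes <- if (countNonsenseAsNonsyn) c("nonsyn", "stop") else "nonsyn"
  EN <- sum(w[tab$type %in% nonsynTypes])
  ES <- sum(w[tab$type == "syn"])
  list(EN = EN, ES = ES,
       ratio = if (ES > 0) EN / ES else NA_real_,
       defined = ES > 0)
}

.snpCdsPositions <- function(snps, genes) {
  m <- match(snps$gene_id, genes$gene_id)
  if (anyNA(m)) stop("SNP gene_id(s) missing from gene table")
  if ("cds_pos" %in% names(snps)) {
    cdsPos <- snps$cds_pos
    ref <- snps$ref
    alt <- snps$alt
  } else {
    strand <- genes$strand[m]
    plus <- strand != "-"
    cdsPos <- ifelse(plus, snps$pos - genes$start[m],
                     genes$end[m] - 1L - snps$pos)
    ref <- ifelse(plus, snps$ref, .compBase(snps$ref))
    alt <- ifelse(plus, snps$alt, .compBase(snps$alt))
  }
  list(idx = m, cdsPos = as.integer(cdsPos), ref = ref, alt = alt)
}

#' Observed PN and PS counts from CDS SNPs
#'
#' Each SNP is scored independently against the reference codon of its
#' gene (codons with several SNPs contribute one comparison per SNP).
#' SNPs with minor allele frequency below `mafMin` are excluded; a SNP
#' whose reference allele disagrees with the CDS sequence is an error.
#' Stop-gaining SNPs follow the same convention as [expectedPnPs()].
#'
#' @param snps SNP data.frame (`context == "cds"` rows are used) with
#'   `gene_id`, `pos`, `ref`, `alt`, `maf`; alternatively a `cds_pos`
#'   column (0-based position inside the CDS) bypasses the genomic
#'   mapping, which otherwise assumes single-interval CDS.
#' @param genes gene data.frame with `gene_id`, `start`, `end`, `strand`,
#'   `cds`.
#' @param mafMin minimum minor allele frequency (0.05 for the deep yeast
#'   isolate panels, 0 when frequencies are not informative).
#' @param countNonsenseAsNonsyn as in [expectedPnPs()].
#' @return list with `PN`, `PS` and `ratio`.
#' @export
observedPnPs <- function(snps, genes, mafMin = 0,
                         countNonsenseAsNonsyn = FALSE) {
  if ("context" %in% names(snps))
    snps <- snps[snps$context == "cds", , drop = FALSE]
  if (mafMin > 0)
    snps <- snps[!is.na(snps$maf) & snps$maf >= mafMin, , drop = FALSE]
  if (nrow(snps) == 0L) return(list(PN = 0L, PS = 0L, ratio = NA_real_))
  loc <- .snpCdsPositions(snps, genes)
  cds <- genes$cds[loc$idx]
  codonIdx <- loc$cdsPos %/% 3L
  off <- loc$cdsPos %% 3L + 1L
  codon <- substr(cds, codonIdx * 3L + 1L, codonIdx * 3L + 3L)
  if (any(nchar(codon) != 3L)) stop("SNP position outside its CDS")
  refBase <- substr(codon, off, off)
  if (any(refBase != loc$ref))
    stop("SNP reference allele disagrees with the CDS sequence")
  mut <- codon
  substr(mut, off, off) <- loc$alt
  aaRef <- .translateCodons(codon)
  aaMut <- geneticCode()[mut]
  PN <- sum(aaMut != "*" & aaMut != aaRef) +
    if (countNonsenseAsNonsyn) sum(aaMut == "*") else 0L
  PS <- sum(aaMut == aaRef)
  list(PN = as.integer(PN), PS = as.integer(PS),
       ratio = if (PS > 0) PN / PS else NA_real_)
}

#' Normalized PN/PS for a group of genes
#'
#' The observed PN/PS ratio divided by the neutral expectation EN/ES;
#' values around 1 indicate absence of purifying selection, values below
#' 1 increasingly strong constraint. Counts are pooled over the group's
#' genes (not averaged per gene). The accompanying chi-square compares
#' the observed (PN, PS) split with the expected split scaled to the
#' observed total.
#'
#' @param genes gene data.frame for the group.
#' @param snps SNP data.frame.
#' @param matrix a [MutationMatrix-class].
#' @param group label for the output row.
#' @param mafMin,countNonsenseAsNonsyn see [observedPnPs()].
#' @return one-row data.frame (`PnPsResult`): group, PN_obs, PS_obs,
#'   ratio_obs, EN, ES, ratio_exp, normalized, chisq_p, n_genes, defined.
#' @export
normalizedPnPs <- function(genes, snps, matrix, group = "all", mafMin = 0,
                           countNonsenseAsNonsyn = FALSE) {
  if (nrow(genes) == 0L) stop("empty gene group")
  snps <- snps[snps$gene_id %in% genes$gene_id | is.na(snps$gene_id), ,
               drop = FALSE]
  obs <- observedPnPs(snps, genes, mafMin, countNonsenseAsNonsyn)
  exp <- expectedPnPs(genes$cds, matrix, countNonsenseAsNonsyn)
  defined <- exp$defined && obs$PS > 0 && exp$ratio > 0
  normalized <- if (defined) obs$ratio / exp$ratio else NA_real_
  chisqP <- NA_real_
  tot <- obs$PN + obs$PS
  if (defined && tot > 0) {
    scale <- tot / (exp$EN + exp$ES)
    chisqP <- yatesChisq2x2(obs$PN, obs$PS,
                            exp$EN * scale, exp$ES * scale)$p_value
  }
  data.frame(group = group, PN_obs = obs$PN, PS_obs = obs$PS,
             ratio_obs = obs$ratio, EN = exp$EN, ES = exp$ES,
             ratio_exp = exp$ratio, normalized = normalized,
             chisq_p = chisqP, n_genes = nrow(genes), defined = defined)
}

#' Subsampling standard deviation of the normalized PN/PS
#'
#' Standard deviation of the normalized PN/PS over `reps` random subsets
#' of `ceiling(frac * n)` genes sampled without replacement, the
#' uncertainty displayed as error bars on group-level PN/PS values.
#'
#' @inheritParams normalizedPnPs
#' @param frac fraction of genes per subsample.
#' @param reps number of subsamples (at least 2).
#' @param seed RNG seed.
#' @return standard deviation (NA-dropping) of the replicate estimates.
#' @export
subsampleSd <- function(genes, snps, matrix, frac = 1 / 3, reps = 1000,
                        seed = 1L, mafMin = 0,
                        countNonsenseAsNonsyn = FALSE) {
  n <- nrow(genes)
  if (n < 3L) stop("need at least 3 genes to subsample")
  if (reps < 2L) stop("need at least 2 subsampling replicates")
  k <- ceiling(frac * n)
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(reps), function(i) {
    idx <- sample.int(n, k)
    sub <- genes[idx, , drop = FALSE]
    normalizedPnPs(sub, snps, matrix, mafMin = mafMin,
                   countNonsenseAsNonsyn = countNonsenseAsNonsyn)$normalized
  }, numeric(1))
  sd(vals, na.rm = TRUE)
}

#' Pool branch labels into representative groups
#'
#' SNP data are sparse for thin branches, so adjacent branch classes are
#' merged: the yeast scheme pools N0 / N1-N4 / N5, the flies scheme
#' N0 / N1-N2 / N3-N4 / N5 / N6; conserved genes form their own group.
#'
#' @param classification data.frame from [classifyGenes()].
#' @param scheme `"yeast"`, `"flies"`, `"none"` (labels pass through), or
#'   a named list mapping group name -> character vector of labels.
#' @return the classification with an added `group` column (NA for
#'   classes outside the scheme, e.g. WGD-excluded genes).
#' @export
groupPool <- function(classification, scheme = "yeast") {
  if (is.character(scheme)) {
    scheme <- switch(scheme,
      yeast = list(N0 = "N0", `N1-N4` = paste0("N", 1:4), N5 = "N5"),
      flies = list(N0 = "N0", `N1-N2` = c("N1", "N2"),
                   `N3-N4` = c("N3", "N4"), N5 = "N5", N6 = "N6"),
      none = NULL,
      stop("unknown pooling scheme"))
  }
  lab <- classification$birth_branch
  group <- rep(NA_character_, nrow(classification))
  if (is.null(scheme)) {
    group <- lab
  } else {
    for (g in names(scheme)) group[lab %in% scheme[[g]]] <- g
    uncovered <- !is.na(lab) & is.na(group)
    if (any(uncovered))
      stop("branch label(s) not covered by the pooling scheme: ",
           paste(unique(lab[uncovered]), collapse = ", "))
  }
  group[classification$klass == "conserved"] <- "conserved"
  classification$group <- group
  classification
}

#' Normalized PN/PS per mechanism and pooled branch group
#'
#' Convenience orchestration: pools branch labels, then computes
#' [normalizedPnPs()] (and optionally the subsampling sd) for every
#' (mechanism, group) combination with at least one gene. Genes classed
#' de novo + duplicated are excluded, as are WGD-excluded and filtered
#' genes.
#'
#' @inheritParams normalizedPnPs
#' @param classification data.frame from [classifyGenes()].
#' @param scheme see [groupPool()].
#' @param reps subsampling replicates (0 skips the sd).
#' @param seed RNG seed for subsampling.
#' @return data.frame of PnPsResult rows with `mechanism` and `sd`.
#' @export
pnpsByGroup <- function(classification, genes, snps, matrix,
                        scheme = "yeast", mafMin = 0, reps = 0, seed = 1L,
                        countNonsenseAsNonsyn = FALSE) {
  cl <- groupPool(classification, scheme)
  cl <- cl[cl$klass %in% c("putative_de_novo", "duplicated", "conserved") &
             !is.na(cl$group), , drop = FALSE]
  out <- NULL
  for (mech in unique(cl$klass)) {
    for (g in unique(cl$group[cl$klass == mech])) {
      ids <- cl$gene_id[cl$klass == mech & cl$group == g]
      sub <- genes[genes$gene_id %in% ids, , drop = FALSE]
      if (nrow(sub) == 0L) next
      row <- normalizedPnPs(sub, snps, matrix, group = g, mafMin = mafMin,
                            countNonsenseAsNonsyn = countNonsenseAsNonsyn)
      row$mechanism <- mech
      row$sd <- if (reps >= 2 && nrow(sub) >= 3)
        subsampleSd(sub, snps, matrix, reps = reps, seed = seed,
                    mafMin = mafMin,
                    countNonsenseAsNonsyn = countNonsenseAsNonsyn)
      else NA_real_
      out <- rbind(out, row)
    }
  }
  out
}
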
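## Branch-wise classification of duplicated vs putative de novo genes,
## event counting and branch-length normalization.

GENE_CLASSES <- c("putative_de_novo", "duplicated", "de_novo_plus_duplicated",
                  "conserved", "excluded_wgd", "removed_outgroup_homology")

#' Outgroup-homology filter for de novo candidates
#'
#' A candidate is removed when homology hits with E-value below `eMax`
#' exist in at least `minSpecies` distinct outgroup species: presence in
#' several species outside the clade means the family is old and its
#' restricted in-clade distribution reflects losses, not a recent birth.
#'
#' @param candidates character vector of gene ids.
#' @param hits homology hit data.frame (`query_gene`, `subject_species`,
#'   `e_value`), restricted to species outside the clade.
#' @param eMax E-value cutoff.
#' @param minSpecies minimum number of distinct outgroup species.
#' @return list with `kept` and `removed` gene-id vectors.
#' @export
filterOutgroupHomology <- function(candidates, hits, eMax = 0.001,
                                   minSpecies = 2L) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(kept = candidates, removed = character(0)))
  good <- hits[hits$e_value < eMax & hits$query_gene %in% candidates, ,
               drop = FALSE]
  nsp <- tapply(good$subject_species, good$query_gene,
                function(s) length(unique(s)))
  removed <- names(nsp)[nsp >= minSpecies]
  list(kept = setdiff(candidates, removed), removed = intersect(candidates, removed))
}

#' Map duplication records to branch events
#'
#' One event per record with support at or above `supportMin`, attributed
#' to the record's species-tree branch. Unknown node labels are an error.
#'
#' @param duplications data.frame from [parseDuplications()].
#' @param tree a [SpeciesTree-class].
#' @param supportMin minimum support fraction.
#' @return the filtered data.frame (one row per event).
#' @export
mapDuplications <- function(duplications, tree, supportMin = 0.5) {
  bad <- setdiff(unique(duplications$node), branchLabels(tree))
  if (length(bad))
    stop("unknown species tree node label(s): ", paste(bad, collapse = ", "))
  duplications[duplications$support >= supportMin, , drop = FALSE]
}

.outgroupPositiveGenes <- function(genes, hits, eMax, minSpecies) {
  filterOutgroupHomology(genes, hits, eMax, minSpecies)$removed
}

#' Classify reference-species genes by mechanism and branch of origin
#'
#' Given orthogroups, per-branch duplication records, the species tree, a
#' whole-genome-duplication exclusion list and homology hits against
#' outgroup species, assigns every reference-species gene exactly one
#' class:
#' \describe{
#'   \item{excluded_wgd}{listed as WGD-derived; removed first so only
#'     small-scale duplications are counted.}
#'   \item{duplicated}{member of a supported duplication event in a
#'     family with outgroup evidence; dated by the most recent event
#'     containing it.}
#'   \item{de_novo_plus_duplicated}{member of a duplication event in a
#'     family without outgroup evidence: a de novo birth (dated by the
#'     species distribution) followed by duplication.}
#'   \item{putative_de_novo}{family without outgroup evidence, gene not
#'     duplicated; dated by the deepest species in the family.}
#'   \item{conserved}{family with outgroup evidence spanning the deepest
#'     branch, gene not duplicated.}
#'   \item{removed_outgroup_homology}{family restricted inside the clade
#'     but with hits in `minOutgroupSpecies`+ outgroup species: a
#'     candidate discarded as a likely multiple-loss artifact.}
#' }
#' Orthogroups lacking the reference species are ignored (the analysis is
#' reference-centric). De novo events are counted once per family;
#' duplication events once per supported record, at the record's branch.
#'
#' @param orthogroups long data.frame (`og_id`, `species`, `gene_id`).
#' @param duplications data.frame from [parseDuplications()]; may be NULL.
#' @param tree a [SpeciesTree-class].
#' @param wgdGenes character vector of WGD-derived reference gene ids.
#' @param outgroupHits homology hits vs outgroup species; may be NULL.
#' @param supportMin duplication support threshold.
#' @param eMax,minOutgroupSpecies outgroup-filter parameters.
#' @return list with `classification` (gene_id, og_id, klass,
#'   birth_branch), `denovoEvents` (og_id, branch), `dupEvents` (og_id,
#'   branch, support, n_reference_genes, reference_seen).
#' @export
classifyGenes <- function(orthogroups, duplications = NULL, tree,
                          wgdGenes = character(0), outgroupHits = NULL,
                          supportMin = 0.5, eMax = 0.001,
                          minOutgroupSpecies = 2L) {
  refClade <- cladeSpecies(tree, "N0")
  deepest <- branchLabels(tree)[length(branchLabels(tree))]
  dups <- if (is.null(duplications) || nrow(duplications) == 0L)
    data.frame(og_id = character(), node = character(), support = numeric())
  else mapDuplications(duplications, tree, supportMin)
  allDupGenes <- unique(unlist(c(dups$genes1, dups$genes2)))
  if (length(allDupGenes) && !all(allDupGenes %in% orthogroups$gene_id))
    stop("duplication event gene(s) absent from orthogroups: ",
         paste(head(setdiff(allDupGenes, orthogroups$gene_id)), collapse = ", "))

  ogIds <- unique(orthogroups$og_id)
  classification <- NULL
  denovoEvents <- NULL
  dupEvents <- NULL
  labOrder <- branchLabels(tree)

  for (og in ogIds) {
    rows <- orthogroups[orthogroups$og_id == og, , drop = FALSE]
    refGenes <- rows$gene_id[rows$species %in% refClade]
    ogDups <- dups[dups$og_id == og, , drop = FALSE]
    if (nrow(ogDups)) {
      refSeen <- vapply(seq_len(nrow(ogDups)), function(i) {
        g <- c(ogDups$genes1[[i]], ogDups$genes2[[i]])
        sum(g %in% refGenes)
      }, numeric(1))
      dupEvents <- rbind(dupEvents, data.frame(
        og_id = og, branch = ogDups$node, support = ogDups$support,
        n_reference_genes = refSeen, reference_seen = refSeen > 0))
    }
    if (length(refGenes) == 0L) next
    birth <- assignBirthBranch(unique(rows$species), tree)
    ancientBy <- .outgroupPositiveGenes(rows$gene_id, outgroupHits,
                                        eMax, minOutgroupSpecies)
    ancient <- length(ancientBy) > 0L
    dupMember <- lapply(refGenes, function(g) {
      hitRec <- which(vapply(seq_len(nrow(ogDups)), function(i)
        g %in% c(ogDups$genes1[[i]], ogDups$genes2[[i]]), logical(1)))
      hitRec
    })
    names(dupMember) <- refGenes
    isWgd <- refGenes %in% wgdGenes
    klass <- character(length(refGenes))
    branch <- rep(NA_character_, length(refGenes))
    for (i in seq_along(refGenes)) {
      g <- refGenes[i]
      if (isWgd[i]) { klass[i] <- "excluded_wgd"; next }
      inDup <- length(dupMember[[g]]) > 0L
      if (inDup) {
        if (ancient) {
          klass[i] <- "duplicated"
          evBranches <- ogDups$node[dupMember[[g]]]
          branch[i] <- evBranches[which.min(match(evBranches, labOrder))]
        } else {
          klass[i] <- "de_novo_plus_duplicated"
          branch[i] <- birth
        }
      } else if (ancient) {
        klass[i] <- if (birth == deepest) "conserved"
                    else "removed_outgroup_homology"
      } else {
        klass[i] <- "putative_de_novo"
        branch[i] <- birth
      }
    }
    classification <- rbind(classification, data.frame(
      gene_id = refGenes, og_id = og, klass = klass, birth_branch = branch))
    if (!ancient && any(klass %in% c("putative_de_novo",
                                     "de_novo_plus_duplicated")))
      denovoEvents <- rbind(denovoEvents,
                            data.frame(og_id = og, branch = birth))
  }
  if (is.null(classification))
    classification <- data.frame(gene_id = character(), og_id = character(),
                                 klass = character(), birth_branch = character())
  if (is.null(denovoEvents))
    denovoEvents <- data.frame(og_id = character(), branch = character())
  if (is.null(dupEvents))
    dupEvents <- data.frame(og_id = character(), branch = character(),
                            support = numeric(), n_reference_genes = numeric(),
                            reference_seen = logical())
  list(classification = classification, denovoEvents = denovoEvents,
       dupEvents = dupEvents)
}

#' Per-branch event counts normalized by branch length
#'
#' Events per branch divided by 100 x branch length (substitutions/site),
#' i.e. events per amino-acid substitution per 100 residues, so branches
#' of very different lengths can be compared. Protein counts (which can
#' exceed event counts when births are followed by duplications) are
#' reported alongside.
#'
#' @param classed result of [classifyGenes()].
#' @param tree a [SpeciesTree-class].
#' @return data.frame with one row per branch label.
#' @export
branchRates <- function(classed, tree) {
  labs <- branchLabels(tree)
  bl <- branchLengths(tree)
  cl <- classed$classification
  nDenovoEv <- table(factor(classed$denovoEvents$branch, labs))
  nDupEv <- table(factor(classed$dupEvents$branch, labs))
  denovoProt <- cl[cl$klass %in% c("putative_de_novo",
                                   "de_novo_plus_duplicated"), , drop = FALSE]
  dupProt <- cl[cl$klass == "duplicated", , drop = FALSE]
  nDenovoProt <- table(factor(denovoProt$birth_branch, labs))
  nDupProt <- table(factor(dupProt$birth_branch, labs))
  out <- data.frame(branch = labs,
                    n_denovo_events = as.integer(nDenovoEv),
                    n_dup_events = as.integer(nDupEv),
                    n_denovo_proteins = as.integer(nDenovoProt),
                    n_dup_proteins = as.integer(nDupProt),
                    branch_length = as.numeric(bl))
  bad <- (is.na(out$branch_length) | out$branch_length == 0) &
    (out$n_denovo_events + out$n_dup_events > 0)
  if (any(bad))
    stop("zero/unknown branch length with events on branch: ",
         paste(out$branch[bad], collapse = ", "))
  out$normalized_denovo <- ifelse(out$n_denovo_events == 0, 0,
                                  out$n_denovo_events / (100 * out$branch_length))
  out$normalized_dup <- ifelse(out$n_dup_events == 0, 0,
                               out$n_dup_events / (100 * out$branch_length))
  out
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' Pearson's chi-squared statistic with continuity correction (|O - E|
#' reduced by 0.5, floored at 0, per cell) on the table rbind(c(a, b),
#' c(c, d)), 1 degree of freedom. All margins must be positive.
#'
#' @param a,b,c,d nonnegative cell counts.
#' @return list with `statistic`, `p_value`, `df`.
#' @examples
#' yatesChisq2x2(35, 23, 1853, 2872)$p_value  # ~0.0017
#' @export
yatesChisq2x2 <- function(a, b, c, d) {
  O <- rbind(c(a, b), c(c, d))
  if (any(O < 0)) stop("negative count")
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("zero margin in 2x2 table")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Fraction of genes located in synteny blocks, per class
#'
#' @param classification data.frame from [classifyGenes()].
#' @param geneRanges data.frame with `gene_id`, `start`, `end` (0-based
#'   half-open) on the queried genome.
#' @param blocks synteny blocks from [clusterMums()].
#' @param side which genome the gene coordinates refer to.
#' @param minFrac minimum overlapping fraction of the gene (0 means any
#'   1-bp overlap).
#' @return data.frame with `klass`, `n_genes`, `n_in_block`, `fraction`.
#' @export
syntenyFraction <- function(classification, geneRanges, blocks,
                            side = c("a", "b"), minFrac = 0) {
  side <- match.arg(side)
  m <- merge(classification, geneRanges, by = "gene_id")
  inBlock <- vapply(seq_len(nrow(m)), function(i)
    geneInBlock(c(m$start[i], m$end[i]), blocks, side, minFrac), logical(1))
  agg <- lapply(split(inBlock, m$klass), function(x)
    c(n = length(x), k = sum(x)))
  out <- data.frame(klass = names(agg),
                    n_genes = vapply(agg, `[[`, numeric(1), "n"),
                    n_in_block = vapply(agg, `[[`, numeric(1), "k"))
  out$fraction <- ifelse(out$n_genes > 0, out$n_in_block / out$n_genes, NA)
  rownames(out) <- NULL
  out
}
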
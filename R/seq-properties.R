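## Protein length, isoelectric point, residue-class composition, the
## translated-intron control set and group comparisons.

#' Default pK table (EMBOSS values)
#'
#' Dissociation constants used by the isoelectric point calculation:
#' N-terminus 8.6, C-terminus 3.6, side chains C 8.5, D 3.9, E 4.1,
#' H 6.5, K 10.8, R 12.5, Y 10.1. The table is configurable because
#' published pI values depend on the chosen scale.
#' @export
defaultPkTable <- function() {
  c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
    H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

.netCharge <- function(counts, nTerm, cTerm, pH, pk) {
  pos <- nTerm / (1 + 10^(pH - pk[["Nterm"]])) +
    sum(counts[c("K", "R", "H")] /
          (1 + 10^(pH - pk[c("K", "R", "H")])))
  neg <- cTerm / (1 + 10^(pk[["Cterm"]] - pH)) +
    sum(counts[c("D", "E", "C", "Y")] /
          (1 + 10^(pk[c("D", "E", "C", "Y")] - pH)))
  pos - neg
}

#' Isoelectric point of a protein
#'
#' The pH at which the Henderson-Hasselbalch net charge of the termini
#' and the ionizable side chains (D, E, C, Y negative; K, R, H positive)
#' crosses zero, found by bisection on [0, 14] to |charge| < 1e-4.
#'
#' @param protein amino-acid sequence(s); nonstandard residues are
#'   ignored for charge.
#' @param pk named pK vector, see [defaultPkTable()].
#' @return numeric vector of pI values.
#' @export
isoelectricPoint <- function(protein, pk = defaultPkTable()) {
  vapply(protein, function(p) {
    if (nchar(p) == 0L) stop("empty protein sequence")
    res <- strsplit(p, "")[[1]]
    counts <- table(factor(res, AA_STANDARD))
    lo <- 0; hi <- 14
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      ch <- .netCharge(counts, 1, 1, mid, pk)
      if (abs(ch) < 1e-4) break
      if (ch > 0) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1), USE.NAMES = FALSE)
}

#' Residue-class composition of a protein
#'
#' Fractions of acidic/basic/polar/nonpolar residues over the
#' classifiable residues; unknown residues are excluded from the
#' denominator.
#' @param protein amino-acid sequence.
#' @param scheme amino acid -> class map.
#' @return named numeric vector over the classes, summing to 1.
#' @export
classFractions <- function(protein, scheme = defaultClassScheme()) {
  res <- strsplit(protein, "")[[1]]
  cls <- scheme[res]
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0L) stop("no classifiable residue in sequence")
  tab <- table(factor(cls, sort(unique(scheme))))
  out <- as.numeric(tab) / length(cls)
  setNames(out, names(tab))
}

#' Translated-intron control peptides
#'
#' Builds the composition control set of peptides from intron sequences:
#' either ORFs from an NTG start to the first in-frame stop of at least
#' `minAa` residues (policy `"orf"`, consistent with the ORF rule used
#' for transcripts), or a fixed frame-1 translation with stop characters
#' removed (policy `"frame1"`).
#'
#' @param introns character vector of intron nucleotide sequences.
#' @param policy `"orf"` or `"frame1"`.
#' @param minAa minimum peptide length under policy `"orf"`.
#' @return character vector of peptides.
#' @export
intronControlSet <- function(introns, policy = c("orf", "frame1"),
                             minAa = 10L) {
  policy <- match.arg(policy)
  if (policy == "orf")
    return(unlist(lapply(introns, extractOrfs, minAa = minAa),
                  use.names = FALSE))
  peptides <- vapply(introns, function(x) {
    len <- (nchar(x) %/% 3L) * 3L
    if (len < 3L) return("")
    aa <- .translateCodons(.splitCodons(substr(x, 1L, len)))
    paste(aa[aa != "*"], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  peptides[nzchar(peptides)]
}

#' Two-sided rank-sum comparison of two groups
#'
#' Mann-Whitney-Wilcoxon test (exact for small samples without ties,
#' normal approximation with tie correction otherwise) plus significance
#' stars: * p < 0.05, ** p < 1e-2, *** p < 1e-3.
#'
#' @param a,b numeric vectors (nonempty).
#' @return list with `p_value`, `stars`, `statistic`.
#' @export
compareGroups <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  p <- wt$p.value
  stars <- if (p < 1e-3) "***" else if (p < 1e-2) "**" else
    if (p < 0.05) "*" else ""
  list(p_value = p, stars = stars, statistic = unname(wt$statistic))
}

#' Per-protein property profiles
#'
#' Length, isoelectric point and residue-class fractions for each
#' protein, labelled by group (a classification column, or any grouping
#' vector).
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param groups character vector parallel to `proteins`.
#' @param scheme amino acid -> class map.
#' @param pk pK table for the pI.
#' @return data.frame: gene_id, group, length, pI and one fraction
#'   column per class.
#' @export
proteinProfiles <- function(proteins, groups,
                            scheme = defaultClassScheme(),
                            pk = defaultPkTable()) {
  stopifnot(length(proteins) == length(groups))
  fr <- t(vapply(proteins, classFractions, numeric(4), scheme = scheme))
  out <- data.frame(gene_id = if (is.null(names(proteins)))
                      paste0("p", seq_along(proteins)) else names(proteins),
                    group = groups,
                    length = nchar(proteins),
                    pI = isoelectricPoint(proteins, pk))
  cbind(out, as.data.frame(fr, row.names = NULL))
}

#' Per-group medians of the property profiles
#'
#' Median length, pI and class fractions per group (median of an
#' even-sized group is the midpoint of the central pair).
#' @param profiles data.frame from [proteinProfiles()].
#' @return data.frame of per-group medians and sizes.
#' @export
groupSummaries <- function(profiles) {
  num <- setdiff(names(profiles), c("gene_id", "group"))
  groups <- unique(profiles$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- profiles[profiles$group == g, num, drop = FALSE]
    med <- vapply(sub, median, numeric(1))
    cbind(data.frame(group = g, n = nrow(sub)),
          as.data.frame(as.list(setNames(med, paste0("median_", num)))))
  }))
  rownames(out) <- NULL
  out
}
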
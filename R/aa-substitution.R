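## Observed vs neutral-expected amino-acid changes and parsimony
## directionality on two- and three-species protein alignments.

#' Default amino-acid property classes
#'
#' acidic {D,E}; basic {K,R,H}; polar {S,T,N,Q,C,Y}; nonpolar
#' {A,V,L,I,P,F,M,W,G}. Returned as a named character vector aa -> class.
#' @export
defaultClassScheme <- function() {
  c(D = "acidic", E = "acidic",
    K = "basic", R = "basic", H = "basic",
    S = "polar", T = "polar", N = "polar", Q = "polar", C = "polar",
    Y = "polar",
    A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
    P = "nonpolar", F = "nonpolar", M = "nonpolar", W = "nonpolar",
    G = "nonpolar")
}

.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "/")
}

## ordered sense-codon pairs at Hamming distance 1 with an aa change
.singleNtChangeTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    mt <- .codonMutantTable()
    tab <<- mt[mt$type == "nonsyn", c("codon", "mutant", "pos", "from", "to",
                                      "aa", "mutant_aa")]
    tab
  }
})

#' Codon routes between two amino acids under single-nucleotide change
#'
#' All ordered sense-codon pairs (c1 -> c2) with code(c1) = aa1,
#' code(c2) = aa2 and Hamming distance 1. An empty result means the two
#' amino acids are not reachable by a single nucleotide change.
#'
#' @param aa1,aa2 distinct standard amino acids (one-letter).
#' @return data.frame with `codon1`, `codon2`, `pos`, `from`, `to`.
#' @examples
#' singleNtPaths("K", "E")  # AAA->GAA and AAG->GAG
#' @export
singleNtPaths <- function(aa1, aa2) {
  if (aa1 == aa2) stop("amino acids must differ")
  if (!aa1 %in% AA_STANDARD || !aa2 %in% AA_STANDARD)
    stop("nonstandard amino acid")
  tab <- .singleNtChangeTable()
  hit <- tab[tab$aa == aa1 & tab$mutant_aa == aa2, , drop = FALSE]
  data.frame(codon1 = hit$codon, codon2 = hit$mutant, pos = hit$pos,
             from = hit$from, to = hit$to, row.names = NULL)
}

#' Unordered amino-acid pairs reachable by a single nucleotide change
#' @return character vector of `"A/B"` keys (alphabetical within pair).
#' @export
reachablePairs <- function() {
  tab <- .singleNtChangeTable()
  sort(unique(.pairKey(tab$aa, tab$mutant_aa)))
}

#' Count differing amino-acid pairs in a pairwise alignment
#'
#' One count per column where both residues are standard amino acids and
#' differ; columns with gaps or ambiguous residues are skipped. Several
#' alignments can be passed as equal-length vectors and are summed.
#'
#' @param a,b aligned sequences (equal length per pair; gaps allowed).
#' @return list with `counts` (named vector over `"A/B"` keys),
#'   `total_changes` and `total_single_nt_explainable`.
#' @export
extractPairCounts <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must pair up")
  keys <- character(0)
  for (i in seq_along(a)) {
    if (nchar(a[i]) != nchar(b[i]))
      stop("aligned sequences differ in length (pair ", i, ")")
    ra <- strsplit(a[i], "")[[1]]
    rb <- strsplit(b[i], "")[[1]]
    use <- ra %in% AA_STANDARD & rb %in% AA_STANDARD & ra != rb
    keys <- c(keys, .pairKey(ra[use], rb[use]))
  }
  counts <- table(keys)
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts,
       total_changes = sum(counts),
       total_single_nt_explainable =
         sum(counts[names(counts) %in% reachablePairs()]))
}

#' Neutral-expected amino-acid change table
#'
#' The raw expected weight of an ordered change aa_i -> aa_j is the sum,
#' over its single-nucleotide codon routes c1 -> c2, of f(c1) x m(base
#' change), with f the codon frequencies of the group under study and m
#' the mutation matrix. Unordered pair expectations add both directions
#' (K/E = K->E plus E->K). The table is restricted to pairs that are
#' single-nucleotide reachable AND observed in the focal set, then
#' normalized so expected counts total the observed count over those
#' pairs.
#'
#' @param codonFreqs named frequency vector over sense codons (see
#'   [codonFrequencies()]), computed per group so composition differences
#'   are controlled for.
#' @param matrix a [MutationMatrix-class].
#' @param observed result of [extractPairCounts()] (or a named count
#'   vector).
#' @return data.frame with `pair`, `observed`, `expected_raw`,
#'   `expected`.
#' @export
expectedChangeTable <- function(codonFreqs, matrix, observed) {
  if (is.list(observed)) observed <- observed$counts
  tab <- .singleNtChangeTable()
  w <- codonFreqs[tab$codon] * mutationFreq(matrix, tab$from, tab$to)
  key <- .pairKey(tab$aa, tab$mutant_aa)
  raw <- tapply(w, key, sum)
  keep <- intersect(names(raw), names(observed)[observed > 0])
  if (length(keep) == 0L || sum(raw[keep]) == 0)
    stop("no overlap between observed pairs and reachable pairs with weight")
  obs <- observed[keep]
  expRaw <- raw[keep]
  expected <- expRaw / sum(expRaw) * sum(obs)
  out <- data.frame(pair = keep, observed = as.numeric(obs),
                    expected_raw = as.numeric(expRaw),
                    expected = as.numeric(expected), row.names = NULL)
  out[order(out$pair), ]
}

#' log2 observed/expected ratios per pair and per class pair
#'
#' Class-pair values aggregate observed and expected counts before the
#' ratio. Pairs with zero expectation are reported as NA; `minCases`
#' restricts the per-pair table to pairs observed more than that many
#' times.
#'
#' @param changeTable data.frame from [expectedChangeTable()].
#' @param scheme amino acid -> class map (see [defaultClassScheme()]).
#' @param minCases per-pair minimum observed count filter (0 keeps all;
#'   5 reproduces a "more than five cases" display rule).
#' @return list with `pairs` and `classes` data.frames.
#' @export
log2OE <- function(changeTable, scheme = defaultClassScheme(), minCases = 0) {
  ct <- changeTable
  ct$log2_oe <- ifelse(ct$expected > 0, log2(ct$observed / ct$expected), NA)
  aa12 <- do.call(rbind, strsplit(ct$pair, "/", fixed = TRUE))
  classKey <- .pairKey(scheme[aa12[, 1]], scheme[aa12[, 2]])
  obs <- tapply(ct$observed, classKey, sum)
  expd <- tapply(ct$expected, classKey, sum)
  classes <- data.frame(class_pair = names(obs), observed = as.numeric(obs),
                        expected = as.numeric(expd),
                        log2_oe = ifelse(expd > 0, log2(obs / expd), NA),
                        row.names = NULL)
  pairs <- ct[ct$observed > minCases, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, classes = classes)
}

#' Infer the direction of amino-acid changes from a three-species
#' alignment
#'
#' A column is informative when exactly two of the three species share a
#' residue and the reference is one of them: the shared residue is taken
#' as ancestral and the differing sister's residue as derived, placing
#' the change on that sister's branch. Columns where the reference is
#' the odd one out, all three differ, or any residue is a gap/ambiguity
#' are excluded.
#'
#' @param ref,sister1,sister2 aligned sequences (equal length).
#' @param labels branch names for the two sisters.
#' @return data.frame with `column`, `ancestral`, `derived`, `branch`.
#' @export
inferDirection <- function(ref, sister1, sister2,
                           labels = c("sister1", "sister2")) {
  if (nchar(ref) != nchar(sister1) || nchar(ref) != nchar(sister2))
    stop("aligned sequences differ in length")
  r <- strsplit(ref, "")[[1]]
  s1 <- strsplit(sister1, "")[[1]]
  s2 <- strsplit(sister2, "")[[1]]
  ok <- r %in% AA_STANDARD & s1 %in% AA_STANDARD & s2 %in% AA_STANDARD
  out <- NULL
  change1 <- ok & r == s2 & s1 != r   # change on sister1 branch
  change2 <- ok & r == s1 & s2 != r   # change on sister2 branch
  if (any(change1))
    out <- rbind(out, data.frame(column = which(change1),
                                 ancestral = r[change1],
                                 derived = s1[change1], branch = labels[1]))
  if (any(change2))
    out <- rbind(out, data.frame(column = which(change2),
                                 ancestral = r[change2],
                                 derived = s2[change2], branch = labels[2]))
  if (is.null(out))
    out <- data.frame(column = integer(), ancestral = character(),
                      derived = character(), branch = character())
  out[order(out$column), , drop = FALSE]
}

#' Tally gains and losses of residue classes
#'
#' A directional change gains the derived residue's class and loses the
#' ancestral one; a K->E change, for instance, increments acidic gains
#' and basic losses. Per-amino-acid net direction is reported alongside
#' (gain, loss, or balanced).
#'
#' @param changes data.frame from [inferDirection()].
#' @param scheme amino acid -> class map.
#' @return list with `classes` (class, gains, losses) and `aminoAcids`
#'   (aa, gains, losses, net).
#' @export
tallyGainLoss <- function(changes, scheme = defaultClassScheme()) {
  classes <- sort(unique(scheme))
  gainsC <- table(factor(scheme[changes$derived], classes))
  lossC <- table(factor(scheme[changes$ancestral], classes))
  aas <- sort(unique(c(changes$ancestral, changes$derived)))
  gainsA <- table(factor(changes$derived, aas))
  lossA <- table(factor(changes$ancestral, aas))
  net <- ifelse(gainsA > lossA, "gain",
                ifelse(gainsA < lossA, "loss", "equal"))
  list(classes = data.frame(class = classes, gains = as.integer(gainsC),
                            losses = as.integer(lossC), row.names = NULL),
       aminoAcids = data.frame(aa = aas, gains = as.integer(gainsA),
                               losses = as.integer(lossA),
                               net = as.character(net), row.names = NULL))
}

#' Per-pair enrichment tests between focal and background counts
#'
#' Fisher's exact test per pair on the 2x2 table (pair vs rest, focal vs
#' background), two-sided and one-sided ("greater" in the focal set),
#' with Benjamini-Hochberg correction across the tested pairs.
#'
#' @param countsFocal,countsBackground named count vectors (e.g. the
#'   `counts` element of [extractPairCounts()]).
#' @param pairs pairs to test; default all pairs seen in either set.
#' @return data.frame with raw and adjusted p-values and the focal odds
#'   ratio.
#' @export
pairEnrichmentTest <- function(countsFocal, countsBackground, pairs = NULL) {
  if (is.list(countsFocal)) countsFocal <- countsFocal$counts
  if (is.list(countsBackground)) countsBackground <- countsBackground$counts
  if (is.null(pairs))
    pairs <- sort(unique(c(names(countsFocal), names(countsBackground))))
  nf <- sum(countsFocal)
  nb <- sum(countsBackground)
  if (nf == 0 || nb == 0) stop("zero-total count set")
  res <- lapply(pairs, function(p) {
    a <- if (p %in% names(countsFocal)) countsFocal[[p]] else 0L
    c_ <- if (p %in% names(countsBackground)) countsBackground[[p]] else 0L
    tab <- rbind(c(a, nf - a), c(c_, nb - c_))
    two <- fisher.test(tab, alternative = "two.sided")
    one <- fisher.test(tab, alternative = "greater")
    data.frame(pair = p, focal = a, background = c_,
               odds_ratio = unname(two$estimate),
               p_two_sided = two$p.value, p_greater = one$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj_two_sided <- p.adjust(out$p_two_sided, "BH")
  out$p_adj_greater <- p.adjust(out$p_greater, "BH")
  out
}
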
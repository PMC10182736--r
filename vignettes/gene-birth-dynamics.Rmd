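---
title: "Dating new genes and profiling their early evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating new genes and profiling their early evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneBirthDynamics)
```

## The problem

New protein-coding genes arise mainly in two ways: by duplication of an
existing gene, and de novo from previously noncoding sequence. Given an
orthology clustering of the proteomes of a clade (gene families plus
reconciled per-branch duplication events) and a rooted species tree,
this package dates each reference-species gene to the branch where it
was born, separates the two mechanisms, and then profiles what the young
genes look like: how strongly purifying selection acts on them
(normalized PN/PS), how their amino-acid composition drifts relative to
a mutational null model, and whether they sit in regions of conserved
synteny.

Every stage can be exercised end to end on synthetic data with known
ground truth, which is how the test suite validates the implementation.

## Branch dating and classification

The species tree is wrapped in a `SpeciesTree` object that labels every
node on the path from the reference species' terminal branch to the
root as N0, N1, ... Nk (N0 = the terminal branch, the root carries the
deepest label). A gene family's birth branch is the label of the most
recent common ancestor of the species represented in it: the most
distant species in the family sets the age. Terminal nodes may stand
for several species (`tipGroups`); presence of any one member counts
the tip as present. Lineage-specific losses can only shrink the species
set, so a family's estimated age is a lower bound — the suite asserts
this "younger bias" explicitly on simulations with 30% lineage loss.

Classification resolves each reference gene to exactly one of six
classes. Whole-genome-duplication paralogs (an input list; WGD is not
inferred) are excluded first so only small-scale duplications are
counted. Outgroup evidence — homology hits in at least 2 species
outside the clade at E < 0.001 — makes a family "ancient": ancient
families spanning the deepest branch contribute `conserved` genes,
while ancient but clade-restricted families are discarded as likely
multiple-loss artifacts (`removed_outgroup_homology`). Families without
outgroup evidence are de novo candidates dated by their species
distribution; members of supported duplication records inside them are
`de_novo_plus_duplicated` (one de novo event, plus duplication events
counted separately), elsewhere `duplicated`, dated by the most recent
event containing them. Duplication records need support >= 0.5 by
default (a conventional reconciliation confidence cutoff; the value is
a parameter). Events whose descendant genes all lie outside the
reference species are still counted on their branch and flagged
(`reference_seen = FALSE`), since branch-level event totals are a
property of the tree, not of the reference proteome.

Per-branch event counts are normalized by 100 x branch length
(substitutions/site), i.e. events per amino-acid substitution per 100
residues, which makes short terminal branches comparable with long
internal ones. A zero-length branch with events is an error rather than
an infinity.

## Normalized PN/PS

For a group of coding sequences, the observed ratio of nonsynonymous to
synonymous SNPs (PN/PS) is divided by its neutral expectation EN/ES.
The expectation enumerates, for every codon occurrence in the group,
all nine single-nucleotide mutants, weighting each by the relative
frequency of that base change in a 4x4 mutation matrix estimated from
intronic SNPs (intronic positions overlapping any exon are excluded
when the matrix is built). Values near 1 mean no purifying selection;
the smaller the value, the stronger the constraint.

Numerical and policy choices:

* **Stop-gaining changes** are excluded from both EN and ES by default
  (nonsense is not missense); `countNonsenseAsNonsyn = TRUE` folds them
  into the nonsynonymous side on both the observed and expected side,
  so the two stay consistent.
* **Matrix orientation** is ref -> alt without strand collapsing;
  `symmetrizeMatrix()` averages complementary entries for data sets
  where the ascertainment is strand-symmetric. Both modes are exposed
  because source panels differ.
* **Codons with several SNPs**: each SNP is scored independently
  against the reference codon.
* **MAF filter**: deep population panels support a minor-allele
  frequency floor (0.05 for yeast-isolate-style panels) to avoid
  private variants; panels without usable frequencies run with 0.
* **Pooling**: SNPs are sparse on thin branches, so branch classes are
  pooled (`groupPool()`): N0 / N1–N4 / N5 for the yeast-shaped tree,
  N0 / N1–N2 / N3–N4 / N5 / N6 for the fly-shaped tree, plus a
  conserved group. Counts are pooled before the ratio — per-gene ratios
  are unstable at these SNP densities (PS is often 0 for a single
  gene).
* **Uncertainty** is the standard deviation of the estimate over 1,000
  random subsamples of one third of the group's genes.
* The group-level observed-vs-expected contrast uses Pearson's
  chi-square with Yates' continuity correction, with the expected
  counts scaled to the observed total.

## The amino-acid substitution null model

For diverged protein pairs, the observed frequency of each unordered
amino-acid pair in the alignment columns is compared with a null
computed from codon frequencies and the mutation matrix: the weight of
an ordered change is the summed f(codon) x m(base change) over its
single-nucleotide codon routes, pair weights add both directions, the
table is restricted to pairs that are single-nucleotide reachable and
actually observed in the focal set, and expected counts are normalized
to the observed total. Route finding is validated against a brute-force
scan of all 61 x 61 codon pairs; the K/E pair, for instance, has
exactly the routes AAA<->GAA and AAG<->GAG.

Directionality uses three-species alignments under parsimony: a column
counts only when exactly two species share a residue and the reference
is one of them; the shared residue is ancestral and the change falls on
the differing sister's branch. Columns with gaps or ambiguity codes in
any of the three sequences are excluded, as are columns where all three
differ. Per-pair enrichment between a focal and a background set uses
Fisher's exact test with Benjamini–Hochberg correction (the correction
method is configurable; both one- and two-sided p-values are reported
because either convention is found in practice).

The residue classes are acidic {D,E}, basic {K,R,H}, polar
{S,T,N,Q,C,Y} and nonpolar {A,V,L,I,P,F,M,W,G}; the scheme is a
parameter and is recorded in outputs. Selenocysteine and ambiguity
codes are skipped.

## Sequence properties

The isoelectric point solves for the pH where the Henderson–Hasselbalch
net charge of the termini and the D/E/C/Y/K/R/H side chains crosses
zero, by bisection to |charge| < 1e-4. The default pK set is the EMBOSS
table (N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8,
R 12.5, Y 10.1); published pI values depend on the pK scale, so the
table is a parameter and the choice should be reported with results.
The translated-intron control set uses the same ORF rule as transcript
translation (NTG start to the first in-frame stop, >= 10 residues);
a fixed-frame policy is provided as an alternative since either
convention produces a composition control. Group comparisons use the
two-sided Mann–Whitney–Wilcoxon test; medians of even-sized groups are
the midpoint of the central pair.

## Synteny blocks from maximal unique matches

A MUM is a maximal exact match whose substring occurs exactly once in
each genome; detection uses a generalized suffix array and is tested
for exact agreement with a brute-force common-substring oracle on
random genome pairs, in both orientations. `N` never matches anything,
itself included. Blocks cluster MUMs that are parallel (same
orientation), consecutive (adjacent in genome-a order with consistent
genome-b order) and neighboring — gap of at most 100 bases, enforced in
*both* genomes, the stricter reading of a single-threshold rule and the
one that keeps blocks collinear. Reverse-orientation MUMs are computed
against the reverse complement and never cluster with forward ones.
The minimum MUM length defaults to 20 (an anchor length typical of
MUM-based aligners); both parameters are recorded in block outputs.

## What the generators emulate — and what they do not

The generators draw the data structures the analysis consumes, with
known truth:

* **Gene histories**: Poisson numbers of de novo and duplication events
  per branch (default 2 per branch and mechanism), per-lineage family
  loss with probability `lossProb` (the reference copy is never lost —
  the analysis is reference-centric and undefined for families without
  the reference), conserved and contaminant families carrying hits in
  two outgroup species at E = 1e-10, duplication records with support
  1.0, and a WGD exclusion list.
* **CDS + SNPs**: codons drawn from a configurable frequency vector
  (uniform over the 61 sense codons by default); SNP proposals drawn
  jointly over (site, alternate allele) proportional to the mutation
  matrix, accepted with probability 1 (synonymous) or f
  (nonsynonymous), stop-gaining proposals rejected. Under this scheme
  the normalized PN/PS estimates f exactly in expectation, which is
  what the recovery tests assert at f in {0.1, 0.3, 1.0} with 500
  genes x 300 codons and 10,000 SNPs. The default mutational spectrum
  is transition-biased (kappa = 2), a typical genome-wide value.
* **Protein families**: each codon of an ancestral sequence mutates at
  most once with probability `divergence` (default 0.05/codon); the
  low-divergence regime in which observed amino-acid pairs follow the
  single-nucleotide null exactly. A charge-shift factor s multiplies
  the acceptance of basic -> acidic changes to plant a directional
  signal.
* **Genome pairs**: genome B is genome A with unrelated insertions
  between conserved segments and optional point mutations inside them.

Not emulated: indels inside coding sequence (alignments are therefore
trivial, and gap handling is tested with hand-written fixtures), the
orthology clustering step itself (orthogroups are generated directly),
recurrent loss heterogeneity across branches, and linkage between SNPs.
Passing the recovery tests therefore shows the estimators are correct
under the stated model, not that real annotation noise, alignment
error, or demography are handled.

A note on calibration variance: at ~5,000 amino-acid changes the
rarest residue-class pairs (acidic/acidic, basic/basic, acidic/basic)
expect only ~100 counts each, so the standard error of their class
log2 O/E is about 0.14. Neutral-simulation class values are unbiased
(mean within 0.02 of 0 across seeds) but individual runs can exceed
0.2 in absolute value without indicating any defect; pair-level
calibration (fraction of pairs beyond |log2 O/E| = 0.5) is the more
stable summary at this depth.

## Determinism and problem sizes

A single top-level seed drives everything; each generator derives its
own child seed, so stages can be regenerated independently and a run
manifest plus config reproduces every output byte for byte
(`runPipeline()` writes the manifest). The shipped test and demo sizes
— 500 x 300-codon genes with 10,000 SNPs for selection recovery,
~72,000 codons (~5,000 changes) for substitution calibration, 50
random pairs up to 1 kb for the MUM oracle, a 6 kb genome pair for
synteny — are chosen so each check runs in seconds while keeping the
statistical resolution stated above.

## Known limitations

* Single-interval CDS mapping in the SNP scorer (spliced CDS need a
  precomputed `cds_pos` column).
* Isoform tie-breaking (equal protein lengths) takes the
  lexicographically smallest transcript id and flags the gene; no
  biological criterion is applied.
* The suffix-array construction is simple comparison-based sorting:
  fine up to a few hundred kb per genome, not engineered for
  chromosome-scale inputs.
* Birth-death dating inherits the general limits of presence/absence
  phylostratigraphy: homology detection failure at long distances
  inflates apparent youth, which is why deep-branch assignments should
  be read as lower bounds and the outgroup filter is applied.

```{r example}
cfg <- simConfig(seed = 1, purifyingFactor = 0.3)
sim <- simulateCdsSnps(cfg)
mat <- buildMutationMatrix(sim$snps)
normalizedPnPs(sim$genes, sim$snps, mat)[, c("PN_obs", "PS_obs",
                                             "ratio_obs", "ratio_exp",
                                             "normalized")]
```
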
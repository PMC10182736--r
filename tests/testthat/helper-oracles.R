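## Independent brute-force oracles used to freeze expected values.

## Enumerate all 9 single-nucleotide mutants of a codon directly.
bruteCodonMutants <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- NULL
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (alt in setdiff(bases, ref)) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      out <- rbind(out, data.frame(pos = pos, from = ref, to = alt,
                                   mutant = mut))
    }
  }
  out
}

## Expected EN/ES of a single codon by brute enumeration against a
## mutation-frequency lookup function.
bruteExpectedPnPs <- function(codon, mfun, countNonsense = FALSE) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  mut <- bruteCodonMutants(codon)
  EN <- 0; ES <- 0
  for (i in seq_len(nrow(mut))) {
    maa <- code[[mut$mutant[i]]]
    w <- mfun(mut$from[i], mut$to[i])
    if (maa == "*") { if (countNonsense) EN <- EN + w }
    else if (maa == aa) ES <- ES + w
    else EN <- EN + w
  }
  c(EN = EN, ES = ES)
}

## All unordered amino-acid pairs reachable by one nucleotide change,
## by scanning every pair of sense codons.
bruteReachablePairs <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  pairs <- character(0)
  for (c1 in sense) for (c2 in sense) {
    d <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (d == 1 && code[[c1]] != code[[c2]]) {
      aa <- sort(c(code[[c1]], code[[c2]]))
      pairs <- c(pairs, paste(aa[1], aa[2], sep = "/"))
    }
  }
  sort(unique(pairs))
}

## Brute-force MUM oracle: all maximal common substrings (diagonal
## run-length DP), filtered for uniqueness by overlapping occurrence
## counts in each sequence.
bruteMumsForward <- function(a, b, minLen) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  sa <- Biostrings::DNAString(a)
  sb <- Biostrings::DNAString(b)
  hits <- NULL
  for (d in (-(n - 1)):(m - 1)) {
    i0 <- max(1, 1 - d); i1 <- min(n, m - d)
    if (i1 < i0) next
    ii <- i0:i1
    jj <- ii + d
    mv <- av[ii] == bv[jj] & av[ii] != "N" & bv[jj] != "N"
    pos <- seq_along(mv)
    lastF <- cummax(ifelse(!mv, pos, 0L))
    L <- pos - lastF
    ## maximal = run ends here (next cell off-grid or mismatch)
    maximal <- mv & (pos == length(mv) | c(!mv[-1], TRUE)) & L >= minLen
    for (k in which(maximal)) {
      len <- L[k]
      ia <- ii[k] - len + 1L
      jb <- jj[k] - len + 1L
      pat <- substr(a, ia, ia + len - 1L)
      if (Biostrings::countPattern(pat, sa) == 1L &&
          Biostrings::countPattern(pat, sb) == 1L)
        hits <- rbind(hits, data.frame(start_a = ia - 1L, start_b = jb - 1L,
                                       length = len))
    }
  }
  if (is.null(hits))
    hits <- data.frame(start_a = integer(), start_b = integer(),
                       length = integer())
  hits[order(hits$start_a, hits$start_b), , drop = FALSE]
}

bruteMums <- function(a, b, minLen, orientation = "forward") {
  fwd <- bruteMumsForward(a, b, minLen)
  fwd$orientation <- rep("forward", nrow(fwd))
  if (orientation == "forward") return(fwd)
  brc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  rc <- bruteMumsForward(a, brc, minLen)
  if (nrow(rc)) {
    rc$start_b <- nchar(b) - (rc$start_b + rc$length)
    rc$orientation <- "reverse"
  } else rc$orientation <- character(0)
  out <- rbind(fwd, rc)
  out[order(out$start_a, out$start_b), , drop = FALSE]
}

## random DNA of length n
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

## pH-grid net-charge scan, an independent check on the pI bisection
gridScanPI <- function(protein, pk) {
  res <- strsplit(protein, "")[[1]]
  cnt <- function(x) sum(res == x)
  charge <- function(pH) {
    pos <- 1 / (1 + 10^(pH - pk[["Nterm"]])) +
      cnt("K") / (1 + 10^(pH - pk[["K"]])) +
      cnt("R") / (1 + 10^(pH - pk[["R"]])) +
      cnt("H") / (1 + 10^(pH - pk[["H"]]))
    neg <- 1 / (1 + 10^(pk[["Cterm"]] - pH)) +
      cnt("D") / (1 + 10^(pk[["D"]] - pH)) +
      cnt("E") / (1 + 10^(pk[["E"]] - pH)) +
      cnt("C") / (1 + 10^(pk[["C"]] - pH)) +
      cnt("Y") / (1 + 10^(pk[["Y"]] - pH))
    pos - neg
  }
  grid <- seq(0, 14, by = 1e-4)
  ch <- vapply(grid, charge, numeric(1))
  grid[which.min(abs(ch))]
}
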
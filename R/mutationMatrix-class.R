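#' MutationMatrix: relative single-nucleotide mutation frequencies
#'
#' Holds the 12 off-diagonal relative frequencies m(X->Y), X,Y in
#' {A,C,G,T}, summing to 1, in ref->alt orientation. Estimated from
#' intronic SNPs (putatively neutral sites) and used as the mutational
#' null in the expected PN/PS and the expected amino-acid change tables.
#'
#' @slot mat 4x4 numeric matrix, dimnames A/C/G/T, `NA` diagonal.
#' @slot nSourceSnps number of SNPs the matrix was estimated from.
#' @export
setClass("MutationMatrix",
  representation(mat = "matrix", nSourceSnps = "integer"))

setValidity("MutationMatrix", function(object) {
  m <- object@mat
  if (!identical(dim(m), c(4L, 4L))) return("mat must be 4x4")
  if (!identical(rownames(m), DNA_BASES) || !identical(colnames(m), DNA_BASES))
    return("dimnames must be A,C,G,T")
  off <- m[row(m) != col(m)]
  if (any(is.na(off)) || any(off < 0)) return("off-diagonal entries must be >= 0")
  if (abs(sum(off) - 1) > 1e-9) return("off-diagonal entries must sum to 1")
  TRUE
})

#' Construct a MutationMatrix
#' @param mat 4x4 numeric with dimnames A/C/G/T (diagonal ignored) or a
#'   12-element named vector `"A>G"` style.
#' @param nSourceSnps integer, SNPs behind the estimate.
#' @param normalize rescale off-diagonal entries to sum to 1.
#' @return a [MutationMatrix-class].
#' @export
mutationMatrix <- function(mat, nSourceSnps = NA_integer_, normalize = FALSE) {
  if (is.vector(mat)) {
    v <- mat
    mat <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    for (nm in names(v)) {
      ft <- strsplit(nm, ">", fixed = TRUE)[[1]]
      mat[ft[1], ft[2]] <- v[[nm]]
    }
  }
  diag(mat) <- 0
  if (normalize) {
    s <- sum(mat)
    if (s <= 0) stop("all-zero mutation matrix")
    mat <- mat / s
  }
  diag(mat) <- NA_real_
  new("MutationMatrix", mat = mat, nSourceSnps = as.integer(nSourceSnps))
}

#' @rdname mutationMatrix
#' @export
uniformMutationMatrix <- function() {
  m <- matrix(1 / 12, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(m) <- NA_real_
  new("MutationMatrix", mat = m, nSourceSnps = NA_integer_)
}

#' Transition-biased mutation matrix
#'
#' Relative frequencies with each of the 4 transitions `kappa` times more
#' frequent than each of the 8 transversions; the generators' default
#' mutational model (kappa = 2, a typical genome-wide bias).
#' @param kappa transition/transversion rate ratio.
#' @export
transitionBiasedMatrix <- function(kappa = 2) {
  m <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  ts <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  m[ts] <- kappa
  diag(m) <- 0
  m <- m / sum(m)
  diag(m) <- NA_real_
  new("MutationMatrix", mat = m, nSourceSnps = NA_integer_)
}

#' Estimate the mutation matrix from intronic SNPs
#'
#' Counts the 12 ref->alt substitution types among SNPs with
#' `context == "intron"` (intronic positions not overlapping any exon,
#' assigned by [parseSnps()]) and normalizes to relative frequencies.
#'
#' @param snps SNP data.frame with columns `ref`, `alt` and (optionally)
#'   `context`; rows with other contexts are ignored.
#' @return a [MutationMatrix-class].
#' @export
buildMutationMatrix <- function(snps) {
  if ("context" %in% names(snps))
    snps <- snps[snps$context == "intron", , drop = FALSE]
  if (nrow(snps) == 0L) stop("no intronic SNPs to estimate the matrix from")
  m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  tab <- table(factor(snps$ref, DNA_BASES), factor(snps$alt, DNA_BASES))
  m[] <- as.numeric(tab)
  mutationMatrix(m, nSourceSnps = nrow(snps), normalize = TRUE)
}

#' Look up mutation frequencies
#' @param object a [MutationMatrix-class].
#' @param from,to base vectors (recycled).
#' @export
mutationFreq <- function(object, from, to) {
  object@mat[cbind(from, to)]
}

#' @rdname mutationMatrix
#' @param object a [MutationMatrix-class].
#' @export
nSourceSnps <- function(object) object@nSourceSnps

#' Average complementary-strand entries
#'
#' Strand-collapses the matrix: m(X->Y) and m(comp(X)->comp(Y)) are
#' replaced by their mean. Whether the source data should be collapsed is
#' dataset-dependent, so both orientations are supported.
#' @param object a [MutationMatrix-class].
#' @export
symmetrizeMatrix <- function(object) {
  m <- object@mat
  out <- m
  for (x in DNA_BASES) for (y in DNA_BASES) {
    if (x == y) next
    out[x, y] <- (m[x, y] + m[.compBase(x), .compBase(y)]) / 2
  }
  new("MutationMatrix", mat = out, nSourceSnps = object@nSourceSnps)
}

#' Read/write a mutation matrix as 3-column TSV (from, to, frequency)
#' @param object a [MutationMatrix-class].
#' @param path file path.
#' @export
writeMutationMatrix <- function(object, path) {
  idx <- which(row(object@mat) != col(object@mat), arr.ind = TRUE)
  df <- data.frame(from = DNA_BASES[idx[, 1]], to = DNA_BASES[idx[, 2]],
                   frequency = object@mat[idx])
  df <- df[order(df$from, df$to), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# n_source_snps=", object@nSourceSnps), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMutationMatrix
#' @export
readMutationMatrix <- function(path) {
  lines <- readLines(path)
  n <- NA_integer_
  meta <- grep("^# n_source_snps=", lines, value = TRUE)
  if (length(meta))
    n <- suppressWarnings(as.integer(sub("^# n_source_snps=", "", meta[1])))
  df <- read.delim(text = paste(lines[!startsWith(lines, "#")], collapse = "\n"))
  v <- setNames(df$frequency, paste0(df$from, ">", df$to))
  mutationMatrix(v, nSourceSnps = n)
}

setMethod("show", "MutationMatrix", function(object) {
  cat("MutationMatrix (relative frequencies, ref->alt)\n")
  print(round(object@mat, 4))
  if (!is.na(object@nSourceSnps))
    cat("estimated from", object@nSourceSnps, "SNPs\n")
})
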
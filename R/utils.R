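#' @import methods
#' @importFrom stats pchisq fisher.test p.adjust wilcox.test median sd rbinom rpois runif setNames
#' @importFrom utils read.delim write.table head
#' @useDynLib geneBirthDynamics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The standard genetic code and its sense codons
#'
#' `geneticCode()` returns the codon -> amino-acid map (standard code,
#' `*` marks stops); `senseCodons()` the 61 stop-free codons in the
#' order used by codon-frequency vectors.
#' @export
geneticCode <- function() Biostrings::GENETIC_CODE

#' @rdname geneticCode
#' @export
senseCodons <- function() {
  gc <- geneticCode()
  names(gc)[gc != "*"]
}

.splitCodons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L)
    stop("sequence length not divisible by 3: ", n)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

.translateCodons <- function(codons) {
  aa <- geneticCode()[codons]
  if (anyNA(aa))
    stop("non-ACGT codon(s): ", paste(unique(codons[is.na(aa)]), collapse = ", "))
  unname(aa)
}

#' Translate a coding sequence
#'
#' Translates an in-frame CDS with the standard genetic code. A single
#' terminal stop codon is dropped; internal stops raise an error unless
#' `allowStops = TRUE` (then kept as `*`).
#'
#' @param cds character vector of nucleotide sequences (A/C/G/T).
#' @param allowStops keep internal stop codons as `*` instead of erroring.
#' @return character vector of amino-acid sequences.
#' @export
translateCds <- function(cds, allowStops = FALSE) {
  vapply(cds, function(x) {
    codons <- .splitCodons(x)
    if (length(codons) && codons[length(codons)] %in% STOP_CODONS)
      codons <- codons[-length(codons)]
    aa <- .translateCodons(codons)
    if (!allowStops && any(aa == "*"))
      stop("internal stop codon in CDS")
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.compBase <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

## deterministic child seed derivation: keeps values < 2^31
.childSeed <- function(seed, stream) {
  (as.integer(seed) * 48271L + stream * 9973L) %% 2147483629L
}

.readLinesMaybe <- function(x) {
  ## accepts a file path or literal text (anything containing a newline or tab)
  if (length(x) == 1L && !grepl("[\n\t>();]", x) && file.exists(x))
    return(readLines(x))
  unlist(strsplit(x, "\n", fixed = TRUE))
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings returning/accepting plain named
#' character vectors, used throughout the package for proteomes, CDS and
#' genome sequences.
#'
#' @param path file path.
#' @param x named character vector of sequences.
#' @return `readFasta`: named character vector.
#' @export
readFasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  setNames(as.character(s), names(s))
}

#' @rdname readFasta
#' @export
writeFasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path)
  invisible(path)
}
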
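## Maximal-unique-match detection between two genomes and clustering of
## parallel, consecutive, neighboring MUMs into synteny blocks.

#' Find maximal unique matches (MUMs) between two genomes
#'
#' A MUM is a maximal exact match whose substring occurs exactly once in
#' each genome on the stated orientation; it cannot be extended by one
#' base on either side without breaking the match or its uniqueness.
#' `N` bases never match. Detection uses a generalized suffix array.
#' Reverse-orientation MUMs (when `orientation = "both"`) are computed
#' against the reverse complement of genome B and reported with
#' forward-strand B coordinates.
#'
#' @param a,b nucleotide sequences over A/C/G/T/N (nonempty).
#' @param minLen minimum MUM length; 20 is an M-GCAT-style anchor length.
#' @param orientation `"forward"` or `"both"`.
#' @return data.frame with `start_a`, `start_b` (0-based, half-open with
#'   `length`), `length`, `orientation`.
#' @export
findMums <- function(a, b, minLen = 20L, orientation = c("forward", "both")) {
  orientation <- match.arg(orientation)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty genome sequence")
  fwd <- .findMumsCpp(toupper(a), toupper(b), as.integer(minLen))
  fwd$orientation <- rep("forward", nrow(fwd))
  out <- fwd
  if (orientation == "both") {
    rc <- .findMumsCpp(toupper(a), .revcomp(toupper(b)), as.integer(minLen))
    if (nrow(rc)) {
      rc$start_b <- nchar(b) - (rc$start_b + rc$length)
      rc$orientation <- "reverse"
      out <- rbind(out, rc)
    }
  }
  out <- out[order(out$start_a, out$start_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster MUMs into synteny blocks
#'
#' Two MUMs are linked when they are parallel (same orientation),
#' consecutive (adjacent in genome-a order with consistent genome-b
#' order: increasing for forward blocks, decreasing for reverse ones)
#' and neighboring (gap at most `maxGap` bases in both genomes). Blocks
#' are the connected components of this linkage; their spans cover all
#' member MUMs.
#'
#' @param mums data.frame from [findMums()].
#' @param maxGap maximum distance between consecutive clustered MUMs.
#' @return data.frame with one row per block: `block_id`, `orientation`,
#'   `n_mums`, `start_a`, `end_a`, `start_b`, `end_b` (0-based
#'   half-open), `matched_bases`.
#' @export
clusterMums <- function(mums, maxGap = 100L) {
  if (nrow(mums) == 0L)
    return(data.frame(block_id = integer(), orientation = character(),
                      n_mums = integer(), start_a = integer(),
                      end_a = integer(), start_b = integer(),
                      end_b = integer(), matched_bases = integer()))
  out <- NULL
  nextId <- 1L
  for (ori in unique(mums$orientation)) {
    m <- mums[mums$orientation == ori, , drop = FALSE]
    m <- m[order(m$start_a, m$start_b), , drop = FALSE]
    comp <- integer(nrow(m))
    comp[1] <- nextId
    if (nrow(m) > 1) for (i in 2:nrow(m)) {
      gapA <- m$start_a[i] - (m$start_a[i - 1] + m$length[i - 1])
      gapB <- if (ori == "forward")
        m$start_b[i] - (m$start_b[i - 1] + m$length[i - 1])
      else
        m$start_b[i - 1] - (m$start_b[i] + m$length[i])
      orderOk <- if (ori == "forward") m$start_b[i] >= m$start_b[i - 1]
                 else m$start_b[i] <= m$start_b[i - 1]
      linked <- orderOk && gapA <= maxGap && gapB <= maxGap
      comp[i] <- if (linked) comp[i - 1] else (max(comp[1:(i - 1)]) + 1L)
    }
    for (k in unique(comp)) {
      mm <- m[comp == k, , drop = FALSE]
      out <- rbind(out, data.frame(
        block_id = nextId, orientation = ori, n_mums = nrow(mm),
        start_a = min(mm$start_a), end_a = max(mm$start_a + mm$length),
        start_b = min(mm$start_b), end_b = max(mm$start_b + mm$length),
        matched_bases = sum(mm$length)))
      nextId <- nextId + 1L
    }
  }
  out <- out[order(out$start_a), , drop = FALSE]
  out$block_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Does a gene interval fall in a synteny block?
#'
#' @param geneInterval numeric c(start, end), 0-based half-open, on the
#'   queried genome.
#' @param blocks data.frame from [clusterMums()].
#' @param side `"a"` or `"b"`: which genome the interval refers to.
#' @param minFrac minimum fraction of the gene that must overlap a
#'   single block (0 means any 1-bp overlap).
#' @return logical.
#' @export
geneInBlock <- function(geneInterval, blocks, side = c("a", "b"),
                        minFrac = 0) {
  side <- match.arg(side)
  if (nrow(blocks) == 0L) return(FALSE)
  s <- blocks[[paste0("start_", side)]]
  e <- blocks[[paste0("end_", side)]]
  ov <- pmin(e, geneInterval[2]) - pmax(s, geneInterval[1])
  len <- geneInterval[2] - geneInterval[1]
  if (minFrac > 0) any(ov / len >= minFrac) else any(ov > 0)
}

#' Export block spans as BED
#' @param blocks data.frame from [clusterMums()].
#' @param path output file.
#' @param side which genome's coordinates to export.
#' @param contig contig name for the BED column.
#' @export
writeBlocksBed <- function(blocks, path, side = c("a", "b"),
                           contig = "genome") {
  side <- match.arg(side)
  bed <- data.frame(contig,
                    blocks[[paste0("start_", side)]],
                    blocks[[paste0("end_", side)]],
                    paste0("block_", blocks$block_id), 0,
                    ifelse(blocks$orientation == "forward", "+", "-"))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
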
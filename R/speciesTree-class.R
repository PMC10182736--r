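#' SpeciesTree: a rooted species tree with reference-path branch labels
#'
#' Wraps an [ape::read.tree()] `phylo` object together with a reference
#' species and the branch labels N0..Nk assigned along the path from the
#' reference terminal branch (N0) to the root (Nk). Terminal nodes may
#' stand for several species (`tipGroups`), as in dense fly phylogenies
#' where sister species are collapsed into one tip.
#'
#' @slot phy a rooted `phylo` object with branch lengths
#'   (substitutions/site).
#' @slot referenceSpecies the species whose terminal branch is N0.
#' @slot refPathNodes ape node numbers from the reference tip to the root.
#' @slot branchLabels labels "N0".."Nk", parallel to `refPathNodes`.
#' @slot tipGroups named list mapping a tip label to the species names it
#'   represents.
#'
#' @export
setClass("SpeciesTree",
  representation(
    phy = "ANY",
    referenceSpecies = "character",
    refPathNodes = "integer",
    branchLabels = "character",
    tipGroups = "list"
  )
)

setValidity("SpeciesTree", function(object) {
  phy <- object@phy
  if (!inherits(phy, "phylo")) return("phy must be a 'phylo' object")
  if (!ape::is.rooted(phy)) return("species tree must be rooted")
  if (is.null(phy$edge.length)) return("species tree must have branch lengths")
  if (any(phy$edge.length < 0)) return("negative branch length")
  n <- length(object@refPathNodes)
  if (n < 1L) return("empty reference path")
  if (!identical(object@branchLabels, paste0("N", seq_len(n) - 1L)))
    return("branch labels must be N0..Nk along the reference path")
  TRUE
})

.tipOfSpecies <- function(object, species) {
  tips <- object@phy$tip.label
  hit <- match(species, tips)
  if (!is.na(hit)) return(hit)
  for (tl in names(object@tipGroups))
    if (species %in% object@tipGroups[[tl]])
      return(match(tl, tips))
  NA_integer_
}

.parentOf <- function(phy, node) {
  e <- phy$edge
  p <- e[e[, 2] == node, 1]
  if (length(p) == 0L) NA_integer_ else p
}

.tipsUnder <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  e <- phy$edge
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    kids <- e[e[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Parse a species tree and assign reference-path branch labels
#'
#' Reads a rooted newick tree with branch lengths, locates the reference
#' species (directly or through a tip group) and labels every node on the
#' path from the reference tip to the root N0, N1, ... Nk; N0 is the
#' reference terminal branch and the root receives the deepest label.
#'
#' @param newick newick text or a file path.
#' @param referenceSpecies species name present in the tree (or in a tip
#'   group).
#' @param tipGroups named list: tip label -> character vector of species
#'   represented by that tip.
#' @return a [SpeciesTree-class] object.
#' @examples
#' tr <- parseSpeciesTree("(A:1,(B:1,C:1):0.5):0.2;", "C")
#' branchLabels(tr)
#' @export
parseSpeciesTree <- function(newick, referenceSpecies, tipGroups = list()) {
  txt <- if (length(newick) == 1L && !grepl("[();]", newick) && file.exists(newick))
    paste(readLines(newick), collapse = "") else newick
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL)
  if (is.null(phy)) stop("malformed newick")
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  obj <- new("SpeciesTree", phy = phy, referenceSpecies = referenceSpecies,
             refPathNodes = 1L, branchLabels = "N0", tipGroups = tipGroups)
  refTip <- .tipOfSpecies(obj, referenceSpecies)
  if (is.na(refTip))
    stop("reference species '", referenceSpecies, "' not found in tree")
  path <- refTip
  nd <- refTip
  repeat {
    p <- .parentOf(phy, nd)
    if (is.na(p)) break
    path <- c(path, p)
    nd <- p
  }
  obj@refPathNodes <- as.integer(path)
  obj@branchLabels <- paste0("N", seq_along(path) - 1L)
  validObject(obj)
  obj
}

#' Write a SpeciesTree back to newick
#' @param tree a [SpeciesTree-class].
#' @param path optional file; when missing the newick string is returned.
#' @export
writeSpeciesTree <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree@phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname SpeciesTree-class
#' @param object,tree a `SpeciesTree`.
#' @export
referenceSpecies <- function(tree) tree@referenceSpecies

#' @rdname SpeciesTree-class
#' @export
branchLabels <- function(tree) tree@branchLabels

#' Branch lengths of the labelled reference-path branches
#'
#' Returns the length (substitutions/site) of the branch above each
#' labelled node. The root label uses the newick root edge when present,
#' `NA` otherwise.
#' @param tree a [SpeciesTree-class].
#' @return named numeric vector, names N0..Nk.
#' @export
branchLengths <- function(tree) {
  phy <- tree@phy
  out <- vapply(tree@refPathNodes, function(nd) {
    i <- which(phy$edge[, 2] == nd)
    if (length(i)) phy$edge.length[i] else
      if (!is.null(phy$root.edge)) phy$root.edge else NA_real_
  }, numeric(1))
  setNames(out, tree@branchLabels)
}

#' Species contained in the clade of a labelled branch
#' @param tree a [SpeciesTree-class].
#' @param label one of `branchLabels(tree)`.
#' @return character vector of species names (tip groups expanded).
#' @export
cladeSpecies <- function(tree, label) {
  i <- match(label, tree@branchLabels)
  if (is.na(i)) stop("unknown branch label: ", label)
  tips <- .tipsUnder(tree@phy, tree@refPathNodes[i])
  labs <- tree@phy$tip.label[tips]
  unlist(lapply(labs, function(tl)
    if (tl %in% names(tree@tipGroups)) tree@tipGroups[[tl]] else tl),
    use.names = FALSE)
}

#' All species named by the tree (tip groups expanded)
#' @param tree a [SpeciesTree-class].
#' @export
allSpecies <- function(tree) {
  labs <- tree@phy$tip.label
  unlist(lapply(labs, function(tl)
    if (tl %in% names(tree@tipGroups)) tree@tipGroups[[tl]] else tl),
    use.names = FALSE)
}

setMethod("show", "SpeciesTree", function(object) {
  cat("SpeciesTree with", length(object@phy$tip.label), "tips;",
      "reference:", object@referenceSpecies, "\n")
  cat("reference path:", paste(object@branchLabels, collapse = " -> "), "\n")
  if (length(object@tipGroups))
    cat("tip groups:", paste(names(object@tipGroups), collapse = ", "), "\n")
})

#' Assign the birth branch for a set of species
#'
#' The branch of origin of a gene family is the label of the most recent
#' common ancestor, on the reference-to-root path, of all species carrying
#' a member: the deepest species in the family sets the age. For grouped
#' terminal nodes, presence of at least one member species counts the tip
#' as present.
#'
#' @param speciesPresent character vector of species names.
#' @param tree a [SpeciesTree-class].
#' @return a single label, e.g. `"N2"`.
#' @examples
#' tr <- yeastTree()
#' assignBirthBranch("Scer", tr)                 # "N0"
#' assignBirthBranch(c("Scer", "Smik"), tr)      # "N2"
#' @export
assignBirthBranch <- function(speciesPresent, tree) {
  speciesPresent <- unique(speciesPresent)
  if (!any(vapply(speciesPresent, function(s)
    isTRUE(.tipOfSpecies(tree, s) == tree@refPathNodes[1]), logical(1))))
    stop("reference species absent from the family")
  depth <- vapply(speciesPresent, function(s) {
    tip <- .tipOfSpecies(tree, s)
    if (is.na(tip)) stop("species not in tree: ", s)
    for (i in seq_along(tree@refPathNodes))
      if (tip %in% .tipsUnder(tree@phy, tree@refPathNodes[i])) return(i)
    stop("species not under the root (unrooted tree?): ", s)
  }, numeric(1))
  tree@branchLabels[max(depth)]
}

#' Built-in species-tree presets for the simulators
#'
#' `yeastTree()` is an 11-tip budding-yeast-like tree whose reference path
#' carries labels N0..N5 (reference terminal branch length 0.043
#' substitutions/site, a realistic value for the *S. cerevisiae* terminal
#' branch); `fliesTree()` is a 16-tip drosophilid-like tree with labels
#' N0..N6 and two multi-species terminal nodes.
#'
#' @return a [SpeciesTree-class].
#' @export
yeastTree <- function() {
  nwk <- paste0(
    "(((((Scer:0.043,Spar:0.034):0.02,Smik:0.05):0.02,",
    "(Skud:0.05,Sarb:0.05):0.03):0.03,(Suva:0.04,Seub:0.04):0.06):0.06,",
    "(Lklu:0.12,(Lthe:0.10,(Lwal:0.10,Lmar:0.10):0.02):0.03):0.10):0.15;")
  parseSpeciesTree(nwk, "Scer")
}

#' @rdname yeastTree
#' @export
fliesTree <- function() {
  nwk <- paste0(
    "((((((Dmel:0.011,(Dsim:0.015,Dsec:0.015):0.005):0.012,",
    "(Dyak:0.03,Dere:0.03):0.012):0.02,(Dana:0.06,Dbus:0.06):0.015):0.03,",
    "(Dpse:0.03,(Dper:0.02,Dmir:0.02):0.012):0.05):0.03,",
    "(Dwil:0.09,Dgri:0.10):0.02):0.05,",
    "((Dmoj:0.05,Dvir:0.05):0.03,(Dhyd:0.08,Dnav:0.08):0.02):0.06):0.25;")
  parseSpeciesTree(nwk, "Dmel",
    tipGroups = list(Dpse = c("Dpse", "Dlow"), Dnav = c("Dnav", "Dari")))
}
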
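#' Construct a labeled tree
#'
#' @param phy an `ape::phylo` object.
#' @param foreground optional logical vector of per-edge foreground flags
#'   (parallel to `phy$edge` rows); defaults to all background.
#' @return a [LabeledTree-class].
#' @export
labeledTree <- function(phy, foreground = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape 'phylo' object")
  if (is.null(foreground)) foreground <- rep(FALSE, nrow(phy$edge))
  new("LabeledTree", phy = phy, foreground = foreground)
}

#' Read a phylogeny from a newick file
#'
#' Accepts rooted or unrooted newick, with or without branch lengths.
#' Engine-style `#1` branch tags on tip or internal-node labels are parsed
#' into foreground flags and stripped from the labels. Trees with fewer
#' than 3 leaves are rejected: unrooted likelihood is undefined for them.
#'
#' @param path newick file path (or a newick string via `text`).
#' @param text optional newick text, used instead of `path`.
#' @return a [LabeledTree-class].
#' @export
readLabeledTree <- function(path, text = NULL) {
  phy <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(phy)) stop("malformed newick input")
  if (length(phy$tip.label) < 3L)
    stop("tree has fewer than 3 leaves; unrooted likelihood needs >= 3")
  ntip <- length(phy$tip.label)
  tagged <- logical(ntip + phy$Nnode)
  hasTag <- grepl("#1$", phy$tip.label)
  tagged[seq_len(ntip)] <- hasTag
  phy$tip.label <- sub("\\s*#1$", "", phy$tip.label)
  if (!is.null(phy$node.label)) {
    nt <- grepl("#1$", phy$node.label)
    tagged[ntip + seq_len(phy$Nnode)] <- nt
    phy$node.label <- sub("\\s*#1$", "", phy$node.label)
    if (all(!nzchar(phy$node.label))) phy$node.label <- NULL
  }
  fg <- tagged[phy$edge[, 2L]]
  labeledTree(phy, fg)
}

#' Write a labeled tree to newick, with engine-style foreground tags
#'
#' Flagged branches are exported by appending `#1` to the label of the
#' child node of each flagged edge (tip labels for terminal branches,
#' node labels for internal ones), the interchange convention of standard
#' codon-model engines.
#'
#' @param tree a [LabeledTree-class].
#' @param path output file; if `NULL` the newick string is returned.
#' @return the newick string, invisibly when written to a file.
#' @export
writeForegroundNewick <- function(tree, path = NULL) {
  phy <- tree@phy
  ntip <- length(phy$tip.label)
  fgNode <- rep(FALSE, ntip + phy$Nnode)
  fgNode[phy$edge[tree@foreground, 2L]] <- TRUE
  phy$tip.label <- paste0(phy$tip.label,
                          ifelse(fgNode[seq_len(ntip)], "#1", ""))
  if (any(fgNode[-seq_len(ntip)])) {
    lab <- if (is.null(phy$node.label)) rep("", phy$Nnode) else phy$node.label
    lab <- paste0(lab, ifelse(fgNode[ntip + seq_len(phy$Nnode)], "#1", ""))
    phy$node.label <- lab
  }
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname codonSelect-accessors
#' @export
setMethod("taxonNames", "LabeledTree", function(x) x@phy$tip.label)

#' @rdname codonSelect-accessors
#' @export
setMethod("nTaxa", "LabeledTree", function(x) length(x@phy$tip.label))

#' @rdname codonSelect-accessors
#' @export
setMethod("foreground", "LabeledTree", function(x) x@foreground)

#' @rdname codonSelect-accessors
#' @export
setMethod("foreground<-", "LabeledTree", function(x, value) {
  x@foreground <- value
  validObject(x)
  x
})

#' @rdname codonSelect-accessors
#' @export
setMethod("branchLengths", "LabeledTree", function(x) x@phy$edge.length)

#' @rdname codonSelect-accessors
#' @export
setMethod("branchLengths<-", "LabeledTree", function(x, value) {
  x@phy$edge.length <- value
  validObject(x)
  x
})

setMethod("show", "LabeledTree", function(object) {
  cat("LabeledTree:", length(object@phy$tip.label), "leaves,",
      nrow(object@phy$edge), "branches,",
      sum(object@foreground), "foreground",
      if (is.null(object@phy$edge.length)) "(branch lengths unset)" else "",
      "\n")
})

#' Unroot a tree
#'
#' Collapses a degree-2 root, summing its two incident branch lengths, so
#' the basal node is a multifurcation; under a reversible substitution
#' model the likelihood is unchanged. Foreground flags are recomputed from
#' the set of flagged terminal branches under the [tagForeground()]
#' convention. An already-unrooted tree is returned unchanged.
#'
#' @param tree a [LabeledTree-class].
#' @return an unrooted [LabeledTree-class].
#' @export
unrootTree <- function(tree) {
  phy <- tree@phy
  if (!ape::is.rooted(phy)) return(tree)
  fgTaxa <- phy$tip.label[phy$edge[tree@foreground, 2L][
    phy$edge[tree@foreground, 2L] <= length(phy$tip.label)]]
  un <- ape::unroot(phy)
  out <- labeledTree(un)
  if (length(fgTaxa)) out <- tagForeground(out, fgTaxa)
  out
}

## logical ntip x nedge: which tips descend from each edge's child
.edgeDescendants <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  desc <- matrix(FALSE, nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in seq_len(nrow(po$edge))) {
    pa <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    desc[pa, ] <- desc[pa, ] | desc[ch, ]
  }
  desc[phy$edge[, 2L], , drop = FALSE]
}

#' Foreground taxa of a labeled tree
#'
#' @param tree a [LabeledTree-class].
#' @return leaf names whose terminal branch is flagged foreground.
#' @export
foregroundTaxa <- function(tree) {
  phy <- tree@phy
  ch <- phy$edge[tree@foreground, 2L]
  phy$tip.label[ch[ch <= length(phy$tip.label)]]
}

#' Flag foreground branches from a taxon set
#'
#' Marks the terminal branch of every foreground taxon plus every internal
#' branch whose descendant leaves are all foreground (so a monophyletic
#' foreground clade gets its stem flagged); all other branches are
#' background. The foreground set must be a non-empty proper subset of the
#' leaves, otherwise no foreground/background contrast exists.
#'
#' @param tree a [LabeledTree-class].
#' @param foregroundTaxa character vector of leaf names.
#' @return the tree with `foreground` flags set.
#' @examples
#' tr <- readLabeledTree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' sum(foreground(tagForeground(tr, c("A", "B"))))   # 3
#' sum(foreground(tagForeground(tr, c("A", "C"))))   # 2
#' @export
tagForeground <- function(tree, foregroundTaxa) {
  phy <- tree@phy
  tips <- phy$tip.label
  bad <- setdiff(foregroundTaxa, tips)
  if (length(bad))
    stop("foreground taxa not in tree: ", paste(bad, collapse = ", "))
  if (length(foregroundTaxa) == 0L)
    stop("foreground set is empty: no contrast possible")
  if (setequal(foregroundTaxa, tips))
    stop("foreground set equals all leaves: no contrast possible")
  isFg <- tips %in% foregroundTaxa
  desc <- .edgeDescendants(phy)
  flags <- vapply(seq_len(nrow(desc)),
                  function(e) all(isFg[desc[e, ]]), logical(1L))
  labeledTree(phy, flags)
}
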
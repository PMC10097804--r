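#' Simulate a random tree with foreground branches
#'
#' Draws a random resolved topology with branch lengths from an exponential
#' distribution (mean `scale`, in expected codon substitutions per codon)
#' and flags a foreground subset of the leaves: by default a clade whose
#' size is as close as possible to `foregroundCount`, or a random leaf
#' subset with `cladeForeground = FALSE`. Foreground flags follow the
#' [tagForeground()] convention (terminals plus foreground-pure internal
#' branches).
#'
#' @param ntaxa number of leaves (>= 4).
#' @param foregroundCount number of foreground leaves (>= 1, < `ntaxa`).
#' @param scale mean branch length (default 0.1).
#' @param seed random seed (mandatory: simulations are reproducible).
#' @param cladeForeground pick a clade (default) or a random subset.
#' @return a [LabeledTree-class], unrooted, with foreground flags.
#' @examples
#' tr <- simulateTree(13, foregroundCount = 6, seed = 7)
#' sum(foreground(tr)) >= 6
#' @export
simulateTree <- function(ntaxa, foregroundCount, scale = 0.1, seed,
                         cladeForeground = TRUE) {
  if (missing(seed)) stop("seed is mandatory for reproducible simulation")
  if (ntaxa < 4L) stop("need at least 4 taxa")
  if (foregroundCount < 1L || foregroundCount >= ntaxa)
    stop("foregroundCount must be in [1, ntaxa - 1]")
  set.seed(seed)
  phy <- ape::rtree(ntaxa, rooted = FALSE,
                    br = function(n) rexp(n, rate = 1 / scale))
  phy$tip.label <- sprintf("t%02d", seq_len(ntaxa))
  tree <- labeledTree(phy)
  if (cladeForeground) {
    desc <- .edgeDescendants(phy)
    sizes <- rowSums(desc)
    ok <- which(sizes < ntaxa)
    pick <- ok[which.min(abs(sizes[ok] - foregroundCount))]
    fgTaxa <- phy$tip.label[desc[pick, ]]
  } else {
    fgTaxa <- sample(phy$tip.label, foregroundCount)
  }
  tagForeground(tree, fgTaxa)
}

## sample next states given current states through a transition matrix,
## grouping sites by current state so each row is sampled once
.evolveStates <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    idx <- which(states == s)
    out[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                           prob = P[s, ])
  }
  out
}

#' Simulate a codon alignment along a tree
#'
#' Generates codons under a fully specified model truth: each site draws a
#' class from the truth proportions, the root codon is drawn from the
#' equilibrium frequencies, and states evolve along each branch with the
#' transition matrix of the class- and branch-flag-appropriate generator
#' (foreground branches use the class's foreground omega). Optional gap
#' masking hides a contiguous codon run per taxon (mimicking missing gene
#' ends) at an expected `gapFraction` of codons.
#'
#' The class assignment and per-site foreground omega truth are recorded in
#' the alignment's `metadata` (`siteClasses`, `positiveSites`).
#'
#' @param tree a [LabeledTree-class] with branch lengths.
#' @param spec a [CodonModelSpec-class] with all parameters fixed (the
#'   truth), e.g. `codonModelSpec("M0", fixed = list(kappa = 2,
#'   omega = 0.2))`.
#' @param length gene length in codons.
#' @param seed random seed (mandatory).
#' @param code the [GeneticCode-class] (default universal).
#' @param frequencies optional [CodonFrequencies-class] truth; default
#'   uniform over sense codons.
#' @param gapFraction expected fraction of codons masked as missing per
#'   taxon (default 0).
#' @param countEvents if `TRUE`, simulate waiting times explicitly
#'   (Gillespie) and record the realized substitution count per branch in
#'   `metadata$edgeEvents` (slower; for calibration checks).
#' @return a [CodonAlignment-class].
#' @export
simulateAlignment <- function(tree, spec, length, seed,
                              code = geneticCode(1L),
                              frequencies = NULL, gapFraction = 0,
                              countEvents = FALSE) {
  if (missing(seed)) stop("seed is mandatory for reproducible simulation")
  set.seed(seed)
  par <- .initParams(spec@name, fixed = spec@fixed)
  missingPar <- setdiff(.modelParamNames(spec@name), names(spec@fixed))
  if (length(missingPar))
    stop("simulation truth must fix every model parameter; missing: ",
         paste(missingPar, collapse = ", "))
  classes <- .classStructure(spec@name, par)
  pi <- if (is.null(frequencies)) {
    n <- length(code@senseCodons)
    stats::setNames(rep(1 / n, n), code@senseCodons)
  } else frequencies@pi
  phy <- tree@phy
  if (is.null(phy$edge.length)) stop("tree branch lengths are unset")
  po <- ape::reorder.phylo(phy, "postorder")
  perm <- match(paste(po$edge[, 1L], po$edge[, 2L]),
                paste(phy$edge[, 1L], phy$edge[, 2L]))
  fg <- tree@foreground[perm]
  tvec <- po$edge.length
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- po$edge[nrow(po$edge), 1L]

  ## class and per-branch-flag generators, mixture-aware scaling (the same
  ## convention as the likelihood engine)
  omegas <- sort(unique(c(classes$omegaBg, classes$omegaFg)))
  raws <- lapply(omegas, function(w) .rawQ(par$kappa, w, pi, code))
  mu <- vapply(raws, `[[`, numeric(1L), "mu")
  iBg <- match(classes$omegaBg, omegas)
  iFg <- match(classes$omegaFg, omegas)
  sBg <- sum(classes$prop * mu[iBg])
  sFg <- sum(classes$prop * mu[iFg])

  eigs <- lapply(omegas, function(w) .eigenQ(par$kappa, w, pi, code))

  nclass <- length(classes$prop)
  siteClass <- sample.int(nclass, length, replace = TRUE,
                          prob = classes$prop)
  rootState <- sample.int(length(pi), length, replace = TRUE, prob = pi)

  states <- matrix(NA_integer_, nnode, length)
  states[root, ] <- rootState
  edgeEvents <- numeric(nrow(po$edge))

  ## pre-order: parents before children
  for (e in rev(seq_len(nrow(po$edge)))) {
    pa <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    scale <- if (fg[e]) sFg else sBg
    t <- tvec[e] / scale
    cur <- states[pa, ]
    nxt <- integer(length)
    for (cc in seq_len(nclass)) {
      idx <- which(siteClass == cc)
      if (!length(idx)) next
      k <- if (fg[e]) iFg[cc] else iBg[cc]
      if (countEvents) {
        Q <- raws[[k]]$Q
        nst <- nrow(Q)
        for (ii in idx) {
          zi <- cur[ii]; rem <- t
          repeat {
            exitRate <- -Q[zi, zi]
            if (exitRate <= 0) break
            wait <- rexp(1L, exitRate)
            if (wait > rem) break
            rem <- rem - wait
            pvec <- Q[zi, ]; pvec[zi] <- 0
            zi <- sample.int(nst, 1L, prob = pvec)
            edgeEvents[e] <- edgeEvents[e] + 1
          }
          nxt[ii] <- zi
        }
      } else {
        E <- eigs[[k]]
        P <- E$U %*% (exp(E$lam * t) * E$Uinv)
        P[P < 0] <- 0
        P <- P / rowSums(P)
        nxt[idx] <- .evolveStates(cur[idx], P)
      }
    }
    states[ch, ] <- nxt
  }

  tipStates <- states[seq_len(ntip), , drop = FALSE]
  rownames(tipStates) <- phy$tip.label

  if (gapFraction > 0) {
    for (k in seq_len(ntip)) {
      run <- min(rpois(1L, gapFraction * length), length - 1L)
      if (run > 0L) {
        if (runif(1L) < 0.5) tipStates[k, seq_len(run)] <- NA_integer_
        else tipStates[k, (length - run + 1L):length] <- NA_integer_
      }
    }
  }

  positive <- which(classes$omegaFg[siteClass] > 1)
  ev <- NULL
  if (countEvents) {
    ev <- numeric(nrow(po$edge))
    ev[perm] <- edgeEvents   # back to the tree's own edge order
  }
  new("CodonAlignment", states = tipStates, code = code,
      siteCoordinates = seq_len(length),
      metadata = list(truth = spec, siteClasses = siteClass,
                      positiveSites = positive, edgeEvents = ev))
}

#' Simulate a study bundle of genes
#'
#' Generates a multi-gene dataset with the statistical structure of a
#' per-gene selection study: one tree with a designated foreground clade,
#' a set of protein-coding genes simulated under per-gene model truths, and
#' a truth table recording each gene's generating model, omegas and planted
#' positively selected sites. Files (FASTA per gene, newick with foreground
#' tags, foreground taxon list, truth TSV) are written when `dir` is given.
#'
#' Per-gene seeds are derived deterministically from the master seed
#' (`seed + gene index`), so bundles are reproducible gene by gene.
#'
#' @param ngenes number of genes (default 13, a typical mitochondrial
#'   protein-coding gene complement).
#' @param ntaxa,foregroundCount,scale tree parameters (defaults 13 taxa
#'   with 6 foreground, matching a small coral-group design).
#' @param lengths gene lengths in codons; default drawn uniformly from
#'   70-1100 (the span of mitochondrial PCGs).
#' @param truths list of [CodonModelSpec-class] truths per gene; default
#'   M0 with per-gene omega drawn uniformly from 0.05-0.35 (strong
#'   purifying selection) and kappa 2.
#' @param gapFraction expected missing-codon fraction per taxon (default
#'   0.02).
#' @param code genetic code (default universal).
#' @param seed master seed (mandatory).
#' @param dir optional output directory for on-disk artifacts.
#' @return a list with `tree`, `alignments` (named list), `foreground`
#'   (taxon names), `truth` (data.frame), and `dir`.
#' @export
simulateStudy <- function(ngenes = 13L, ntaxa = 13L, foregroundCount = 6L,
                          scale = 0.1, lengths = NULL, truths = NULL,
                          gapFraction = 0.02, code = geneticCode(1L),
                          seed, dir = NULL) {
  if (missing(seed)) stop("seed is mandatory for reproducible simulation")
  set.seed(seed)
  tree <- simulateTree(ntaxa, foregroundCount, scale = scale, seed = seed)
  if (is.null(lengths)) lengths <- sample(70:1100, ngenes, replace = TRUE)
  if (is.null(truths)) {
    omegaTruth <- runif(ngenes, 0.05, 0.35)
    truths <- lapply(omegaTruth, function(w)
      codonModelSpec("M0", fixed = list(kappa = 2, omega = w)))
  }
  stopifnot(length(lengths) == ngenes, length(truths) == ngenes)
  geneNames <- sprintf("gene%02d", seq_len(ngenes))
  alignments <- vector("list", ngenes)
  names(alignments) <- geneNames
  rows <- vector("list", ngenes)
  for (g in seq_len(ngenes)) {
    alignments[[g]] <- simulateAlignment(tree, truths[[g]], lengths[g],
                                         seed = seed + g, code = code,
                                         gapFraction = gapFraction)
    truth <- truths[[g]]
    fx <- truth@fixed
    pos <- alignments[[g]]@metadata$positiveSites
    rows[[g]] <- data.frame(
      gene = geneNames[g], model = truth@name, length = lengths[g],
      kappa = if (is.null(fx$kappa)) NA_real_ else fx$kappa,
      omega = if (is.null(fx$omega)) NA_real_ else fx$omega,
      omega0 = if (is.null(fx$omega0)) NA_real_ else fx$omega0,
      omega2 = if (is.null(fx$omega2)) NA_real_ else fx$omega2,
      positiveSites = if (length(pos)) paste(pos, collapse = ",") else "",
      stringsAsFactors = FALSE)
  }
  truthTab <- do.call(rbind, rows)
  fgTaxa <- foregroundTaxa(tree)
  bundle <- list(tree = tree, alignments = alignments,
                 foreground = fgTaxa, truth = truthTab, dir = dir)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (g in seq_len(ngenes))
      writeCodonFasta(alignments[[g]],
                      file.path(dir, paste0(geneNames[g], ".fasta")))
    writeForegroundNewick(tree, file.path(dir, "tree.nwk"))
    writeLines(fgTaxa, file.path(dir, "foreground.txt"))
    write.table(truthTab, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  bundle
}
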
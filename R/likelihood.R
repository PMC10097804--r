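## ---- internal: alignment/tree preparation for the pruning engine ----------

## Postorder edge table, 0-based tip-state pattern matrix, pattern weights.
## The tree's taxa must match the alignment's exactly.
.likPrep <- function(aln, tree) {
  phy <- tree@phy
  tips <- phy$tip.label
  if (!setequal(tips, rownames(aln@states)))
    stop("taxon mismatch between tree and alignment: tree-only {",
         paste(setdiff(tips, rownames(aln@states)), collapse = ","),
         "}, alignment-only {",
         paste(setdiff(rownames(aln@states), tips), collapse = ","), "}")
  cp <- compressPatterns(aln)
  po <- ape::reorder.phylo(phy, "postorder")
  edgeKey <- paste(phy$edge[, 1L], phy$edge[, 2L])
  poKey <- paste(po$edge[, 1L], po$edge[, 2L])
  perm <- match(poKey, edgeKey)
  fg <- tree@foreground[perm]
  blens <- if (is.null(po$edge.length)) NULL else po$edge.length
  st <- cp$patterns[tips, , drop = FALSE]
  st[is.na(st)] <- 0L
  st <- st - 1L                       # 0-based, missing -> -1
  list(
    tipState = st,
    edge = po$edge - 1L,
    perm = perm,
    foreground = fg,
    blens = blens,
    weights = cp$weights,
    index = cp$index,
    nnode = length(tips) + phy$Nnode,
    root = po$edge[nrow(po$edge), 1L] - 1L,
    ntip = length(tips),
    code = aln@code
  )
}

## Engine assembly for a class structure: eigen systems per distinct omega,
## per-edge/per-class eigen indices, mixture-aware rate scaling (one scale
## per branch flag so lengths are expected substitutions per codon averaged
## over classes), and subtree-sharing hints for branch-site classes.
.engineParts <- function(prep, kappa, classes, pi) {
  omegas <- sort(unique(c(classes$omegaBg, classes$omegaFg)))
  eig <- lapply(omegas, function(w) .eigenQ(kappa, w, pi, prep$code))
  mu <- vapply(eig, `[[`, numeric(1L), "mu")
  iBg <- match(classes$omegaBg, omegas)
  iFg <- match(classes$omegaFg, omegas)
  sBg <- sum(classes$prop * mu[iBg])
  sFg <- sum(classes$prop * mu[iFg])
  fg <- prep$foreground
  nclass <- length(classes$prop)
  eidx <- matrix(0L, nrow(prep$edge), nclass)
  for (cc in seq_len(nclass))
    eidx[, cc] <- ifelse(fg, iFg[cc], iBg[cc]) - 1L
  ## share subtree partials with the first earlier class having the same
  ## background generator (branch-site classes 2a/2b vs 0/1)
  shareBase <- rep(-1L, nclass)
  for (cc in seq_len(nclass)[-1L]) {
    prior <- which(seq_len(nclass) < cc & iBg == iBg[cc])
    if (length(prior)) shareBase[cc] <- prior[1L] - 1L
  }
  list(eig = lapply(eig, function(e) e[c("U", "Uinv", "lam")]),
       eidx = eidx, shareBase = as.integer(shareBase),
       rate = ifelse(fg, 1 / sFg, 1 / sBg))
}

## Per-pattern per-class log-likelihood matrix for a class structure at
## fixed branch lengths; `t` is aligned with prep$edge rows.
.classLogLik <- function(prep, t, kappa, classes, pi) {
  parts <- .engineParts(prep, kappa, classes, pi)
  codon_clik(prep$tipState, prep$edge, t, parts$rate, parts$eig,
             parts$eidx, parts$shareBase, pi, prep$nnode, prep$root)
}

## weighted mixture total from a per-pattern per-class log-likelihood matrix
.mixtureLogLik <- function(classLogLik, prop, weights) {
  lp <- log(prop)
  M <- apply(classLogLik, 1L, function(r) max(r + lp))
  tot <- M + log(rowSums(exp(sweep(classLogLik, 2L, lp, "+") - M)))
  bad <- !is.finite(tot)
  if (any(bad))
    stop("zero site likelihood at pattern index ",
         paste(which(bad), collapse = ", "),
         " (impossible data under the model, e.g. omega = 0 with observed ",
         "amino-acid change)")
  sum(weights * tot)
}

## ---- exported surface -----------------------------------------------------

#' Per-site, per-class likelihoods under a codon model
#'
#' Runs Felsenstein pruning over the sense-codon state space for each site
#' class of a model, at the supplied parameter values. Missing codons
#' contribute a vector of ones; on branch-site models each branch uses the
#' omega its foreground flag assigns to the class. Sites are compressed to
#' patterns internally; the returned matrix is expanded back to one row per
#' codon site.
#'
#' @param aln a [CodonAlignment-class].
#' @param tree a [LabeledTree-class] with branch lengths set; taxa must
#'   match the alignment.
#' @param spec a [CodonModelSpec-class].
#' @param params named list of parameter values for the model (`kappa` plus
#'   the model's omegas/proportions, see [codonModelSpec()]).
#' @param frequencies a [CodonFrequencies-class]; default F3x4 from `aln`.
#' @param log return log-likelihoods (default) or likelihoods.
#' @return numeric matrix, sites x classes; attribute `"proportions"`
#'   carries the class proportions.
#' @export
siteClassLikelihoods <- function(aln, tree, spec, params,
                                 frequencies = NULL, log = TRUE) {
  if (is.null(frequencies))
    frequencies <- estimateCodonFrequencies(aln, "F3x4")
  prep <- .likPrep(aln, tree)
  if (is.null(prep$blens))
    stop("tree branch lengths are unset; optimize or supply them first")
  par <- .initParams(spec@name, fixed = c(spec@fixed, params))
  classes <- .classStructure(spec@name, par)
  ll <- .classLogLik(prep, prep$blens, par$kappa, classes, frequencies@pi)
  out <- ll[prep$index, , drop = FALSE]
  if (!log) out <- exp(out)
  structure(out, proportions = classes$prop)
}

#' Total mixture log-likelihood from per-class site likelihoods
#'
#' Combines per-pattern (or per-site) class log-likelihoods into the total
#' log-likelihood `sum_patterns w * log(sum_classes p_c L_c)`.
#'
#' @param classLogLik matrix of per-pattern per-class log-likelihoods.
#' @param proportions class proportions on the simplex.
#' @param weights pattern multiplicities (default all 1).
#' @return the total log-likelihood (finite; a zero site likelihood raises
#'   an error naming the offending pattern).
#' @export
totalLogLikelihood <- function(classLogLik, proportions,
                               weights = rep(1, nrow(classLogLik))) {
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0))
    stop("class proportions must be non-negative and sum to 1")
  .mixtureLogLik(as.matrix(classLogLik), proportions, weights)
}
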
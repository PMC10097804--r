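## star flags at strict thresholds: "*" > 0.95, "**" > 0.99
.starFlag <- function(p) {
  ifelse(p > 0.99, "**", ifelse(p > 0.95, "*", ""))
}

## reference amino acids from the first sequence of the alignment
.referenceAa <- function(aln) {
  st <- aln@states[1L, ]
  aa <- rep("-", length(st))
  obs <- !is.na(st)
  aa[obs] <- translateCodons(aln@code, aln@code@senseCodons[st[obs]])
  aa
}

.positiveClasses <- function(name) {
  switch(name, M2a = 3L, MA_ALT = c(3L, 4L),
         stop("site posteriors are defined for M2a and MA_ALT fits only; ",
              "got ", name))
}

.makePosteriorTable <- function(aln, posterior, model, method) {
  tab <- data.frame(position = aln@siteCoordinates,
                    aa = .referenceAa(aln),
                    posterior = pmin(pmax(posterior, 0), 1),
                    flag = .starFlag(posterior),
                    stringsAsFactors = FALSE)
  new("SitePosteriorTable", table = tab, model = model, method = method)
}

#' @rdname codonSelect-accessors
#' @export
setMethod("posteriorTable", "SitePosteriorTable", function(x) x@table)

setMethod("show", "SitePosteriorTable", function(object) {
  cat("SitePosteriorTable (", object@method, ", ", object@model, "): ",
      nrow(object@table), " sites, ",
      sum(object@table$posterior > 0.95), " with posterior > 0.95\n",
      sep = "")
})

#' Naive Empirical Bayes site posteriors
#'
#' Posterior probability that each codon site belongs to the
#' positive-selection class(es), with all parameters held at their MLEs:
#' `P(class c | site) = p_c L_c / sum_k p_k L_k`. The cheap companion to
#' [bebPosteriors()]; it ignores uncertainty in the mixture parameters.
#'
#' @param fit a [FitResult-class] for `M2a` or `MA_ALT`.
#' @param aln the [CodonAlignment-class] the model was fitted to.
#' @param tree optional [LabeledTree-class]; defaults to the fitted tree
#'   (which carries the branch lengths at the optimum).
#' @return a [SitePosteriorTable-class].
#' @export
nebPosteriors <- function(fit, aln, tree = NULL) {
  posIdx <- .positiveClasses(fit@spec@name)
  if (is.null(tree)) tree <- fit@tree
  prep <- .likPrep(aln, tree)
  par <- .initParams(fit@spec@name,
                     fixed = fit@mle[.modelParamNames(fit@spec@name)])
  classes <- .classStructure(fit@spec@name, par)
  ll <- .classLogLik(prep, prep$blens, par$kappa, classes,
                     fit@frequencies@pi)
  lp <- sweep(ll, 2L, log(classes$prop), "+")
  m <- apply(lp, 1L, max)
  pr <- exp(lp - m)
  pr <- pr / rowSums(pr)
  post <- rowSums(pr[, posIdx, drop = FALSE])
  .makePosteriorTable(aln, post[prep$index], fit@spec@name, "NEB")
}

## grid midpoints of n equal-probability categories on (lo, hi)
.gridMid <- function(n, lo, hi) lo + (hi - lo) * (2 * seq_len(n) - 1) / (2 * n)

#' Bayes Empirical Bayes site posteriors
#'
#' Site posteriors of the positive-selection class(es) that integrate over
#' a discrete uniform prior grid on the model's mixture parameters, in the
#' spirit of the published BEB construction: `ncat` equal-probability
#' categories per dimension, with `omega0` on (0, 1), `omega2` on (1, 11),
#' and the proportion pair `(p0, p1)` on the uniform triangle (grid pairs
#' with `p0 + p1 < 1`). All other parameters (kappa, branch lengths, codon
#' frequencies, and the branch-rate scaling) stay fixed at their MLEs. The
#' posterior weight of each grid point is computed from the whole
#' alignment, then site class posteriors are averaged over the grid.
#'
#' @param fit a [FitResult-class] for `M2a` or `MA_ALT`.
#' @param aln the fitted [CodonAlignment-class].
#' @param tree optional tree; defaults to the fitted tree.
#' @param ncat grid categories per dimension (default 10; must be >= 2).
#' @param degenerateAtMLE if `TRUE`, collapse the grid to the single point
#'   at the MLEs, which reduces BEB to NEB exactly (a consistency check,
#'   not an analysis mode).
#' @return a [SitePosteriorTable-class].
#' @export
bebPosteriors <- function(fit, aln, tree = NULL, ncat = 10L,
                          degenerateAtMLE = FALSE) {
  posIdx <- .positiveClasses(fit@spec@name)
  model <- fit@spec@name
  if (degenerateAtMLE) {
    out <- nebPosteriors(fit, aln, tree)
    out@method <- "BEB"
    return(out)
  }
  if (ncat < 2L)
    stop("BEB grid needs at least 2 categories per dimension")
  if (is.null(tree)) tree <- fit@tree
  prep <- .likPrep(aln, tree)
  pi <- fit@frequencies@pi
  kappa <- fit@mle$kappa
  mlePar <- .initParams(model, fixed = fit@mle[.modelParamNames(model)])
  mleClasses <- .classStructure(model, mlePar)

  ## branch-rate scaling held at the MLE: reuse the fitted engine parts
  mleParts <- .engineParts(prep, kappa, mleClasses, pi)
  rate <- mleParts$rate

  w0g <- .gridMid(ncat, 0, 1)
  w2g <- .gridMid(ncat, 1, 11)
  pg <- .gridMid(ncat, 0, 1)
  pairs <- expand.grid(i = seq_len(ncat), j = seq_len(ncat))
  pairs <- pairs[pg[pairs$i] + pg[pairs$j] < 1, , drop = FALSE]
  npair <- nrow(pairs)

  npat <- length(prep$weights)
  w <- prep$weights

  ## per-pattern log-likelihood columns for every needed (bg, fg) omega pair
  clikFor <- function(omegaBg, omegaFg) {
    omegas <- sort(unique(c(omegaBg, omegaFg)))
    eig <- lapply(omegas, function(x) .eigenQ(kappa, x, pi, prep$code))
    iBg <- match(omegaBg, omegas); iFg <- match(omegaFg, omegas)
    nclass <- length(omegaBg)
    eidx <- matrix(0L, nrow(prep$edge), nclass)
    for (cc in seq_len(nclass))
      eidx[, cc] <- ifelse(prep$foreground, iFg[cc], iBg[cc]) - 1L
    shareBase <- rep(-1L, nclass)
    for (cc in seq_len(nclass)[-1L]) {
      prior <- which(seq_len(nclass) < cc & iBg == iBg[cc])
      if (length(prior)) shareBase[cc] <- prior[1L] - 1L
    }
    codon_clik(prep$tipState, prep$edge, prep$blens, rate,
               lapply(eig, function(e) e[c("U", "Uinv", "lam")]),
               eidx, as.integer(shareBase), pi, prep$nnode, prep$root)
  }

  if (model == "M2a") {
    ## site likelihood depends on a single omega per class
    llW0 <- clikFor(w0g, w0g)                      # npat x ncat
    llW1 <- clikFor(1, 1)                          # npat x 1
    llW2 <- clikFor(w2g, w2g)                      # npat x ncat
    ll2 <- function(i, j) cbind(llW0[, i], llW1[, 1L], llW2[, j])
  } else {
    llW1 <- clikFor(1, 1)                          # class 1 piece
    ll2b <- clikFor(rep(1, ncat), w2g)             # class 2b pieces
    ## class 0 and 2a pieces per omega0 grid value (2a shares bg subtrees)
    ll0 <- vector("list", ncat)
    ll2a <- vector("list", ncat)
    for (i in seq_len(ncat)) {
      block <- clikFor(rep(w0g[i], ncat + 1L), c(w0g[i], w2g))
      ll0[[i]] <- block[, 1L]
      ll2a[[i]] <- block[, -1L, drop = FALSE]
    }
    ll2 <- function(i, j) cbind(ll0[[i]], llW1[, 1L],
                                ll2a[[i]][, j], ll2b[, j])
  }

  rowMax <- function(lp) do.call(pmax, lapply(seq_len(ncol(lp)),
                                              function(k) lp[, k]))
  ## accumulate: first pass grid posterior, second pass site posteriors
  siteNum <- numeric(npat)
  gridLogF <- array(NA_real_, c(npair, ncat, ncat))
  classProps <- vector("list", npair)
  for (q in seq_len(npair)) {
    p0 <- pg[pairs$i[q]]; p1 <- pg[pairs$j[q]]
    par <- list(p0 = p0, p1 = p1,
                omega0 = 0.5, omega2 = 2)  # omegas substituted per cell
    classProps[[q]] <- .classStructure(model, par)$prop
  }
  for (i in seq_len(ncat)) for (j in seq_len(ncat)) {
    llc <- ll2(i, j)
    for (q in seq_len(npair)) {
      lp <- sweep(llc, 2L, log(classProps[[q]]), "+")
      m <- rowMax(lp)
      gridLogF[q, i, j] <- sum(w * (m + log(rowSums(exp(lp - m)))))
    }
  }
  ## uniform prior over all grid points
  gmax <- max(gridLogF)
  gw <- exp(gridLogF - gmax)
  gw <- gw / sum(gw)
  for (i in seq_len(ncat)) for (j in seq_len(ncat)) {
    llc <- ll2(i, j)
    for (q in seq_len(npair)) {
      wq <- gw[q, i, j]
      if (wq < 1e-12) next
      lp <- sweep(llc, 2L, log(classProps[[q]]), "+")
      m <- rowMax(lp)
      pr <- exp(lp - m)
      siteNum <- siteNum +
        wq * rowSums(pr[, posIdx, drop = FALSE]) / rowSums(pr)
    }
  }
  .makePosteriorTable(aln, siteNum[prep$index], model, "BEB")
}

#' Filter a site posterior table at a reporting threshold
#'
#' Keeps the rows whose posterior strictly exceeds `threshold` (default
#' 0.95, the conventional reporting rule), preserving original codon
#' coordinates, reference amino acids and star flags.
#'
#' @param table a [SitePosteriorTable-class].
#' @param threshold posterior cutoff (strict inequality).
#' @return a data.frame with the selected rows.
#' @export
reportSelectedSites <- function(table, threshold = 0.95) {
  stopifnot(is(table, "SitePosteriorTable"))
  tab <- table@table
  tab[tab$posterior > threshold, , drop = FALSE]
}
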
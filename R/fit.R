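## ---- parameter packing ----------------------------------------------------
## Free parameters are optimized on transformed scales: log for kappa and
## omegas (box-bounded), additive log-ratio for class proportions.

.thetaSpec <- function(name, fixed) {
  free <- setdiff(.modelParamNames(name), names(fixed))
  ent <- list()
  for (p in intersect(free, c("kappa", "omega", "omegaBg", "omegaFg",
                              "omega0", "omega2"))) {
    b <- .PARAM_BOUNDS[[p]]
    ent[[p]] <- list(type = "log", lower = log(b[1L]), upper = log(b[2L]))
  }
  simplexPars <- intersect(c("p0", "p1"), .modelParamNames(name))
  if (length(simplexPars) && !all(simplexPars %in% names(fixed))) {
    for (p in simplexPars)
      ent[[p]] <- list(type = "alr", lower = -25, upper = 25)
  }
  ent
}

.packTheta <- function(par, tspec, name) {
  theta <- numeric(0)
  hasP1 <- "p1" %in% .modelParamNames(name)
  for (p in names(tspec)) {
    e <- tspec[[p]]
    v <- switch(e$type,
      log = log(par[[p]]),
      alr = {
        rest <- if (hasP1) 1 - par$p0 - par$p1 else 1 - par$p0
        log(par[[p]] / rest)
      })
    theta <- c(theta, setNames(v, p))
  }
  theta
}

.unpackTheta <- function(theta, par, tspec, name) {
  alr <- character(0)
  for (p in names(tspec)) {
    if (tspec[[p]]$type == "log") par[[p]] <- exp(theta[[p]])
    else alr <- c(alr, p)
  }
  if (length(alr)) {
    z <- exp(theta[alr])
    tot <- 1 + sum(z)
    for (p in alr) par[[p]] <- z[[p]] / tot
  }
  par
}

.thetaBounds <- function(tspec) {
  list(lower = vapply(tspec, `[[`, numeric(1L), "lower"),
       upper = vapply(tspec, `[[`, numeric(1L), "upper"))
}

## ---- fitting --------------------------------------------------------------

#' Fit a codon model by maximum likelihood
#'
#' Maximizes the log-likelihood of a codon alignment on an unrooted tree
#' under one of the six model structures. Substitution parameters (kappa,
#' omegas, class proportions) are optimized by box-constrained
#' quasi-Newton iterations on transformed scales (log for rates, additive
#' log-ratio for proportions; omega bounded in `[1e-4, 999]`), alternating
#' with edge-wise branch-length optimization sweeps; multiple starts guard
#' against local optima. Branch lengths can instead be held fixed at
#' supplied values (e.g. at the M0 optimum) for a fast approximate mode.
#'
#' @param aln a [CodonAlignment-class].
#' @param tree a [LabeledTree-class]; must carry foreground flags for
#'   `TWO_RATIO`/`MA_*` models, and branch lengths when
#'   `branchLengths = "fixed"`. Rooted input is unrooted first.
#' @param spec a [CodonModelSpec-class].
#' @param frequencies optional [CodonFrequencies-class]; default estimated
#'   from `aln` by `freqMethod`.
#' @param freqMethod frequency convention when `frequencies` is `NULL`.
#' @param branchLengths `"optimize"` (default, per-model re-optimization)
#'   or `"fixed"`.
#' @param restarts number of optimization starts with staggered initial
#'   omegas (0.1, 0.5, 1.5, ...).
#' @param gene optional gene identifier carried into results.
#' @param control list of optimizer knobs: `maxOuter` (alternation rounds,
#'   default 6), `sweeps` (branch-length sweeps per round, default 2),
#'   `maxit` (quasi-Newton iterations per round, default 200), `tol`
#'   (log-likelihood convergence tolerance, default 1e-4), `minT`/`maxT`
#'   (branch-length box, defaults 1e-6 and 20).
#' @return a [FitResult-class].
#' @examples
#' set.seed(1)
#' tr <- simulateTree(6, foregroundCount = 2, scale = 0.2, seed = 1)
#' truth <- codonModelSpec("M0", fixed = list(kappa = 2, omega = 0.2))
#' aln <- simulateAlignment(tr, truth, length = 120, seed = 2)
#' fit <- fitModel(aln, tr, codonModelSpec("M0"), restarts = 1)
#' mleParams(fit)$omega
#' @export
fitModel <- function(aln, tree, spec,
                     frequencies = NULL,
                     freqMethod = c("F3x4", "F1x4", "equal", "empirical"),
                     branchLengths = c("optimize", "fixed"),
                     restarts = 3L,
                     gene = NA_character_,
                     control = list()) {
  freqMethod <- match.arg(freqMethod)
  branchLengths <- match.arg(branchLengths)
  ctl <- modifyList(list(maxOuter = 6L, sweeps = 2L, maxit = 200L,
                         tol = 1e-4, minT = 1e-6, maxT = 20), control)
  if (is.null(frequencies))
    frequencies <- estimateCodonFrequencies(aln, freqMethod)
  pi <- frequencies@pi
  tree <- unrootTree(tree)
  needsFg <- spec@name %in% c("TWO_RATIO", "MA_NULL", "MA_ALT")
  if (needsFg && !any(tree@foreground))
    stop("model ", spec@name, " needs foreground branches; see tagForeground()")
  prep <- .likPrep(aln, tree)
  optimizeBl <- branchLengths == "optimize"
  if (is.null(prep$blens)) {
    if (!optimizeBl)
      stop("branchLengths = 'fixed' but the tree has no branch lengths")
    prep$blens <- rep(0.1, nrow(prep$edge))
  }
  tspec <- .thetaSpec(spec@name, spec@fixed)
  bounds <- .thetaBounds(tspec)

  evalLnL <- function(par, t) {
    classes <- .classStructure(spec@name, par)
    ll <- .classLogLik(prep, t, par$kappa, classes, pi)
    .mixtureLogLik(ll, classes$prop, prep$weights)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    par <- .initParams(spec@name, restart = r, fixed = spec@fixed)
    t <- prep$blens
    theta <- .packTheta(par, tspec, spec@name)
    lnL <- -Inf
    convergedOpt <- TRUE
    for (round in seq_len(ctl$maxOuter)) {
      if (length(theta)) {
        op <- optim(theta,
                    fn = function(th) {
                      p <- .unpackTheta(setNames(th, names(theta)), par,
                                        tspec, spec@name)
                      -evalLnL(p, t)
                    },
                    method = "L-BFGS-B",
                    lower = bounds$lower, upper = bounds$upper,
                    control = list(maxit = ctl$maxit))
        theta <- setNames(op$par, names(theta))
        par <- .unpackTheta(theta, par, tspec, spec@name)
        convergedOpt <- op$convergence == 0L
        newLnL <- -op$value
      } else newLnL <- evalLnL(par, t)
      if (optimizeBl) {
        classes <- .classStructure(spec@name, par)
        parts <- .engineParts(prep, par$kappa, classes, pi)
        t <- codon_optblens(prep$tipState, prep$edge, t, parts$rate,
                            parts$eig, parts$eidx, pi,
                            log(classes$prop), prep$weights,
                            prep$nnode, prep$root,
                            ctl$minT, ctl$maxT, ctl$sweeps, 1e-4)
        newLnL <- evalLnL(par, t)
      }
      if (!optimizeBl) { lnL <- newLnL; break }
      if (is.finite(lnL) && newLnL - lnL < ctl$tol) { lnL <- max(lnL, newLnL); break }
      lnL <- newLnL
    }
    cand <- list(par = par, t = t, lnL = lnL, converged = convergedOpt,
                 restart = r)
    if (is.null(best) || cand$lnL > best$lnL) best <- cand
  }

  ## write optimized branch lengths back in the tree's own edge order
  phy <- tree@phy
  bl <- numeric(nrow(phy$edge))
  bl[prep$perm] <- best$t
  phy$edge.length <- bl
  outTree <- labeledTree(phy, tree@foreground)

  classes <- .classStructure(spec@name, best$par)
  mle <- best$par[.modelParamNames(spec@name)]
  mle$proportions <- classes$prop
  mle$omegaClasses <- data.frame(
    class = seq_along(classes$prop) - 1L,
    proportion = classes$prop,
    omegaBackground = classes$omegaBg,
    omegaForeground = classes$omegaFg)
  nfree <- length(tspec) + if (optimizeBl) nrow(prep$edge) else 0L
  new("FitResult",
      spec = spec, lnL = best$lnL, mle = mle,
      nFreeParams = as.integer(nfree),
      converged = best$converged,
      nRestartsUsed = as.integer(restarts),
      tree = outTree, frequencies = frequencies,
      details = list(gene = gene, branchLengths = branchLengths,
                     bestRestart = best$restart, control = ctl))
}

#' @rdname codonSelect-accessors
#' @export
setMethod("logLikelihood", "FitResult", function(x) x@lnL)

#' @rdname codonSelect-accessors
#' @export
setMethod("mleParams", "FitResult", function(x) x@mle)

#' @rdname codonSelect-accessors
#' @export
setMethod("modelName", "FitResult", function(x) x@spec@name)

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", object@spec@name,
      sprintf("lnL = %.4f", object@lnL),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  om <- object@mle$omegaClasses
  if (!is.null(om)) {
    cat(sprintf("  kappa = %.4f\n", object@mle$kappa))
    print(om, row.names = FALSE)
  }
})
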
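## Unscaled GY94 generator pieces, shared by the user-facing builder, the
## likelihood engine and the simulator. Returns the dense unscaled Q and
## mu = -sum(pi * diag(Q)), the expected substitutions per unit time.
.rawQ <- function(kappa, omega, pi, code) {
  info <- .qinfo(code)
  n <- info$n
  rate <- pi[info$j] * ifelse(info$ts, kappa, 1) * ifelse(info$ns, omega, 1)
  Q <- matrix(0, n, n)
  Q[cbind(info$i, info$j)] <- rate
  diag(Q) <- -rowSums(Q)
  list(Q = Q, mu = -sum(pi * diag(Q)))
}

## Eigendecomposition of the reversible generator via its symmetrization
## B = D^{1/2} Q D^{-1/2}. Returns U, Uinv with Q = U diag(lam) Uinv, and mu
## for the scaling conventions.
.eigenQ <- function(kappa, omega, pi, code) {
  raw <- .rawQ(kappa, omega, pi, code)
  s <- sqrt(pi)
  B <- raw$Q * (s %o% (1 / s))
  B <- (B + t(B)) / 2
  E <- eigen(B, symmetric = TRUE)
  U <- E$vectors / s
  Uinv <- t(E$vectors * s)
  list(U = U, Uinv = Uinv, lam = E$values, mu = raw$mu)
}

#' Build a codon substitution rate matrix
#'
#' GY94-structure generator over the sense codons of `code`: codons
#' differing at more than one nucleotide have rate 0; a single-nucleotide
#' change i -> j has rate `pi_j * kappa^[transition] * omega^[nonsynonymous]`.
#' The returned matrix is scaled so `-sum(pi * diag(Q)) == 1`: time is
#' measured in expected codon substitutions.
#'
#' @param kappa transition/transversion rate ratio, > 0.
#' @param omega nonsynonymous/synonymous rate ratio (dN/dS), >= 0.
#' @param pi a [CodonFrequencies-class] (or bare numeric vector over sense
#'   codons summing to 1).
#' @param code the [GeneticCode-class] defining synonymy.
#' @return a [RateMatrix-class].
#' @examples
#' code <- geneticCode(1)
#' aln <- codonAlignment(c(a = "ATGAAA", b = "ATGAAG"))
#' pi <- estimateCodonFrequencies(aln, "equal")
#' Q <- buildRateMatrix(kappa = 2, omega = 0.2, pi = pi, code = code)
#' @export
buildRateMatrix <- function(kappa, omega, pi, code) {
  if (!is.numeric(kappa) || kappa <= 0)
    stop("kappa must be positive")
  if (!is.numeric(omega) || omega < 0)
    stop("omega must be non-negative")
  piv <- if (is(pi, "CodonFrequencies")) pi@pi else pi
  if (length(piv) != length(code@senseCodons))
    stop("pi must have one entry per sense codon of the code")
  raw <- .rawQ(kappa, omega, piv, code)
  Q <- raw$Q / raw$mu
  dimnames(Q) <- list(code@senseCodons, code@senseCodons)
  new("RateMatrix", Q = Q, pi = as.numeric(piv), scale = raw$mu)
}

#' Transition probability matrix
#'
#' Computes `P(t) = exp(Q t)` by eigendecomposition of the symmetrized
#' reversible generator. Tiny negative entries from roundoff are clipped to
#' zero and rows renormalized.
#'
#' @param Q a [RateMatrix-class].
#' @param t branch length (expected substitutions per codon), >= 0.
#' @return a stochastic matrix over sense codons.
#' @export
transitionMatrix <- function(Q, t) {
  if (!is.numeric(t) || t < 0) stop("branch length t must be non-negative")
  pi <- Q@pi
  s <- sqrt(pi)
  B <- Q@Q * (s %o% (1 / s))
  B <- (B + t(B)) / 2
  E <- eigen(B, symmetric = TRUE)
  P <- (E$vectors %*% (exp(E$values * t) * t(E$vectors))) * ((1 / s) %o% s)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q@Q)
  P
}
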
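#' Estimate equilibrium codon frequencies
#'
#' Computes the stationary codon distribution used by the substitution
#' models, by one of the standard conventions:
#' \describe{
#'   \item{equal}{uniform over sense codons.}
#'   \item{F1x4}{product of pooled nucleotide frequencies, renormalized
#'     over sense codons.}
#'   \item{F3x4}{product of codon-position-specific nucleotide frequencies,
#'     renormalized over sense codons (the default throughout the package).}
#'   \item{empirical}{observed sense-codon proportions.}
#' }
#' Missing codons are ignored in all counts. Codons with zero estimated
#' frequency are floored at 1e-10 and the vector renormalized, so
#' log-likelihoods stay finite when a codon is absent from the data.
#'
#' @param aln a [CodonAlignment-class].
#' @param method one of `"equal"`, `"F1x4"`, `"F3x4"`, `"empirical"`.
#' @return a [CodonFrequencies-class] with `pi` named by sense codon.
#' @examples
#' aln <- codonAlignment(c(a = "ATGAAA", b = "ATGAAG"))
#' estimateCodonFrequencies(aln, "equal")
#' @export
estimateCodonFrequencies <- function(aln,
                                     method = c("F3x4", "F1x4", "equal",
                                                "empirical")) {
  method <- match.arg(method)
  code <- aln@code
  sense <- code@senseCodons
  n <- length(sense)
  if (method == "equal") {
    pi <- rep(1 / n, n)
  } else {
    obs <- table(factor(aln@states[!is.na(aln@states)], levels = seq_len(n)))
    obs <- as.numeric(obs)
    if (method == "empirical") {
      pi <- obs / max(sum(obs), 1)
    } else {
      codMat <- do.call(rbind, strsplit(sense, ""))
      if (method == "F1x4") {
        ntCount <- stats::setNames(numeric(4L), .CODON_BASES)
        for (p in 1:3)
          ntCount <- ntCount +
            tapply(obs, factor(codMat[, p], levels = .CODON_BASES), sum)
        ntFreq <- ntCount / sum(ntCount)
        pi <- ntFreq[codMat[, 1]] * ntFreq[codMat[, 2]] * ntFreq[codMat[, 3]]
      } else { # F3x4
        pi <- rep(1, n)
        for (p in 1:3) {
          cnt <- tapply(obs, factor(codMat[, p], levels = .CODON_BASES), sum)
          frq <- cnt / sum(cnt)
          pi <- pi * frq[codMat[, p]]
        }
      }
      pi <- pi / sum(pi)
    }
  }
  pi <- pmax(pi, 1e-10)
  pi <- pi / sum(pi)
  pi <- stats::setNames(as.numeric(pi), sense)
  new("CodonFrequencies", method = method, pi = pi)
}
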
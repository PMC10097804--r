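.DF_RULES <- list(
  "M0|TWO_RATIO" = 1L,    # one extra free omega on the foreground
  "M1a|M2a" = 2L,         # extra class proportion and omega2
  "MA_NULL|MA_ALT" = 1L   # omega2 freed from 1
)

#' Degrees of freedom for a nested model comparison
#'
#' The three standard pairwise comparisons: branch (`M0` vs `TWO_RATIO`,
#' df 1), site (`M1a` vs `M2a`, df 2) and branch-site (`MA_NULL` vs
#' `MA_ALT`, df 1).
#'
#' @param nullSpec,altSpec model names or [CodonModelSpec-class] objects.
#' @return integer degrees of freedom.
#' @examples
#' dfRule("M0", "TWO_RATIO")  # 1
#' dfRule("M1a", "M2a")       # 2
#' @export
dfRule <- function(nullSpec, altSpec) {
  n <- if (is(nullSpec, "CodonModelSpec")) nullSpec@name else nullSpec
  a <- if (is(altSpec, "CodonModelSpec")) altSpec@name else altSpec
  key <- paste(n, a, sep = "|")
  df <- .DF_RULES[[key]]
  if (is.null(df))
    stop("unrecognized model pair: ", n, " vs ", a,
         "; supported: M0/TWO_RATIO, M1a/M2a, MA_NULL/MA_ALT")
  df
}

#' Chi-square upper-tail p-value for a likelihood-ratio statistic
#'
#' @param stat the statistic `2 * (lnL_alt - lnL_null)` (negative values
#'   are clamped to 0).
#' @param df chi-square degrees of freedom.
#' @return the upper-tail probability.
#' @examples
#' lrtPValue(8.57, 1)   # 0.0034
#' @export
lrtPValue <- function(stat, df) {
  pchisq(pmax(stat, 0), df = df, lower.tail = FALSE)
}

#' Likelihood-ratio test between two fitted nested models
#'
#' Forms `2 * (lnL_alt - lnL_null)` (clamped at zero, with a warning when
#' optimizer noise makes it negative), looks up the comparison's degrees of
#' freedom via [dfRule()], and reports the chi-square upper-tail p-value.
#' The branch-site comparison uses the plain chi-square df = 1 reference
#' (not the 50:50 boundary mixture), the convention that reproduces the
#' printed significance levels of standard engine output.
#'
#' @param nullFit,altFit [FitResult-class] objects for the null and
#'   alternative model of a recognized pair, fitted to the same gene.
#' @param alpha significance level (default 0.05).
#' @return an [LRTResult-class].
#' @export
lrt <- function(nullFit, altFit, alpha = 0.05) {
  g1 <- nullFit@details$gene; g2 <- altFit@details$gene
  if (!is.na(g1) && !is.na(g2) && g1 != g2)
    stop("fits are for different genes: '", g1, "' vs '", g2, "'")
  df <- dfRule(nullFit@spec, altFit@spec)
  stat <- 2 * (altFit@lnL - nullFit@lnL)
  if (stat < 0) {
    if (stat < -1e-6)
      warning("negative LRT statistic (", format(stat),
              "): optimizer noise; clamping to 0")
    stat <- 0
  }
  p <- lrtPValue(stat, df)
  new("LRTResult", nullModel = nullFit@spec@name,
      altModel = altFit@spec@name,
      stat = stat, df = df, p = p, alpha = alpha,
      significant = p < alpha)
}

#' @rdname codonSelect-accessors
#' @export
setMethod("pvalue", "LRTResult", function(x) x@p)

setMethod("show", "LRTResult", function(object) {
  cat(sprintf("LRT %s vs %s: 2dlnL = %.4f, df = %d, p = %.4g %s\n",
              object@nullModel, object@altModel, object@stat, object@df,
              object@p,
              if (object@significant) "(significant)" else ""))
})

#' Branch-model rule for adaptive evolution
#'
#' Applies the inference rule for the branch comparison: adaptive evolution
#' on the foreground is called when the LRT is significant (p < alpha) and
#' the foreground omega estimate exceeds 1.
#'
#' @param branchLrt an [LRTResult-class] for `M0` vs `TWO_RATIO`.
#' @param omegaForeground the foreground omega MLE from the `TWO_RATIO`
#'   fit.
#' @return `TRUE` or `FALSE`.
#' @export
inferAdaptive <- function(branchLrt, omegaForeground) {
  if (branchLrt@altModel != "TWO_RATIO")
    stop("inferAdaptive applies to the branch comparison (M0 vs TWO_RATIO)")
  isTRUE(branchLrt@p < branchLrt@alpha && omegaForeground > 1)
}
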
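#' @import methods
NULL

#' Genetic code table
#'
#' Maps the 64 codons to amino acids and fixes the ordered list of sense
#' (non-stop) codons that serves as the state space of every codon model in
#' the package. Codons are ordered lexicographically over the bases
#' T, C, A, G (first codon position varying slowest); this ordering is used
#' consistently for frequency vectors, rate matrices and alignment states.
#'
#' @slot tableId integer translation-table identifier (1 universal,
#'   2 vertebrate mitochondrial, 4 mold/protozoan/coelenterate mitochondrial,
#'   5 invertebrate mitochondrial).
#' @slot name human-readable table name.
#' @slot codonToAa named character of length 64 mapping codon to IUPAC
#'   one-letter amino acid, with `"*"` for stop.
#' @slot senseCodons ordered character vector of non-stop codons.
#'
#' @seealso [geneticCode()]
#' @export
setClass("GeneticCode",
  representation(
    tableId = "integer",
    name = "character",
    codonToAa = "character",
    senseCodons = "character"
  )
)

setValidity("GeneticCode", function(object) {
  msg <- NULL
  if (length(object@codonToAa) != 64L || is.null(names(object@codonToAa)))
    msg <- c(msg, "codonToAa must map exactly 64 named codons")
  if (any(object@senseCodons %in%
          names(object@codonToAa)[object@codonToAa == "*"]))
    msg <- c(msg, "senseCodons must exclude every stop codon")
  if (length(object@senseCodons) !=
      sum(object@codonToAa != "*"))
    msg <- c(msg, "senseCodons must contain every non-stop codon")
  if (is.null(msg)) TRUE else msg
})

#' In-frame codon alignment
#'
#' Holds one aligned protein-coding gene as a matrix of codon states: rows
#' are taxa, columns are codon sites, entries are 1-based indices into the
#' sense codons of the attached [GeneticCode-class] and `NA` marks a missing
#' or ambiguous codon (gap, `N`, `?`, ambiguity letter, or terminal stop).
#' `siteCoordinates` keeps the original 1-based codon position of every
#' column so reports stay in input coordinates after region excision.
#'
#' @slot states integer matrix, taxa x codon sites, with taxon rownames.
#' @slot code the [GeneticCode-class] defining the state space.
#' @slot siteCoordinates integer vector of original 1-based codon positions.
#' @slot metadata free-form list (simulation truth, provenance).
#'
#' @seealso [readCodonFasta()], [codonAlignment()], [exciseRegions()]
#' @export
setClass("CodonAlignment",
  representation(
    states = "matrix",
    code = "GeneticCode",
    siteCoordinates = "integer",
    metadata = "list"
  )
)

setValidity("CodonAlignment", function(object) {
  msg <- NULL
  st <- object@states
  if (is.null(rownames(st)) || anyDuplicated(rownames(st)))
    msg <- c(msg, "taxon names must be present and unique")
  ns <- length(object@code@senseCodons)
  v <- st[!is.na(st)]
  if (length(v) && (any(v < 1L) || any(v > ns)))
    msg <- c(msg, "states must index sense codons of the genetic code")
  if (length(object@siteCoordinates) != ncol(st))
    msg <- c(msg, "siteCoordinates must have one entry per codon column")
  if (ncol(st) < 1L)
    msg <- c(msg, "alignment must contain at least one codon column")
  if (is.null(msg)) TRUE else msg
})

#' Phylogeny with foreground branch labels
#'
#' Wraps an `ape` `phylo` tree together with a per-edge logical flag marking
#' foreground branches (the lineages of interest in branch and branch-site
#' models, e.g. deep-sea taxa). Branch lengths are expected numbers of codon
#' substitutions per codon; a tree without lengths is treated as "unset"
#' until they are optimized or simulated.
#'
#' @slot phy an `ape::phylo` object.
#' @slot foreground logical vector parallel to `phy$edge` rows; `TRUE`
#'   marks a foreground branch.
#'
#' @seealso [readLabeledTree()], [tagForeground()], [unrootTree()]
#' @export
setClass("LabeledTree",
  representation(
    phy = "ANY",
    foreground = "logical"
  )
)

setValidity("LabeledTree", function(object) {
  msg <- NULL
  if (!inherits(object@phy, "phylo"))
    msg <- c(msg, "phy must be an ape 'phylo' object")
  else {
    if (anyDuplicated(object@phy$tip.label))
      msg <- c(msg, "leaf names must be unique")
    ne <- nrow(object@phy$edge)
    if (length(object@foreground) != ne)
      msg <- c(msg, "foreground flags must be one per edge")
    bl <- object@phy$edge.length
    if (!is.null(bl) && any(!is.finite(bl) | bl < 0))
      msg <- c(msg, "branch lengths must be finite and non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' Equilibrium codon frequencies
#'
#' @slot method one of `"equal"`, `"F1x4"`, `"F3x4"`, `"empirical"`.
#' @slot pi numeric probability vector over sense codons (named, sums to 1).
#'
#' @seealso [estimateCodonFrequencies()]
#' @export
setClass("CodonFrequencies",
  representation(method = "character", pi = "numeric")
)

setValidity("CodonFrequencies", function(object) {
  msg <- NULL
  if (any(object@pi < 0) || abs(sum(object@pi) - 1) > 1e-8)
    msg <- c(msg, "pi must be non-negative and sum to 1")
  if (!object@method %in% c("equal", "F1x4", "F3x4", "empirical"))
    msg <- c(msg, "unknown frequency method")
  if (is.null(msg)) TRUE else msg
})

#' Codon model specification
#'
#' Names one of the six supported model structures and optionally pins
#' parameters at fixed values. The site-class structure implied by each
#' name:
#' \describe{
#'   \item{M0}{one ratio: a single omega shared by all sites and branches.}
#'   \item{TWO_RATIO}{one site class, separate foreground and background
#'     omega (the "branch" alternative model).}
#'   \item{M1a}{nearly neutral: classes `0 < omega0 < 1` and `omega1 = 1`.}
#'   \item{M2a}{positive selection: M1a plus a class `omega2 >= 1`.}
#'   \item{MA_NULL}{branch-site Model A with the foreground class pinned at
#'     `omega2 = 1` (purifying/neutral only).}
#'   \item{MA_ALT}{branch-site Model A with free `omega2 >= 1` on the
#'     foreground in classes 2a/2b.}
#' }
#'
#' @slot name model name, one of the six above.
#' @slot fixed named list of parameters held fixed during fitting
#'   (e.g. `list(kappa = 2)`); the truth values when used for simulation.
#'
#' @seealso [codonModelSpec()], [fitModel()]
#' @export
setClass("CodonModelSpec",
  representation(name = "character", fixed = "list")
)

.MODEL_NAMES <- c("M0", "TWO_RATIO", "M1a", "M2a", "MA_NULL", "MA_ALT")

setValidity("CodonModelSpec", function(object) {
  if (!object@name %in% .MODEL_NAMES)
    paste("model name must be one of:", paste(.MODEL_NAMES, collapse = ", "))
  else TRUE
})

#' Codon substitution rate matrix
#'
#' Instantaneous rate matrix over sense codons (GY94 structure): only
#' single-nucleotide changes have positive rate, transitions are scaled by
#' kappa and nonsynonymous changes by omega, and detailed balance holds
#' against `pi`. The matrix is scaled so that `-sum(pi * diag(Q)) == 1`,
#' i.e. branch lengths are expected substitutions per codon.
#'
#' @slot Q square numeric matrix over sense codons.
#' @slot pi stationary distribution used to build `Q`.
#' @slot scale the expected-rate divisor applied to reach unit mean rate.
#'
#' @seealso [buildRateMatrix()], [transitionMatrix()]
#' @export
setClass("RateMatrix",
  representation(Q = "matrix", pi = "numeric", scale = "numeric")
)

#' Maximum-likelihood fit of one codon model
#'
#' @slot spec the fitted [CodonModelSpec-class].
#' @slot lnL maximized log-likelihood.
#' @slot mle named list of parameter estimates (`kappa`, omegas,
#'   `proportions`, branch lengths are carried on `tree`).
#' @slot nFreeParams number of independently optimized parameters
#'   (including branch lengths when they were optimized).
#' @slot converged logical convergence flag (best restart).
#' @slot nRestartsUsed number of optimization starts performed.
#' @slot tree [LabeledTree-class] carrying the branch lengths at the optimum.
#' @slot frequencies the [CodonFrequencies-class] used.
#' @slot details list of diagnostics (per-restart log-likelihoods, options).
#'
#' @export
setClass("FitResult",
  representation(
    spec = "CodonModelSpec",
    lnL = "numeric",
    mle = "list",
    nFreeParams = "integer",
    converged = "logical",
    nRestartsUsed = "integer",
    tree = "LabeledTree",
    frequencies = "CodonFrequencies",
    details = "list"
  )
)

#' Likelihood-ratio test between nested codon models
#'
#' @slot nullModel,altModel model names.
#' @slot stat `2 * (lnL_alt - lnL_null)`, clamped at zero.
#' @slot df chi-square degrees of freedom for the comparison.
#' @slot p upper-tail chi-square probability.
#' @slot alpha significance level used for `significant`.
#' @slot significant `TRUE` iff `p < alpha`.
#'
#' @seealso [lrt()], [dfRule()]
#' @export
setClass("LRTResult",
  representation(
    nullModel = "character",
    altModel = "character",
    stat = "numeric",
    df = "integer",
    p = "numeric",
    alpha = "numeric",
    significant = "logical"
  )
)

setValidity("LRTResult", function(object) {
  msg <- NULL
  if (object@stat < 0) msg <- c(msg, "stat must be clamped at 0")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0,1]")
  if (is.null(msg)) TRUE else msg
})

#' Per-site posterior probabilities of positive selection
#'
#' One row per codon site: the original 1-based codon coordinate, the
#' reference amino acid (taken from the first sequence of the alignment,
#' rendered "-" at a gap), the posterior probability that the site belongs
#' to the positive-selection class(es), and a star flag (`"*"` for
#' posterior > 0.95, `"**"` for > 0.99, strict inequalities).
#'
#' @slot table data.frame with columns `position`, `aa`, `posterior`,
#'   `flag`.
#' @slot model name of the model the posteriors were computed under.
#' @slot method `"NEB"` or `"BEB"`.
#'
#' @seealso [nebPosteriors()], [bebPosteriors()], [reportSelectedSites()]
#' @export
setClass("SitePosteriorTable",
  representation(table = "data.frame", model = "character",
                 method = "character")
)

setValidity("SitePosteriorTable", function(object) {
  tab <- object@table
  msg <- NULL
  need <- c("position", "aa", "posterior", "flag")
  if (!all(need %in% names(tab)))
    msg <- c(msg, "table must have columns position, aa, posterior, flag")
  else {
    if (nrow(tab) && any(tab$posterior < -1e-12 | tab$posterior > 1 + 1e-12))
      msg <- c(msg, "posteriors must lie in [0,1]")
    if (nrow(tab) > 1L && any(diff(tab$position) <= 0))
      msg <- c(msg, "positions must be strictly increasing")
  }
  if (is.null(msg)) TRUE else msg
})
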
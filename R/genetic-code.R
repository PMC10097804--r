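.CODON_BASES <- c("T", "C", "A", "G")

## all 64 codons, first position varying slowest, in T,C,A,G order
.allCodons <- local({
  b <- .CODON_BASES
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  codons <- paste0(g$p1, g$p2, g$p3)
  function() codons
})

## standard code in TCAG order (TTT, TTC, TTA, TTG, TCT, ...)
.STANDARD_AA <-
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.CODE_TABLES <- list(
  `1` = list(name = "standard", diff = character(0)),
  `2` = list(name = "vertebrate mitochondrial",
             diff = c(TGA = "W", ATA = "M", AGA = "*", AGG = "*")),
  `4` = list(name = "mold/protozoan/coelenterate mitochondrial",
             diff = c(TGA = "W")),
  `5` = list(name = "invertebrate mitochondrial",
             diff = c(TGA = "W", ATA = "M", AGA = "S", AGG = "S"))
)

#' Construct a genetic code
#'
#' Builds a [GeneticCode-class] for one of the supported NCBI translation
#' tables: 1 (standard/universal), 2 (vertebrate mitochondrial), 4
#' (mold, protozoan and coelenterate mitochondrial -- the table usually
#' applied to anthozoan mitochondria) and 5 (invertebrate mitochondrial).
#' Codons are ordered lexicographically over T, C, A, G.
#'
#' Applied to a [CodonAlignment-class], `geneticCode` instead returns the
#' code attached to the alignment.
#'
#' @param x integer translation-table identifier (1, 2, 4 or 5), or a
#'   [CodonAlignment-class].
#' @return a [GeneticCode-class] object.
#' @examples
#' uni <- geneticCode(1)
#' length(senseCodons(uni))          # 61
#' mito <- geneticCode(4)
#' length(senseCodons(mito))         # 62: TGA codes tryptophan
#' @name geneticCode
#' @aliases geneticCode,numeric-method
#' @export
setMethod("geneticCode", "numeric", function(x) .makeGeneticCode(x))

.makeGeneticCode <- function(tableId = 1L) {
  key <- as.character(as.integer(tableId))
  if (!key %in% names(.CODE_TABLES))
    stop("unsupported translation table ", tableId,
         "; available: ", paste(names(.CODE_TABLES), collapse = ", "))
  codons <- .allCodons()
  aa <- strsplit(.STANDARD_AA, "")[[1]]
  names(aa) <- codons
  diff <- .CODE_TABLES[[key]]$diff
  if (length(diff)) aa[names(diff)] <- diff
  new("GeneticCode",
      tableId = as.integer(tableId),
      name = .CODE_TABLES[[key]]$name,
      codonToAa = aa,
      senseCodons = codons[aa != "*"])
}

#' @rdname codonSelect-accessors
#' @export
setMethod("senseCodons", "GeneticCode", function(x) x@senseCodons)

#' Translate codon strings
#'
#' @param code a [GeneticCode-class].
#' @param codons character vector of codon triplets.
#' @return character vector of one-letter amino acids (`"*"` for stop,
#'   `NA` for codons containing non-ACGT characters).
#' @export
translateCodons <- function(code, codons) {
  stopifnot(is(code, "GeneticCode"))
  out <- unname(code@codonToAa[codons])
  out
}

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode: table", object@tableId, paste0("(", object@name, ")"),
      "\n  sense codons:", length(object@senseCodons),
      " stop codons:", 64L - length(object@senseCodons), "\n")
})

## -- precomputed single-nucleotide-neighbour structure -----------------------
## For each ordered pair of sense codons differing at exactly one nucleotide:
## i, j (1-based sense indices), whether the change is a transition, and
## whether it is nonsynonymous under the code. Cached per table id.
.qinfoCache <- new.env(parent = emptyenv())

.qinfo <- function(code) {
  key <- as.character(code@tableId)
  hit <- .qinfoCache[[key]]
  if (!is.null(hit)) return(hit)
  sense <- code@senseCodons
  n <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  ii <- integer(0); jj <- integer(0); ts <- logical(0); ns <- logical(0)
  aa <- code@codonToAa[sense]
  for (pos in 1:3) {
    same <- matrix(TRUE, n, n)
    for (q in setdiff(1:3, pos))
      same <- same & outer(mat[, q], mat[, q], "==")
    diffp <- outer(mat[, pos], mat[, pos], "!=")
    hitm <- same & diffp
    idx <- which(hitm, arr.ind = TRUE)
    if (nrow(idx)) {
      b1 <- mat[idx[, 1], pos]; b2 <- mat[idx[, 2], pos]
      is.ts <- (b1 == "A" & b2 == "G") | (b1 == "G" & b2 == "A") |
               (b1 == "C" & b2 == "T") | (b1 == "T" & b2 == "C")
      ii <- c(ii, idx[, 1]); jj <- c(jj, idx[, 2])
      ts <- c(ts, is.ts)
      ns <- c(ns, aa[idx[, 1]] != aa[idx[, 2]])
    }
  }
  info <- list(i = ii, j = jj, ts = ts, ns = ns, n = n)
  assign(key, info, envir = .qinfoCache)
  info
}
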
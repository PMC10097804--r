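#' Build a codon alignment from nucleotide sequences
#'
#' Converts equal-length, in-frame nucleotide sequences to a
#' [CodonAlignment-class]. Any codon containing a gap (`-`), `N`, `?` or an
#' IUPAC ambiguity letter becomes the missing state, as does a stop codon at
#' the terminal position; a stop codon anywhere else is treated as an
#' out-of-frame or wrong-code signal and raises an error naming the taxon
#' and codon position.
#'
#' @param sequences named character vector of aligned nucleotide sequences,
#'   equal lengths divisible by 3.
#' @param code a [GeneticCode-class]; default universal (table 1).
#' @return a [CodonAlignment-class].
#' @examples
#' aln <- codonAlignment(c(s1 = "ATGAAA", s2 = "ATGAAG"))
#' nSites(aln)   # 2 codons
#' @export
codonAlignment <- function(sequences, code = geneticCode(1L)) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named by taxon")
  if (anyDuplicated(names(sequences)))
    stop("duplicate taxon name: ",
         names(sequences)[duplicated(names(sequences))][1L])
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop("sequences must all have the same aligned length")
  if (len %% 3L != 0L)
    stop("frame error: aligned length ", len, " is not divisible by 3")
  nsite <- len %/% 3L
  if (nsite < 1L) stop("alignment must contain at least one codon")
  sense <- code@senseCodons
  senseIdx <- stats::setNames(seq_along(sense), sense)
  stops <- names(code@codonToAa)[code@codonToAa == "*"]
  states <- matrix(NA_integer_, nrow = length(sequences), ncol = nsite,
                   dimnames = list(names(sequences), NULL))
  starts <- seq(1L, len, by = 3L)
  for (k in seq_along(sequences)) {
    s <- toupper(sequences[[k]])
    cod <- substring(s, starts, starts + 2L)
    idx <- unname(senseIdx[cod])
    isStop <- cod %in% stops
    if (any(isStop)) {
      internal <- which(isStop & seq_len(nsite) < nsite)
      if (length(internal))
        stop("internal stop codon in taxon '", names(sequences)[k],
             "' at codon position ", internal[1L])
      idx[isStop] <- NA_integer_       # terminal stop -> missing
    }
    states[k, ] <- idx
  }
  new("CodonAlignment", states = states, code = code,
      siteCoordinates = seq_len(nsite), metadata = list())
}

#' Read an in-frame codon alignment from FASTA
#'
#' Reads an aligned nucleotide FASTA and converts it to a
#' [CodonAlignment-class]; see [codonAlignment()] for the gap/ambiguity and
#' stop-codon conventions.
#'
#' @param path FASTA file of aligned nucleotide sequences.
#' @param code a [GeneticCode-class]; default universal (table 1).
#' @return a [CodonAlignment-class].
#' @export
readCodonFasta <- function(path, code = geneticCode(1L)) {
  seqs <- Biostrings::readBStringSet(path)
  v <- as.character(seqs)
  names(v) <- sub("\\s.*$", "", names(seqs))
  codonAlignment(v, code = code)
}

#' Write a codon alignment to FASTA
#'
#' Missing codons are written as `---`; the written file round-trips through
#' [readCodonFasta()] to identical states.
#'
#' @param aln a [CodonAlignment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCodonFasta <- function(aln, path) {
  sense <- aln@code@senseCodons
  lines <- character(0)
  for (k in seq_len(nrow(aln@states))) {
    cod <- sense[aln@states[k, ]]
    cod[is.na(cod)] <- "---"
    lines <- c(lines, paste0(">", rownames(aln@states)[k]),
               paste(cod, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname codonSelect-accessors
#' @export
setMethod("taxonNames", "CodonAlignment", function(x) rownames(x@states))

#' @rdname codonSelect-accessors
#' @export
setMethod("nTaxa", "CodonAlignment", function(x) nrow(x@states))

#' @rdname codonSelect-accessors
#' @export
setMethod("nSites", "CodonAlignment", function(x) ncol(x@states))

#' @rdname codonSelect-accessors
#' @export
setMethod("siteCoordinates", "CodonAlignment", function(x) x@siteCoordinates)

#' @rdname geneticCode
#' @export
setMethod("geneticCode", "CodonAlignment", function(x) x@code)

#' @rdname codonSelect-accessors
#' @export
setMethod("codonStates", "CodonAlignment", function(x) x@states)

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", nrow(object@states), "taxa x",
      ncol(object@states), "codons",
      sprintf("(code table %d, %.1f%% missing)\n",
              object@code@tableId,
              100 * mean(is.na(object@states))))
})

#' Keep a subset of taxa
#'
#' @param aln a [CodonAlignment-class].
#' @param taxa character vector of taxon names to keep (order preserved as
#'   in the alignment).
#' @return a [CodonAlignment-class] restricted to `taxa`.
#' @export
subsetTaxa <- function(aln, taxa) {
  missing <- setdiff(taxa, rownames(aln@states))
  if (length(missing))
    stop("taxa not in alignment: ", paste(missing, collapse = ", "))
  keep <- rownames(aln@states)[rownames(aln@states) %in% taxa]
  new("CodonAlignment", states = aln@states[keep, , drop = FALSE],
      code = aln@code, siteCoordinates = aln@siteCoordinates,
      metadata = aln@metadata)
}

#' Excise codon regions (e.g. introns) from an alignment
#'
#' Removes the listed closed 1-based codon intervals (positions in the
#' current alignment columns) and concatenates the flanks in order, the way
#' intron-bearing genes are reassembled into a single exonic block before
#' selection analysis. Original codon coordinates are preserved in
#' `siteCoordinates` so site reports stay in input numbering.
#'
#' @param aln a [CodonAlignment-class].
#' @param ranges a 2-column matrix or list of length-2 vectors of closed
#'   1-based codon intervals to remove; must be in range, non-overlapping.
#' @return the excised [CodonAlignment-class].
#' @examples
#' aln <- codonAlignment(c(a = strrep("ATG", 30), b = strrep("ATG", 30)))
#' out <- exciseRegions(aln, list(c(11, 20)))
#' nSites(out)              # 20
#' siteCoordinates(out)[11] # 21
#' @export
exciseRegions <- function(aln, ranges) {
  if (is.matrix(ranges)) ranges <- asplit(ranges, 1L)
  if (length(ranges) == 0L) return(aln)
  ns <- ncol(aln@states)
  drop <- logical(ns)
  for (r in ranges) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1L] > r[2L])
      stop("each range must be a (start, end) pair with start <= end")
    if (r[1L] < 1L || r[2L] > ns)
      stop("range [", r[1L], ",", r[2L], "] out of bounds for ", ns,
           " codons")
    if (any(drop[r[1L]:r[2L]]))
      stop("overlapping excision ranges")
    drop[r[1L]:r[2L]] <- TRUE
  }
  if (all(drop))
    stop("excision would remove every codon column")
  keep <- !drop
  new("CodonAlignment",
      states = aln@states[, keep, drop = FALSE],
      code = aln@code,
      siteCoordinates = aln@siteCoordinates[keep],
      metadata = aln@metadata)
}

#' Compress alignment columns into site patterns
#'
#' Groups identical codon columns so likelihood work is done once per
#' distinct pattern and weighted by multiplicity.
#'
#' @param aln a [CodonAlignment-class].
#' @return a list with `patterns` (taxa x pattern matrix of states),
#'   `weights` (multiplicity of each pattern) and `index` (per-site pattern
#'   index such that `patterns[, index]` reconstructs the alignment).
#' @export
compressPatterns <- function(aln) {
  st <- aln@states
  key <- apply(st, 2L, function(col) paste(col, collapse = ","))
  first <- !duplicated(key)
  patIdx <- match(key, key[first])
  patterns <- st[, first, drop = FALSE]
  weights <- as.vector(table(factor(patIdx, levels = seq_len(sum(first)))))
  list(patterns = patterns, weights = weights, index = patIdx)
}
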
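writeTempFasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(unlist(mapply(function(n, s) c(paste0(">", n), s),
                           names(records), records, SIMPLIFY = FALSE)),
             path)
  path
}

test_that("FASTA ingest enforces frame, uniqueness and stop-codon rules", {
  p <- writeTempFasta(c(s1 = "ATGAAA", s2 = "ATGAAG"))
  aln <- readCodonFasta(p)
  expect_identical(nTaxa(aln), 2L)
  expect_identical(nSites(aln), 2L)
  expect_identical(siteCoordinates(aln), 1:2)

  expect_error(readCodonFasta(writeTempFasta(c(a = "ATGAAAG", b = "ATGAAAG"))),
               "frame")
  expect_error(codonAlignment(c(a = "ATGAAA", a = "ATGAAG")),
               "duplicate")
  ## internal stop names taxon and position
  expect_error(codonAlignment(c(ok = "ATGTAAAAA", bad = "ATGAAAAAA")),
               "ok.*position 2")
  ## terminal stop becomes missing, not an error
  aln2 <- codonAlignment(c(a = "ATGTAA", b = "ATGAAA"))
  expect_true(is.na(codonStates(aln2)["a", 2]))
})

test_that("gapped and ambiguous codons become the missing state", {
  aln <- codonAlignment(c(a = "A-GAAA", b = "ATGANA", c = "ATG???"))
  st <- codonStates(aln)
  expect_true(is.na(st["a", 1]))   # A-G
  expect_true(is.na(st["b", 2]))   # ANA
  expect_true(is.na(st["c", 2]))   # ???
  expect_false(is.na(st["b", 1]))
})

test_that("FASTA round trip reproduces states and coordinates exactly", {
  tr <- smallTestTree(5, 2, seed = 9)
  aln <- simulateAlignment(tr, codonModelSpec("M0",
           fixed = list(kappa = 2, omega = 0.3)), length = 40, seed = 10,
           gapFraction = 0.1)
  aln <- exciseRegions(aln, list(c(5, 9)))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeCodonFasta(aln, path)
  back <- readCodonFasta(path)
  expect_identical(rownames(codonStates(back)), taxonNames(aln))
  expect_identical(unname(codonStates(back)), unname(codonStates(aln)))
  ## coordinates themselves are carried by the object, not the file
  expect_identical(siteCoordinates(aln)[11], 16L)
})

test_that("region excision drops columns and preserves original coordinates", {
  aln <- codonAlignment(c(a = strrep("ATG", 30), b = strrep("ATG", 30)))
  out <- exciseRegions(aln, list(c(11, 20)))
  expect_identical(nSites(out), 20L)
  expect_identical(siteCoordinates(out)[11], 21L)
  ## identity on empty range list
  expect_identical(exciseRegions(aln, list()), aln)
  ## degenerate and invalid ranges
  expect_error(exciseRegions(aln, list(c(1, 30))), "every codon")
  expect_error(exciseRegions(aln, list(c(25, 31))), "out of bounds")
  expect_error(exciseRegions(aln, list(c(1, 5), c(5, 8))), "overlap")
  ## missing-state counts outside the excised range are untouched
  aln2 <- codonAlignment(c(a = paste0("A-G", strrep("ATG", 29)),
                           b = strrep("ATG", 30)))
  out2 <- exciseRegions(aln2, list(c(11, 20)))
  expect_identical(sum(is.na(codonStates(out2))),
                   sum(is.na(codonStates(aln2))))
})

test_that("pattern compression is lossless and multiplicities sum to sites", {
  aln <- codonAlignment(c(a = strrep("ATG", 7), b = strrep("ATG", 7)))
  cp <- compressPatterns(aln)
  expect_identical(ncol(cp$patterns), 1L)
  expect_identical(sum(cp$weights), 7L)

  tr <- smallTestTree(4, 2, seed = 3)
  aln2 <- smallTestAln(tr, nsites = 25, seed = 4)
  cp2 <- compressPatterns(aln2)
  expect_identical(sum(cp2$weights), nSites(aln2))
  expect_identical(unname(cp2$patterns[, cp2$index]),
                   unname(codonStates(aln2)))
})

test_that("duplicating every column doubles the total log-likelihood", {
  tr <- smallTestTree(4, 2, seed = 3)
  aln <- smallTestAln(tr, nsites = 10, seed = 4)
  spec <- codonModelSpec("M0", fixed = list(kappa = 2, omega = 0.2))
  fr <- estimateCodonFrequencies(aln, "equal")
  ll1 <- siteClassLikelihoods(aln, tr, spec, list(), frequencies = fr)
  dup <- codonAlignment(setNames(
    vapply(seq_len(nTaxa(aln)), function(k) {
      s <- senseCodons(geneticCode(aln))[codonStates(aln)[k, ]]
      paste(rep(paste(s, collapse = ""), 2), collapse = "")
    }, character(1)), taxonNames(aln)))
  ll2 <- siteClassLikelihoods(dup, tr, spec, list(), frequencies = fr)
  expect_equal(2 * sum(ll1), sum(ll2), tolerance = 1e-10)
})
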
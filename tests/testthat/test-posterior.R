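# shared fixture: one planted-positive-selection gene and its MA_ALT fit
plantedFit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tr <- simulateTree(12, foregroundCount = 4, scale = 0.15, seed = 51)
    truth <- codonModelSpec("MA_ALT",
      fixed = list(kappa = 2, omega0 = 0.1, p0 = 0.65, p1 = 0.25,
                   omega2 = 5))
    aln <- simulateAlignment(tr, truth, length = 300, seed = 52)
    m0 <- fitModel(aln, tr, codonModelSpec("M0"), restarts = 1)
    alt <- fitModel(aln, m0@tree, codonModelSpec("MA_ALT"),
                    branchLengths = "fixed", restarts = 1)
    cache <<- list(tree = tr, aln = aln, fit = alt)
    cache
  }
})

test_that("posteriors are defined only for models with a positive class", {
  tr <- smallTestTree(4, 2, seed = 3)
  aln <- smallTestAln(tr, nsites = 30, seed = 4)
  f0 <- fitModel(aln, tr, codonModelSpec("M0"), restarts = 1)
  expect_error(nebPosteriors(f0, aln), "M2a and MA_ALT")
  expect_error(bebPosteriors(f0, aln), "M2a and MA_ALT")
})

test_that("NEB ranks a strongly selected site highest", {
  fx <- plantedFit()
  neb <- nebPosteriors(fx$fit, fx$aln)
  tab <- posteriorTable(neb)
  expect_true(all(tab$posterior >= 0 & tab$posterior <= 1))
  planted <- fx$aln@metadata$positiveSites
  expect_gt(length(planted), 5)
  top <- tab$position[which.max(tab$posterior)]
  expect_true(top %in% planted)
})

test_that("a degenerate BEB grid at the MLEs reduces to NEB", {
  fx <- plantedFit()
  neb <- nebPosteriors(fx$fit, fx$aln)
  beb0 <- bebPosteriors(fx$fit, fx$aln, degenerateAtMLE = TRUE)
  expect_equal(posteriorTable(beb0)$posterior,
               posteriorTable(neb)$posterior, tolerance = 1e-9)
  expect_error(bebPosteriors(fx$fit, fx$aln, ncat = 1), "at least 2")
})

test_that("BEB integrates over the grid and flags planted sites", {
  fx <- plantedFit()
  beb <- bebPosteriors(fx$fit, fx$aln)
  tab <- posteriorTable(beb)
  expect_true(all(tab$posterior >= 0 & tab$posterior <= 1))
  sel <- reportSelectedSites(beb, 0.95)
  expect_gt(nrow(sel), 0)
  planted <- fx$aln@metadata$positiveSites
  expect_gt(mean(sel$position %in% planted), 0.5)
  ## flagged-site count is non-increasing in the threshold
  n95 <- nrow(reportSelectedSites(beb, 0.95))
  n99 <- nrow(reportSelectedSites(beb, 0.99))
  expect_lte(n99, n95)
  expect_identical(nrow(reportSelectedSites(beb, 0)), nrow(tab))
})

test_that("posterior tables honour the reporting conventions", {
  ## star boundaries are strict: 0.990 -> *, 1.000 -> **, 0.954 -> *
  tab <- new("SitePosteriorTable",
             table = data.frame(position = c(10L, 20L, 30L, 40L),
                                aa = c("V", "S", "-", "M"),
                                posterior = c(0.954, 0.990, 1.000, 0.2),
                                flag = codonSelect:::.starFlag(
                                  c(0.954, 0.990, 1.000, 0.2))),
             model = "MA_ALT", method = "BEB")
  expect_identical(tab@table$flag, c("*", "*", "**", ""))
  sel <- reportSelectedSites(tab, 0.95)
  expect_identical(sel$position, c(10L, 20L, 30L))
  expect_identical(nrow(reportSelectedSites(tab, 0.999)), 1L)
})

test_that("reference amino acids come from the first sequence, gaps as '-'", {
  aln <- codonAlignment(c(first = "ATG---AAA", second = "ATGTTTAAA",
                          third = "ATGTTCAAA"))
  expect_identical(codonSelect:::.referenceAa(aln), c("M", "-", "K"))
})

test_that("permuting taxa leaves posteriors unchanged", {
  fx <- plantedFit()
  st <- codonStates(fx$aln)
  aln2 <- new("CodonAlignment", states = st[c(rev(rownames(st))), ],
              code = geneticCode(fx$aln),
              siteCoordinates = siteCoordinates(fx$aln),
              metadata = fx$aln@metadata)
  neb1 <- posteriorTable(nebPosteriors(fx$fit, fx$aln))
  neb2 <- posteriorTable(nebPosteriors(fx$fit, aln2))
  ## note the reference row changes, so compare posteriors only
  expect_equal(neb1$posterior, neb2$posterior, tolerance = 1e-9)
})
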
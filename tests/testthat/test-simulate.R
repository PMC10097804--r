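test_that("simulation is deterministic given the seed", {
  t1 <- simulateTree(13, foregroundCount = 6, seed = 61)
  t2 <- simulateTree(13, foregroundCount = 6, seed = 61)
  expect_identical(ape::write.tree(t1@phy), ape::write.tree(t2@phy))
  expect_identical(foreground(t1), foreground(t2))
  spec <- codonModelSpec("M0", fixed = list(kappa = 2, omega = 0.2))
  a1 <- simulateAlignment(t1, spec, length = 50, seed = 62)
  a2 <- simulateAlignment(t1, spec, length = 50, seed = 62)
  expect_identical(codonStates(a1), codonStates(a2))
  expect_error(simulateTree(13, foregroundCount = 0, seed = 1),
               "foregroundCount")
  expect_error(simulateAlignment(t1, spec, length = 10),
               "seed is mandatory")
})

test_that("the tree generator mirrors the small-group study design", {
  tr <- simulateTree(13, foregroundCount = 6, seed = 63)
  expect_identical(nTaxa(tr), 13L)
  expect_gte(length(foregroundTaxa(tr)), 1L)
  expect_true(all(branchLengths(tr) >= 0))
  ## truth must be fully specified
  expect_error(simulateAlignment(tr, codonModelSpec("M0",
    fixed = list(kappa = 2)), length = 10, seed = 1),
    "must fix every model parameter")
})

test_that("omega = 0 permits no amino-acid variation anywhere", {
  tr <- simulateTree(8, foregroundCount = 3, scale = 0.4, seed = 65)
  aln <- simulateAlignment(tr, codonModelSpec("M0",
           fixed = list(kappa = 2, omega = 0)), length = 120, seed = 66)
  code <- geneticCode(aln)
  sense <- senseCodons(code)
  st <- codonStates(aln)
  for (s in seq_len(ncol(st))) {
    aa <- translateCodons(code, sense[st[!is.na(st[, s]), s]])
    expect_lte(length(unique(aa)), 1L)
  }
})

test_that("tip frequencies approach equilibrium on a long branch", {
  phy <- ape::read.tree(text = "(A:25,B:25);")  # 50 substitutions apart
  tr <- labeledTree(phy)
  aln <- simulateAlignment(tr, codonModelSpec("M0",
           fixed = list(kappa = 2, omega = 0.5)), length = 50000, seed = 67)
  freq <- tabulate(codonStates(aln)["B", ], nbins = 61) / 50000
  expect_lt(max(abs(freq - 1 / 61)), 0.005)
})

test_that("gap masking hides contiguous runs at the expected rate", {
  tr <- simulateTree(10, foregroundCount = 3, seed = 68)
  aln <- simulateAlignment(tr, codonModelSpec("M0",
           fixed = list(kappa = 2, omega = 0.2)), length = 400, seed = 69,
           gapFraction = 0.1)
  miss <- is.na(codonStates(aln))
  expect_gt(mean(miss), 0.02)
  expect_lt(mean(miss), 0.25)
  ## runs are contiguous at an end of each sequence
  for (k in seq_len(nrow(miss))) {
    w <- which(miss[k, ])
    if (length(w))
      expect_true(all(diff(w) == 1) &&
                    (w[1] == 1 || w[length(w)] == ncol(miss)))
  }
})

test_that("study bundles keep truth bookkeeping and are byte-reproducible", {
  mkBundle <- function(dir) simulateStudy(
    ngenes = 3L, ntaxa = 8L, foregroundCount = 3L,
    lengths = c(60L, 80L, 70L),
    truths = list(
      codonModelSpec("M0", fixed = list(kappa = 2, omega = 0.1)),
      codonModelSpec("M0", fixed = list(kappa = 2, omega = 0.3)),
      codonModelSpec("MA_ALT", fixed = list(kappa = 2, omega0 = 0.1,
                                            p0 = 0.6, p1 = 0.3,
                                            omega2 = 4))),
    seed = 71, dir = dir)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- mkBundle(d1); b2 <- mkBundle(d2)
  expect_identical(nrow(b1$truth), 3L)
  expect_identical(b1$truth$positiveSites[1], "")
  expect_gt(nchar(b1$truth$positiveSites[3]), 0)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})
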
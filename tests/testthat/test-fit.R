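test_that("df rules match the three standard comparisons", {
  expect_identical(dfRule("M0", "TWO_RATIO"), 1L)
  expect_identical(dfRule("M1a", "M2a"), 2L)
  expect_identical(dfRule("MA_NULL", "MA_ALT"), 1L)
  expect_identical(dfRule(codonModelSpec("M0"),
                          codonModelSpec("TWO_RATIO")), 1L)
  expect_error(dfRule("M0", "M2a"), "unrecognized")
})

test_that("chi-square tails reproduce published statistic/p-value pairs", {
  expect_equal(lrtPValue(0, 1), 1)
  expect_equal(lrtPValue(8.57, 1), 0.0034, tolerance = 2e-2)
  expect_equal(lrtPValue(21.20, 1), 4.13e-6, tolerance = 2e-3)
  expect_equal(lrtPValue(121.80, 2), 3.56e-27, tolerance = 2e-3)
  expect_equal(lrtPValue(5.63, 1), 0.0177, tolerance = 5e-3)
})

test_that("the branch-model adaptive rule needs both significance and omega > 1", {
  mk <- function(p, alpha = 0.05)
    new("LRTResult", nullModel = "M0", altModel = "TWO_RATIO",
        stat = 1, df = 1L, p = p, alpha = alpha, significant = p < alpha)
  expect_true(inferAdaptive(mk(0.0034), 1.3263))
  expect_false(inferAdaptive(mk(0.001), 0.3))
  expect_false(inferAdaptive(mk(0.2), 2.0))
  bs <- new("LRTResult", nullModel = "MA_NULL", altModel = "MA_ALT",
            stat = 1, df = 1L, p = 0.01, alpha = 0.05, significant = TRUE)
  expect_error(inferAdaptive(bs, 2), "branch comparison")
})

test_that("lrt clamps negative statistics and checks gene identity", {
  tr <- smallTestTree(6, 2, seed = 23)
  aln <- smallTestAln(tr, nsites = 60, seed = 24)
  f0 <- fitModel(aln, tr, codonModelSpec("M0"), restarts = 1, gene = "g1")
  f2 <- fitModel(aln, f0@tree, codonModelSpec("TWO_RATIO"),
                 branchLengths = "fixed", restarts = 1, gene = "g1")
  out <- lrt(f0, f2)
  expect_gte(out@stat, 0)
  expect_true(out@p >= 0 && out@p <= 1)
  f2b <- f2; f2b@details$gene <- "g2"
  expect_error(lrt(f0, f2b), "different genes")
})

test_that("nested alternatives never fit worse than their null", {
  tr <- smallTestTree(8, 3, seed = 25, scale = 0.15)
  aln <- simulateAlignment(tr, codonModelSpec("M1a",
           fixed = list(kappa = 2, omega0 = 0.1, p0 = 0.8)),
           length = 150, seed = 26)
  f1 <- fitModel(aln, tr, codonModelSpec("M1a"), restarts = 1)
  f2 <- fitModel(aln, f1@tree, codonModelSpec("M2a"),
                 branchLengths = "fixed", restarts = 1)
  expect_gte(logLikelihood(f2), logLikelihood(f1) - 1e-6)
})

test_that("M0 recovers kappa and omega across the simulation grid", {
  ## one small gene per omega regime; estimates within a loose factor
  tr <- simulateTree(8, foregroundCount = 3, scale = 0.15, seed = 31)
  for (w in c(0.05, 0.2, 1, 3)) {
    aln <- simulateAlignment(tr, codonModelSpec("M0",
             fixed = list(kappa = 2, omega = w)), length = 200,
             seed = 310 + round(100 * w))
    fit <- fitModel(aln, tr, codonModelSpec("M0"), restarts = 1)
    est <- mleParams(fit)$omega
    expect_gt(est, w * 0.55)
    expect_lt(est, w * 1.9)
    expect_gt(mleParams(fit)$kappa, 1.2)
    expect_lt(mleParams(fit)$kappa, 3.2)
  }
})

test_that("a foreground with no synonymous change pins omega at the bound", {
  ## two-ratio truth with an essentially infinite foreground omega: the
  ## foreground accumulates only nonsynonymous substitutions, so the MLE
  ## runs to the 999 upper bound
  tr <- simulateTree(8, foregroundCount = 2, scale = 0.12, seed = 33)
  truth <- codonModelSpec("TWO_RATIO",
    fixed = list(kappa = 2, omegaBg = 0.1, omegaFg = 999))
  aln <- simulateAlignment(tr, truth, length = 200, seed = 34)
  f0 <- fitModel(aln, tr, codonModelSpec("M0"), restarts = 1)
  f2 <- fitModel(aln, f0@tree, codonModelSpec("TWO_RATIO"),
                 branchLengths = "fixed", restarts = 1)
  expect_gt(mleParams(f2)$omegaFg, 900)
})

test_that("re-optimizing branch lengths under a mixture model never fits worse", {
  tr <- simulateTree(8, foregroundCount = 3, scale = 0.15, seed = 35)
  truth <- codonModelSpec("MA_ALT",
    fixed = list(kappa = 2, omega0 = 0.1, p0 = 0.6, p1 = 0.3, omega2 = 4))
  aln <- simulateAlignment(tr, truth, length = 120, seed = 36)
  m0 <- fitModel(aln, tr, codonModelSpec("M0"), restarts = 1)
  fixed <- fitModel(aln, m0@tree, codonModelSpec("MA_ALT"),
                    branchLengths = "fixed", restarts = 1)
  full <- fitModel(aln, m0@tree, codonModelSpec("MA_ALT"),
                   branchLengths = "optimize", restarts = 1)
  expect_gte(logLikelihood(full), logLikelihood(fixed) - 1e-4)
  expect_identical(full@nFreeParams,
                   fixed@nFreeParams + nrow(full@tree@phy$edge))
})

test_that("fitting is invariant to taxon-order shuffling", {
  tr <- smallTestTree(6, 2, seed = 27)
  aln <- smallTestAln(tr, nsites = 60, seed = 28)
  st <- codonStates(aln)
  aln2 <- new("CodonAlignment", states = st[rev(rownames(st)), ],
              code = geneticCode(aln),
              siteCoordinates = siteCoordinates(aln), metadata = list())
  f1 <- fitModel(aln, tr, codonModelSpec("M0"), restarts = 1)
  f2 <- fitModel(aln2, tr, codonModelSpec("M0"), restarts = 1)
  expect_lt(abs(logLikelihood(f1) - logLikelihood(f2)), 1e-6)
})

test_that("multi-start reporting and convergence flags are populated", {
  tr <- smallTestTree(5, 2, seed = 29)
  aln <- smallTestAln(tr, nsites = 50, seed = 30)
  fit <- fitModel(aln, tr, codonModelSpec("M0"), restarts = 2)
  expect_identical(fit@nRestartsUsed, 2L)
  expect_true(is.logical(fit@converged))
  expect_identical(fit@nFreeParams,
                   2L + nrow(fit@tree@phy$edge))
})
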
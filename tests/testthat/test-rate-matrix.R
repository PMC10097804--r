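randomPi <- function(code, seed) {
  set.seed(seed)
  x <- runif(length(senseCodons(code)), 0.2, 1)
  x / sum(x)
}

test_that("GY94 structure: single-nucleotide moves, kappa and omega factors", {
  code <- geneticCode(1)
  n <- length(senseCodons(code))
  pi <- rep(1 / n, n)
  Q <- buildRateMatrix(kappa = 1, omega = 1, pi = pi, code = code)@Q
  off <- Q[row(Q) != col(Q)]
  pos <- off[off > 0]
  ## kappa = omega = 1 with equal pi: all permitted rates identical
  expect_lt(diff(range(pos)), 1e-12)
  ## codons differing at >1 position have rate exactly 0
  sense <- senseCodons(code)
  ndiff <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_identical(Q["TTT", "TCC"], 0)
  expect_identical(Q["ATG", "GTA"], 0)
  expect_gt(Q["TTT", "TTC"], 0)
  expect_identical(ndiff("TTT", "TCC"), 2L)
})

test_that("detailed balance and unit scaling hold for random parameters", {
  code <- geneticCode(4)
  for (seed in 1:3) {
    pi <- randomPi(code, seed)
    Q <- buildRateMatrix(kappa = 1 + seed, omega = 0.1 * seed, pi = pi,
                         code = code)
    flux <- pi * Q@Q
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    expect_equal(-sum(pi * diag(Q@Q)), 1, tolerance = 1e-12)
    expect_lt(max(abs(rowSums(Q@Q))), 1e-12)
  }
})

test_that("omega = 0 silences every nonsynonymous rate", {
  code <- geneticCode(1)
  n <- length(senseCodons(code))
  Q <- buildRateMatrix(kappa = 2, omega = 0, pi = rep(1 / n, n),
                       code = code)@Q
  aa <- translateCodons(code, senseCodons(code))
  nonsyn <- outer(aa, aa, "!=")
  expect_true(all(Q[nonsyn] == 0))
  expect_error(buildRateMatrix(kappa = -1, omega = 1,
                               pi = rep(1 / n, n), code = code),
               "kappa")
  expect_error(buildRateMatrix(kappa = 2, omega = -0.1,
                               pi = rep(1 / n, n), code = code),
               "omega")
})

test_that("transition matrices are stochastic, ergodic, and match expm", {
  code <- geneticCode(1)
  pi <- randomPi(code, 7)
  Q <- buildRateMatrix(kappa = 3, omega = 0.4, pi = pi, code = code)
  expect_equal(transitionMatrix(Q, 0), diag(61), tolerance = 1e-12,
               ignore_attr = TRUE)
  P <- transitionMatrix(Q, 0.3)
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, 61), tolerance = 1e-10)
  ## ergodic limit: every row approaches pi
  Pinf <- transitionMatrix(Q, 1e6)
  expect_lt(max(abs(sweep(Pinf, 2, pi, "-"))), 1e-6)
  ## independent scaling-and-squaring oracle
  Pexpm <- as.matrix(Matrix::expm(Q@Q * 0.3))
  expect_lt(max(abs(P - Pexpm)), 1e-9)
  expect_error(transitionMatrix(Q, -1), "non-negative")
})

test_that("Chapman-Kolmogorov holds for random time splits", {
  code <- geneticCode(1)
  pi <- randomPi(code, 11)
  Q <- buildRateMatrix(kappa = 2, omega = 0.2, pi = pi, code = code)
  set.seed(2)
  for (k in 1:3) {
    s <- runif(1, 0.05, 0.5); t <- runif(1, 0.05, 0.5)
    expect_lt(max(abs(transitionMatrix(Q, s) %*% transitionMatrix(Q, t) -
                        transitionMatrix(Q, s + t))), 1e-8)
  }
})

test_that("branch lengths count expected substitutions per codon", {
  ## event-counting simulation: realized substitutions per codon per branch
  ## match the branch length within 3 standard errors
  tr <- readLabeledTree(text = "((A:0.3,B:0.5):0.2,C:0.4);")
  spec <- codonModelSpec("M0", fixed = list(kappa = 2, omega = 0.5))
  n <- 4000
  aln <- simulateAlignment(tr, spec, length = n, seed = 13,
                           countEvents = TRUE)
  ev <- aln@metadata$edgeEvents / n
  bl <- branchLengths(tr)
  se <- sqrt(bl / n)        # Poisson-ish standard error per codon
  expect_true(all(abs(ev - bl) < 3.5 * se))
})
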
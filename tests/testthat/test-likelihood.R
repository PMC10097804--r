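test_that("two-taxon likelihood reduces to the reversible closed form", {
  ## L(site) = pi_i P_ij(t1 + t2)
  phy <- ape::read.tree(text = "(A:0.2,B:0.3);")
  tr <- labeledTree(phy)
  aln <- codonAlignment(c(A = "ATGTTT", B = "ATGTTC"))
  code <- geneticCode(aln)
  fr <- estimateCodonFrequencies(aln, "equal")
  spec <- codonModelSpec("M0", fixed = list(kappa = 2, omega = 0.2))
  ll <- siteClassLikelihoods(aln, tr, spec, list(), frequencies = fr)
  Q <- buildRateMatrix(2, 0.2, fr@pi, code)
  P <- transitionMatrix(Q, 0.5)
  sense <- senseCodons(code)
  closed <- log(fr@pi[c("ATG", "TTT")] *
                  P[cbind(match(c("ATG", "TTT"), sense),
                          match(c("ATG", "TTC"), sense))])
  expect_equal(as.numeric(ll), unname(closed), tolerance = 1e-10)
})

test_that("an all-missing column contributes likelihood one to every class", {
  tr <- smallTestTree(4, 2, seed = 3)
  aln <- smallTestAln(tr, nsites = 4, seed = 4)
  st <- codonStates(aln)
  sense <- senseCodons(geneticCode(aln))
  seqs <- vapply(seq_len(nrow(st)), function(k) {
    cod <- sense[st[k, ]]
    cod[2] <- "---"
    paste(cod, collapse = "")
  }, character(1))
  names(seqs) <- rownames(st)
  aln2 <- codonAlignment(seqs)
  spec <- codonModelSpec("MA_ALT",
    fixed = list(kappa = 2, omega0 = 0.2, p0 = 0.6, p1 = 0.3, omega2 = 3))
  ll <- siteClassLikelihoods(aln2, tr, spec, list(),
                             frequencies = estimateCodonFrequencies(aln2,
                                                                    "equal"))
  expect_equal(unname(ll[2, ]), rep(0, 4), tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration for every model structure", {
  tr <- smallTestTree(4, 2, seed = 5)
  aln <- smallTestAln(tr, nsites = 5, seed = 6)
  fr <- estimateCodonFrequencies(aln, "equal")
  pars <- list(
    M0 = list(kappa = 2, omega = 0.2),
    TWO_RATIO = list(kappa = 2, omegaBg = 0.1, omegaFg = 1.8),
    M1a = list(kappa = 2, omega0 = 0.15, p0 = 0.7),
    M2a = list(kappa = 2, omega0 = 0.15, omega2 = 2.5, p0 = 0.6, p1 = 0.3),
    MA_NULL = list(kappa = 2, omega0 = 0.15, p0 = 0.6, p1 = 0.3),
    MA_ALT = list(kappa = 2, omega0 = 0.15, omega2 = 3, p0 = 0.6, p1 = 0.3)
  )
  for (m in names(pars)) {
    spec <- codonModelSpec(m, fixed = pars[[m]])
    ll <- siteClassLikelihoods(aln, tr, spec, list(), frequencies = fr)
    tot <- totalLogLikelihood(ll, attr(ll, "proportions"))
    oracle <- oracleLogLik(aln, tr, m, pars[[m]], fr@pi)
    expect_equal(tot, oracle, tolerance = 1e-10, label = m)
  }
})

test_that("mixture totals: single class reduction and nesting inequality", {
  tr <- smallTestTree(4, 2, seed = 5)
  aln <- smallTestAln(tr, nsites = 20, seed = 6)
  fr <- estimateCodonFrequencies(aln, "equal")
  m0 <- codonModelSpec("M0", fixed = list(kappa = 2, omega = 0.2))
  ll <- siteClassLikelihoods(aln, tr, m0, list(), frequencies = fr)
  expect_equal(totalLogLikelihood(ll, 1), sum(ll), tolerance = 1e-12)
  ## M2a at p2 = 0 equals M1a at shared parameters
  m1a <- codonModelSpec("M1a", fixed = list(kappa = 2, omega0 = 0.2, p0 = 0.7))
  m2a <- codonModelSpec("M2a", fixed = list(kappa = 2, omega0 = 0.2,
                                            omega2 = 2, p0 = 0.7,
                                            p1 = 0.3 - 1e-9))
  ll1 <- siteClassLikelihoods(aln, tr, m1a, list(), frequencies = fr)
  ll2 <- siteClassLikelihoods(aln, tr, m2a, list(), frequencies = fr)
  t1 <- totalLogLikelihood(ll1, attr(ll1, "proportions"))
  t2 <- totalLogLikelihood(ll2, attr(ll2, "proportions"))
  expect_equal(t1, t2, tolerance = 1e-6)
  expect_error(totalLogLikelihood(ll1, c(0.5, 0.2)), "sum to 1")
})

test_that("likelihood is invariant to taxon order", {
  tr <- smallTestTree(6, 2, seed = 15)
  aln <- smallTestAln(tr, nsites = 40, seed = 16)
  fr <- estimateCodonFrequencies(aln, "equal")
  spec <- codonModelSpec("M0", fixed = list(kappa = 2, omega = 0.2))
  ll <- siteClassLikelihoods(aln, tr, spec, list(), frequencies = fr)
  shuffled <- codonStates(aln)[rev(taxonNames(aln)), ]
  aln2 <- new("CodonAlignment", states = shuffled, code = geneticCode(aln),
              siteCoordinates = siteCoordinates(aln), metadata = list())
  ll2 <- siteClassLikelihoods(aln2, tr, spec, list(), frequencies = fr)
  expect_lt(abs(sum(ll) - sum(ll2)), 1e-8)
})

test_that("per-node scaling survives long alignments on many taxa", {
  tr <- simulateTree(30, foregroundCount = 8, scale = 0.2, seed = 41)
  spec <- codonModelSpec("M0", fixed = list(kappa = 2, omega = 0.1))
  aln <- simulateAlignment(tr, spec, length = 2000, seed = 42)
  ll <- siteClassLikelihoods(aln, tr, spec, list(),
                             frequencies = estimateCodonFrequencies(aln,
                                                                    "F3x4"))
  expect_true(all(is.finite(ll)))
  expect_true(sum(ll) < 0)
})
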
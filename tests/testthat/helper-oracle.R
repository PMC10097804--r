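# Independent likelihood oracle: builds the GY94 generator from codon
# strings, exponentiates with Matrix::expm, and sums over all internal-node
# state assignments by exhaustive enumeration. Shares no code with the
# package's pruning engine beyond the class-structure definitions it is
# meant to verify.

oracleQ <- function(kappa, omega, pi, code) {
  sense <- senseCodons(code)
  n <- length(sense)
  aa <- translateCodons(code, sense)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(strsplit(sense[i], "")[[1]] != strsplit(sense[j], "")[[1]])
    if (length(d) != 1L) next
    b <- c(substr(sense[i], d, d), substr(sense[j], d, d))
    ts <- all(b %in% c("A", "G")) || all(b %in% c("C", "T"))
    r <- pi[j]
    if (ts) r <- r * kappa
    if (aa[i] != aa[j]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# per-site-class structure of the models, written out independently
oracleClasses <- function(name, par) {
  w2 <- if (name == "MA_NULL") 1 else par$omega2
  switch(name,
    M0 = list(prop = 1, bg = par$omega, fg = par$omega),
    TWO_RATIO = list(prop = 1, bg = par$omegaBg, fg = par$omegaFg),
    M1a = list(prop = c(par$p0, 1 - par$p0),
               bg = c(par$omega0, 1), fg = c(par$omega0, 1)),
    M2a = list(prop = c(par$p0, par$p1, 1 - par$p0 - par$p1),
               bg = c(par$omega0, 1, par$omega2),
               fg = c(par$omega0, 1, par$omega2)),
    MA_NULL = ,
    MA_ALT = {
      pr <- 1 - par$p0 - par$p1
      list(prop = c(par$p0, par$p1, pr * par$p0 / (par$p0 + par$p1),
                    pr * par$p1 / (par$p0 + par$p1)),
           bg = c(par$omega0, 1, par$omega0, 1),
           fg = c(par$omega0, 1, w2, w2))
    })
}

# total log-likelihood by exhaustive summation over internal-node states
oracleLogLik <- function(aln, tree, specName, par, pi) {
  code <- geneticCode(aln)
  cls <- oracleClasses(specName, par)
  phy <- tree@phy
  po <- ape::reorder.phylo(phy, "postorder")
  fg <- foreground(tree)[match(paste(po$edge[, 1], po$edge[, 2]),
                               paste(phy$edge[, 1], phy$edge[, 2]))]
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- po$edge[nrow(po$edge), 1]
  states <- codonStates(aln)[phy$tip.label, , drop = FALSE]
  n <- length(pi)

  omegas <- sort(unique(c(cls$bg, cls$fg)))
  Qs <- lapply(omegas, function(w) oracleQ(par$kappa, w, pi, code))
  mu <- vapply(Qs, function(Q) -sum(pi * diag(Q)), numeric(1))
  iBg <- match(cls$bg, omegas); iFg <- match(cls$fg, omegas)
  sBg <- sum(cls$prop * mu[iBg]); sFg <- sum(cls$prop * mu[iFg])

  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  combos <- as.matrix(expand.grid(rep(list(seq_len(n)), length(internal))))
  totalLL <- 0
  for (s in seq_len(ncol(states))) {
    mix <- 0
    for (cc in seq_along(cls$prop)) {
      Ps <- lapply(seq_len(nrow(po$edge)), function(e) {
        k <- if (fg[e]) iFg[cc] else iBg[cc]
        sc <- if (fg[e]) sFg else sBg
        as.matrix(Matrix::expm(Qs[[k]] * po$edge.length[e] / sc))
      })
      assign <- matrix(0L, nrow(combos), nnode)
      for (k in seq_len(ntip)) {
        if (is.na(states[k, s])) next   # handled below
        assign[, k] <- states[k, s]
      }
      assign[, internal] <- combos
      p <- pi[assign[, root]]
      for (e in seq_len(nrow(po$edge))) {
        pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
        if (ch <= ntip && is.na(states[ch, s])) next  # missing tip: sums to 1
        p <- p * Ps[[e]][cbind(assign[, pa], assign[, ch])]
      }
      mix <- mix + cls$prop[cc] * sum(p)
    }
    totalLL <- totalLL + log(mix)
  }
  totalLL
}

# tiny deterministic fixtures -------------------------------------------------

smallTestTree <- function(ntaxa = 4, fgCount = 2, seed = 5, scale = 0.3) {
  simulateTree(ntaxa, foregroundCount = fgCount, scale = scale, seed = seed)
}

smallTestAln <- function(tree, nsites = 5, seed = 6,
                         spec = codonModelSpec("M0",
                           fixed = list(kappa = 2, omega = 0.2))) {
  simulateAlignment(tree, spec, length = nsites, seed = seed)
}
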
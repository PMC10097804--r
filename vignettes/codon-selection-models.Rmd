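---
title: "Detecting positive selection in protein-coding genes with codon models"
author: "codonSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positive selection with codon models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonSelect)
```

# The question and the models

A protein-coding gene evolving under no selective constraint accumulates
nonsynonymous (amino-acid changing) and synonymous substitutions at the same
relative rate; their ratio ω = dN/dS is the central quantity of this
package. ω < 1 indicates purifying selection, ω = 1 neutrality, and ω > 1
positive (diversifying or adaptive) selection. Mitochondrial protein-coding
genes — the motivating application is coral mitogenomes sampled across a
shallow-water/deep-sea depth gradient — are typically under strong purifying
selection (gene-average ω of roughly 0.05–0.35), so positive selection, when
present, is episodic: confined to particular branches (e.g. deep-sea
lineages) and particular codon sites. The three classical paired tests
target exactly those scenarios.

## The substitution process

All models share a GY94-style Markov process on the sense codons of a
genetic code. The instantaneous rate from codon *i* to codon *j* is

* 0 if *i* and *j* differ at more than one nucleotide position;
* π~j~ · κ^[transition]^ · ω^[nonsynonymous]^ otherwise,

where π is the equilibrium codon distribution, κ the
transition/transversion rate ratio, and ω multiplies only amino-acid
changing moves. The generator is reversible against π by construction.
Branch lengths are measured in expected codon substitutions per codon: each
generator is divided by the mixture-average rate so that one unit of branch
length is one expected substitution averaged over site classes. For models
whose foreground branches use different ω values than the background, the
average is taken per branch class (one scale for background branches, one
for foreground), so a branch length retains the same meaning on both branch
types. This convention matters: scaling choices change the numerical values
of branch-length and ω MLEs, so it is stated here once and used everywhere
(likelihood, optimization and simulation go through the same code path).

Equilibrium frequencies default to F3x4 (position-specific nucleotide
frequencies multiplied per codon and renormalized over sense codons), the
convention most users of codon-model engines will expect; `equal`, `F1x4`
and `empirical` are available. Codons absent from the data are floored at
1e-10 and renormalized so log-likelihoods stay finite.

The genetic code defaults to the universal table (1), mirroring the common
engine default; the mold/protozoan/coelenterate mitochondrial table (4),
the usual choice for anthozoan mitochondria, plus tables 2 and 5, are
selectable per run (`geneticCode(4)`). The state space (61 or 62 sense
codons) and synonymy structure follow the chosen table; codons are ordered
lexicographically over T, C, A, G throughout.

## The six model structures

| name | site classes | free parameters |
|------|--------------|-----------------|
| M0 | one ω everywhere | κ, ω |
| TWO_RATIO | one class, separate foreground/background ω | κ, ω~bg~, ω~fg~ |
| M1a | 0 < ω₀ < 1 (p₀), ω₁ = 1 | κ, ω₀, p₀ |
| M2a | M1a + ω₂ ≥ 1 (p₂) | κ, ω₀, ω₂, p₀, p₁ |
| MA_NULL | Model A with ω₂ = 1 | κ, ω₀, p₀, p₁ |
| MA_ALT | Model A with free ω₂ ≥ 1 | κ, ω₀, ω₂, p₀, p₁ |

Branch-site Model A has four site classes: class 0 (ω₀ on every branch,
proportion p₀), class 1 (neutral everywhere, p₁), and classes 2a/2b, which
behave like classes 0/1 on background branches but share ω₂ on foreground
branches, with proportions split proportionally,
p~2a~ = (1 − p₀ − p₁)·p₀/(p₀+p₁) and p~2b~ likewise with p₁. This is the
standard four-class parameterization; descriptions that abbreviate the
background classes as "(ω = 0, ω = 1)" are read as the conventional
(0 < ω₀ < 1, ω = 1) pair — the background purifying class has a free ω₀,
not a hard zero.

Free parameters are bounded: ω in [1e-4, 999] (a foreground with no
synonymous substitutions runs to the 999 ceiling, the conventional sentinel
for "effectively infinite"), ω₀ in [1e-4, 1], ω₂ in [1, 999], κ in
[0.01, 100].

## Tests and inference rules

Each comparison is a likelihood-ratio test: 2ΔlnL referred to a chi-square
with df equal to the number of freed parameters — branch test df = 1, site
test df = 2, branch-site test df = 1. The branch-site test uses the plain
chi-square df = 1 reference rather than the 50:50 boundary mixture; because
the null pins ω₂ at the boundary, this choice is conservative, which the
calibration test verifies empirically. Negative 2ΔlnL values (optimizer
noise on flat likelihoods) are clamped to zero with a warning.

Adaptive evolution on the foreground is called from the branch test only
when both p < α and ω̂~fg~ > 1. For the site and branch-site tests, sites
are reported when the LRT is significant and the site's Bayes Empirical
Bayes posterior for the positive class exceeds 0.95 (strictly); a verbose
mode surfaces BEB tables for non-significant comparisons too, since a
high-posterior site under a non-significant LRT is occasionally of
interest but is not, by the inference rule, evidence of selection. No
multiple-testing correction is applied across genes by default, mirroring
per-gene reporting practice; the summary table contains everything needed
to apply one.

## Site posteriors: NEB and BEB

NEB evaluates P(class|site) at the MLEs. BEB additionally integrates over
a discrete uniform prior grid on the mixture parameters — here ω₀ on
(0, 1), ω₂ on (1, 11), and the proportion pair (p₀, p₁) on the uniform
triangle — with 10 equal-probability categories per dimension by default
(grid midpoints; proportion pairs with p₀ + p₁ ≥ 1 are excluded). κ,
branch lengths, codon frequencies and the branch-rate scaling stay at
their MLEs. The grid posterior is computed from the full alignment, then
per-site class posteriors are averaged over the grid. A degenerate
single-point "grid" at the MLEs reproduces NEB exactly and is exposed only
as a consistency check. Reported coordinates are original 1-based codon
positions (surviving intron excision), and the reference amino acid is
taken from the first sequence of the alignment, rendered `-` at a gap.

# Likelihood engine

Likelihoods are computed by Felsenstein pruning over the sense-codon state
space, vectorized over compressed site patterns in compiled code, with
per-node scaling factors accumulated in log space so alignments of
thousands of codons on scores of taxa do not underflow. Transition
probabilities come from the eigendecomposition of the symmetrized
reversible generator (D^1/2^ Q D^−1/2^), which is numerically robust for
these matrices; tiny negative entries from roundoff are clipped. Missing
codons (gaps, ambiguities, terminal stops) contribute a vector of ones at
the tip — they carry no information rather than being treated as data.
Trees are unrooted before fitting (a degree-2 root is collapsed, summing
its incident branch lengths); under a reversible model the likelihood is
invariant to the collapsed root position, which the tests verify.

For branch-site models, classes 2a/2b differ from classes 0/1 only on
foreground branches, so subtree partials of purely-background subtrees are
shared between the class pairs rather than recomputed.

## Optimization

Substitution parameters are maximized by box-constrained quasi-Newton
iterations (L-BFGS-B) on transformed scales — log for κ and every ω,
additive log-ratio for class proportions — alternating with edge-wise
branch-length optimization: one sweep computes lower (postorder) and upper
(preorder) partial vectors, reduces each edge's likelihood to
Σ~k~ c~k~ e^(λ~k~ t)^ in the eigenbasis, and maximizes each length by
bounded golden-section search on log t within [1e-6, 20]. Alternation
stops when the log-likelihood improves by less than 1e-4. Multi-start
fitting (default 3 starts with initial ω staggered over 0.1, 0.5, 1.5)
guards against local optima in the mixture models; the best start is
reported along with a convergence flag.

Branch lengths are re-optimized under every model by default. A fast mode
fixes them (and, if the caller chooses, κ) at the M0 optimum for the other
five models; it is an approximation — clearly labeled in the output — that
is useful for large replicate studies, and it leaves LRTs between models
fitted on the same fixed lengths well behaved because null and alternative
share the constraint.

# The simulator

The generative model is the exact mirror of the likelihood: a site draws
its class from the truth proportions, the root codon comes from π, and
states evolve along each branch with the transition matrix of the class-
and branch-flag-appropriate generator under the same scaling convention.
Trees are random resolved topologies with exponential branch lengths
(default mean 0.1 substitutions/codon) and a foreground clade (or random
subset); the default study shape — 13 taxa with 6 foreground, 13 genes of
70–1100 codons, gene-average ω drawn from 0.05–0.35, κ = 2, ~2% missing
data — matches a small coral-group design dominated by strong purifying
selection. Gap masking removes one contiguous codon run per taxon at a
sequence end, mimicking incompletely recovered gene ends, rather than
i.i.d. missing sites. An event-counting mode simulates exponential waiting
times explicitly so that realized substitution counts can be checked
against branch lengths.

What the simulator does not emulate: indel evolution, introns (excision is
supported on real data, but the generator produces exon-only genes),
recombination, codon-usage bias beyond the stationary distribution,
among-site rate variation other than the discrete ω classes, and
non-stationary base composition. Passing tests therefore demonstrate
correctness and calibration of the inference machinery under the model's
own assumptions — not robustness to model violation in real alignments.

Master seeds fan out deterministically (seed + gene index) so bundles are
reproducible piecewise; every simulation function requires an explicit
seed.

# Worked example

```{r example, eval = FALSE}
tr <- simulateTree(13, foregroundCount = 6, scale = 0.12, seed = 7)
truth <- codonModelSpec("TWO_RATIO",
  fixed = list(kappa = 2, omegaBg = 0.1, omegaFg = 1.5))
aln <- simulateAlignment(tr, truth, length = 300, seed = 8)

res <- runGeneAnalysis(aln, tr, foregroundTaxa(tr), gene = "atp6-like",
                       restarts = 1, branchMode = "fast")
res$lrts$branch
res$adaptive
```

The same interface runs on real data: `readCodonFasta()` +
`readLabeledTree()` + `tagForeground()` (or engine-style `#1` tags in the
newick), `exciseRegions()` for intron-bearing genes, and `runStudy()` for
a full gene × foreground-set design with TSV and figure artifacts.

# Numerical and design choices, in one place

* Scaling: per-branch-flag mixture-average rate; stated above, used by
  likelihood and simulator alike.
* Transition probabilities: symmetric eigendecomposition; negatives
  clipped; rows renormalized in the user-facing `transitionMatrix()`.
* Scalers: per-node, per-pattern log scalers, rescaling when partials
  leave [1e-100, 1e100].
* Zero site likelihood (possible only for structurally impossible data,
  e.g. ω = 0 with an observed amino-acid change) raises an error naming
  the pattern rather than returning −Inf silently.
* Star flags on posteriors are strict: `*` means > 0.95, `**` means
  > 0.99; 0.990 therefore earns one star, 1.000 two.
* Foreground convention: terminal branches of foreground taxa plus every
  internal branch whose descendant leaves are all foreground. Whether a
  study intends internal branches of a foreground clade to be foreground
  is often unstated; this convention is declared, deterministic, and can
  be overridden by explicit `#1` labels in the input newick.
* Tree tips absent from a gene's alignment are dropped (and logged) for
  that gene, keeping per-gene analyses maximal rather than forcing a
  shared taxon set.
* Polytomies are accepted as-is; no arbitrary resolution is introduced.

## Problem sizes in the test suite

The shipped tests exercise the full pipeline at deliberately scaled
designs: exhaustive-enumeration oracle checks at 4 taxa × 5 codons
(every model structure, agreement to 1e-10); M0 parameter recovery over
20 replicate genes at 8 taxa × 300 codons; branch-site null calibration
over 100 replicates at 12 taxa × 300 codons (rejection ≤ ~7% at α = 0.05,
reflecting the boundary-null conservatism); BEB site recovery at 16 taxa ×
500 codons with 10% planted ω₂ = 4 sites; and a deterministic 14-gene ×
2-foreground study. These sizes are the package's choices for a thorough
but quick default suite; the engine itself is routinely used at the
84-taxon, multi-kilobase scale of real mitogenome studies.

# Known limitations

* The branch-site null reference is the plain χ²₁; the boundary mixture
  alternative would be slightly less conservative.
* BEB integrates over mixture parameters only; κ and branch lengths are
  treated as known at their MLEs, as in the published construction.
* Fast mode's fixed branch lengths bias per-model MLEs slightly when the
  null and alternative would prefer different trees; use full mode for
  final reported estimates.
* Gene-by-gene analysis: no sharing of κ or branch lengths across genes,
  and no joint multi-gene models.
* No ancestral-state reconstruction, no gamma rate variation, no
  empirical-codon exchangeabilities.
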
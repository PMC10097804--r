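#' Run the three model comparisons for one gene
#'
#' Fits the branch pair (M0 vs two-ratio), the site pair (M1a vs M2a) and
#' the branch-site pair (Model A null vs alternative) on one codon
#' alignment, shares the tree and data across each pair, computes the
#' three likelihood-ratio tests, and attaches BEB site tables for the
#' alternatives that allow omega > 1. Tree leaves absent from the gene are
#' dropped (and reported); gene taxa absent from the tree are an error.
#'
#' @param aln a [CodonAlignment-class].
#' @param tree a [LabeledTree-class] (foreground flags are re-derived from
#'   `foregroundTaxa` after dropping missing leaves).
#' @param foregroundTaxa character vector naming the foreground leaves.
#' @param gene gene identifier used in outputs.
#' @param alpha significance level (default 0.05).
#' @param freqMethod codon frequency convention (default F3x4).
#' @param restarts optimization starts per model (default 3).
#' @param branchMode `"full"` re-optimizes branch lengths under every
#'   model; `"fast"` optimizes them under M0 only and holds them fixed for
#'   the other five models (an approximation, clearly labeled in output).
#' @param bebNcat BEB grid categories per dimension.
#' @param verboseSites include BEB tables even when the matching LRT is
#'   not significant (default `FALSE`, mirroring the usual reporting rule).
#' @param code genetic code used to interpret `aln` (only needed if `aln`
#'   was built elsewhere; default taken from the alignment).
#' @return a list with `fits` (named [FitResult-class] list), `lrts`
#'   (named [LRTResult-class] list: branch, site, branchSite), `beb`
#'   (named [SitePosteriorTable-class] list), `adaptive` (branch-rule
#'   flag), `summary` (one-row data.frame), or `NULL` when the foreground
#'   is empty after intersection (with a warning).
#' @export
runGeneAnalysis <- function(aln, tree, foregroundTaxa, gene = "gene",
                            alpha = 0.05, freqMethod = "F3x4",
                            restarts = 3L, branchMode = c("full", "fast"),
                            bebNcat = 10L, verboseSites = FALSE,
                            code = NULL) {
  branchMode <- match.arg(branchMode)
  tips <- taxonNames(tree)
  alnTaxa <- taxonNames(aln)
  missingFromTree <- setdiff(alnTaxa, tips)
  if (length(missingFromTree))
    stop("gene '", gene, "': taxa absent from the tree: ",
         paste(missingFromTree, collapse = ", "))
  dropTips <- setdiff(tips, alnTaxa)
  phy <- tree@phy
  if (length(dropTips)) {
    message("gene '", gene, "': dropping ", length(dropTips),
            " tree leaves absent from the alignment: ",
            paste(dropTips, collapse = ", "))
    phy <- ape::drop.tip(phy, dropTips)
  }
  fg <- intersect(foregroundTaxa, phy$tip.label)
  if (length(fg) == 0L || length(fg) == length(phy$tip.label)) {
    warning("gene '", gene, "': foreground empty (or all taxa) after ",
            "intersection; skipping")
    return(NULL)
  }
  tr <- tagForeground(labeledTree(phy), fg)
  tr <- unrootTree(tr)

  fitOne <- function(name, bl, tree0)
    fitModel(aln, tree0, codonModelSpec(name), freqMethod = freqMethod,
             branchLengths = bl, restarts = restarts, gene = gene)

  fits <- list()
  fits$M0 <- fitOne("M0", "optimize", tr)
  baseTree <- fits$M0@tree
  blMode <- if (branchMode == "fast") "fixed" else "optimize"
  for (m in c("TWO_RATIO", "M1a", "M2a", "MA_NULL", "MA_ALT"))
    fits[[m]] <- fitOne(m, blMode, baseTree)

  lrts <- list(
    branch = lrt(fits$M0, fits$TWO_RATIO, alpha),
    site = lrt(fits$M1a, fits$M2a, alpha),
    branchSite = lrt(fits$MA_NULL, fits$MA_ALT, alpha)
  )
  adaptive <- inferAdaptive(lrts$branch, fits$TWO_RATIO@mle$omegaFg)

  beb <- list()
  if (verboseSites || lrts$site@significant)
    beb$site <- bebPosteriors(fits$M2a, aln, ncat = bebNcat)
  if (verboseSites || lrts$branchSite@significant)
    beb$branchSite <- bebPosteriors(fits$MA_ALT, aln, ncat = bebNcat)

  nSel <- function(tab) if (is.null(tab)) 0L else
    nrow(reportSelectedSites(tab, 0.95))
  summary <- data.frame(
    gene = gene, foregroundSize = length(fg),
    nTaxa = length(phy$tip.label), nSites = nSites(aln),
    branchMode = branchMode,
    omegaM0 = fits$M0@mle$omega,
    omegaBg = fits$TWO_RATIO@mle$omegaBg,
    omegaFg = fits$TWO_RATIO@mle$omegaFg,
    branchStat = lrts$branch@stat, branchP = lrts$branch@p,
    adaptive = adaptive,
    siteStat = lrts$site@stat, siteP = lrts$site@p,
    siteSelected = nSel(beb$site),
    branchSiteStat = lrts$branchSite@stat,
    branchSiteP = lrts$branchSite@p,
    branchSiteSelected = nSel(beb$branchSite),
    stringsAsFactors = FALSE)

  list(gene = gene, fits = fits, lrts = lrts, beb = beb,
       adaptive = adaptive, summary = summary)
}

.readForegroundFile <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Run a complete multi-gene, multi-foreground selection study
#'
#' Iterates [runGeneAnalysis()] over every gene and every named foreground
#' set, collects a study summary, and (when `outDir` is set) writes
#' machine-readable artifacts: `fits.tsv` (per model: lnL, kappa, omega
#' classes, proportions), `sites.tsv` (BEB tables with test statistics),
#' `summary.tsv`, and a per-gene omega bar figure comparing foreground and
#' background estimates. Output is deterministic given the seed.
#'
#' @param config either a list, a YAML file path, or a bundle from
#'   [simulateStudy()]. A config list understands: `genes` (named list of
#'   FASTA paths or [CodonAlignment-class] objects), `introns` (optional
#'   named list of codon-interval lists to excise), `tree` (newick path or
#'   [LabeledTree-class]), `foregroundSets` (named list: taxon vectors or
#'   paths to one-name-per-line files), `excludeTaxa`, `codeTable`
#'   (default 1), `freqMethod`, `alpha`, `restarts`, `branchMode`,
#'   `bebNcat`, `outDir`, `figure` (default `TRUE`), `seed`. Paths are
#'   resolved relative to the YAML file when one is used.
#' @param ... overrides applied on top of `config`.
#' @return a list with `results` (per gene x foreground), `summary`
#'   (data.frame), and `config` (the resolved options).
#' @export
runStudy <- function(config, ...) {
  if (is.character(config) && length(config) == 1L) {
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    config$.base <- base
  }
  if (!is.null(config$alignments)) {           # simulateStudy bundle
    config <- list(genes = config$alignments,
                   tree = config$tree,
                   foregroundSets = list(deep = config$foreground))
  }
  config <- modifyList(config, list(...))
  base <- if (is.null(config$.base)) "." else config$.base
  opt <- modifyList(
    list(codeTable = 1L, freqMethod = "F3x4", alpha = 0.05,
         restarts = 3L, branchMode = "full", bebNcat = 10L,
         outDir = NULL, figure = TRUE, seed = 1L, excludeTaxa = character(0),
         introns = list(), verboseSites = FALSE),
    config)
  set.seed(opt$seed)
  code <- geneticCode(opt$codeTable)

  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  tree <- opt$tree
  if (is.character(tree)) tree <- readLabeledTree(rel(tree))
  if (length(opt$excludeTaxa)) {
    keep <- setdiff(taxonNames(tree), opt$excludeTaxa)
    tree <- labeledTree(ape::keep.tip(tree@phy, keep))
  }
  fgSets <- lapply(opt$foregroundSets, function(s) {
    s <- if (is.character(s) && length(s) == 1L && file.exists(rel(s)))
      .readForegroundFile(rel(s)) else s
    setdiff(s, opt$excludeTaxa)
  })
  bad <- names(fgSets)[!vapply(fgSets, function(s)
    length(intersect(s, taxonNames(tree))) > 0, logical(1L))]
  if (length(bad))
    stop("foreground set(s) with no taxa left on the tree: ",
         paste(bad, collapse = ", "))

  results <- list()
  rows <- list()
  for (g in names(opt$genes)) {
    aln <- opt$genes[[g]]
    if (is.character(aln)) aln <- readCodonFasta(rel(aln), code = code)
    if (length(opt$excludeTaxa)) {
      keep <- setdiff(taxonNames(aln), opt$excludeTaxa)
      aln <- subsetTaxa(aln, keep)
    }
    if (!is.null(opt$introns[[g]]))
      aln <- exciseRegions(aln, opt$introns[[g]])
    for (f in names(fgSets)) {
      res <- runGeneAnalysis(aln, tree, fgSets[[f]], gene = g,
                             alpha = opt$alpha,
                             freqMethod = opt$freqMethod,
                             restarts = opt$restarts,
                             branchMode = opt$branchMode,
                             bebNcat = opt$bebNcat,
                             verboseSites = opt$verboseSites)
      if (is.null(res)) next
      res$foreground <- f
      res$summary <- cbind(foreground = f, res$summary)
      results[[paste(g, f, sep = "|")]] <- res
      rows[[paste(g, f, sep = "|")]] <- res$summary
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  report <- list(results = results, summary = summary, config = opt)
  if (!is.null(opt$outDir)) .writeStudyArtifacts(report, opt)
  report
}

.writeStudyArtifacts <- function(report, opt) {
  dir.create(opt$outDir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) formatC(x, digits = 6, format = "g")
  fitRows <- list()
  siteRows <- list()
  for (res in report$results) {
    for (m in names(res$fits)) {
      fit <- res$fits[[m]]
      oc <- fit@mle$omegaClasses
      fitRows[[length(fitRows) + 1L]] <- data.frame(
        gene = res$gene, foreground = res$foreground, model = m,
        lnL = fmt(fit@lnL), kappa = fmt(fit@mle$kappa),
        proportions = paste(fmt(oc$proportion), collapse = ","),
        omegaBackground = paste(fmt(oc$omegaBackground), collapse = ","),
        omegaForeground = paste(fmt(oc$omegaForeground), collapse = ","),
        converged = fit@converged, stringsAsFactors = FALSE)
    }
    for (comp in names(res$beb)) {
      ltr <- res$lrts[[if (comp == "site") "site" else "branchSite"]]
      sel <- reportSelectedSites(res$beb[[comp]], 0.95)
      if (!nrow(sel)) next
      siteRows[[length(siteRows) + 1L]] <- data.frame(
        gene = res$gene, foreground = res$foreground,
        comparison = comp, stat = fmt(ltr@stat), p = fmt(ltr@p),
        codon = sel$position, aa = sel$aa,
        beb = sprintf("%.3f", sel$posterior), flag = sel$flag,
        stringsAsFactors = FALSE)
    }
  }
  write.table(do.call(rbind, fitRows), file.path(opt$outDir, "fits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  siteTab <- if (length(siteRows)) do.call(rbind, siteRows) else
    data.frame(gene = character(0), foreground = character(0),
               comparison = character(0), stat = character(0),
               p = character(0), codon = integer(0), aa = character(0),
               beb = character(0), flag = character(0))
  write.table(siteTab, file.path(opt$outDir, "sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$summary, file.path(opt$outDir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (isTRUE(opt$figure) && !is.null(report$summary)) {
    df <- report$summary
    long <- rbind(
      data.frame(gene = df$gene, foreground = df$foreground,
                 branch = "background", omega = df$omegaBg),
      data.frame(gene = df$gene, foreground = df$foreground,
                 branch = "foreground", omega = df$omegaFg))
    p <- ggplot2::ggplot(long,
           ggplot2::aes(x = gene, y = omega, fill = branch)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(~foreground) +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::labs(x = NULL, y = expression(omega~"(dN/dS)")) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x =
                       ggplot2::element_text(angle = 60, hjust = 1))
    grDevices::pdf(file.path(opt$outDir, "omega_by_gene.pdf"),
                   width = 8, height = 4)
    print(p)
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' Render human-readable selection tables
#'
#' Formats a study report into the two conventional blocks: the site-model
#' table (genes whose M1a vs M2a comparison was significant, with BEB
#' sites) and the branch-site table (Model A comparisons), using the star
#' convention `*` for BEB > 95% and `**` for > 99% (strict inequalities).
#'
#' @param report the list returned by [runStudy()].
#' @param file optional path; when given the text is also written there.
#' @return the rendered lines, invisibly when `file` is given.
#' @export
renderReport <- function(report, file = NULL) {
  lines <- character(0)
  block <- function(title, comp) {
    out <- c(title,
             sprintf("%-10s %-12s %9s %10s %6s %3s %6s",
                     "Foreground", "Gene", "2dlnL", "p", "Codon", "AA",
                     "BEB"))
    any <- FALSE
    for (res in report$results) {
      tab <- res$beb[[comp]]
      if (is.null(tab)) next
      ltr <- res$lrts[[if (comp == "site") "site" else "branchSite"]]
      sel <- reportSelectedSites(tab, 0.95)
      if (!nrow(sel)) next
      any <- TRUE
      for (k in seq_len(nrow(sel)))
        out <- c(out, sprintf("%-10s %-12s %9.2f %10.3g %6d %3s %6s",
                              res$foreground, res$gene,
                              ltr@stat, ltr@p, sel$position[k], sel$aa[k],
                              paste0(sprintf("%.3f", sel$posterior[k]),
                                     sel$flag[k])))
    }
    if (!any) out <- c(out, "(no sites above threshold)")
    c(out, "*BEB > 95%, **> 99%", "")
  }
  lines <- c(lines,
             block("Sites under positive selection (site models M1a vs M2a)",
                   "site"),
             block(paste("Sites under positive selection on foreground",
                         "branches (branch-site Model A)"), "branchSite"))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
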
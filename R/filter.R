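## Post-calling SNP panel filters: completeness (fraction of individuals
## with at least one read), minor allele frequency estimated by EM from the
## genotype likelihoods under HWE, and positional thinning to one SNP per
## fixed genomic block. Stages telescope into a FilterReport.

#' Completeness filter: require reads in a fraction of individuals
#'
#' A site is kept iff at least \code{ceiling(threshold * N)} individuals
#' have depth >= 1 there (a site must meet or exceed the fraction). With the
#' default 0.92 and 171 individuals the required count is 158.
#'
#' @param gl a [GenotypeLikelihoodSet-class].
#' @param threshold fraction in (0, 1], default 0.92.
#' @return the filtered GenotypeLikelihoodSet, site order preserved.
#' @export
completenessFilter <- function(gl, threshold = 0.92) {
  stopifnot(threshold > 0, threshold <= 1)
  need <- ceiling(threshold * nSamples(gl))
  keep <- rowSums(depths(gl) >= 1L) >= need
  gl[keep, ]
}

#' Maximum-likelihood allele frequency from genotype likelihoods
#'
#' Per-site EM under Hardy-Weinberg: given current frequency f, the
#' posterior expected dosage of each individual is computed from its
#' likelihood triple and the HWE prior, and the update is the mean dosage
#' over 2N. Iterated to |delta f| < 1e-8 or 200 iterations. Symmetric under
#' allele relabelling (f <-> 1-f with likelihood columns reversed). Sites
#' where every individual is informationless (all-flat likelihoods) return
#' 0.5 and are flagged in \code{attr(, "flat")} with a warning.
#'
#' @param gl a [GenotypeLikelihoodSet-class].
#' @param tol convergence tolerance on f (default 1e-8).
#' @param maxIter iteration cap (default 200).
#' @return numeric vector of alternate-allele frequencies, one per site.
#' @export
estimateAlleleFreqEM <- function(gl, tol = 1e-8, maxIter = 200) {
  g0 <- SummarizedExperiment::assay(gl, "glHomRef")
  g1 <- SummarizedExperiment::assay(gl, "glHet")
  g2 <- SummarizedExperiment::assay(gl, "glHomAlt")
  L <- nrow(g0); N <- ncol(g0)
  flat <- rowSums(abs(g0 - g1) + abs(g1 - g2)) < 1e-12
  f <- rep(0.5, L)
  active <- !flat
  for (it in seq_len(maxIter)) {
    if (!any(active)) break
    fa <- f
    w0 <- (1 - f)^2; w1 <- 2 * f * (1 - f); w2 <- f^2
    num <- g1 * w1 + 2 * g2 * w2
    den <- g0 * w0 + g1 * w1 + g2 * w2
    eg <- num / pmax(den, 1e-300)
    f2 <- rowSums(eg) / (2 * N)
    f[active] <- f2[active]
    if (max(abs(f - fa)) < tol) break
  }
  if (any(flat)) {
    warning(sum(flat), " site(s) have all-flat likelihoods; ",
            "frequency reported as 0.5")
    f[flat] <- 0.5
  }
  attr(f, "flat") <- flat
  f
}

#' Minor allele frequency filter
#'
#' A site is kept iff \code{min(f, 1 - f) >= mafMin}: sites with minor
#' allele frequency strictly below the threshold are excluded, the boundary
#' is kept. Frequencies come from [estimateAlleleFreqEM()].
#'
#' @param gl a [GenotypeLikelihoodSet-class].
#' @param mafMin minimum minor allele frequency, default 0.05.
#' @return the filtered GenotypeLikelihoodSet.
#' @export
mafFilter <- function(gl, mafMin = 0.05) {
  stopifnot(mafMin >= 0, mafMin < 0.5)
  f <- suppressWarnings(estimateAlleleFreqEM(gl))
  maf <- pmin(f, 1 - f)
  gl[maf >= mafMin - 1e-9, ]    # tiny slack: EM converges to, not onto, f
}

#' Thin to a single SNP per genomic block
#'
#' Each scaffold is partitioned into fixed half-open blocks [0, b), [b, 2b),
#' ... of \code{blockBp} base pairs (1-based positions 1..b fall in the
#' first block), and exactly one site is retained uniformly at random per
#' non-empty block. Deterministic given \code{seed}.
#'
#' @param gl a [GenotypeLikelihoodSet-class], sites sorted within scaffold.
#' @param blockBp block size in bp, default 1000.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return the thinned GenotypeLikelihoodSet (a subset of input sites).
#' @export
thinSites <- function(gl, blockBp = 1000, seed = NULL) {
  stopifnot(blockBp >= 1)
  st <- siteTable(gl)
  block <- paste(st$scaffold, (st$position - 1L) %/% blockBp)
  withSeed(seed, {
    keep <- vapply(split(seq_len(nrow(st)), block), function(ix)
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)],
      integer(1))
  })
  gl[sort(unname(keep)), ]
}

#' Run the full SNP panel filter with an attrition report
#'
#' Applies, in order: completeness, minor-allele-frequency, and positional
#' thinning; returns the analysis-ready panel together with a telescoping
#' per-stage report (sites in, removed, out). A count of non-biallelic
#' records removed upstream (e.g. by [readVcfGL()]) can be folded in as the
#' first stage.
#'
#' @param gl a [GenotypeLikelihoodSet-class].
#' @param completenessMin,mafMin,thinBlock stage thresholds (defaults 0.92,
#'   0.05, 1000 bp).
#' @param seed seed for the thinning draw.
#' @param nonBiallelicRemoved integer, records already removed for not being
#'   biallelic SNPs; defaults to the attribute left by [readVcfGL()], else 0.
#' @return list(\code{gl} filtered set, \code{report} data.frame with
#'   columns stage, sites_in, sites_removed, sites_out).
#' @export
filterPanel <- function(gl, completenessMin = 0.92, mafMin = 0.05,
                        thinBlock = 1000, seed = NULL,
                        nonBiallelicRemoved = NULL) {
  if (is.null(nonBiallelicRemoved))
    nonBiallelicRemoved <- attr(gl, "nonBiallelicRemoved")
  if (is.null(nonBiallelicRemoved)) nonBiallelicRemoved <- 0L
  n0 <- nSites(gl) + nonBiallelicRemoved
  g1 <- completenessFilter(gl, completenessMin)
  g2 <- mafFilter(g1, mafMin)
  g3 <- thinSites(g2, thinBlock, seed)
  report <- data.frame(
    stage = c("biallelic", "completeness", "maf", "thinning"),
    sites_in = c(n0, nSites(gl), nSites(g1), nSites(g2)),
    sites_removed = c(nonBiallelicRemoved,
                      nSites(gl) - nSites(g1),
                      nSites(g1) - nSites(g2),
                      nSites(g2) - nSites(g3)),
    sites_out = c(nSites(gl), nSites(g1), nSites(g2), nSites(g3)),
    stringsAsFactors = FALSE)
  list(gl = g3, report = report)
}
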
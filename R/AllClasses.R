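#' GenotypeLikelihoodSet: per-site, per-individual genotype likelihoods
#'
#' The pipeline's central container. It extends
#' \linkS4class{RangedSummarizedExperiment} with four assays, all sites x
#' samples: \code{glHomRef}, \code{glHet}, \code{glHomAlt} (genotype
#' likelihoods, rescaled so the largest of the three is 1 at every cell) and
#' \code{depth} (integer read counts). Rows are biallelic SNP (or invariant)
#' sites carried as a \link[GenomicRanges]{GRanges} with \code{ref} and
#' \code{alt} metadata columns; columns are individuals.
#'
#' Validity requires positions strictly increasing within each scaffold,
#' finite non-negative likelihoods with max 1 per cell, and flat (equal)
#' likelihoods wherever depth is 0 -- zero reads carry no genotype
#' information.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}; no extra slots.
#' @seealso [GenotypeLikelihoodSet()] the constructor, [readVcfGL()],
#'   [simulateMetapopulation()]
#' @exportClass GenotypeLikelihoodSet
setClass("GenotypeLikelihoodSet",
         contains = "RangedSummarizedExperiment")

.validGLS <- function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("glHomRef", "glHet", "glHomAlt", "depth")
  if (!all(need %in% an))
    return(paste("missing assays:", paste(setdiff(need, an), collapse = ", ")))
  g0 <- SummarizedExperiment::assay(object, "glHomRef")
  g1 <- SummarizedExperiment::assay(object, "glHet")
  g2 <- SummarizedExperiment::assay(object, "glHomAlt")
  dp <- SummarizedExperiment::assay(object, "depth")
  if (any(!is.finite(g0)) || any(!is.finite(g1)) || any(!is.finite(g2)))
    msg <- c(msg, "likelihoods must be finite")
  if (min(g0, g1, g2) < 0)
    msg <- c(msg, "likelihoods must be non-negative")
  mx <- pmax(g0, pmax(g1, g2))
  if (length(mx) && any(mx <= 0))
    msg <- c(msg, "likelihoods must not be all zero at any site/individual")
  if (any(dp < 0) || any(dp != round(dp)))
    msg <- c(msg, "depths must be non-negative integers")
  flat <- dp == 0
  if (any(flat) && (any(abs(g0[flat] - g1[flat]) > 1e-9) ||
                    any(abs(g1[flat] - g2[flat]) > 1e-9)))
    msg <- c(msg, "cells with depth 0 must carry flat (equal) likelihoods")
  rr <- SummarizedExperiment::rowRanges(object)
  if (!all(c("ref", "alt") %in% colnames(S4Vectors::mcols(rr))))
    msg <- c(msg, "rowRanges must carry 'ref' and 'alt' metadata columns")
  pos <- GenomicRanges::start(rr)
  sc <- as.character(GenomicRanges::seqnames(rr))
  if (length(pos) > 1L) {
    ord <- unlist(lapply(split(pos, sc)[unique(sc)],
                         function(p) length(p) < 2L || all(diff(p) > 0)))
    if (!all(ord))
      msg <- c(msg, "positions must be strictly increasing within scaffold")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeLikelihoodSet", .validGLS)

#' Construct a GenotypeLikelihoodSet
#'
#' @param likelihoods numeric array of dimension sites x samples x 3, genotype
#'   order (hom-ref, het, hom-alt), or a list of three sites x samples
#'   matrices in that order. Any positive scaling per cell is accepted; values
#'   are rescaled so the per-cell maximum is 1.
#' @param depths integer matrix, sites x samples, read depth per cell.
#' @param scaffold character vector of scaffold names per site.
#' @param position 1-based bp position per site (strictly increasing within
#'   scaffold).
#' @param ref,alt single-base alleles per site.
#' @param sampleIds character vector of unique individual ids.
#' @return a [GenotypeLikelihoodSet-class] object.
#' @examples
#' gl <- GenotypeLikelihoodSet(
#'   likelihoods = array(rep(c(1, 1e-3, 1e-30), each = 2), c(1, 2, 3)),
#'   depths = matrix(5L, 1, 2), scaffold = "scaf_1", position = 101L,
#'   ref = "A", alt = "G", sampleIds = c("s1", "s2"))
#' nSites(gl)
#' @export
GenotypeLikelihoodSet <- function(likelihoods, depths, scaffold, position,
                                  ref, alt, sampleIds) {
  if (is.list(likelihoods))
    likelihoods <- array(c(likelihoods[[1]], likelihoods[[2]], likelihoods[[3]]),
                         dim = c(dim(likelihoods[[1]]), 3L))
  stopifnot(length(dim(likelihoods)) == 3L, dim(likelihoods)[3] == 3L)
  L <- dim(likelihoods)[1]; N <- dim(likelihoods)[2]
  g0 <- likelihoods[, , 1, drop = FALSE]; dim(g0) <- c(L, N)
  g1 <- likelihoods[, , 2, drop = FALSE]; dim(g1) <- c(L, N)
  g2 <- likelihoods[, , 3, drop = FALSE]; dim(g2) <- c(L, N)
  mx <- pmax(g0, pmax(g1, g2))
  if (any(mx <= 0 | !is.finite(mx)))
    stop("each (site, individual) cell needs at least one positive finite likelihood")
  g0 <- g0 / mx; g1 <- g1 / mx; g2 <- g2 / mx
  depths <- matrix(as.integer(round(depths)), L, N)
  rr <- GenomicRanges::GRanges(
    seqnames = scaffold,
    ranges = IRanges::IRanges(start = as.integer(position), width = 1L),
    ref = as.character(ref), alt = as.character(alt))
  dn <- list(NULL, as.character(sampleIds))
  dimnames(g0) <- dimnames(g1) <- dimnames(g2) <- dimnames(depths) <- dn
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(glHomRef = g0, glHet = g1, glHomAlt = g2, depth = depths),
    rowRanges = rr)
  new("GenotypeLikelihoodSet", se)
}

#' @describeIn GenotypeLikelihoodSet number of sites (rows)
#' @param x,object a GenotypeLikelihoodSet
#' @export
nSites <- function(x) nrow(x)

#' @describeIn GenotypeLikelihoodSet number of individuals (columns)
#' @export
nSamples <- function(x) ncol(x)

#' @describeIn GenotypeLikelihoodSet sample identifiers
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn GenotypeLikelihoodSet read-depth matrix (sites x samples)
#' @export
depths <- function(x) SummarizedExperiment::assay(x, "depth")

#' @describeIn GenotypeLikelihoodSet likelihood array (sites x samples x 3)
#' @export
glArray <- function(x) {
  array(c(SummarizedExperiment::assay(x, "glHomRef"),
          SummarizedExperiment::assay(x, "glHet"),
          SummarizedExperiment::assay(x, "glHomAlt")),
        dim = c(nrow(x), ncol(x), 3L),
        dimnames = list(NULL, colnames(x), c("homRef", "het", "homAlt")))
}

#' @describeIn GenotypeLikelihoodSet per-site table (scaffold, position, ref, alt)
#' @export
siteTable <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(scaffold = as.character(GenomicRanges::seqnames(rr)),
             position = GenomicRanges::start(rr),
             ref = S4Vectors::mcols(rr)$ref,
             alt = S4Vectors::mcols(rr)$alt,
             stringsAsFactors = FALSE)
}

setMethod("show", "GenotypeLikelihoodSet", function(object) {
  dp <- depths(object)
  cat("GenotypeLikelihoodSet with", nrow(object), "sites x",
      ncol(object), "individuals\n")
  cat("  scaffolds:",
      length(unique(as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(object))))),
      " mean depth:", signif(mean(dp), 3),
      " missing (depth 0):",
      sprintf("%.1f%%", 100 * mean(dp == 0)), "\n")
})

#' AncestryFit: posterior summary of the admixture model
#'
#' Result of [gibbsAdmixture()]: an admixture model with \code{k} ancestral
#' clusters fit to genotype likelihoods by Gibbs sampling. Holds
#' posterior-mean ancestry coefficients \code{q} (individuals x k,
#' rows summing to 1), cluster allele frequencies \code{p} (k x sites),
#' per-cell genotype posteriors and posterior-mean dosages, the DIC and its
#' components, and the retained per-chain deviance samples.
#'
#' @slot k integer, number of clusters.
#' @slot q numeric matrix N x k of posterior-mean ancestry proportions.
#' @slot p numeric matrix k x L of posterior-mean cluster allele frequencies.
#' @slot genotypePosterior numeric array N x L x 3.
#' @slot dosage numeric matrix N x L, posterior-mean genotype in [0, 2].
#' @slot dic,pD,devianceBar,devianceAtMean numeric DIC decomposition.
#' @slot chainDeviance list of retained deviance samples, one per chain.
#' @slot settings list of MCMC settings used.
#' @exportClass AncestryFit
setClass("AncestryFit",
         representation(k = "integer", q = "matrix", p = "matrix",
                        genotypePosterior = "array", dosage = "matrix",
                        dic = "numeric", pD = "numeric",
                        devianceBar = "numeric", devianceAtMean = "numeric",
                        chainDeviance = "list", settings = "list"))

setValidity("AncestryFit", function(object) {
  msg <- character()
  if (ncol(object@q) != object@k) msg <- c(msg, "q must have k columns")
  if (nrow(object@p) != object@k) msg <- c(msg, "p must have k rows")
  if (any(abs(rowSums(object@q) - 1) > 1e-6))
    msg <- c(msg, "rows of q must sum to 1")
  if (length(object@p) && (min(object@p) < -1e-12 || max(object@p) > 1 + 1e-12))
    msg <- c(msg, "p entries must lie in [0,1]")
  if (length(object@dosage) &&
      (min(object@dosage) < -1e-9 || max(object@dosage) > 2 + 1e-9))
    msg <- c(msg, "dosages must lie in [0,2]")
  if (length(msg)) msg else TRUE
})

#' @describeIn AncestryFit posterior-mean ancestry matrix (N x k)
#' @param object an AncestryFit
#' @export
ancestryQ <- function(object) object@q

#' @describeIn AncestryFit posterior-mean cluster allele frequencies (k x L)
#' @export
clusterFreqs <- function(object) object@p

#' @describeIn AncestryFit posterior-mean genotype dosage matrix (N x L)
#' @export
dosageMatrix <- function(object) object@dosage

#' @describeIn AncestryFit deviance information criterion of the fit
#' @export
dic <- function(object) object@dic

setMethod("show", "AncestryFit", function(object) {
  cat("AncestryFit: k =", object@k, "clusters,",
      nrow(object@q), "individuals x", ncol(object@p), "sites\n")
  cat("  DIC:", round(object@dic, 2), " (Dbar =",
      round(object@devianceBar, 2), ", pD =", round(object@pD, 2), ")\n")
  cat("  chains:", length(object@chainDeviance), " retained samples/chain:",
      length(object@chainDeviance[[1]]), "\n")
})
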
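## PCA on posterior genotype dosages and Nei's (1972) standard genetic
## distance between populations from biallelic allele frequencies.

#' PCA of a genotype dosage matrix
#'
#' Columns (sites) are centered but not scaled -- dosages share units -- and
#' the covariance eigendecomposition gives scores and loadings. Sign
#' convention: within each component the largest-magnitude loading is made
#' positive, so results are reproducible across platforms.
#'
#' @param dosage numeric matrix, individuals x sites, no missing cells
#'   (posterior dosages are complete by construction).
#' @return list of class \code{"pikaPca"}: \code{scores} (N x C),
#'   \code{proportionVariance} (length C, non-increasing, sums to 1 over all
#'   components), \code{loadings} (sites x C).
#' @export
runPca <- function(dosage) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) < 2) stop("PCA needs at least 2 individuals")
  if (anyNA(dosage)) stop("dosage matrix must have no missing cells")
  pc <- prcomp(dosage, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(c) {
    j <- which.max(abs(pc$rotation[, c]))
    if (pc$rotation[j, c] < 0) -1 else 1
  }, 0)
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  structure(list(scores = scores,
                 proportionVariance = pc$sdev^2 / sum(pc$sdev^2),
                 loadings = loadings),
            class = "pikaPca")
}

#' @export
print.pikaPca <- function(x, ...) {
  pv <- x$proportionVariance
  cat("PCA:", nrow(x$scores), "individuals,", length(pv), "components\n")
  cat("  variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_len(min(4, length(pv))),
                     100 * pv[seq_len(min(4, length(pv)))]),
             collapse = ", "), "\n")
  invisible(x)
}

#' Population allele frequencies from dosages
#'
#' The alternate-allele frequency of population p at site l is the mean
#' dosage of its members divided by 2.
#'
#' @param dosage individuals x sites matrix (e.g. [dosageMatrix()] of an
#'   [AncestryFit-class], or true genotypes).
#' @param samples data.frame with \code{sample_id} and \code{population},
#'   rows matching the dosage rows (matched by rowname when present,
#'   else by order).
#' @return populations x sites matrix of frequencies in [0, 1], population
#'   order = first appearance in \code{samples}.
#' @export
popAlleleFreqs <- function(dosage, samples) {
  dosage <- as.matrix(dosage)
  if (!is.null(rownames(dosage)) &&
      all(rownames(dosage) %in% samples$sample_id)) {
    samples <- samples[match(rownames(dosage), samples$sample_id), ]
  } else if (nrow(dosage) != nrow(samples)) {
    stop("dosage rows and sample table rows do not match")
  }
  pops <- unique(samples$population)
  f <- t(vapply(pops, function(p)
    colMeans(dosage[samples$population == p, , drop = FALSE]) / 2,
    numeric(ncol(dosage))))
  rownames(f) <- pops
  f
}

#' Nei's standard genetic distance between populations
#'
#' For biallelic loci with alternate-allele frequencies x and y the mean
#' homozygosities are \code{Jx = mean(x^2 + (1-x)^2)} (likewise Jy) and the
#' mean inter-population identity \code{Jxy = mean(x y + (1-x)(1-y))}; the
#' normalized identity is \code{I = Jxy / sqrt(Jx Jy)} and \code{D = -ln I}.
#' D is 0 iff the frequency vectors are identical, symmetric, invariant to
#' consistent allele relabelling, and +Inf when the populations are
#' oppositely fixed at every locus (I = 0).
#'
#' @param freqs populations x sites frequency matrix
#'   (see [popAlleleFreqs()]).
#' @return symmetric matrix of Nei's D with zero diagonal; +Inf entries are
#'   flagged in \code{attr(, "infinite")}.
#' @export
neiDistance <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) < 2) stop("need at least two populations")
  if (any(freqs < -1e-9 | freqs > 1 + 1e-9))
    stop("frequencies must lie in [0, 1]")
  L <- ncol(freqs)
  J <- (freqs %*% t(freqs) + (1 - freqs) %*% t(1 - freqs)) / L
  Jdiag <- diag(J)
  I <- J / sqrt(outer(Jdiag, Jdiag))
  D <- -log(I)
  diag(D) <- 0
  D[D < 0 & D > -1e-12] <- 0           # clip numerical negatives
  dimnames(D) <- list(rownames(freqs), rownames(freqs))
  attr(D, "infinite") <- !is.finite(D)
  D
}

#' Write a distance matrix in PHYLIP format
#'
#' Square lower+upper full-matrix PHYLIP layout, for external tree builders
#' (e.g. neighbor-joining of a Nei's D matrix).
#'
#' @param D symmetric numeric matrix with dimnames.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePhylipDist <- function(D, path) {
  nm <- rownames(D)
  if (is.null(nm)) nm <- paste0("pop", seq_len(nrow(D)))
  nm <- formatC(substr(gsub("[^A-Za-z0-9_]", "_", nm), 1, 10),
                width = 10, flag = "-")
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i)
               paste(nm[i], paste(sprintf("%.6f", D[i, ]), collapse = " ")),
               ""))
  writeLines(lines, path)
  invisible(path)
}
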
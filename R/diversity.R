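## Genotype-likelihood diversity estimation per population, in the
## empirical-Bayes lineage of ANGSD/realSFS: site allele-frequency (SAF)
## likelihoods by dynamic programming over individuals, folded SFS by EM,
## per-site posterior expectations of the pi and Watterson-theta
## contributions using the SFS as prior, and Tajima's D in fixed
## non-overlapping genomic windows.

#' Site allele-frequency likelihoods for one population
#'
#' For each site, computes \code{P(reads | j alternate alleles among n = 2 *
#' n_ind chromosomes)} for j = 0..n by a dynamic programming pass over
#' individuals: the likelihood triple of each diploid is convolved in with
#' genotype multiplicities (1, 2, 1), and column j is finally divided by
#' \code{choose(n, j)} -- the hypergeometric weighting of assigning j
#' alleles to unordered genotype configurations. Rows are rescaled to max 1.
#'
#' @param gl a [GenotypeLikelihoodSet-class] subset to the population's
#'   individuals (at least 2).
#' @return list of class \code{"safLik"}: \code{saf} (sites x (n+1) matrix,
#'   max-normalized), \code{n} (chromosome count), \code{sites} (site
#'   table), \code{hasData} (logical: any read at the site).
#' @export
computeSaf <- function(gl) {
  nInd <- nSamples(gl)
  if (nInd < 2) stop("SAF needs at least 2 individuals")
  g0 <- SummarizedExperiment::assay(gl, "glHomRef")
  g1 <- SummarizedExperiment::assay(gl, "glHet")
  g2 <- SummarizedExperiment::assay(gl, "glHomAlt")
  L <- nrow(g0)
  n <- 2L * nInd
  U <- matrix(0, L, n + 1L)
  U[, 1] <- 1
  for (m in seq_len(nInd)) {
    top <- 2L * m                       # alleles seen so far
    V <- matrix(0, L, n + 1L)
    prev <- seq_len(top - 1L)           # columns 1..(top-1) of U may be nonzero
    V[, prev] <- U[, prev] * g0[, m]
    V[, prev + 1L] <- V[, prev + 1L] + U[, prev] * 2 * g1[, m]
    V[, prev + 2L] <- V[, prev + 2L] + U[, prev] * g2[, m]
    mx <- do.call(pmax, c(as.data.frame(V[, seq_len(top + 1L), drop = FALSE]),
                          list(1e-300)))
    U <- V / mx                          # rescale to dodge underflow
  }
  U <- U / matrix(choose(n, 0:n), L, n + 1L, byrow = TRUE)
  U <- U / do.call(pmax, c(as.data.frame(U), list(1e-300)))
  structure(list(saf = U, n = n, sites = siteTable(gl),
                 hasData = rowSums(depths(gl)) > 0),
            class = "safLik")
}

# Fold a SAF matrix: column j (0-based) of the folded matrix sums the
# unfolded entries for j and n - j; the middle class (n even) is unpaired.
.foldSaf <- function(saf, n) {
  half <- n %/% 2L
  fold <- saf[, 1:(half + 1L), drop = FALSE]
  for (j in 0:(half - 1L))
    fold[, j + 1L] <- fold[, j + 1L] + saf[, n - j + 1L]
  if (n %% 2L == 1L) fold[, half + 1L] <- fold[, half + 1L] +
      saf[, n - half + 1L]
  fold
}

#' Estimate the folded site-frequency spectrum by EM
#'
#' Maximizes \code{sum_sites log sum_j phi_j SAF_fold(j)} over the folded
#' spectrum phi (minor-allele counts 0..floor(n/2)): the E-step computes the
#' per-site posterior over j, the M-step averages it. Converges when
#' \code{max |delta phi| < 1e-6} or after 500 iterations.
#'
#' @param saf a \code{"safLik"} from [computeSaf()].
#' @param tol,maxIter EM controls.
#' @param onlyData restrict to sites with at least one read (default TRUE;
#'   no-read sites carry no information and would just echo the prior).
#' @return list of class \code{"foldedSfs"}: \code{prob} (probabilities over
#'   0..floor(n/2), summing to 1), \code{counts} (prob * number of sites),
#'   \code{n}, \code{nSitesUsed}, \code{iterations}.
#' @export
estimateFoldedSfs <- function(saf, tol = 1e-6, maxIter = 500,
                              onlyData = TRUE) {
  stopifnot(inherits(saf, "safLik"))
  fold <- .foldSaf(saf$saf, saf$n)
  if (onlyData) fold <- fold[saf$hasData, , drop = FALSE]
  Ls <- nrow(fold)
  if (Ls == 0) stop("no sites with data; cannot estimate an SFS")
  if (Ls < 100)
    warning("only ", Ls, " sites; the SFS estimate will be noisy")
  K <- ncol(fold)
  phi <- rep(1 / K, K)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- fold * matrix(phi, Ls, K, byrow = TRUE)
    w <- w / pmax(rowSums(w), 1e-300)
    phiNew <- colMeans(w)
    delta <- max(abs(phiNew - phi))
    phi <- phiNew
    if (delta < tol || iter >= maxIter) break
  }
  structure(list(prob = phi, counts = phi * Ls, n = saf$n,
                 nSitesUsed = Ls, iterations = iter),
            class = "foldedSfs")
}

#' Per-site posterior expectations of pi and Watterson-theta contributions
#'
#' With the estimated folded SFS as an empirical-Bayes prior, the posterior
#' over the minor-allele count j at each site is proportional to
#' \code{phi_j * SAF_fold(j)}. The per-site nucleotide-diversity
#' contribution uses the pairwise-difference weight \code{j (n-j) /
#' choose(n, 2)} (symmetric under folding), and the Watterson contribution
#' is \code{P(segregating) / a1} with \code{a1 = sum_{i<n} 1/i}.
#'
#' @param saf a \code{"safLik"} from [computeSaf()].
#' @param sfsPrior a \code{"foldedSfs"} from [estimateFoldedSfs()].
#' @param onlyData restrict to sites with at least one read (default TRUE).
#' @return data.frame of class \code{"thetaTrack"}: scaffold, position, pi,
#'   thetaW (posterior expected per-site contributions, both >= 0), with the
#'   chromosome count in \code{attr(, "n")}.
#' @export
perSiteThetas <- function(saf, sfsPrior, onlyData = TRUE) {
  stopifnot(inherits(saf, "safLik"), inherits(sfsPrior, "foldedSfs"))
  n <- saf$n
  half <- n %/% 2L
  if (length(sfsPrior$prob) != half + 1L)
    stop("SFS prior length ", length(sfsPrior$prob),
         " does not match folded SAF classes ", half + 1L)
  fold <- .foldSaf(saf$saf, n)
  keep <- if (onlyData) saf$hasData else rep(TRUE, nrow(fold))
  fold <- fold[keep, , drop = FALSE]
  Ls <- nrow(fold)
  post <- fold * matrix(sfsPrior$prob, Ls, half + 1L, byrow = TRUE)
  post <- post / pmax(rowSums(post), 1e-300)
  j <- 0:half
  wPi <- j * (n - j) / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1L))
  wTh <- as.numeric(j >= 1L) / a1
  out <- data.frame(scaffold = saf$sites$scaffold[keep],
                    position = saf$sites$position[keep],
                    pi = as.numeric(post %*% wPi),
                    thetaW = as.numeric(post %*% wTh),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  class(out) <- c("thetaTrack", "data.frame")
  out
}

#' Tajima's D normalizing constants
#'
#' The standard constants for a sample of n chromosomes: \code{a1 = sum 1/i}
#' and \code{a2 = sum 1/i^2} over i = 1..n-1, \code{b1 = (n+1)/(3(n-1))},
#' \code{b2 = 2(n^2+n+3)/(9n(n-1))}, \code{c1 = b1 - 1/a1}, \code{c2 = b2 -
#' (n+2)/(a1 n) + a2/a1^2}, \code{e1 = c1/a1}, \code{e2 = c2/(a1^2 + a2)}.
#'
#' @param n chromosome count, >= 4.
#' @return named list (a1, a2, b1, b2, c1, c2, e1, e2).
#' @export
tajimaConstants <- function(n) {
  if (n < 4) stop("Tajima's D needs n >= 4 chromosomes")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D in fixed genomic windows
#'
#' Scaffolds are partitioned into non-overlapping half-open windows of
#' \code{windowBp} base pairs (0-based [start, end)). Per window the pi and
#' Watterson contributions are summed (S_pi, S_theta), the implied
#' segregating-site count is \code{S = a1 * S_theta}, and \code{D = (S_pi -
#' S_theta) / sqrt(e1 S + e2 S (S-1))}. Windows with no data sites or S = 0
#' emit no value; a non-positive variance term skips the window with a
#' message.
#'
#' @param track a \code{"thetaTrack"} from [perSiteThetas()].
#' @param windowBp window (= step) size in bp, default 50000.
#' @param stepBp step size; only non-overlapping windows are supported, so
#'   it must equal \code{windowBp}.
#' @return list(\code{windows} data.frame(scaffold, start, end, nSites,
#'   sPi, sTheta, D), \code{meanD} mean over emitted windows).
#' @export
windowedTajima <- function(track, windowBp = 50000, stepBp = windowBp) {
  stopifnot(inherits(track, "thetaTrack"))
  if (stepBp != windowBp)
    stop("only non-overlapping windows (stepBp == windowBp) are supported")
  n <- attr(track, "n")
  cst <- tajimaConstants(n)
  blk <- (track$position - 1L) %/% windowBp
  key <- paste(track$scaffold, blk, sep = "\r")
  sPi <- tapply(track$pi, key, sum)
  sTh <- tapply(track$thetaW, key, sum)
  cnt <- tapply(track$pi, key, length)
  parts <- do.call(rbind, strsplit(names(sPi), "\r", fixed = TRUE))
  start <- as.integer(parts[, 2]) * windowBp
  S <- cst$a1 * sTh
  varTerm <- cst$e1 * S + cst$e2 * S * (S - 1)
  ok <- S > 0 & varTerm > 0
  if (any(S > 0 & varTerm <= 0))
    message("windowedTajima: skipped ", sum(S > 0 & varTerm <= 0),
            " window(s) with non-positive variance term")
  D <- rep(NA_real_, length(S))
  D[ok] <- (sPi[ok] - sTh[ok]) / sqrt(varTerm[ok])
  windows <- data.frame(scaffold = parts[, 1], start = start,
                        end = start + windowBp,
                        nSites = as.integer(cnt),
                        sPi = as.numeric(sPi), sTheta = as.numeric(sTh),
                        D = D, stringsAsFactors = FALSE)
  windows <- windows[ok, , drop = FALSE]
  windows <- windows[order(windows$scaffold, windows$start), ]
  rownames(windows) <- NULL
  list(windows = windows,
       meanD = if (nrow(windows)) mean(windows$D) else NA_real_)
}

#' Per-population diversity summary
#'
#' Runs the whole empirical-Bayes chain for each population: SAF, folded SFS
#' by EM, per-site theta contributions, and windowed Tajima's D. Per-site
#' rates are sites-weighted means -- total contribution over the number of
#' sites with data (variant and invariant alike), so the denominator is not
#' biased by SNP-panel filtering; run this on a set that has not been
#' MAF-filtered.
#'
#' @param gl a [GenotypeLikelihoodSet-class] covering all individuals.
#' @param samples sample table with \code{sample_id} and \code{population}.
#' @param windowBp Tajima window size, default 50000.
#' @return data.frame, one row per population: population, nInd, nSites,
#'   pi, thetaW, meanTajimaD, nWindows.
#' @export
diversitySummary <- function(gl, samples, windowBp = 50000) {
  pops <- unique(samples$population)
  rows <- lapply(pops, function(pp) {
    ids <- samples$sample_id[samples$population == pp]
    sub <- gl[, colnames(gl) %in% ids]
    saf <- computeSaf(sub)
    sfs <- suppressWarnings(estimateFoldedSfs(saf))
    track <- perSiteThetas(saf, sfs)
    wt <- windowedTajima(track, windowBp)
    data.frame(population = pp, nInd = nSamples(sub),
               nSites = nrow(track),
               pi = sum(track$pi) / nrow(track),
               thetaW = sum(track$thetaW) / nrow(track),
               meanTajimaD = wt$meanD, nWindows = nrow(wt$windows),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
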
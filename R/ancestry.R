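## Hierarchical Bayesian admixture on genotype likelihoods: k-means + LDA
## initialization of ancestry coefficients, Gibbs sampling (Rcpp) of
## genotypes, copy ancestries, cluster frequencies and q, DIC over k.

# Posterior-mean dosage under a flat genotype prior: normalize the
# likelihood triple and take 1*P(het) + 2*P(hom-alt). N x L (individuals
# as rows, ready for PCA).
naiveDosage <- function(gl) {
  g0 <- SummarizedExperiment::assay(gl, "glHomRef")
  g1 <- SummarizedExperiment::assay(gl, "glHet")
  g2 <- SummarizedExperiment::assay(gl, "glHomAlt")
  tot <- g0 + g1 + g2
  t((g1 + 2 * g2) / tot)
}

#' Initialize ancestry coefficients from k-means + LDA on PC scores
#'
#' Computes naive flat-prior dosages, takes principal component scores,
#' clusters individuals with k-means (k clusters), then fits a linear
#' discriminant analysis to the k-means labels; the per-individual LDA class
#' posterior probabilities, floored at 0.001 and renormalized, are the
#' initial ancestry matrix. This speeds stabilization of the MCMC chains.
#'
#' @param gl a filtered [GenotypeLikelihoodSet-class].
#' @param k number of clusters (1 <= k <= N; k = 1 returns a column of 1s).
#' @param seed integer seed for the k-means restarts.
#' @return N x k matrix of initial ancestry proportions, rows summing to 1.
#' @export
initAncestry <- function(gl, k, seed = 1) {
  N <- nSamples(gl)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k > N) stop("k = ", k, " exceeds the number of individuals (", N, ")")
  if (k == 1L) return(matrix(1, N, 1))
  dos <- naiveDosage(gl)
  pc <- prcomp(dos, center = TRUE, scale. = FALSE)
  nPc <- min(max(k, 2L), 5L, ncol(pc$x))
  sc <- pc$x[, seq_len(nPc), drop = FALSE]
  withSeed(seed, {
    km <- kmeans(sc, centers = k, nstart = 10)
    qInit <- tryCatch({
      ld <- MASS::lda(sc, grouping = factor(km$cluster, levels = seq_len(k)))
      post <- predict(ld, sc)$posterior
      full <- matrix(0, N, k)
      full[, as.integer(colnames(post))] <- post
      full
    }, error = function(e) {
      # degenerate geometry (tiny or collinear clusters): fall back to
      # one-hot k-means assignments
      oh <- matrix(0, N, k)
      oh[cbind(seq_len(N), km$cluster)] <- 1
      oh
    })
    qInit <- pmax(qInit, 0.001)
    qInit / rowSums(qInit)
  })
}

# Greedy label alignment: permutation of rows of p2 minimizing mean |p1-p2|
# row-by-row (smallest cost pair first). Returns the permutation vector.
.alignLabels <- function(p1, p2) {
  k <- nrow(p1)
  cost <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k))
    cost[a, b] <- mean(abs(p1[a, ] - p2[b, ]))
  perm <- integer(k)
  free_a <- seq_len(k); free_b <- seq_len(k)
  while (length(free_a)) {
    sub <- cost[free_a, free_b, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    perm[free_a[ij[1]]] <- free_b[ij[2]]
    free_a <- free_a[-ij[1]]; free_b <- free_b[-ij[2]]
  }
  perm
}

# Deviance (-2 log marginal likelihood, genotypes summed out) at given q, p.
.devianceAt <- function(gl, q, p) {
  g0 <- SummarizedExperiment::assay(gl, "glHomRef")
  g1 <- SummarizedExperiment::assay(gl, "glHet")
  g2 <- SummarizedExperiment::assay(gl, "glHomAlt")
  m <- t(q %*% p)                      # L x N
  tot <- g0 * (1 - m)^2 + g1 * 2 * m * (1 - m) + g2 * m^2
  -2 * sum(log(pmax(tot, 1e-300)))
}

#' Fit the admixture model by Gibbs sampling
#'
#' Each of the two allele copies of individual i at locus l carries an
#' ancestry z ~ Categorical(q_i) and an allele ~ Bernoulli(p_zl); the data
#' enter through the genotype likelihoods, so genotype uncertainty is
#' propagated rather than collapsed to hard calls. Priors are uniform
#' (Dirichlet(1) on each q_i, Beta(1,1) on each p_kl). Replicate chains are
#' initialized from [initAncestry()], label switching across chains is
#' resolved by greedy alignment of the cluster frequency vectors to the
#' first chain, and posterior means are averaged over aligned chains.
#' The DIC is \code{Dbar + pD} with \code{pD = Dbar - D(posterior mean)} and
#' the deviance marginalizes genotypes.
#'
#' Defaults follow the chain design of range-wide entropy-style analyses:
#' 40,000 steps after a 10,000-step burn-in, keeping one step in ten, five
#' replicate chains. Smaller studies (and the package tests) use shortened
#' chains.
#'
#' @param gl a filtered [GenotypeLikelihoodSet-class].
#' @param k number of ancestral clusters (>= 1).
#' @param nSteps,burnIn,thin,nChains MCMC settings; \code{burnIn} counts
#'   toward \code{nSteps}, samples are retained every \code{thin} steps
#'   after it.
#' @param seed integer seed; chain c uses \code{seed + c}.
#' @return an [AncestryFit-class].
#' @export
gibbsAdmixture <- function(gl, k, nSteps = 40000L, burnIn = 10000L,
                           thin = 10L, nChains = 5L, seed = 1) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  stopifnot(burnIn < nSteps, thin >= 1, nChains >= 1)
  N <- nSamples(gl); L <- nSites(gl)
  g0 <- SummarizedExperiment::assay(gl, "glHomRef")
  g1 <- SummarizedExperiment::assay(gl, "glHet")
  g2 <- SummarizedExperiment::assay(gl, "glHomAlt")
  dosN <- naiveDosage(gl)                # N x L
  chains <- vector("list", nChains)
  for (ch in seq_len(nChains)) {
    chains[[ch]] <- withSeed(seed + ch, {
      qInit <- initAncestry(gl, k, seed = seed + ch)
      wts <- pmax(colSums(qInit), 1e-9)
      pInit <- (t(qInit) %*% dosN / 2) / wts
      pInit <- pmin(pmax(pInit, 0.01), 0.99)
      .gibbsAdmixtureCpp(g0, g1, g2, qInit, pInit,
                         as.integer(nSteps), as.integer(burnIn),
                         as.integer(thin))
    })
  }
  # align labels across chains to chain 1, then average
  ref <- chains[[1]]
  qAcc <- ref$q; pAcc <- ref$p
  gp0 <- ref$gpost0; gp1 <- ref$gpost1; gp2 <- ref$gpost2
  if (nChains > 1) for (ch in 2:nChains) {
    cc <- chains[[ch]]
    perm <- .alignLabels(ref$p, cc$p)
    qAcc <- qAcc + cc$q[, perm, drop = FALSE]
    pAcc <- pAcc + cc$p[perm, , drop = FALSE]
    gp0 <- gp0 + cc$gpost0; gp1 <- gp1 + cc$gpost1; gp2 <- gp2 + cc$gpost2
  }
  q <- qAcc / nChains; p <- pAcc / nChains
  q <- q / rowSums(q)
  gp0 <- gp0 / nChains; gp1 <- gp1 / nChains; gp2 <- gp2 / nChains
  devs <- lapply(chains, `[[`, "deviance")
  dBar <- mean(unlist(devs))
  dHat <- .devianceAt(gl, q, p)
  pD <- dBar - dHat
  if (pD < 0)
    warning("negative effective parameter count (pD = ", signif(pD, 4),
            "); chains may disagree or be too short")
  gpost <- array(c(t(gp0), t(gp1), t(gp2)), c(N, L, 3))
  dosage <- t(gp1 + 2 * gp2)
  rownames(q) <- sampleIds(gl); rownames(dosage) <- sampleIds(gl)
  new("AncestryFit", k = k, q = q, p = p, genotypePosterior = gpost,
      dosage = dosage, dic = dBar + pD, pD = pD, devianceBar = dBar,
      devianceAtMean = dHat, chainDeviance = devs,
      settings = list(nSteps = nSteps, burnIn = burnIn, thin = thin,
                      nChains = nChains, seed = seed))
}

#' Deviance Information Criterion from retained deviance samples
#'
#' \code{DIC = Dbar + pD} with \code{pD = Dbar - D(theta_bar)}: posterior
#' mean deviance plus the effective number of parameters. At least 30
#' retained samples are required for a stable mean.
#'
#' @param devianceSamples numeric vector (or list of per-chain vectors) of
#'   retained deviance values.
#' @param devianceAtMean deviance evaluated at the posterior mean of (q, p).
#' @return list(dic, pD, devianceBar). Negative pD triggers a warning, not
#'   an error.
#' @export
computeDic <- function(devianceSamples, devianceAtMean) {
  d <- unlist(devianceSamples)
  if (length(d) < 30)
    stop("need at least 30 retained deviance samples, got ", length(d))
  dBar <- mean(d)
  pD <- dBar - devianceAtMean
  if (pD < 0)
    warning("negative effective parameter count (pD = ", signif(pD, 4), ")")
  list(dic = dBar + pD, pD = pD, devianceBar = dBar)
}

#' Scan cluster counts and select k by DIC
#'
#' Fits [gibbsAdmixture()] for each k in \code{kRange} and returns the DIC
#' table with the minimizer; exact ties go to the smallest k (and are
#' messaged).
#'
#' @param gl a filtered [GenotypeLikelihoodSet-class].
#' @param kRange integer vector of cluster counts to scan (default 2:8).
#' @param ... passed to [gibbsAdmixture()] (chain settings, seed).
#' @return list(\code{bestK}, \code{table} data.frame(k, dic, pD),
#'   \code{fits} named list of AncestryFit objects).
#' @export
selectK <- function(gl, kRange = 2:8, ...) {
  kRange <- sort(unique(as.integer(kRange)))
  fits <- lapply(kRange, function(k) gibbsAdmixture(gl, k, ...))
  names(fits) <- paste0("k", kRange)
  tab <- data.frame(k = kRange,
                    dic = vapply(fits, function(f) f@dic, 0),
                    pD = vapply(fits, function(f) f@pD, 0))
  best <- tab$k[which.min(tab$dic)]
  if (sum(tab$dic == min(tab$dic)) > 1)
    message("selectK: DIC tie; returning the smallest tied k")
  list(bestK = best, table = tab, fits = fits)
}
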
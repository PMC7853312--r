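## Synthetic-data generators. These emulate the statistical structure the
## downstream analyses assume -- Balding-Nichols population divergence,
## Dirichlet admixture, HWE genotypes, Poisson read depth with a binomial
## base-error read model -- with known truth, so every stage is testable
## without raw sequencing data. They are not coalescent simulators: no
## linkage, recombination or demographic history.

# Draw positions for `total` sites spread across scaffolds, unique within
# scaffold, sorted. Returns data.frame(scaffold, position).
.drawSitePositions <- function(nScaffolds, scaffoldLength, total) {
  per <- rep(total %/% nScaffolds, nScaffolds)
  extra <- total %% nScaffolds
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  if (any(per > scaffoldLength))
    stop("scaffold_length ", scaffoldLength, " bp cannot host ",
         max(per), " distinct site positions")
  scaf <- sprintf("scaffold_%02d", seq_len(nScaffolds))
  do.call(rbind, lapply(seq_len(nScaffolds), function(s) {
    if (per[s] == 0L) return(NULL)
    data.frame(scaffold = scaf[s],
               position = sort(sample.int(scaffoldLength, per[s])),
               stringsAsFactors = FALSE)
  }))
}

# Read-level genotype likelihoods for true genotypes g (0/1/2) under the
# binomial error model: alt reads r ~ Binom(d, c(eps, 1/2, 1-eps)[g+1]).
# Returns list(gl = L x N x 3 array, depth = L x N, altReads = L x N).
.readLikelihoods <- function(g, meanDepth, errorRate) {
  L <- nrow(g); N <- ncol(g)
  d <- matrix(rpois(L * N, meanDepth), L, N)
  eAlt <- c(errorRate, 0.5, 1 - errorRate)
  r <- matrix(rbinom(L * N, d, eAlt[g + 1L]), L, N)
  gl <- array(NA_real_, c(L, N, 3))
  for (gg in 0:2) gl[, , gg + 1L] <- dbinom(r, d, eAlt[gg + 1L])
  # depth 0: dbinom(0, 0, p) = 1 for all genotypes, flat by construction
  list(gl = gl, depth = d, altReads = r)
}

#' Simulate a structured metapopulation with genotype likelihoods
#'
#' Generates a [GenotypeLikelihoodSet-class] plus sample metadata and a
#' ground-truth record under a Balding-Nichols divergence model: ancestral
#' allele frequencies are Beta-distributed (truncated to (0.02, 0.98) to
#' avoid degenerate fixed loci), each source population draws its frequency
#' from \code{Beta(pi(1-F)/F, (1-pi)(1-F)/F)} around the ancestral value,
#' individual ancestries are Dirichlet (or pure when \code{admixtureAlpha =
#' 0}), genotypes are binomial in the ancestry-mixed frequency, and reads
#' follow a Poisson-depth binomial-error model from which genotype
#' likelihoods are computed. Invariant (monomorphic) covered sites are
#' emitted alongside SNPs because per-site diversity denominators need them.
#'
#' Defaults mirror a range-wide pika-style sampling design: four
#' differentiated clusters totalling 171 individuals at mean depth 6.2x.
#'
#' @param nPopulations number of source populations (clusters) K.
#' @param samplesPerPopulation integer vector of length K.
#' @param nScaffolds,scaffoldLength genome layout for site placement.
#' @param nVariantSites number of SNPs to simulate.
#' @param fstPerPopulation per-population divergence F, each strictly in (0,1).
#' @param admixtureAlpha Dirichlet concentration for individual ancestries;
#'   0 gives pure ancestry in the home population.
#' @param meanDepth Poisson mean read depth per site per individual.
#' @param errorRate per-base error in [0, 0.5).
#' @param ancestralFreqBeta two Beta shape parameters for ancestral
#'   frequencies.
#' @param invariantFraction fraction of emitted positions that are
#'   monomorphic (default 0.9).
#' @param seed integer seed; the simulation is deterministic given it.
#' @return list with elements \code{gl} (GenotypeLikelihoodSet over all
#'   emitted sites, invariant + variant), \code{samples} (data.frame:
#'   sample_id, population, latitude, longitude, elevation), and
#'   \code{truth} (list: \code{q} N x K, \code{p} K x L cluster frequencies
#'   over all sites, \code{genotypes} N x L dosages in 0/1/2, \code{variant}
#'   logical per site).
#' @examples
#' sim <- simulateMetapopulation(nPopulations = 2,
#'   samplesPerPopulation = c(5, 5), nVariantSites = 50,
#'   invariantFraction = 0, meanDepth = 20, seed = 1)
#' sim$gl
#' @export
simulateMetapopulation <- function(nPopulations = 4,
                                   samplesPerPopulation = c(35, 21, 28, 87),
                                   nScaffolds = 10,
                                   scaffoldLength = 1e6,
                                   nVariantSites = 1000,
                                   fstPerPopulation = rep(0.3, nPopulations),
                                   admixtureAlpha = 0,
                                   meanDepth = 6.2,
                                   errorRate = 0.005,
                                   ancestralFreqBeta = c(0.8, 0.8),
                                   invariantFraction = 0.9,
                                   seed = 1) {
  K <- as.integer(nPopulations)
  stopifnot(length(samplesPerPopulation) == K,
            length(fstPerPopulation) == K,
            length(ancestralFreqBeta) == 2)
  if (sum(samplesPerPopulation) == 0) stop("zero total samples")
  if (any(fstPerPopulation <= 0 | fstPerPopulation >= 1))
    stop("all Fst values must lie strictly in (0, 1)")
  if (meanDepth <= 0) stop("mean_depth must be > 0")
  if (errorRate < 0 || errorRate >= 0.5) stop("error_rate must be in [0, 0.5)")
  if (admixtureAlpha < 0) stop("admixture_alpha must be >= 0")
  if (invariantFraction < 0 || invariantFraction >= 1)
    stop("invariantFraction must be in [0, 1)")
  N <- sum(samplesPerPopulation)
  Lv <- as.integer(nVariantSites)
  Li <- as.integer(round(Lv * invariantFraction / (1 - invariantFraction)))
  L <- Lv + Li
  withSeed(seed, {
    siteDf <- .drawSitePositions(nScaffolds, scaffoldLength, L)
    variant <- rep(FALSE, L)
    variant[sample.int(L, Lv)] <- TRUE
    # ancestral frequencies: truncated Beta for SNPs, 0 for invariant sites
    piAnc <- numeric(L)
    nv <- sum(variant)
    repeat_draw <- function(n) {
      x <- rbeta(n, ancestralFreqBeta[1], ancestralFreqBeta[2])
      bad <- x <= 0.02 | x >= 0.98
      while (any(bad)) {
        x[bad] <- rbeta(sum(bad), ancestralFreqBeta[1], ancestralFreqBeta[2])
        bad <- x <= 0.02 | x >= 0.98
      }
      x
    }
    piAnc[variant] <- repeat_draw(nv)
    # Balding-Nichols population frequencies
    p <- matrix(0, K, L)
    for (k in seq_len(K)) {
      Fk <- fstPerPopulation[k]
      p[k, variant] <- rbeta(nv, piAnc[variant] * (1 - Fk) / Fk,
                             (1 - piAnc[variant]) * (1 - Fk) / Fk)
    }
    # individual ancestries
    popOf <- rep(seq_len(K), samplesPerPopulation)
    if (admixtureAlpha == 0) {
      q <- matrix(0, N, K)
      q[cbind(seq_len(N), popOf)] <- 1
    } else {
      g <- matrix(rgamma(N * K, shape = admixtureAlpha), N, K)
      # home population gets an extra unit of concentration so the label
      # still means something at small alpha
      g[cbind(seq_len(N), popOf)] <- g[cbind(seq_len(N), popOf)] +
        rgamma(N, shape = 1)
      q <- g / rowSums(g)
    }
    # genotypes: Binomial(2, sum_k q_ik p_kl), computed sites x samples
    mix <- t(q %*% p)                      # L x N
    geno <- matrix(rbinom(L * N, 2L, mix), L, N)
    rl <- .readLikelihoods(geno, meanDepth, errorRate)
    popNames <- sprintf("pop_%02d", seq_len(K))
    ids <- sprintf("%s_ind%03d", popNames[popOf], seq_len(N))
    gl <- GenotypeLikelihoodSet(rl$gl, rl$depth,
                                scaffold = siteDf$scaffold,
                                position = siteDf$position,
                                ref = rep("A", L), alt = rep("G", L),
                                sampleIds = ids)
    # population layout along a simple SW-NE transect (artifact geography)
    lat0 <- seq(38, 45, length.out = K)
    lon0 <- seq(-119, -106, length.out = K)
    ele0 <- seq(2200, 3400, length.out = K)
    samples <- data.frame(sample_id = ids,
                          population = popNames[popOf],
                          latitude = lat0[popOf],
                          longitude = lon0[popOf],
                          elevation = ele0[popOf],
                          stringsAsFactors = FALSE)
    list(gl = gl, samples = samples,
         truth = list(q = q, p = p, genotypes = t(geno), variant = variant))
  })
}

#' Simulate one population's sites from a chosen site-frequency spectrum
#'
#' Draws segregating sites whose minor/derived allele counts follow an
#' arbitrary unfolded SFS over counts 1..(n-1) (default: the neutral
#' equilibrium expectation proportional to 1/j), assigns the alleles to
#' chromosomes at random, and simulates reads under the same Poisson-depth
#' binomial-error model as [simulateMetapopulation()]. Useful for testing
#' diversity estimators: depleting rare classes pushes Tajima's D positive,
#' inflating singletons pushes it negative.
#'
#' @param nInd number of diploid individuals.
#' @param nVariantSites number of segregating sites.
#' @param sfsWeights positive weights over allele counts 1..(2*nInd - 1);
#'   default proportional to 1/j (neutral equilibrium).
#' @param invariantFraction fraction of emitted positions monomorphic.
#' @param meanDepth,errorRate read model parameters.
#' @param nScaffolds,scaffoldLength genome layout.
#' @param seed integer seed.
#' @return list(\code{gl} GenotypeLikelihoodSet, \code{genotypes} true dosage
#'   matrix sites x individuals, \code{alleleCount} true alt-allele count per
#'   site).
#' @export
simulateSfsSites <- function(nInd, nVariantSites,
                             sfsWeights = NULL,
                             invariantFraction = 0.9,
                             meanDepth = 6.2, errorRate = 0.005,
                             nScaffolds = 5, scaffoldLength = 1e6,
                             seed = 1) {
  n <- 2L * as.integer(nInd)
  if (nInd < 2) stop("need at least 2 individuals")
  if (is.null(sfsWeights)) sfsWeights <- 1 / seq_len(n - 1L)
  stopifnot(length(sfsWeights) == n - 1L, all(sfsWeights >= 0),
            sum(sfsWeights) > 0)
  Lv <- as.integer(nVariantSites)
  Li <- as.integer(round(Lv * invariantFraction / (1 - invariantFraction)))
  L <- Lv + Li
  withSeed(seed, {
    siteDf <- .drawSitePositions(nScaffolds, scaffoldLength, L)
    variant <- rep(FALSE, L)
    variant[sample.int(L, Lv)] <- TRUE
    j <- integer(L)
    j[variant] <- sample.int(n - 1L, Lv, replace = TRUE,
                             prob = sfsWeights / sum(sfsWeights))
    geno <- matrix(0L, L, nInd)
    idx <- which(variant)
    for (s in idx) {
      carriers <- sample.int(n, j[s])            # chromosomes 1..n
      tab <- tabulate((carriers - 1L) %/% 2L + 1L, nbins = nInd)
      geno[s, ] <- as.integer(tab)
    }
    rl <- .readLikelihoods(geno, meanDepth, errorRate)
    ids <- sprintf("ind%03d", seq_len(nInd))
    gl <- GenotypeLikelihoodSet(rl$gl, rl$depth,
                                scaffold = siteDf$scaffold,
                                position = siteDf$position,
                                ref = rep("A", L), alt = rep("G", L),
                                sampleIds = ids)
    list(gl = gl, genotypes = geno, alleleCount = j)
  })
}

#' Simulate co-varying geography and climate tables
#'
#' Emits per-site coordinates, elevations and 19 bioclim-style climate
#' variables with a controllable two-gradient correlation structure: the
#' eleven temperature-block variables (bio1..bio11) decrease linearly with
#' elevation at the given lapse rate, and the eight precipitation/seasonality
#' variables (bio12..bio19) follow a single smooth spatial gradient, each
#' block plus independent Gaussian noise. With little noise the climate PCA
#' therefore concentrates variance on two components, as bioclim layers do in
#' practice.
#'
#' @param nSites number of sampling localities (>= 3; climate PCA is
#'   undefined below that).
#' @param elevationRange numeric length-2, metres.
#' @param tempLapseRate temperature decrease per km of elevation (default
#'   6.5, the standard environmental lapse rate).
#' @param precipSpatialScale km scale of the precipitation gradient.
#' @param noiseSd per-variable noise, as a fraction of each variable's
#'   signal amplitude.
#' @param seed integer seed.
#' @return list(\code{samples} data.frame population/latitude/longitude/
#'   elevation, \code{climate} data.frame population + bio1..bio19).
#' @export
simulateClimateGeography <- function(nSites = 11,
                                     elevationRange = c(1800, 3700),
                                     tempLapseRate = 6.5,
                                     precipSpatialScale = 300,
                                     noiseSd = 0.2,
                                     seed = 1) {
  if (nSites < 3) stop("n_sites must be >= 3 (climate PCA undefined below)")
  if (noiseSd < 0) stop("noise_sd must be >= 0")
  withSeed(seed, {
    lat <- runif(nSites, 37.5, 45.5)
    lon <- runif(nSites, -119.5, -105.5)
    elev <- runif(nSites, elevationRange[1], elevationRange[2])
    pops <- sprintf("site_%02d", seq_len(nSites))
    # temperature block: strictly decreasing in elevation (exact when noiseless)
    tsig <- -tempLapseRate * elev / 1000
    tBase <- c(8, 12, 40, 700, 25, -8, 30, 2, 14, 16, -4)     # bio1..bio11
    tAmp <- c(1, 0.6, 2, 40, 1.2, 1.5, 2.5, 1, 1, 1.1, 1.4)
    # precipitation block: one smooth SW-NE spatial gradient
    u <- (lon - mean(lon)) * 111.195 * cos(mean(lat) * pi / 180) +
      (lat - mean(lat)) * 111.195
    psig <- sin(pi * u / (2 * precipSpatialScale))
    pBase <- c(600, 90, 35, 180, 40, 150, 60, 130)            # bio12..bio19
    pAmp <- c(250, 35, 12, 70, 18, 60, 25, 50)
    clim <- matrix(NA_real_, nSites, 19)
    for (v in 1:11) {
      sig <- tAmp[v] * tsig
      clim[, v] <- tBase[v] + sig +
        rnorm(nSites, 0, noiseSd * tAmp[v] * tempLapseRate *
                diff(elevationRange) / 4000)
    }
    for (v in 1:8) {
      sig <- pAmp[v] * psig
      clim[, 11 + v] <- pBase[v] + sig + rnorm(nSites, 0, noiseSd * pAmp[v] / 2)
    }
    colnames(clim) <- paste0("bio", 1:19)
    samples <- data.frame(population = pops, latitude = lat, longitude = lon,
                          elevation = elev, stringsAsFactors = FALSE)
    climate <- data.frame(population = pops, clim, stringsAsFactors = FALSE)
    list(samples = samples, climate = climate)
  })
}
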
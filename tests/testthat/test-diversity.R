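test_that("SAF concentrates on the true allele count for certain genotypes", {
  # 2 diploids, one het in one individual: mass only at j = 1
  gl <- glCertain(matrix(c(1L, 0L), 1, 2), depth = 10L)
  saf <- computeSaf(gl)
  expect_equal(saf$n, 4L)
  expect_equal(which(saf$saf[1, ] > 1e-12), 2L)    # j = 1 (1-based col 2)
  # all hom-ref: mass at j = 0
  gl0 <- glCertain(matrix(0L, 1, 3), depth = 10L)
  saf0 <- computeSaf(gl0)
  expect_equal(which(saf0$saf[1, ] > 1e-12), 1L)
  expect_error(computeSaf(gl[, 1]), "2 individuals")
})

test_that("flat likelihoods give a flat SAF (configuration-count identity)", {
  arr <- array(1, c(1, 3, 3))
  gl <- GenotypeLikelihoodSet(arr, matrix(0L, 1, 3), "sc", 10L, "A", "G",
                              c("a", "b", "c"))
  saf <- computeSaf(gl)
  # sum over genotype configs of prod C(2, g_i) at total j is C(6, j):
  # dividing by C(n, j) flattens the SAF exactly
  expect_equal(as.numeric(saf$saf[1, ]), rep(1, 7))
})

test_that("DP SAF equals brute-force enumeration over genotype configurations", {
  set.seed(101)
  for (nInd in 2:4) {
    L <- 50
    geno <- matrix(rbinom(L * nInd, 2, runif(L)), L, nInd)
    gl <- glFromGenotypes(geno, depth = matrix(rpois(L * nInd, 3), L, nInd))
    saf <- computeSaf(gl)
    arr <- glArray(gl)
    for (l in seq_len(L)) {
      bf <- safBruteForce(cbind(arr[l, , 1], arr[l, , 2], arr[l, , 3]))
      bf <- bf / max(bf)
      expect_equal(saf$saf[l, ], bf, tolerance = 1e-10)
    }
  }
})

test_that("certainty limit: folded SFS equals the genotype-count histogram and pi the pairwise difference", {
  s <- simulateSfsSites(nInd = 6, nVariantSites = 100,
                        invariantFraction = 0.8, meanDepth = 1000,
                        errorRate = 0.001, seed = 55)
  saf <- computeSaf(s$gl)
  sfs <- estimateFoldedSfs(saf)
  n <- 12
  jTrue <- rowSums(s$genotypes)
  mTrue <- pmin(jTrue, n - jTrue)                     # minor-allele counts
  hist <- tabulate(mTrue + 1L, nbins = n / 2 + 1)
  expect_equal(sfs$counts, hist, tolerance = 1e-6, ignore_attr = TRUE)

  track <- perSiteThetas(saf, sfs)
  piDirect <- mean(jTrue * (n - jTrue) / choose(n, 2))
  expect_equal(sum(track$pi) / nrow(track), piDirect, tolerance = 1e-8)
})

test_that("monomorphic-certain input puts all SFS mass in class 0 and zero thetas", {
  gl <- glCertain(matrix(0L, 200, 4), depth = 10L)
  saf <- computeSaf(gl)
  sfs <- estimateFoldedSfs(saf)
  expect_equal(sfs$prob[1], 1)
  track <- perSiteThetas(saf, sfs)
  expect_equal(max(track$pi), 0)
  expect_equal(max(track$thetaW), 0)
})

test_that("per-site theta contributions match hand computations (n = 4)", {
  # sites: 99 monomorphic + 1 certain singleton among 2 diploids
  geno <- matrix(0L, 100, 2); geno[40, 1] <- 1L
  gl <- glCertain(geno, depth = 50L)
  saf <- computeSaf(gl)
  # fix the prior at the truth to keep the arithmetic exact
  prior <- structure(list(prob = c(0.99, 0.01, 0), n = 4L,
                          nSitesUsed = 100L, iterations = 0L,
                          counts = c(99, 1, 0)), class = "foldedSfs")
  track <- perSiteThetas(saf, prior)
  a1 <- 1 + 1 / 2 + 1 / 3
  expect_equal(track$pi[40], 1 * 3 / 6)
  expect_equal(track$thetaW[40], 1 / a1, tolerance = 1e-12)
  expect_equal(sum(track$pi) / 100, 0.005)
  # a certain doubleton instead: pi contribution 2*2/6, mean over 100 sites
  geno2 <- matrix(0L, 100, 2); geno2[40, 1] <- 2L
  gl2 <- glCertain(geno2, depth = 50L)
  saf2 <- computeSaf(gl2)
  prior2 <- structure(list(prob = c(0.99, 0, 0.01), n = 4L,
                           nSitesUsed = 100L, iterations = 0L,
                           counts = c(99, 0, 1)), class = "foldedSfs")
  track2 <- perSiteThetas(saf2, prior2)
  expect_equal(sum(track2$pi) / 100, (2 * 2 / 6) / 100 * 1)
})

test_that("Tajima constants match closed forms and an independent implementation", {
  cst <- tajimaConstants(4)
  expect_equal(cst$a1, 11 / 6)
  expect_equal(cst$a2, 49 / 36)
  expect_error(tajimaConstants(2), "n >= 4")
  # independent textbook-formula implementation as oracle at n = 10
  n <- 10
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  oracle <- list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
                 e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
  got <- tajimaConstants(10)
  for (nm in names(oracle)) expect_equal(got[[nm]], oracle[[nm]],
                                         tolerance = 1e-12)
})

test_that("windowed Tajima's D matches hand computation for a single singleton window", {
  geno <- matrix(0L, 10, 2); geno[3, 2] <- 1L
  gl <- glCertain(geno, depth = 100L,
                  position = as.integer(seq(1000, 46000, length.out = 10)))
  saf <- computeSaf(gl)
  prior <- structure(list(prob = c(0.9, 0.1, 0), n = 4L, nSitesUsed = 10L,
                          iterations = 0L, counts = NULL),
                     class = "foldedSfs")
  track <- perSiteThetas(saf, prior)
  wt <- windowedTajima(track, windowBp = 50000)
  expect_equal(nrow(wt$windows), 1L)
  cst <- tajimaConstants(4)
  sPi <- 0.5; sTh <- 1 / cst$a1; S <- cst$a1 * sTh   # S = 1
  dHand <- (sPi - sTh) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  expect_equal(wt$windows$D[1], dHand, tolerance = 1e-9)
  expect_equal(wt$meanD, dHand, tolerance = 1e-9)
})

test_that("D = 0 when pi- and Watterson-sums coincide in a window", {
  track <- structure(data.frame(scaffold = "s", position = c(10L, 20L),
                                pi = c(0.3, 0.2), thetaW = c(0.25, 0.25)),
                     class = c("thetaTrack", "data.frame"))
  attr(track, "n") <- 8L
  wt <- windowedTajima(track, windowBp = 50000)
  expect_equal(wt$windows$D[1], 0)
})

test_that("fold symmetry: relabelling ref/alt at every site changes nothing", {
  s <- simulateSfsSites(nInd = 5, nVariantSites = 150,
                        invariantFraction = 0.5, meanDepth = 8, seed = 66)
  gl <- s$gl
  arr <- glArray(gl)
  glSwap <- GenotypeLikelihoodSet(arr[, , 3:1], depths(gl),
                                  siteTable(gl)$scaffold,
                                  siteTable(gl)$position,
                                  siteTable(gl)$alt, siteTable(gl)$ref,
                                  sampleIds(gl))
  saf1 <- computeSaf(gl); saf2 <- computeSaf(glSwap)
  sfs1 <- estimateFoldedSfs(saf1); sfs2 <- estimateFoldedSfs(saf2)
  expect_equal(sfs1$prob, sfs2$prob, tolerance = 1e-9)
  t1 <- perSiteThetas(saf1, sfs1); t2 <- perSiteThetas(saf2, sfs2)
  expect_equal(t1$pi, t2$pi, tolerance = 1e-9)
  expect_equal(t1$thetaW, t2$thetaW, tolerance = 1e-9)
  w1 <- windowedTajima(t1); w2 <- windowedTajima(t2)
  expect_equal(w1$meanD, w2$meanD, tolerance = 1e-9)
})

test_that("SFS shape drives the sign of mean windowed D", {
  n <- 20
  neutral <- 1 / (1:(n - 1))
  noRare <- neutral; noRare[c(1, 2, n - 2, n - 1)] <- 0   # depleted rare
  onlyRare <- numeric(n - 1); onlyRare[c(1, n - 1)] <- 1  # singleton excess
  mk <- function(w, seed) {
    s <- simulateSfsSites(nInd = n / 2, nVariantSites = 400,
                          sfsWeights = w, invariantFraction = 0.8,
                          meanDepth = 1000, errorRate = 0.001, seed = seed)
    saf <- computeSaf(s$gl)
    sfs <- estimateFoldedSfs(saf)
    windowedTajima(perSiteThetas(saf, sfs))$meanD
  }
  expect_gt(mk(noRare, 71), 0)
  expect_lt(mk(onlyRare, 72), 0)
})

test_that("diversity summary runs per population and reports finite values", {
  sim <- simulateMetapopulation(nPopulations = 2,
                                samplesPerPopulation = c(8, 8),
                                nVariantSites = 80, invariantFraction = 0.8,
                                meanDepth = 8, seed = 83,
                                nScaffolds = 3, scaffoldLength = 2e5)
  ds <- suppressWarnings(diversitySummary(sim$gl, sim$samples,
                                          windowBp = 50000))
  expect_equal(nrow(ds), 2L)
  expect_true(all(is.finite(ds$pi)))
  expect_true(all(is.finite(ds$thetaW)))
  expect_true(all(ds$nWindows >= 1))
})
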
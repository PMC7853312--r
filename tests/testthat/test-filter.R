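test_that("completeness requires ceil(threshold * N) covered individuals", {
  # brute-force check of the rule around the 171-sample study design:
  # a site with c covered individuals passes 0.92 iff c >= ceiling(157.32)
  N <- 171
  need <- ceiling(0.92 * N)
  expect_equal(need, 158)
  for (cov in c(150, 157, 158, 165, 171)) {
    geno <- matrix(1L, 1, N)
    dep <- matrix(5L, 1, N)
    if (cov < N) dep[1, seq_len(N - cov)] <- 0L
    arr <- array(1, c(1, N, 3))          # flat everywhere is fine here
    gl <- GenotypeLikelihoodSet(arr, dep, "sc", 10L, "A", "G",
                                sprintf("i%03d", 1:N))
    kept <- nSites(completenessFilter(gl, 0.92))
    expect_equal(kept, as.integer(cov >= 158), info = paste("cov =", cov))
  }
})

test_that("completeness boundary behaviour: threshold 1 removes any zero-depth site", {
  dep <- matrix(3L, 2, 4); dep[2, 1] <- 0L
  a <- array(0, c(2, 4, 3)); a[, , 1] <- 1      # certain hom-ref
  for (g in 2:3) a[2, 1, g] <- 1                # flat at the zero-depth cell
  gl2 <- GenotypeLikelihoodSet(a, dep, rep("scafA", 2), c(10L, 20L),
                               c("A", "A"), c("G", "G"), sprintf("s%03d", 1:4))
  expect_equal(nSites(completenessFilter(gl2, 1.0)), 1L)
  expect_equal(nSites(completenessFilter(gl2, 0.75)), 2L)   # all-covered: identity
})

test_that("EM allele frequency counts certain genotypes and matches truth under noise", {
  # certain (hom-ref, het, hom-alt): f = 3/6 = 0.5; all hom-ref: f = 0
  gl <- glCertain(rbind(c(0L, 1L, 2L), c(0L, 0L, 0L)), depth = 10L)
  f <- estimateAlleleFreqEM(gl)
  expect_equal(as.numeric(f), c(0.5, 0), tolerance = 1e-7)

  # N = 50 at true f = 0.3, depth 20: within 0.07 (1.5x binomial SE)
  set.seed(123)
  geno <- matrix(rbinom(40 * 50, 2, 0.3), 40, 50)
  gln <- glFromGenotypes(geno, depth = 20L)
  fn <- estimateAlleleFreqEM(gln)
  expect_lt(max(abs(fn - rowMeans(geno) / 2)), 0.03)  # EM vs realized counts
  expect_lt(mean(abs(fn - 0.3)), 0.07)                # binomial error budget
  expect_lt(abs(mean(fn) - 0.3), 0.02)

  # symmetry under allele relabelling: f <-> 1 - f
  a <- glArray(gln)
  rev <- a[, , 3:1]
  glr <- GenotypeLikelihoodSet(rev, depths(gln),
                               siteTable(gln)$scaffold,
                               siteTable(gln)$position,
                               rep("G", 40), rep("A", 40), sampleIds(gln))
  expect_equal(as.numeric(estimateAlleleFreqEM(glr)), 1 - as.numeric(fn),
               tolerance = 1e-6)
})

test_that("all-flat sites return frequency 0.5 with a warning", {
  arr <- array(1, c(2, 5, 3))
  gl <- GenotypeLikelihoodSet(arr, matrix(0L, 2, 5), rep("sc", 2),
                              c(1L, 2L), c("A", "A"), c("G", "G"),
                              sprintf("i%d", 1:5))
  expect_warning(f <- estimateAlleleFreqEM(gl), "flat")
  expect_equal(as.numeric(f), c(0.5, 0.5))
  expect_true(all(attr(f, "flat")))
})

test_that("MAF filter keeps the 5% boundary and drops below it, symmetrically", {
  # 20 chromosomes: 1 alt -> f = 0.05 exactly (kept); rows engineered for
  # f = 0.049 and f = 0.96 via explicit frequencies are checked through
  # certain genotype counts
  genoKeep <- matrix(c(1L, rep(0L, 9)), 1, 10)       # f = 0.05
  glk <- glCertain(genoKeep, depth = 10L)
  expect_equal(nSites(mafFilter(glk, 0.05)), 1L)

  genoDrop <- matrix(0L, 1, 10)                       # f = 0
  gld <- glCertain(genoDrop, depth = 10L)
  expect_equal(nSites(mafFilter(gld, 0.05)), 0L)

  genoHigh <- matrix(c(1L, rep(2L, 9)), 1, 10)        # f = 0.95, MAF 0.05
  glh <- glCertain(genoHigh, depth = 10L)
  expect_equal(nSites(mafFilter(glh, 0.05)), 1L)

  genoFixed <- matrix(2L, 1, 10)                      # f = 1, MAF 0
  glf <- glCertain(genoFixed, depth = 10L)
  expect_equal(nSites(mafFilter(glf, 0.05)), 0L)
})

test_that("thinning keeps one site per non-empty 1000-bp block", {
  geno <- matrix(1L, 3, 4)
  gl <- glCertain(geno, depth = 5L, position = c(100L, 600L, 1500L))
  th <- thinSites(gl, 1000, seed = 1)
  st <- siteTable(th)
  expect_equal(nSites(th), 2L)
  expect_true(st$position[1] %in% c(100L, 600L))
  expect_equal(st$position[2], 1500L)

  # one site per block already: identity
  gl1 <- glCertain(matrix(1L, 3, 4), depth = 5L,
                   position = c(100L, 1500L, 2500L))
  expect_equal(siteTable(thinSites(gl1, 1000, seed = 2)), siteTable(gl1))
})

test_that("thinned count equals a brute-force block scan on dense sites", {
  set.seed(7)
  pos <- sort(sample.int(1e6, 10000))
  L <- length(pos)
  geno <- matrix(rbinom(L * 2, 2, 0.5), L, 2)
  gl <- glCertain(geno, depth = 4L, position = pos)
  th <- thinSites(gl, 1000, seed = 3)
  # independent oracle: scan fixed blocks [0,1000), [1000,2000), ...
  expected <- length(unique((pos - 1L) %/% 1000L))
  expect_equal(nSites(th), expected)
  expect_true(all(siteTable(th)$position %in% pos))   # subset of input
  # same seed, same choice
  th2 <- thinSites(gl, 1000, seed = 3)
  expect_identical(siteTable(th2), siteTable(th))
})

test_that("filter report telescopes and tightening thresholds is monotone", {
  sim <- simulateMetapopulation(nPopulations = 2,
                                samplesPerPopulation = c(10, 10),
                                nVariantSites = 300, invariantFraction = 0,
                                meanDepth = 3, seed = 17)
  fp <- filterPanel(sim$gl, completenessMin = 0.8, mafMin = 0.05,
                    thinBlock = 1000, seed = 1)
  rep <- fp$report
  expect_equal(rep$sites_out[-nrow(rep)], rep$sites_in[-1])
  expect_equal(rep$sites_in - rep$sites_removed, rep$sites_out)
  # monotonicity in the thresholds
  n_loose <- nSites(completenessFilter(sim$gl, 0.6))
  n_tight <- nSites(completenessFilter(sim$gl, 0.95))
  expect_lte(n_tight, n_loose)
  m_loose <- nSites(mafFilter(sim$gl, 0.02))
  m_tight <- nSites(mafFilter(sim$gl, 0.10))
  expect_lte(m_tight, m_loose)
})

test_that("filters commute with sample reordering", {
  sim <- simulateMetapopulation(nPopulations = 2,
                                samplesPerPopulation = c(6, 6),
                                nVariantSites = 120, invariantFraction = 0,
                                meanDepth = 3, seed = 23)
  gl <- sim$gl
  perm <- sample(seq_len(nSamples(gl)))
  glp <- gl[, perm]
  expect_equal(siteTable(completenessFilter(gl, 0.8)),
               siteTable(completenessFilter(glp, 0.8)))
  expect_equal(siteTable(mafFilter(gl, 0.05)),
               siteTable(mafFilter(glp, 0.05)))
})
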
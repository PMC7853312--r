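# Shared fixture builders. Oracles used to check package output are written
# here from first principles, independent of the code paths they test.

# Build a GenotypeLikelihoodSet directly from true genotypes with a fixed
# depth matrix and binomial read model (alt-read counts drawn here, not via
# the package generator). geno: sites x individuals in {0,1,2}.
glFromGenotypes <- function(geno, depth, eps = 0.005,
                            scaffold = NULL, position = NULL) {
  L <- nrow(geno); N <- ncol(geno)
  if (length(depth) == 1L) depth <- matrix(depth, L, N)
  eAlt <- c(eps, 0.5, 1 - eps)
  r <- matrix(rbinom(L * N, depth, eAlt[geno + 1L]), L, N)
  arr <- array(NA_real_, c(L, N, 3))
  for (g in 0:2) arr[, , g + 1L] <- dbinom(r, depth, eAlt[g + 1L])
  if (is.null(scaffold)) scaffold <- rep("scafA", L)
  if (is.null(position)) position <- seq_len(L) * 10L
  GenotypeLikelihoodSet(arr, depth, scaffold = scaffold,
                        position = position,
                        ref = rep("A", L), alt = rep("G", L),
                        sampleIds = sprintf("s%03d", seq_len(N)))
}

# Certain-genotype likelihood triples (1 for the true genotype, 0 otherwise).
glCertain <- function(geno, depth = 10L, ...) {
  L <- nrow(geno); N <- ncol(geno)
  arr <- array(0, c(L, N, 3))
  for (g in 0:2) arr[, , g + 1L][geno == g] <- 1
  if (length(depth) == 1L) depth <- matrix(depth, L, N)
  args <- list(...)
  GenotypeLikelihoodSet(arr, depth,
                        scaffold = args$scaffold %||% rep("scafA", L),
                        position = args$position %||% (seq_len(L) * 10L),
                        ref = rep("A", L), alt = rep("G", L),
                        sampleIds = sprintf("s%03d", seq_len(N)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force SAF oracle: enumerate all 3^nInd genotype
# configurations; P(data | j) = sum over configs with total j of
# prod GL_i(g_i) * prod choose(2, g_i) / choose(n, j).
safBruteForce <- function(glTriples) {
  # glTriples: nInd x 3 matrix of likelihoods for ONE site
  nInd <- nrow(glTriples)
  n <- 2L * nInd
  confs <- as.matrix(expand.grid(rep(list(0:2), nInd)))
  out <- numeric(n + 1L)
  w2 <- c(1, 2, 1)
  for (r in seq_len(nrow(confs))) {
    g <- confs[r, ]
    j <- sum(g)
    contrib <- prod(glTriples[cbind(seq_len(nInd), g + 1L)]) * prod(w2[g + 1L])
    out[j + 1L] <- out[j + 1L] + contrib
  }
  out / choose(n, 0:n)
}

# Align a fitted k=2 ancestry matrix to the truth (labels are arbitrary)
# and return the mean absolute error.
qErrorK2 <- function(qFit, qTrue) {
  min(mean(abs(qFit - qTrue)), mean(abs(qFit[, 2:1] - qTrue)))
}
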
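## Landscape genetics: population-level predictor distance matrices
## (haversine geography, elevation, climate-PC distances) and multiple
## regression on distance matrices (MRM) with matrix-permutation inference,
## scanned over all predictor subsets.

.EARTH_RADIUS_KM <- 6371   # conventional mean Earth radius

#' Aggregate samples to population coordinates
#'
#' Population location is the midpoint (mean latitude, mean longitude, mean
#' elevation) of its member samples. A table that already has one row per
#' population passes through unchanged.
#'
#' @param samples data.frame with population, latitude, longitude and
#'   elevation columns.
#' @return data.frame: population, latitude, longitude, elevation; one row
#'   per population, order of first appearance.
#' @export
populationCoordinates <- function(samples) {
  pops <- unique(samples$population)
  out <- do.call(rbind, lapply(pops, function(p) {
    s <- samples[samples$population == p, ]
    data.frame(population = p, latitude = mean(s$latitude),
               longitude = mean(s$longitude),
               elevation = mean(s$elevation), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Haversine geographic distance matrix (km)
#'
#' Great-circle distances between population midpoints on a sphere of
#' radius 6371 km.
#'
#' @param samples sample or population table (see
#'   [populationCoordinates()]).
#' @return symmetric km matrix with zero diagonal, populations as dimnames.
#' @export
haversineMatrix <- function(samples) {
  pc <- populationCoordinates(samples)
  xy <- cbind(pc$longitude, pc$latitude)
  D <- geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_KM * 1000)) / 1000
  dimnames(D) <- list(pc$population, pc$population)
  D
}

#' Elevational distance matrix (m)
#'
#' Absolute difference in (mean) elevation between populations.
#'
#' @inheritParams haversineMatrix
#' @return symmetric matrix in metres.
#' @export
elevationMatrix <- function(samples) {
  pc <- populationCoordinates(samples)
  D <- abs(outer(pc$elevation, pc$elevation, `-`))
  dimnames(D) <- list(pc$population, pc$population)
  D
}

#' PCA of the climate table
#'
#' Centers the 19 climate variables and, by default, scales them to unit
#' variance before the PCA (they mix degrees, millimetres and
#' dimensionless indices); set \code{scale = FALSE} for a covariance PCA.
#' Sign convention as in [runPca()].
#'
#' @param climate data.frame from [readClimateTable()] or
#'   [simulateClimateGeography()].
#' @param scale logical, default TRUE.
#' @return list of class \code{"pikaPca"}: scores (populations x PCs, with
#'   population rownames), proportionVariance, loadings.
#' @export
climatePca <- function(climate, scale = TRUE) {
  if (nrow(climate) < 3) stop("climate PCA needs at least 3 populations")
  vars <- setdiff(names(climate), "population")
  X <- as.matrix(climate[vars])
  if (scale) {
    const <- vars[apply(X, 2, function(v) diff(range(v)) == 0)]
    if (length(const))
      stop("constant climate variable(s) cannot be scaled: ",
           paste(const, collapse = ", "))
  }
  pc <- prcomp(X, center = TRUE, scale. = scale)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(c) {
    j <- which.max(abs(pc$rotation[, c]))
    if (pc$rotation[j, c] < 0) -1 else 1
  }, 0)
  scores <- sweep(pc$x, 2, flip, `*`)
  rownames(scores) <- climate$population
  structure(list(scores = scores,
                 proportionVariance = pc$sdev^2 / sum(pc$sdev^2),
                 loadings = sweep(pc$rotation, 2, flip, `*`)),
            class = "pikaPca")
}

#' Climate distance on one principal component
#'
#' Pairwise absolute difference of the scores on a single climate PC (the
#' "Climate 1" / "Climate 2" predictors).
#'
#' @param scores score matrix from [climatePca()] (or a numeric vector).
#' @param component which PC, default 1.
#' @return symmetric distance matrix.
#' @export
climateDistance <- function(scores, component = 1) {
  v <- if (is.matrix(scores)) scores[, component] else scores
  D <- abs(outer(v, v, `-`))
  nm <- if (is.matrix(scores)) rownames(scores) else names(v)
  dimnames(D) <- list(nm, nm)
  D
}

.lowerVec <- function(M) M[lower.tri(M)]

.checkSquare <- function(M, P, what) {
  if (!is.matrix(M) || nrow(M) != P || ncol(M) != P)
    stop(what, " is not a ", P, " x ", P, " matrix")
  if (max(abs(M - t(M))) > 1e-8) stop(what, " is not symmetric")
}

#' Multiple regression on distance matrices
#'
#' Unfolds the strictly-lower triangles of the response and predictor
#' matrices to vectors of n(n-1)/2 pairwise distances and fits ordinary
#' least squares (with intercept). Significance of R-squared and of each
#' coefficient comes from a permutation test: rows and columns of the
#' response matrix are permuted jointly (a fresh random permutation per
#' iteration), the regression is recomputed, and \code{p = (1 + #(perm stat
#' >= observed)) / (1 + nPerm)} -- for coefficients the statistic is |t|.
#'
#' @param response symmetric distance matrix (e.g. Nei's D from
#'   [neiDistance()]).
#' @param predictors named list of symmetric matrices with the same
#'   population order.
#' @param nPerm number of permutations, default 999 (>= 99 required).
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return list of class \code{"mrmResult"}: coefficients (data.frame:
#'   term, estimate, t, p), r.squared, p.value, nPerm, seed.
#' @export
mrm <- function(response, predictors, nPerm = 999, seed = NULL) {
  if (nPerm < 99) stop("nPerm must be at least 99")
  P <- nrow(response)
  .checkSquare(response, P, "response")
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    stop("predictors must be a named list")
  for (nm in names(predictors)) .checkSquare(predictors[[nm]], P, nm)
  X <- cbind(`(Intercept)` = 1,
             do.call(cbind, lapply(predictors, .lowerVec)))
  y <- .lowerVec(response)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient predictor set; collinear: ",
         paste(drop, collapse = ", "))
  }
  fitStats <- function(yy) {
    fit <- lm.fit(X, yy)
    rss <- sum(fit$residuals^2)
    tss <- sum((yy - mean(yy))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 0
    dfRes <- length(yy) - ncol(X)
    sigma2 <- rss / dfRes
    XtXinv <- chol2inv(qr.R(qr(X)))
    se <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
    tval <- ifelse(se > 0, fit$coefficients / se, Inf * sign(fit$coefficients))
    list(coef = fit$coefficients, t = tval, r2 = r2)
  }
  obs <- fitStats(y)
  withSeed(seed, {
    geR2 <- 0L
    geT <- integer(ncol(X))
    for (b in seq_len(nPerm)) {
      pr <- sample.int(P)
      yp <- .lowerVec(response[pr, pr])
      st <- fitStats(yp)
      geR2 <- geR2 + (st$r2 >= obs$r2 - 1e-12)
      geT <- geT + (abs(st$t) >= abs(obs$t) - 1e-12)
    }
    structure(list(
      coefficients = data.frame(term = colnames(X),
                                estimate = unname(obs$coef),
                                t = unname(obs$t),
                                p = unname((1 + geT) / (1 + nPerm)),
                                stringsAsFactors = FALSE),
      r.squared = obs$r2,
      p.value = (1 + geR2) / (1 + nPerm),
      nPerm = nPerm, seed = seed), class = "mrmResult")
  })
}

#' @export
print.mrmResult <- function(x, ...) {
  cat(sprintf("MRM: R2 = %.3f, P = %.4g (%d permutations)\n",
              x$r.squared, x$p.value, x$nPerm))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Scan all predictor subsets with MRM
#'
#' Fits [mrm()] for every non-empty subset of the named predictors (15
#' models for 4 predictors) and tabulates model label (names joined by
#' " + "), R-squared and permutation P, sorted by R-squared descending.
#'
#' @inheritParams mrm
#' @return list of class \code{"modelScan"}: \code{table}
#'   (data.frame: model, r.squared, p.value), \code{fits} (named list of
#'   mrmResult objects), \code{nPerm}.
#' @export
modelScan <- function(response, predictors, nPerm = 999, seed = NULL) {
  m <- length(predictors)
  stopifnot(m >= 1)
  nms <- names(predictors)
  subsets <- unlist(lapply(seq_len(m), function(sz)
    utils::combn(nms, sz, simplify = FALSE)), recursive = FALSE)
  withSeed(seed, {
    fits <- lapply(subsets, function(ss)
      mrm(response, predictors[ss], nPerm = nPerm, seed = NULL))
  })
  labels <- vapply(subsets, paste, "", collapse = " + ")
  names(fits) <- labels
  tab <- data.frame(model = labels,
                    r.squared = vapply(fits, function(f) f$r.squared, 0),
                    p.value = vapply(fits, function(f) f$p.value, 0),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$r.squared), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, nPerm = nPerm),
            class = "modelScan")
}

#' @export
print.modelScan <- function(x, ...) {
  cat("MRM model scan (", nrow(x$table), " models, ", x$nPerm,
      " permutations)\n", sep = "")
  tab <- x$table
  tab$r.squared <- round(tab$r.squared, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Build the standard predictor set for landscape models
#'
#' Convenience wrapper assembling the four canonical predictor matrices --
#' Geography (haversine km), Elevation (m), Climate 1 and Climate 2
#' (distances on the first two climate PCs) -- in a shared population order.
#'
#' @param samples sample or population table.
#' @param climate climate table (population + 19 variables).
#' @param scaleClimate passed to [climatePca()].
#' @return named list of four matrices, plus the climate PCA as
#'   \code{attr(, "climatePca")}.
#' @export
landscapePredictors <- function(samples, climate, scaleClimate = TRUE) {
  pc <- populationCoordinates(samples)
  climate <- climate[match(pc$population, climate$population), ]
  if (anyNA(climate$population))
    stop("climate table is missing population(s): ",
         paste(setdiff(pc$population, climate$population), collapse = ", "))
  cp <- climatePca(climate, scale = scaleClimate)
  out <- list(Elevation = elevationMatrix(pc),
              Geography = haversineMatrix(pc),
              `Climate 1` = climateDistance(cp$scores, 1),
              `Climate 2` = climateDistance(cp$scores, 2))
  attr(out, "climatePca") <- cp
  out
}
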
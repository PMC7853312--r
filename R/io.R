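## Reading and writing the standard formats: VCF v4.2 with GT/PL/DP (via
## vcfR for parsing), sample metadata CSV, climate CSV. Internal convention:
## VCF positions are 1-based inclusive; all window arithmetic elsewhere uses
## half-open 0-based [start, end) blocks, converted at the boundary.

.parsePL <- function(plChar) {
  # "a,b,c" phred triplets -> 3-col numeric matrix; NA/"." -> NA row
  out <- matrix(NA_real_, length(plChar), 3)
  ok <- !is.na(plChar) & plChar != "." & plChar != ""
  if (any(ok)) {
    sp <- strsplit(plChar[ok], ",", fixed = TRUE)
    bad <- lengths(sp) != 3L
    if (any(bad)) stop("malformed PL field (expected 3 values): ",
                       plChar[ok][bad][1])
    out[ok, ] <- matrix(as.numeric(unlist(sp)), ncol = 3, byrow = TRUE)
  }
  out
}

#' Read a genotype-likelihood VCF
#'
#' Ingests a VCF v4.x carrying per-individual phred-scaled genotype
#' likelihoods (FORMAT/PL, or log10-scaled FORMAT/GL) and read depth
#' (FORMAT/DP) for biallelic SNPs, the shape of file a bcftools-style
#' variant-calling pipeline produces. Phred values are converted by
#' \code{10^(-PL/10)} and rescaled to a per-cell maximum of 1. Records that
#' are not biallelic SNPs are skipped (with a message) or raise an error,
#' per \code{multiallelic}. Cells with missing PL and DP = 0 become flat
#' likelihoods (no reads, no information); missing PL at positive depth is
#' treated as flat with a warning.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param multiallelic "skip" (default) or "error".
#' @return a [GenotypeLikelihoodSet-class]; the number of skipped
#'   non-biallelic records is attached as \code{attr(, "nonBiallelicRemoved")}.
#' @export
readVcfGL <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1,
                                     dimnames = list(NULL, names(fx)))
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  hasPL <- "PL" %in% fmt; hasGL <- "GL" %in% fmt
  if (!hasPL && !hasGL)
    stop("VCF carries neither PL nor GL FORMAT fields; ",
         "genotype likelihoods are required")
  alt <- fx[, "ALT"]; ref <- fx[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  if (any(!biallelic)) {
    if (multiallelic == "error")
      stop(sum(!biallelic), " record(s) are not biallelic SNPs ",
           "(first at line for ", fx[!biallelic, "CHROM"][1], ":",
           fx[!biallelic, "POS"][1], ")")
    message("readVcfGL: skipped ", sum(!biallelic),
            " non-biallelic record(s)")
  }
  keep <- which(biallelic)
  if (!length(keep)) stop("no biallelic SNP records in ", path)
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)[keep, , drop = FALSE]
  dp[is.na(dp)] <- 0
  nm <- if (hasPL) "PL" else "GL"
  plc <- vcfR::extract.gt(vcf, nm)[keep, , drop = FALSE]
  L <- length(keep); N <- ncol(plc)
  tri <- .parsePL(as.vector(plc))
  if (nm == "PL") {
    lik <- 10^(-tri / 10)
  } else {
    lik <- 10^(tri - apply(tri, 1, max))    # GL is log10-likelihood
  }
  miss <- is.na(tri[, 1])
  if (any(miss & as.vector(dp) > 0))
    warning("missing PL at ", sum(miss & as.vector(dp) > 0),
            " cell(s) with positive depth; treated as flat likelihoods")
  lik[miss, ] <- 1
  arr <- array(lik, c(L, N, 3))
  # depth-0 cells are informationless regardless of what was written
  flat <- as.vector(dp) == 0
  for (g in 1:3) { m <- arr[, , g]; m[flat] <- 1; arr[, , g] <- m }
  gls <- GenotypeLikelihoodSet(arr, dp,
                               scaffold = fx[keep, "CHROM"],
                               position = as.integer(fx[keep, "POS"]),
                               ref = ref[keep], alt = alt[keep],
                               sampleIds = colnames(plc))
  attr(gls, "nonBiallelicRemoved") <- sum(!biallelic)
  gls
}

#' Write a GenotypeLikelihoodSet as a VCF v4.2 file
#'
#' Emits plain-text VCF with contig header lines per scaffold and FORMAT
#' fields GT (the most-likely genotype, "./." where depth is 0), PL
#' (phred-scaled, rounded, capped at 9999) and DP.
#'
#' @param gl a [GenotypeLikelihoodSet-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeVcfGL <- function(gl, path) {
  st <- siteTable(gl)
  dp <- depths(gl)
  arr <- glArray(gl)
  L <- nrow(st); N <- ncol(dp)
  # likelihoods are max-normalized per cell, so the smallest phred value is 0
  pl <- pmin(round(-10 * log10(pmax(arr, 1e-300))), 9999)
  m1 <- arr[, , 1]; m2 <- arr[, , 2]; m3 <- arr[, , 3]
  gidx <- ifelse(m1 >= m2 & m1 >= m3, 1L, ifelse(m2 >= m3, 2L, 3L))
  gtStr <- c("0/0", "0/1", "1/1")[gidx]
  gtStr[dp == 0] <- "./."
  cell <- matrix(paste0(gtStr, ":",
                        pl[, , 1], ",", pl[, , 2], ",", pl[, , 3],
                        ":", dp), L, N)
  scafs <- unique(st$scaffold)
  maxPos <- vapply(scafs, function(s) max(st$position[st$scaffold == s]), 0)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pikapop",
           sprintf("##contig=<ID=%s,length=%d>", scafs,
                   as.integer(pmax(maxPos, 1))),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleIds(gl)), collapse = "\t"))
  body <- paste(st$scaffold, st$position, ".", st$ref, st$alt, ".", "PASS",
                ".", "GT:PL:DP",
                apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a per-sample metadata table
#'
#' CSV with headers \code{sample_id, population, latitude, longitude,
#' elevation_m}. Coordinates are validated (latitude in [-90, 90],
#' longitude in [-180, 180]) and sample ids must be unique; violations name
#' the offending row.
#'
#' @param path CSV file.
#' @return data.frame with columns sample_id, population, latitude,
#'   longitude, elevation.
#' @export
readSampleTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "latitude", "longitude", "elevation_m")
  missingCols <- setdiff(need, names(df))
  if (length(missingCols))
    stop("sample table is missing required column(s): ",
         paste(missingCols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1])
  badLat <- which(!is.finite(df$latitude) | abs(df$latitude) > 90)
  if (length(badLat))
    stop("latitude out of range [-90, 90] at row ", badLat[1],
         " (sample ", df$sample_id[badLat[1]], ")")
  badLon <- which(!is.finite(df$longitude) | abs(df$longitude) > 180)
  if (length(badLon))
    stop("longitude out of range [-180, 180] at row ", badLon[1],
         " (sample ", df$sample_id[badLon[1]], ")")
  data.frame(sample_id = as.character(df$sample_id),
             population = as.character(df$population),
             latitude = df$latitude, longitude = df$longitude,
             elevation = df$elevation_m, stringsAsFactors = FALSE)
}

#' Read a per-population climate table
#'
#' CSV with a \code{population} column plus exactly 19 numeric bioclim-style
#' variables, one row per population.
#'
#' @param path CSV file.
#' @return data.frame: population + 19 numeric columns.
#' @export
readClimateTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"population" %in% names(df))
    stop("climate table needs a 'population' column")
  vars <- setdiff(names(df), "population")
  if (length(vars) != 19)
    stop("climate table must carry exactly 19 variable columns, found ",
         length(vars))
  if (anyDuplicated(df$population))
    stop("duplicate population in climate table: ",
         df$population[duplicated(df$population)][1])
  if (!all(vapply(df[vars], is.numeric, TRUE)))
    stop("all 19 climate columns must be numeric")
  df
}

#' Pika study sampling localities
#'
#' The 11-population range-wide pika sampling design shipped with the
#' package (population, sample size, elevation, latitude, longitude, region),
#' and its expansion to a per-sample table with synthesized sample ids.
#'
#' @return \code{pikaPopulations()}: one row per population.
#'   \code{pikaSampleTable()}: one row per individual (171 rows), with the
#'   columns of [readSampleTable()].
#' @export
pikaPopulations <- function() {
  read.csv(system.file("extdata", "pika_populations.csv",
                       package = "pikapop"),
           stringsAsFactors = FALSE)
}

#' @rdname pikaPopulations
#' @export
pikaSampleTable <- function() {
  pp <- pikaPopulations()
  idx <- rep(seq_len(nrow(pp)), pp$n)
  within_i <- sequence(pp$n)
  data.frame(
    sample_id = sprintf("%s_%02d", gsub("[^A-Za-z]", "", pp$population[idx]),
                        within_i),
    population = pp$population[idx],
    latitude = pp$latitude[idx],
    longitude = pp$longitude[idx],
    elevation = pp$elevation_m[idx],
    stringsAsFactors = FALSE)
}
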
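#' Construct a MarkerMatrix from a dosage matrix
#'
#' @param dosages numeric genotype-by-marker matrix with values 0/1/2/NA
#'   (count of the alternate allele) and genotype/marker dimnames.
#' @return A validated [MarkerMatrix-class].
#' @examples
#' d <- matrix(c(0, 1, 2, 2, NA, 0), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("m1", "m2", "m3")))
#' markerMatrix(d)
#' @export
markerMatrix <- function(dosages) {
  storage.mode(dosages) <- "double"
  new("MarkerMatrix", dosages = dosages)
}

#' Read a dosage CSV
#'
#' Reads the package's dosage dialect: a header row of marker ids, one row
#' per genotype with the genotype id in the first column and cells 0, 1, 2
#' or NA.
#'
#' @param path CSV file path.
#' @return A [MarkerMatrix-class].
#' @export
readDosageCSV <- function(path) {
  tb <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- tb[[1L]]
  d <- as.matrix(tb[-1L])
  rownames(d) <- ids
  markerMatrix(d)
}

#' Read diploid biallelic genotypes from a VCF into dosages
#'
#' Converts diploid GT calls of biallelic records to alternate-allele
#' dosages (0/0 -> 0, 0/1 -> 1, 1/1 -> 2, missing -> NA). Multiallelic
#' records are skipped with a message reporting the count.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return A [MarkerMatrix-class] (genotypes are the VCF samples).
#' @export
readDosageVCF <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readDosageVCF() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% c("0/0")] <- 0
  dose[gt %in% c("0/1", "1/0")] <- 1
  dose[gt %in% c("1/1")] <- 2
  ids <- vcfR::getID(v)
  if (any(is.na(ids)) || anyDuplicated(ids))
    ids <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))
  rownames(dose) <- ids
  markerMatrix(t(dose))  # genotypes as rows
}

#' Per-marker alternate-allele frequencies
#'
#' Computed from non-missing cells only, as (mean dosage)/2.
#'
#' @param x a [MarkerMatrix-class].
#' @return Named numeric vector in [0, 1] (NaN for fully missing markers).
#' @export
alleleFrequencies <- function(x) {
  stopifnot(is(x, "MarkerMatrix"))
  colMeans(x@dosages, na.rm = TRUE) / 2
}

.sampleCallRate <- function(d) rowMeans(!is.na(d))
.markerCallRate <- function(d) colMeans(!is.na(d))
.sampleHet <- function(d) {
  obs <- !is.na(d)
  het <- rowSums(d == 1, na.rm = TRUE)
  n <- rowSums(obs)
  ifelse(n > 0, het / n, 0)
}

#' Quality-control a marker panel
#'
#' Two-stage filter matching genotyping-service practice: samples are
#' screened first (call rate below \code{sampleCallMin}, or
#' heterozygosity above \code{hetMax} -- inbred rice lines are expected
#' nearly homozygous), then markers on the surviving samples (call rate
#' below \code{markerCallMin}, or minor-allele frequency below
#' \code{mafMin}). Each dropped id carries exactly one primary reason, in
#' the order the rules are stated.
#'
#' @param m a [MarkerMatrix-class].
#' @param sampleCallMin minimum per-sample call rate (default 0.66, the
#'   pass bar reported for the study's panel).
#' @param markerCallMin minimum per-marker call rate (default 0.90).
#' @param mafMin minimum minor-allele frequency (default 0.01).
#' @param hetMax maximum per-sample heterozygosity (default 0.10; the
#'   study reported 2.3% mean heterozygosity).
#' @return A list with elements \code{markers} (filtered
#'   [MarkerMatrix-class]) and \code{report} ([MarkerQCReport-class]).
#' @examples
#' m <- simulateMarkers(simConfig(nMarkers = 100L, rngSeed = 5L))
#' qc <- qcMarkers(m)
#' qc$report
#' @export
qcMarkers <- function(m, sampleCallMin = 0.66, markerCallMin = 0.90,
                      mafMin = 0.01, hetMax = 0.10) {
  stopifnot(is(m, "MarkerMatrix"))
  d <- m@dosages
  if (!nrow(d) || !ncol(d)) stop("empty marker matrix")
  scr <- .sampleCallRate(d)
  het <- .sampleHet(d)
  dropS <- data.frame(id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  bad_cr <- scr < sampleCallMin
  bad_het <- !bad_cr & het > hetMax
  if (any(bad_cr))
    dropS <- rbind(dropS, data.frame(id = rownames(d)[bad_cr],
                                     reason = "call_rate"))
  if (any(bad_het))
    dropS <- rbind(dropS, data.frame(id = rownames(d)[bad_het],
                                     reason = "heterozygosity"))
  keepS <- !(bad_cr | bad_het)
  if (!any(keepS))
    stop("empty panel: all samples removed by quality control")
  d2 <- d[keepS, , drop = FALSE]
  mcr <- .markerCallRate(d2)
  p <- colMeans(d2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # fully-missing markers fail on call rate first
  bad_mcr <- mcr < markerCallMin
  bad_maf <- !bad_mcr & maf < mafMin
  dropM <- data.frame(id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  if (any(bad_mcr))
    dropM <- rbind(dropM, data.frame(id = colnames(d)[bad_mcr],
                                     reason = "call_rate"))
  if (any(bad_maf))
    dropM <- rbind(dropM, data.frame(id = colnames(d)[bad_maf],
                                     reason = "maf"))
  keepM <- !(bad_mcr | bad_maf)
  out <- markerMatrix(d2[, keepM, drop = FALSE])
  stopifnot(nrow(dosages(out)) + nrow(dropS) == nrow(d),
            ncol(dosages(out)) + nrow(dropM) == ncol(d))
  report <- new("MarkerQCReport",
                sampleCallRate = scr, markerCallRate = mcr,
                sampleHeterozygosity = het,
                droppedSamples = dropS, droppedMarkers = dropM,
                thresholds = c(sample_call_min = sampleCallMin,
                               marker_call_min = markerCallMin,
                               maf_min = mafMin, het_max = hetMax))
  list(markers = out, report = report)
}

#' Impute missing dosages by the marker mean
#'
#' Each missing cell is replaced by its marker's mean observed dosage
#' (2p), leaving every non-missing cell untouched; allele frequencies are
#' therefore unchanged by imputation.
#'
#' @param m a [MarkerMatrix-class].
#' @return A complete [MarkerMatrix-class]. Note the imputed matrix may
#'   hold non-integer dosages; it is intended for relationship-matrix
#'   computation, not re-QC.
#' @export
imputeMissing <- function(m) {
  stopifnot(is(m, "MarkerMatrix"))
  d <- m@dosages
  if (!anyNA(d)) return(m)
  nobs <- colSums(!is.na(d))
  if (any(nobs == 0L))
    stop("marker(s) with zero non-missing observations: ",
         paste(utils::head(colnames(d)[nobs == 0L], 5), collapse = ", "))
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2L]]
  out <- m
  out@dosages <- d
  out
}
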
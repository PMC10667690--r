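#' Compute the VanRaden genomic relationship matrix
#'
#' Method-1 estimator: dosages are centred by twice the sample allele
#' frequency, \eqn{Z = M - 2p}, and
#' \deqn{G = \frac{Z Z'}{2 \sum_j p_j (1 - p_j)}}
#' with allele frequencies estimated from the panel itself. A small ridge
#' is added to the diagonal so the matrix stays invertible inside the
#' mixed-model equations.
#'
#' @param m a complete [MarkerMatrix-class] (run [imputeMissing()] first);
#'   at least 2 genotypes and 2 markers.
#' @param ridge value added to the diagonal (default 1e-6).
#' @return A [GenomicRelationshipMatrix-class].
#' @examples
#' m <- simulateMarkers(simConfig(nMarkers = 200L, rngSeed = 2L))
#' g <- computeGRM(m)
#' mean(diag(grmValues(g)))  # near 1 for a Hardy-Weinberg-like panel
#' @export
computeGRM <- function(m, ridge = 1e-6) {
  stopifnot(is(m, "MarkerMatrix"))
  d <- m@dosages
  if (anyNA(d))
    stop("marker matrix has missing cells; run imputeMissing() first")
  if (nrow(d) < 2L || ncol(d) < 2L)
    stop("need at least 2 genotypes and 2 markers")
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic: VanRaden denominator is zero")
  Z <- sweep(d, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2  # enforce exact symmetry against rounding
  diag(G) <- diag(G) + ridge
  new("GenomicRelationshipMatrix", values = G, denominator = denom,
      ridge = ridge)
}

#' Write / read a genomic relationship matrix as TSV
#'
#' Tab-separated square matrix with a header row and first column of
#' genotype ids; round-trips through \code{readGRM()} (denominator and
#' ridge are stored as comment header lines).
#'
#' @param g a [GenomicRelationshipMatrix-class].
#' @param path file path.
#' @return \code{path} (write) or the reconstructed object (read).
#' @export
writeGRM <- function(g, path) {
  stopifnot(is(g, "GenomicRelationshipMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# denominator\t%.15g", g@denominator), con)
  writeLines(sprintf("# ridge\t%.15g", g@ridge), con)
  tb <- cbind(genotype = rownames(g@values),
              as.data.frame(format(g@values, digits = 15, trim = TRUE)))
  utils::write.table(tb, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGRM
#' @export
readGRM <- function(path) {
  hdr <- readLines(path, n = 2L)
  denom <- as.numeric(sub("^# denominator\t", "", hdr[1L]))
  ridge <- as.numeric(sub("^# ridge\t", "", hdr[2L]))
  tb <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2L,
                          check.names = FALSE)
  v <- as.matrix(tb[-1L])
  rownames(v) <- tb[[1L]]
  v <- (v + t(v)) / 2
  new("GenomicRelationshipMatrix", values = v, denominator = denom,
      ridge = ridge)
}

#' Write a marker QC report as TSV
#'
#' Writes one section per table (per-sample statistics, per-marker call
#' rates, dropped ids with reasons), separated by comment lines.
#'
#' @param report a [MarkerQCReport-class].
#' @param path file path.
#' @export
writeQCReport <- function(report, path) {
  stopifnot(is(report, "MarkerQCReport"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# samples", con)
  utils::write.table(
    data.frame(id = names(report@sampleCallRate),
               call_rate = report@sampleCallRate,
               heterozygosity = report@sampleHeterozygosity),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("# dropped_samples", con)
  utils::write.table(report@droppedSamples, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines("# dropped_markers", con)
  utils::write.table(report@droppedMarkers, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
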
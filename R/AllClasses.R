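#' @import methods
NULL

#' SimConfig: configuration of a synthetic screening trial
#'
#' Describes one synthetic anaerobic-germination screening study: the
#' germplasm panel (test entries plus replicated checks), the resolvable
#' incomplete-block (alpha-lattice) geometry, the marker panel, and the
#' genetic architecture of the eight recorded traits (means per water
#' condition, genetic standard deviations, broad-sense heritabilities and
#' the genetic correlation structure).
#'
#' The design identity
#' \code{nEntries + nChecks * checkReps == blocksPerReplication * plotsPerBlock}
#' must hold so that every replication is exactly filled (224 plots for the
#' default 200 entries + 8 checks x 3 in a 14 x 16 lattice).
#'
#' @slot nEntries number of test entries (appear once per replication).
#' @slot nChecks number of check genotypes.
#' @slot checkReps times each check is replicated within a replication.
#' @slot nMarkers number of biallelic SNP markers.
#' @slot nReplications replications per environment.
#' @slot blocksPerReplication incomplete blocks (crates) per replication.
#' @slot plotsPerBlock entries accommodated per block.
#' @slot experiments labels of the repeated experiments (runs).
#' @slot conditions water regimes, \code{c("anaerobic", "aerobic")}.
#' @slot seedsPerPlot seeds sown per plot (two rows of 15 by default).
#' @slot missingRate marker missing-call rate in [0, 1).
#' @slot inbreeding inbreeding coefficient F of the panel in [0, 1];
#'   selfing rice landraces are nearly fully inbred.
#' @slot traitHeritabilities named plot-basis H^2 per trait, in [0, 1].
#' @slot traitMeans trait-by-condition matrix of condition means (trait units).
#' @slot geneticSD named genetic standard deviation per trait (trait units).
#' @slot geneticCorrelation trait-by-trait genetic correlation matrix
#'   (symmetric, unit diagonal, positive semi-definite).
#' @slot blockVariance incomplete-block variance as a fraction of the
#'   trait phenotypic variance.
#' @slot replicationEffectSize fixed replication shift in phenotypic SD units.
#' @slot environmentEffectSize fixed experiment (run) shift in phenotypic SD
#'   units.
#' @slot rngSeed integer seed driving all randomisation.
#' @seealso [simConfig()] for the user constructor with study defaults.
#' @export
setClass("SimConfig", representation(
  nEntries = "integer", nChecks = "integer", checkReps = "integer",
  nMarkers = "integer", nReplications = "integer",
  blocksPerReplication = "integer", plotsPerBlock = "integer",
  experiments = "character", conditions = "character",
  seedsPerPlot = "integer", missingRate = "numeric",
  inbreeding = "numeric",
  traitHeritabilities = "numeric", traitMeans = "matrix",
  geneticSD = "numeric", geneticCorrelation = "matrix",
  blockVariance = "numeric", replicationEffectSize = "numeric",
  environmentEffectSize = "numeric", rngSeed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  slots_pos <- c("nEntries", "nMarkers", "nReplications",
                 "blocksPerReplication", "plotsPerBlock", "seedsPerPlot")
  for (s in slots_pos)
    if (slot(object, s) <= 0L) msg <- c(msg, paste0(s, " must be positive"))
  lhs <- object@nEntries + object@nChecks * object@checkReps
  rhs <- object@blocksPerReplication * object@plotsPerBlock
  if (lhs != rhs)
    msg <- c(msg, sprintf(
      "design identity violated: nEntries + nChecks*checkReps = %d + %d*%d = %d but blocksPerReplication*plotsPerBlock = %d*%d = %d",
      object@nEntries, object@nChecks, object@checkReps, lhs,
      object@blocksPerReplication, object@plotsPerBlock, rhs))
  h2 <- object@traitHeritabilities
  if (any(h2 < 0 | h2 > 1)) msg <- c(msg, "heritabilities must lie in [0, 1]")
  G <- object@geneticCorrelation
  if (!isSymmetric(unname(G), tol = 1e-8))
    msg <- c(msg, "geneticCorrelation must be symmetric")
  else {
    if (max(abs(diag(G) - 1)) > 1e-8)
      msg <- c(msg, "geneticCorrelation must have unit diagonal")
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      msg <- c(msg, "geneticCorrelation must be positive semi-definite")
  }
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (object@inbreeding < 0 || object@inbreeding > 1)
    msg <- c(msg, "inbreeding must lie in [0, 1]")
  tn <- names(h2)
  if (!setequal(tn, rownames(object@traitMeans)) ||
      !setequal(tn, names(object@geneticSD)) ||
      !setequal(tn, rownames(G)))
    msg <- c(msg, "trait names must agree across heritabilities, means, SDs and correlations")
  if (length(msg)) msg else TRUE
})

#' MarkerMatrix: biallelic SNP dosages for a genotype panel
#'
#' Genotype-by-marker matrix of alternate-allele dosages (0, 1, 2 or
#' \code{NA} for missing calls). Row names are genotype ids, column names
#' marker ids.
#'
#' @slot dosages numeric matrix with values in \{0, 1, 2, NA\}.
#' @seealso [markerMatrix()], [alleleFrequencies()], [qcMarkers()],
#'   [imputeMissing()], [computeGRM()]
#' @export
setClass("MarkerMatrix", representation(dosages = "matrix"))

setValidity("MarkerMatrix", function(object) {
  d <- object@dosages
  msg <- character()
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosages must carry genotype row names and marker column names")
  v <- d[!is.na(d)]
  # raw panels hold 0/1/2; mean-imputed panels may hold fractional dosages
  if (length(v) && (min(v) < 0 || max(v) > 2))
    msg <- c(msg, "dosage values must lie in [0, 2] or be NA")
  if (anyDuplicated(rownames(d))) msg <- c(msg, "duplicated genotype ids")
  if (anyDuplicated(colnames(d))) msg <- c(msg, "duplicated marker ids")
  if (length(msg)) msg else TRUE
})

#' MarkerQCReport: outcome of marker/sample quality control
#'
#' @slot sampleCallRate named per-sample call rates (input panel).
#' @slot markerCallRate named per-marker call rates (after sample filtering).
#' @slot sampleHeterozygosity named per-sample heterozygous-call fractions.
#' @slot droppedSamples data.frame with columns \code{id}, \code{reason}.
#' @slot droppedMarkers data.frame with columns \code{id}, \code{reason}.
#' @slot thresholds named numeric of the thresholds applied.
#' @export
setClass("MarkerQCReport", representation(
  sampleCallRate = "numeric", markerCallRate = "numeric",
  sampleHeterozygosity = "numeric",
  droppedSamples = "data.frame", droppedMarkers = "data.frame",
  thresholds = "numeric"))

#' GenomicRelationshipMatrix: VanRaden genomic relationships
#'
#' Symmetric genotype-by-genotype relationship matrix
#' \eqn{G = Z Z' / (2 \sum_j p_j (1 - p_j))} computed from dosages centred
#' by twice the sample allele frequency, with a small ridge added to the
#' diagonal to guarantee invertibility in the mixed-model equations.
#'
#' @slot values symmetric numeric matrix with genotype dimnames.
#' @slot denominator the VanRaden scaling \eqn{2 \sum_j p_j(1-p_j)}.
#' @slot ridge the value added to the diagonal.
#' @seealso [computeGRM()]
#' @export
setClass("GenomicRelationshipMatrix", representation(
  values = "matrix", denominator = "numeric", ridge = "numeric"))

setValidity("GenomicRelationshipMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!isSymmetric(unname(v), tol = 1e-10)) msg <- c(msg, "values must be symmetric")
  if (is.null(rownames(v))) msg <- c(msg, "values must carry genotype dimnames")
  if (object@denominator <= 0) msg <- c(msg, "denominator must be positive")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: declaration of a single-trait mixed model
#'
#' Declares the model layer used to analyse one trait: the
#' single-experiment analysis (SEA)
#' \deqn{y = \beta_0 + \beta_1 r + u + b + \epsilon}
#' with fixed replication \eqn{r} and fixed blocks-within-replication
#' \eqn{b}, or the multi-environment analysis (MEA)
#' \deqn{y = \beta_0 + \beta_1 E + \beta_2 r + \beta_3 B + u + \epsilon}
#' which adds a fixed environment term \eqn{E}. Genotype \eqn{u} is always
#' random, with identity covariance (phenotypic BLUP) or a genomic
#' relationship matrix (GBLUP).
#'
#' @slot trait trait id the model is fitted to.
#' @slot analysis \code{"sea"} or \code{"mea"}.
#' @slot blocksFixed logical; blocks-within-replication as fixed effects
#'   (the default, matching the declared models) or as a second random term
#'   is not supported -- when \code{FALSE} blocks are simply omitted.
#' @export
setClass("ModelSpec", representation(
  trait = "character", analysis = "character", blocksFixed = "logical"))

setValidity("ModelSpec", function(object) {
  if (!object@analysis %in% c("sea", "mea")) "analysis must be 'sea' or 'mea'" else TRUE
})

#' VarianceComponents: REML estimates for the two-component model
#'
#' @slot sigma2g genetic variance (>= 0).
#' @slot sigma2e residual variance (> 0, bounded below).
#' @slot convergence \code{"converged"}, \code{"max-iter"} or
#'   \code{"boundary"}.
#' @slot nIterations iterations (EM) or objective evaluations (profiled).
#' @slot loglikTrace restricted log-likelihood trace; nondecreasing for EM.
#' @slot method \code{"profile"} or \code{"em"}.
#' @export
setClass("VarianceComponents", representation(
  sigma2g = "numeric", sigma2e = "numeric", convergence = "character",
  nIterations = "integer", loglikTrace = "numeric", method = "character"))

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (object@sigma2g < 0) msg <- c(msg, "sigma2g must be nonnegative")
  if (object@sigma2e <= 0) msg <- c(msg, "sigma2e must be positive")
  if (length(msg)) msg else TRUE
})

#' FitResult: a solved mixed model
#'
#' Fixed-effect estimates, genotype BLUPs with prediction error variances
#' and the REML variance components for one trait/one model layer.
#'
#' @slot fixedEstimates named fixed-effect estimates (reference-level
#'   coding; aliased columns dropped).
#' @slot blups named genotype BLUPs.
#' @slot pev named prediction error variances (>= 0).
#' @slot varcomp a [VarianceComponents-class] object.
#' @slot fittedMean mean fitted fixed-effect value over the observations
#'   (the grand trait mean on the model scale; used to recentre BLUPs
#'   back to the trait scale).
#' @slot nObs observations used.
#' @slot nDropped records dropped for missing response.
#' @export
setClass("FitResult", representation(
  fixedEstimates = "numeric", blups = "numeric", pev = "numeric",
  varcomp = "VarianceComponents", fittedMean = "numeric",
  nObs = "integer", nDropped = "integer"))

#' GEBVTable: per-genotype breeding values for the eight traits
#'
#' Genotype-by-trait matrix of (genomic) estimated breeding values in one
#' evaluation environment (\code{"anaerobic"}, \code{"aerobic"} or
#' \code{"across"}). Values are reported on the trait scale, recentred by
#' the model intercept, unless the table has been standardised.
#'
#' @slot environment evaluation environment label.
#' @slot values genotype-by-trait numeric matrix.
#' @slot standardized logical; columns centred/scaled per trait.
#' @slot intercepts named per-trait model intercepts used for recentring.
#' @slot zeroVarianceTraits traits flagged as zero-variance during
#'   standardisation.
#' @export
setClass("GEBVTable", representation(
  environment = "character", values = "matrix", standardized = "logical",
  intercepts = "numeric", zeroVarianceTraits = "character"))

#' DonorList: ranked donors surviving a selection rule
#'
#' @slot rule \code{"anaerobic"}, \code{"aerobic"} or \code{"across"}.
#' @slot table data.frame with columns \code{genotype},
#'   \code{selection_index}, \code{germ21_blup}, \code{is_check}, sorted by
#'   index descending.
#' @slot indexMin selection-index threshold applied.
#' @slot germMin germination-BLUP threshold applied (percent, 21 DAS).
#' @export
setClass("DonorList", representation(
  rule = "character", table = "data.frame",
  indexMin = "numeric", germMin = "numeric"))

setValidity("DonorList", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("genotype", "selection_index", "germ21_blup", "is_check")
  if (!all(need %in% names(tb)))
    msg <- c(msg, paste("table must have columns", paste(need, collapse = ", ")))
  else if (nrow(tb)) {
    if (any(tb$selection_index < object@indexMin - 1e-9) ||
        any(tb$germ21_blup < object@germMin - 1e-9))
      msg <- c(msg, "rows must satisfy the rule thresholds")
    if (is.unsorted(rev(tb$selection_index)))
      msg <- c(msg, "rows must be sorted by selection index, descending")
  }
  if (length(msg)) msg else TRUE
})
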
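#' Configure a synthetic anaerobic-germination screening trial
#'
#' Builds a [SimConfig-class] whose defaults reproduce the geometry and
#' genetic architecture of the screening study the package models: 200
#' test entries plus 8 checks replicated three times within each
#' replication, filling a 14 x 16 alpha lattice (224 plots) with 2
#' replications, repeated in two experiments under two water regimes
#' (anaerobic = 7 cm standing floodwater from dry seeding; aerobic =
#' moist control), 30 dry seeds per plot (two rows of 15), and a 1000-SNP
#' marker panel. Trait condition means come from the published
#' across-experiment summaries; plot-basis heritabilities average the two
#' anaerobic experiments (0.71 for germination 14 DAS).
#'
#' @param nEntries,nChecks,checkReps panel composition; the design identity
#'   \code{nEntries + nChecks*checkReps == blocksPerReplication*plotsPerBlock}
#'   must hold.
#' @param nMarkers number of biallelic SNPs.
#' @param nReplications replications per environment.
#' @param blocksPerReplication,plotsPerBlock lattice geometry.
#' @param experiments labels of the repeated experimental runs.
#' @param conditions water regimes; the first is treated as the stress
#'   condition.
#' @param seedsPerPlot seeds sown per plot.
#' @param missingRate marker missing-call rate.
#' @param inbreeding inbreeding coefficient F of the panel. The default
#'   0.95 emulates selfing rice landraces: expected heterozygosity
#'   (1 - F) * 2E[p(1-p)] is about 2%, matching genotyping-service
#'   reports for such panels. Set 0 for a Hardy-Weinberg (outbred) panel.
#' @param traitHeritabilities,traitMeans,geneticSD,geneticCorrelation
#'   genetic architecture; defaults as described above. Partial named
#'   vectors override the matching defaults.
#' @param blockVariance incomplete-block variance as a fraction of
#'   phenotypic variance.
#' @param replicationEffectSize,environmentEffectSize fixed replication and
#'   experiment shifts in phenotypic-SD units.
#' @param rngSeed integer seed; all randomisation derives from it.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(rngSeed = 42)
#' cfg
#' @export
simConfig <- function(nEntries = 200L, nChecks = 8L, checkReps = 3L,
                      nMarkers = 1000L, nReplications = 2L,
                      blocksPerReplication = 16L, plotsPerBlock = 14L,
                      experiments = c("exp1", "exp2"),
                      conditions = c("anaerobic", "aerobic"),
                      seedsPerPlot = 30L, missingRate = 0,
                      inbreeding = 0.95,
                      traitHeritabilities = NULL, traitMeans = NULL,
                      geneticSD = NULL, geneticCorrelation = NULL,
                      blockVariance = 0.05, replicationEffectSize = 0.1,
                      environmentEffectSize = 0.2, rngSeed = 1L) {
  h2 <- .DEFAULT_HERITABILITIES
  if (!is.null(traitHeritabilities)) {
    stopifnot(all(names(traitHeritabilities) %in% .TRAITS))
    h2[names(traitHeritabilities)] <- traitHeritabilities
  }
  mu <- .DEFAULT_TRAIT_MEANS
  if (!is.null(traitMeans)) mu <- traitMeans
  sg <- .DEFAULT_GENETIC_SD
  if (!is.null(geneticSD)) {
    stopifnot(all(names(geneticSD) %in% .TRAITS))
    sg[names(geneticSD)] <- geneticSD
  }
  R <- if (is.null(geneticCorrelation)) .DEFAULT_GENETIC_CORRELATION else geneticCorrelation
  new("SimConfig",
      nEntries = as.integer(nEntries), nChecks = as.integer(nChecks),
      checkReps = as.integer(checkReps), nMarkers = as.integer(nMarkers),
      nReplications = as.integer(nReplications),
      blocksPerReplication = as.integer(blocksPerReplication),
      plotsPerBlock = as.integer(plotsPerBlock),
      experiments = experiments, conditions = conditions,
      seedsPerPlot = as.integer(seedsPerPlot), missingRate = missingRate,
      inbreeding = inbreeding,
      traitHeritabilities = h2, traitMeans = mu, geneticSD = sg,
      geneticCorrelation = R, blockVariance = blockVariance,
      replicationEffectSize = replicationEffectSize,
      environmentEffectSize = environmentEffectSize,
      rngSeed = as.integer(rngSeed))
}

.simGenotypeIds <- function(cfg) {
  c(sprintf("ENT%03d", seq_len(cfg@nEntries)),
    if (cfg@nChecks > 0L) sprintf("CHK%02d", seq_len(cfg@nChecks)))
}

#' Check ids of a synthetic panel
#'
#' @param cfg a [SimConfig-class].
#' @return Character vector of check genotype ids (empty when
#'   \code{nChecks} is 0).
#' @export
checkIds <- function(cfg) {
  if (cfg@nChecks > 0L) sprintf("CHK%02d", seq_len(cfg@nChecks)) else character()
}

# Phenotypic SD implied by genetic SD and plot-basis heritability.
# h2 = 0 degenerates to a purely environmental trait with the configured
# SD as residual SD.
.simTraitSDs <- function(cfg, trait) {
  h2 <- cfg@traitHeritabilities[trait]
  sg <- if (h2 > 0) cfg@geneticSD[trait] else 0
  se <- if (h2 > 0) {
    if (h2 < 1) cfg@geneticSD[trait] * sqrt((1 - h2) / h2) else 0
  } else cfg@geneticSD[trait]
  c(genetic = unname(sg), residual = unname(se),
    phenotypic = unname(sqrt(sg^2 + se^2)))
}

#' Simulate a biallelic SNP marker panel
#'
#' Draws per-marker allele frequencies uniformly on [0.05, 0.95] and
#' genotype dosages as counts of the alternate allele, emulating a fixed
#' custom amplicon panel of about a thousand SNPs. Each genotype-marker
#' cell is autozygous (dosage 0 or 2, probability \code{inbreeding}) or
#' Hardy-Weinberg binomial(2, p), so the panel's heterozygosity matches
#' an inbred landrace collection; \code{inbreeding = 0} recovers the pure
#' binomial(2, p) draw. Optional missing calls are planted completely at
#' random.
#'
#' @param cfg a [SimConfig-class]; \code{missingRate} controls missingness.
#' @return A [MarkerMatrix-class] over all entries and checks.
#' @examples
#' m <- simulateMarkers(simConfig(nMarkers = 50L, rngSeed = 7L))
#' dim(dosages(m))
#' @export
simulateMarkers <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  ids <- .simGenotypeIds(cfg)
  n <- length(ids)
  if (cfg@nMarkers <= 0L || n <= 0L)
    stop("configuration error: marker and genotype counts must be positive")
  set.seed(cfg@rngSeed + 1L)
  p <- stats::runif(cfg@nMarkers, 0.05, 0.95)
  pcell <- rep(p, each = n)
  auto <- stats::runif(n * cfg@nMarkers) < cfg@inbreeding
  d <- ifelse(auto, 2 * stats::rbinom(n * cfg@nMarkers, 1L, pcell),
              stats::rbinom(n * cfg@nMarkers, 2L, pcell))
  d <- matrix(as.numeric(d), nrow = n, ncol = cfg@nMarkers,
              dimnames = list(ids, sprintf("SNP%04d", seq_len(cfg@nMarkers))))
  if (cfg@missingRate > 0) {
    miss <- stats::runif(length(d)) < cfg@missingRate
    d[miss] <- NA_real_
  }
  new("MarkerMatrix", dosages = d)
}

#' Simulate correlated true breeding values from a marker panel
#'
#' Marker effects are drawn i.i.d. normal per trait and linearly mixed
#' through the matrix square root of the configured genetic correlation;
#' true breeding values (TBV) are the product of 2p-centred dosages and
#' effects, rescaled per trait so the TBV variance over genotypes equals
#' the configured genetic variance exactly. Traits with heritability 0
#' receive all-zero TBVs.
#'
#' @param markers a complete [MarkerMatrix-class] (impute first if needed).
#' @param cfg a [SimConfig-class].
#' @return A list (ground truth for recovery tests) with elements
#'   \code{alleleFrequencies}, \code{markerEffects} (marker-by-trait) and
#'   \code{tbv} (genotype-by-trait, zero column means).
#' @export
simulateBreedingValues <- function(markers, cfg) {
  stopifnot(is(markers, "MarkerMatrix"), is(cfg, "SimConfig"))
  d <- markers@dosages
  if (anyNA(d))
    stop("marker matrix has missing cells; run imputeMissing() first")
  R <- cfg@geneticCorrelation
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("configuration error: genetic correlation matrix is not positive semi-definite")
  Rhalf <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  p <- colMeans(d) / 2
  Zc <- sweep(d, 2L, 2 * p)
  set.seed(cfg@rngSeed + 2L)
  traits <- names(cfg@traitHeritabilities)
  M <- matrix(stats::rnorm(ncol(d) * length(traits)), ncol = length(traits))
  E <- M %*% Rhalf
  colnames(E) <- traits
  raw <- Zc %*% E
  scale <- vapply(traits, function(tr) {
    sds <- .simTraitSDs(cfg, tr)
    s <- stats::sd(raw[, tr])
    if (sds["genetic"] == 0 || s == 0) 0 else sds["genetic"] / s
  }, numeric(1))
  tbv <- sweep(raw, 2L, scale, `*`)
  tbv <- sweep(tbv, 2L, colMeans(tbv))  # exact zero column means
  list(alleleFrequencies = p,
       markerEffects = sweep(E, 2L, scale, `*`),
       tbv = tbv)
}

#' Generate a randomised alpha-lattice trial design
#'
#' Allocates genotypes to plots for every experiment x condition x
#' replication: each entry appears exactly once per replication and each
#' check exactly \code{checkReps} times, filling
#' \code{blocksPerReplication} incomplete blocks of \code{plotsPerBlock}
#' plots by constrained random permutation (no concurrence optimisation).
#'
#' @param cfg a [SimConfig-class]; the design identity must hold.
#' @return A data.frame with columns \code{experiment}, \code{condition},
#'   \code{replication}, \code{block}, \code{plot}, \code{genotype},
#'   \code{is_check}.
#' @examples
#' des <- generateTrialDesign(simConfig(rngSeed = 3L))
#' nrow(des)  # 224 plots x 2 replications x 4 environments
#' @export
generateTrialDesign <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)  # reports the design-identity arithmetic on violation
  entries <- setdiff(.simGenotypeIds(cfg), checkIds(cfg))
  units <- c(entries, rep(checkIds(cfg), each = cfg@checkReps))
  nPlots <- cfg@blocksPerReplication * cfg@plotsPerBlock
  set.seed(cfg@rngSeed + 3L)
  out <- list()
  for (exp in cfg@experiments) for (cond in cfg@conditions)
    for (rep_ in seq_len(cfg@nReplications)) {
      perm <- sample(units)
      out[[length(out) + 1L]] <- data.frame(
        experiment = exp, condition = cond,
        replication = paste0("R", rep_),
        block = paste0("B", rep(seq_len(cfg@blocksPerReplication),
                                each = cfg@plotsPerBlock)),
        plot = rep(seq_len(cfg@plotsPerBlock), cfg@blocksPerReplication),
        genotype = perm, stringsAsFactors = FALSE)
    }
  des <- do.call(rbind, out)
  des$is_check <- des$genotype %in% checkIds(cfg)
  rownames(des) <- NULL
  stopifnot(nrow(des) == nPlots * cfg@nReplications *
              length(cfg@experiments) * length(cfg@conditions))
  des
}

#' Simulate plot-level phenotypes for a trial design
#'
#' Each plot value is the condition-specific trait mean, plus a fixed
#' experiment shift and a fixed replication shift (centred ladders in
#' phenotypic-SD units, so the configured condition means remain the
#' grand means), a normal incomplete-block effect, the genotype's true breeding
#' value, and i.i.d. normal residual noise sized from the configured
#' plot-basis heritability. Germination traits are realised as seed
#' counts: the latent percentage is converted to a count out of
#' \code{seedsPerPlot}, rounded and truncated to the valid range. All
#' other measurements are floored at zero.
#'
#' @param design a trial design from [generateTrialDesign()].
#' @param genetics ground truth from [simulateBreedingValues()].
#' @param cfg a [SimConfig-class].
#' @return A data.frame of plot records with columns \code{experiment},
#'   \code{condition}, \code{replication}, \code{block}, \code{genotype},
#'   \code{seeds_sown}, \code{germ14_count}, \code{germ21_count},
#'   \code{height14_cm}, \code{height21_cm}, \code{culm_mm},
#'   \code{rootlen_cm}, \code{shootdm_g}, \code{rootdm_g}.
#' @export
simulatePhenotypes <- function(design, genetics, cfg) {
  stopifnot(is(cfg, "SimConfig"), is.data.frame(design))
  tbv <- genetics$tbv
  missing_ids <- setdiff(unique(design$genotype), rownames(tbv))
  if (length(missing_ids))
    stop("input error: design references genotypes absent from genetics: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  set.seed(cfg@rngSeed + 4L)
  n <- nrow(design)
  # centred fixed shifts, so configured condition means stay grand means
  expIdx <- match(design$experiment, cfg@experiments) -
    (length(cfg@experiments) + 1) / 2
  repIdx <- as.integer(sub("^R", "", design$replication)) -
    (cfg@nReplications + 1) / 2
  blockKey <- interaction(design$experiment, design$condition,
                          design$replication, design$block, drop = TRUE)
  traits <- names(cfg@traitHeritabilities)
  latent <- matrix(NA_real_, n, length(traits),
                   dimnames = list(NULL, traits))
  for (tr in traits) {
    sds <- .simTraitSDs(cfg, tr)
    mu <- cfg@traitMeans[tr, design$condition]
    blockEff <- stats::rnorm(nlevels(blockKey),
                             sd = sqrt(cfg@blockVariance) * sds["phenotypic"])
    latent[, tr] <- mu +
      expIdx * cfg@environmentEffectSize * sds["phenotypic"] +
      repIdx * cfg@replicationEffectSize * sds["phenotypic"] +
      blockEff[as.integer(blockKey)] +
      tbv[design$genotype, tr] +
      stats::rnorm(n, sd = sds["residual"])
  }
  toCount <- function(pct) {
    pmin(pmax(round(pct / 100 * cfg@seedsPerPlot), 0L), cfg@seedsPerPlot)
  }
  data.frame(design[c("experiment", "condition", "replication", "block",
                      "genotype")],
             seeds_sown = cfg@seedsPerPlot,
             germ14_count = toCount(latent[, "germ14_pct"]),
             germ21_count = toCount(latent[, "germ21_pct"]),
             height14_cm = pmax(latent[, "height14"], 0),
             height21_cm = pmax(latent[, "height21"], 0),
             culm_mm = pmax(latent[, "culm"], 0),
             rootlen_cm = pmax(latent[, "rootlen"], 0),
             shootdm_g = pmax(latent[, "shootdm"], 0),
             rootdm_g = pmax(latent[, "rootdm"], 0),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic screening trial
#'
#' Convenience wrapper chaining [simulateMarkers()] (with mean imputation
#' of any planted missing calls for the ground-truth computation),
#' [simulateBreedingValues()], [generateTrialDesign()] and
#' [simulatePhenotypes()].
#'
#' @param cfg a [SimConfig-class].
#' @return A list with elements \code{config}, \code{markers} (as
#'   simulated, including any missing calls), \code{genetics},
#'   \code{design} and \code{phenotypes}.
#' @examples
#' trial <- simulateTrial(simConfig(nMarkers = 100L, rngSeed = 11L))
#' head(trial$phenotypes)
#' @export
simulateTrial <- function(cfg) {
  markers <- simulateMarkers(cfg)
  complete <- if (anyNA(markers@dosages)) imputeMissing(markers) else markers
  genetics <- simulateBreedingValues(complete, cfg)
  design <- generateTrialDesign(cfg)
  phenotypes <- simulatePhenotypes(design, genetics, cfg)
  list(config = cfg, markers = markers, genetics = genetics,
       design = design, phenotypes = phenotypes)
}

#' Write synthetic-trial fixtures as plain text
#'
#' \code{writePhenotypeCSV} writes the plot-record CSV dialect;
#' \code{writeDosageCSV} the genotype-by-marker dosage CSV (cells 0/1/2 or
#' empty for missing); \code{writeTruthTSV} the true-breeding-value table
#' (genotype by trait) for test use. All writers are deterministic: equal
#' inputs produce byte-identical files.
#'
#' @param x the object to write (plot records, [MarkerMatrix-class], or a
#'   genetics list from [simulateBreedingValues()]).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @name fixtureWriters
NULL

#' @rdname fixtureWriters
#' @export
writePhenotypeCSV <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname fixtureWriters
#' @export
writeDosageCSV <- function(x, path) {
  stopifnot(is(x, "MarkerMatrix"))
  d <- as.data.frame(x@dosages)
  d <- cbind(genotype = rownames(x@dosages), d)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname fixtureWriters
#' @export
writeTruthTSV <- function(x, path) {
  tb <- as.data.frame(x$tbv)
  tb <- cbind(genotype = rownames(x$tbv), tb)
  utils::write.table(tb, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
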
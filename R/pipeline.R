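#' Configure an end-to-end screening pipeline run
#'
#' Exactly one input mode must be active: synthetic (a [SimConfig-class]
#' via \code{sim}) or real inputs (\code{phenotypes} + \code{markers} file
#' paths in the package's CSV dialects).
#'
#' @param sim a [SimConfig-class] for synthetic mode.
#' @param phenotypes,markers input file paths for real mode.
#' @param checks genotype ids to flag as checks (synthetic mode fills this
#'   automatically).
#' @param outDir output directory.
#' @param seed integer seed recorded in the run (synthetic mode overrides
#'   the SimConfig seed with it).
#' @param qc named list of QC thresholds passed to [qcMarkers()].
#' @param outlierAlpha Bonferroni outlier-screen level (0 disables).
#' @param weights selection-index weights (default
#'   [defaultIndexWeights()]).
#' @param rules selection thresholds (default [defaultSelectionRules()]).
#' @param standardize standardise GEBVs before weighting (default TRUE).
#' @param remlMethod REML method for all fits (default \code{"profile"}).
#' @return A validated run-configuration list of class
#'   \code{"anaerGSRunConfig"}.
#' @export
runConfig <- function(sim = NULL, phenotypes = NULL, markers = NULL,
                      checks = character(), outDir = tempfile("anaerGS_run"),
                      seed = 1L, qc = list(), outlierAlpha = 0.05,
                      weights = defaultIndexWeights(),
                      rules = defaultSelectionRules(),
                      standardize = TRUE, remlMethod = "profile") {
  synthetic <- !is.null(sim)
  real <- !is.null(phenotypes) || !is.null(markers)
  if (synthetic && real)
    stop("config error: choose either synthetic mode or real input paths, not both")
  if (!synthetic && (is.null(phenotypes) || is.null(markers)))
    stop("config error: real mode needs both phenotype and marker paths")
  cfg <- list(sim = sim, phenotypes = phenotypes, markers = markers,
              checks = checks, outDir = outDir, seed = as.integer(seed),
              qc = qc, outlierAlpha = outlierAlpha, weights = weights,
              rules = rules, standardize = standardize,
              remlMethod = remlMethod)
  class(cfg) <- "anaerGSRunConfig"
  cfg
}

.writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

.fitReportRow <- function(trait, layer, fit) {
  vc <- fit@varcomp
  rel <- suppressWarnings(reliability(fit))
  data.frame(trait = trait, layer = layer,
             sigma2_g = vc@sigma2g, sigma2_e = vc@sigma2e,
             H2 = suppressWarnings(heritability(vc)),
             mean_reliability = rel$mean, n_obs = fit@nObs,
             convergence = vc@convergence, stringsAsFactors = FALSE)
}

#' Run the full donor-screening pipeline
#'
#' Executes the stages in order: simulate or ingest, phenotype
#' preparation with the Bonferroni outlier screen, marker QC and the
#' genomic relationship matrix, single-experiment fits per experiment and
#' condition, joint per-condition fits, the multi-environment fit,
#' genomic breeding values per evaluation environment, selection indices,
#' and donor lists under the three selection rules. All outputs are
#' plain-text TSV/CSV in \code{cfg$outDir}; \code{manifest.tsv} lists
#' every output file with its MD5 checksum, so identical configurations
#' reproduce byte-identical results.
#'
#' @param cfg a run configuration from [runConfig()].
#' @return Invisibly, a list with the donor lists, GEBV tables, fit
#'   report, manifest data.frame and output paths.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "anaerGSRunConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outDir, f)
  paths <- character()

  # -- stage: simulate / ingest -------------------------------------------
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    sim@rngSeed <- cfg$seed
    trial <- simulateTrial(sim)
    records <- trial$phenotypes
    markers <- trial$markers
    checks <- checkIds(sim)
    paths <- c(paths,
               writePhenotypeCSV(records, out("phenotypes.csv")),
               writeDosageCSV(markers, out("markers.csv")),
               writeTruthTSV(trial$genetics, out("true_breeding_values.tsv")))
  } else {
    records <- utils::read.csv(cfg$phenotypes, stringsAsFactors = FALSE)
    markers <- readDosageCSV(cfg$markers)
    checks <- cfg$checks
  }

  # -- stage: phenotype preparation ---------------------------------------
  traits <- plotsToTraitTable(records)
  filt <- bonferroniOutlierFilter(traits, alpha = cfg$outlierAlpha)
  traits <- filt$table
  paths <- c(paths, .writeTSV(traits, out("trait_table.tsv")),
             .writeTSV(filt$outliers, out("outliers.tsv")),
             .writeTSV(stressImpact(traits), out("stress_impact.tsv")))

  # -- stage: marker QC + GRM ---------------------------------------------
  qcArgs <- c(list(markers), cfg$qc)
  qc <- do.call(qcMarkers, qcArgs)
  grm <- computeGRM(imputeMissing(qc$markers))
  paths <- c(paths, writeQCReport(qc$report, out("marker_qc.tsv")),
             writeGRM(grm, out("grm.tsv")))

  # -- stage: mixed-model fits --------------------------------------------
  conditions <- unique(traits$condition)
  experiments <- unique(traits$experiment)
  report <- list()
  germBlups <- list()   # phenotypic germ21 BLUPs (+ intercept) per rule
  blupTables <- list()  # per-condition across BLUPs for correlations
  for (cond in conditions) {
    for (exp_ in experiments) {
      for (tr in traitNames()) {
        fit <- fitTrait(traits, tr, condition = cond, experiment = exp_,
                        analysis = "sea", method = cfg$remlMethod)
        report[[length(report) + 1L]] <-
          .fitReportRow(tr, paste0("sea:", exp_, ":", cond), fit)
      }
    }
    condBlups <- matrix(NA_real_, 0, 0)
    condFits <- lapply(traitNames(), function(tr)
      fitTrait(traits, tr, condition = cond, analysis = "mea",
               method = cfg$remlMethod))
    names(condFits) <- traitNames()
    for (tr in traitNames())
      report[[length(report) + 1L]] <-
        .fitReportRow(tr, paste0("across:", cond), condFits[[tr]])
    ids <- names(condFits[[1L]]@blups)
    condBlups <- vapply(condFits, function(f)
      f@fittedMean + f@blups[ids], numeric(length(ids)))
    rownames(condBlups) <- ids
    blupTables[[cond]] <- condBlups
    germBlups[[cond]] <- condBlups[, "germ21_pct"]
    paths <- c(paths, .writeTSV(
      cbind(genotype = ids, as.data.frame(condBlups)),
      out(paste0("blups_", cond, ".tsv"))))
    paths <- c(paths, .writeTSV(
      cbind(trait = rownames(traitCorrelations(condBlups)),
            as.data.frame(traitCorrelations(condBlups))),
      out(paste0("correlations_", cond, ".tsv"))))
  }
  meaFits <- lapply(traitNames(), function(tr)
    fitTrait(traits, tr, analysis = "mea", method = cfg$remlMethod))
  names(meaFits) <- traitNames()
  for (tr in traitNames())
    report[[length(report) + 1L]] <-
      .fitReportRow(tr, "mea:across", meaFits[[tr]])
  idsM <- names(meaFits[[1L]]@blups)
  germBlups[["across"]] <-
    meaFits[["germ21_pct"]]@fittedMean + meaFits[["germ21_pct"]]@blups[idsM]
  fitReport <- do.call(rbind, report)
  paths <- c(paths, .writeTSV(fitReport, out("fit_report.tsv")))

  # -- stage: GEBVs, index, donors ----------------------------------------
  donorLists <- list()
  gebvTables <- list()
  for (env in c("anaerobic", "aerobic", "across")) {
    if (env != "across" && !env %in% conditions) next
    g <- gblupGEBVs(traits, grm, environment = env,
                    method = cfg$remlMethod)
    gebvTables[[env]] <- g
    gs <- if (cfg$standardize) standardizeGEBVs(g) else g
    idx <- suppressWarnings(selectionIndex(gs, cfg$weights))
    rule <- cfg$rules[[env]]
    donorLists[[env]] <- selectDonors(
      idx, germBlups[[env]], rule = env,
      indexMin = rule[["index_min"]], germMin = rule[["germ_min"]],
      checks = checks)
    paths <- c(paths, .writeTSV(
      cbind(genotype = rownames(g@values), as.data.frame(g@values)),
      out(paste0("gebvs_", env, ".tsv"))))
  }
  paths <- c(paths, donorReport(donorLists, cfg$outDir))

  # -- stage: manifest -----------------------------------------------------
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  .writeTSV(manifest, out("manifest.tsv"))
  invisible(list(donorLists = donorLists, gebvTables = gebvTables,
                 fitReport = fitReport, manifest = manifest,
                 paths = c(paths, out("manifest.tsv"))))
}
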
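#' Genomic estimated breeding values by GBLUP
#'
#' Fits the screening mixed model per trait with the genomic relationship
#' matrix as genotype covariance and reports each genotype's breeding
#' value recentred by the model's grand fitted mean (the intercept plus
#' the average fixed-level effects), so germination GEBVs live on the
#' 0--100% scale whatever the reference coding. The evaluation environment selects the data layer:
#' \code{"anaerobic"} and \code{"aerobic"} analyse the two experiments of
#' that condition jointly (experiment as the fixed environment term);
#' \code{"across"} fits the multi-environment model over all experiment x
#' condition cells.
#'
#' Phenotyped genotypes must be covered by the relationship matrix: up to
#' 10% uncovered genotypes are excluded with a message, more is an error.
#'
#' @param table long trait table ([plotsToTraitTable()]).
#' @param grm a [GenomicRelationshipMatrix-class].
#' @param environment \code{"anaerobic"}, \code{"aerobic"} or
#'   \code{"across"}.
#' @param traits trait ids to evaluate (default all eight).
#' @param method REML method, see [remlFit()].
#' @return A [GEBVTable-class] over the relationship-matrix genotypes.
#' @export
gblupGEBVs <- function(table, grm, environment = c("anaerobic", "aerobic",
                                                   "across"),
                       traits = traitNames(), method = "profile") {
  environment <- match.arg(environment)
  stopifnot(is(grm, "GenomicRelationshipMatrix"))
  ids <- rownames(grm@values)
  pheno <- unique(table$genotype)
  uncovered <- setdiff(pheno, ids)
  if (length(uncovered) > 0.10 * length(pheno))
    stop("panel/phenotype mismatch: relationship matrix misses ",
         length(uncovered), " of ", length(pheno), " phenotyped genotypes")
  if (length(uncovered)) {
    message(length(uncovered),
            " phenotyped genotype(s) absent from the relationship matrix; excluded")
    table <- table[!table$genotype %in% uncovered, , drop = FALSE]
  }
  condition <- if (environment == "across") NULL else environment
  vals <- matrix(NA_real_, length(ids), length(traits),
                 dimnames = list(ids, traits))
  intercepts <- stats::setNames(numeric(length(traits)), traits)
  for (tr in traits) {
    fit <- fitTrait(table, tr, condition = condition, analysis = "mea",
                    K = grm, method = method)
    b0 <- fit@fittedMean
    intercepts[tr] <- b0
    vals[names(fit@blups), tr] <- b0 + fit@blups
  }
  new("GEBVTable", environment = environment, values = vals,
      standardized = FALSE, intercepts = intercepts,
      zeroVarianceTraits = character())
}

#' Standardise a GEBV table per trait
#'
#' Centres and scales each trait column over genotypes (mean 0, SD 1)
#' within the evaluation environment, the usual preparation before
#' applying economic weights so traits with different units contribute
#' comparably. Zero-variance columns become all zeros and are flagged.
#'
#' @param g a [GEBVTable-class] with at least 2 genotypes.
#' @return A standardised [GEBVTable-class]; already-standardised input is
#'   returned unchanged (the operation is idempotent).
#' @export
standardizeGEBVs <- function(g) {
  stopifnot(is(g, "GEBVTable"))
  v <- g@values
  if (nrow(v) < 2L) stop("standardisation needs at least 2 genotypes")
  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2L, stats::sd, na.rm = TRUE)
  zero <- !is.na(sdv) & sdv < 1e-12
  out <- sweep(v, 2L, mu)
  out[, !zero] <- sweep(out[, !zero, drop = FALSE], 2L, sdv[!zero], `/`)
  out[, zero] <- 0
  res <- g
  res@values <- out
  res@standardized <- TRUE
  res@zeroVarianceTraits <- union(g@zeroVarianceTraits, colnames(v)[zero])
  res
}

#' Weighted selection index over the eight traits
#'
#' \deqn{I_g = \sum_i b_i x_{gi}} over the weighted traits, where
#' \eqn{x_{gi}} are (standardised) GEBVs and \eqn{b_i} the relative
#' economic weights. Traits absent from the weight map contribute
#' nothing; a genotype missing any weighted trait value gets a missing
#' index rather than a silently partial sum.
#'
#' @param g a [GEBVTable-class], normally standardised first (a warning is
#'   issued otherwise, since raw trait scales are incommensurable).
#' @param weights named nonnegative weights (default
#'   [defaultIndexWeights()]); all-zero weights yield all-zero indices.
#' @return Named numeric vector of selection indices per genotype.
#' @export
selectionIndex <- function(g, weights = defaultIndexWeights()) {
  stopifnot(is(g, "GEBVTable"))
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (!g@standardized)
    warning("GEBV table is not standardised; weights apply to raw trait scales")
  use <- intersect(names(weights), colnames(g@values))
  idx <- drop(g@values[, use, drop = FALSE] %*% weights[use])
  names(idx) <- rownames(g@values)
  idx
}

#' Select donor genotypes under a threshold rule
#'
#' Keeps genotypes whose selection index reaches \code{indexMin} AND whose
#' phenotypic germination-21-DAS BLUP reaches \code{germMin}, sorted by
#' index descending (ties: germination descending, then genotype id).
#' Checks are flagged but retained. An empty result is a valid list.
#'
#' @param index named selection indices ([selectionIndex()]).
#' @param germ21Blups named germination-21-DAS BLUPs on the percent scale
#'   (phenotypic, intercept-recentred).
#' @param rule \code{"anaerobic"}, \code{"aerobic"} or \code{"across"};
#'   supplies default thresholds ([defaultSelectionRules()]).
#' @param indexMin,germMin threshold overrides.
#' @param checks genotype ids to flag as checks.
#' @return A [DonorList-class].
#' @examples
#' idx <- c(A = 30, B = 20, C = 28)
#' germ <- c(A = 75, B = 90, C = 60)
#' selectDonors(idx, germ, "anaerobic")  # A only
#' @export
selectDonors <- function(index, germ21Blups, rule = c("anaerobic", "aerobic",
                                                      "across"),
                         indexMin = NULL, germMin = NULL,
                         checks = character()) {
  rule <- match.arg(rule)
  defaults <- .DEFAULT_SELECTION_RULES[[rule]]
  if (is.null(indexMin)) indexMin <- defaults[["index_min"]]
  if (is.null(germMin)) germMin <- defaults[["germ_min"]]
  ids <- as.character(intersect(names(index), names(germ21Blups)))
  idx <- index[ids]
  germ <- germ21Blups[ids]
  keep <- !is.na(idx) & !is.na(germ) & idx >= indexMin & germ >= germMin
  tb <- data.frame(genotype = ids[keep],
                   selection_index = unname(idx[keep]),
                   germ21_blup = unname(germ[keep]),
                   is_check = ids[keep] %in% checks,
                   stringsAsFactors = FALSE)
  ord <- order(-tb$selection_index, -tb$germ21_blup, tb$genotype)
  tb <- tb[ord, , drop = FALSE]
  rownames(tb) <- NULL
  new("DonorList", rule = rule, table = tb, indexMin = indexMin,
      germMin = germMin)
}

#' Write donor-list report files
#'
#' One TSV per selection rule with columns \code{Genotype},
#' \code{Condition}, \code{SelectionIndex}, \code{Germination21DAS},
#' \code{Remarks} (Entry/Check), plus a combined \code{donors_summary.tsv}
#' with per-rule entry and check counts. Re-running on identical inputs
#' reproduces byte-identical files.
#'
#' @param lists list of [DonorList-class] objects (typically one per rule).
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
donorReport <- function(lists, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  summary <- list()
  for (dl in lists) {
    tb <- dl@table
    out <- data.frame(Genotype = tb$genotype,
                      Condition = dl@rule,
                      SelectionIndex = sprintf("%.2f", tb$selection_index),
                      Germination21DAS = sprintf("%.1f", tb$germ21_blup),
                      Remarks = ifelse(tb$is_check, "Check", "Entry"),
                      stringsAsFactors = FALSE)
    path <- file.path(dir, paste0("donors_", dl@rule, ".tsv"))
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, path)
    summary[[dl@rule]] <- data.frame(
      rule = dl@rule, entries = sum(!tb$is_check), checks = sum(tb$is_check),
      index_min = dl@indexMin, germ_min = dl@germMin,
      stringsAsFactors = FALSE)
  }
  spath <- file.path(dir, "donors_summary.tsv")
  utils::write.table(do.call(rbind, summary), spath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(paths, spath))
}
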
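#' Percentage germination of a plot
#'
#' Percentage germination (survival): the number of seedlings that emerged
#' above the water surface divided by the seeds sown, times 100.
#'
#' @param germinated count of germinated (emerged) seeds; may be a vector.
#' @param sown count of seeds sown; recycled against \code{germinated}.
#' @return Numeric percentage(s) in [0, 100].
#' @examples
#' percentGermination(24, 30)  # 80
#' @export
percentGermination <- function(germinated, sown) {
  if (any(sown <= 0)) stop("undefined denominator: seeds sown must be positive")
  if (any(germinated < 0)) stop("input error: germinated count is negative")
  if (any(germinated > sown))
    stop("input error: germinated count exceeds seeds sown")
  germinated * 100 / sown
}

#' Convert plot records to a long-format trait table
#'
#' Derives the two germination percentages from the raw counts and
#' reshapes the eight traits to long format, one record per plot per
#' trait. Missing measurements are kept as NA values.
#'
#' @param records plot-record data.frame in the package's phenotype
#'   dialect (see [simulatePhenotypes()] for the columns).
#' @return A data.frame with columns \code{experiment}, \code{condition},
#'   \code{replication}, \code{block}, \code{genotype}, \code{trait},
#'   \code{value}; traits are the ids of [traitNames()].
#' @export
plotsToTraitTable <- function(records) {
  need <- c("experiment", "condition", "replication", "block", "genotype",
            "seeds_sown", "germ14_count", "germ21_count", "height14_cm",
            "height21_cm", "culm_mm", "rootlen_cm", "shootdm_g", "rootdm_g")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("plot records lack columns: ", paste(miss, collapse = ", "))
  vals <- cbind(
    germ14_pct = percentGermination(records$germ14_count, records$seeds_sown),
    germ21_pct = percentGermination(records$germ21_count, records$seeds_sown),
    height14 = records$height14_cm, height21 = records$height21_cm,
    culm = records$culm_mm, rootlen = records$rootlen_cm,
    shootdm = records$shootdm_g, rootdm = records$rootdm_g)
  keys <- records[c("experiment", "condition", "replication", "block",
                    "genotype")]
  out <- do.call(rbind, lapply(.TRAITS, function(tr) {
    cbind(keys, trait = tr, value = vals[, tr], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Studentized conditional residuals from the screening mixed model
# (replication + blocks fixed, genotype random) with Bonferroni-adjusted
# two-sided p-values. Random genotype matters: with two replicates a
# fixed-genotype residual cannot tell the aberrant plot from its partner,
# while shrinkage borrows strength across the trial and points at the
# shifted observation.
.studentizedScreen <- function(dat) {
  # term-dropping warnings are irrelevant while screening residuals
  des <- suppressWarnings(buildDesign(dat, analysis = "sea"))
  n <- length(des$y)
  if (n - ncol(des$X) < 5L) return(NULL)
  vc <- remlFit(des$X, des$Z, des$y)
  s2g <- max(vc@sigma2g, 1e-10)
  lambda <- vc@sigma2e / s2g
  W <- cbind(des$X, des$Z)
  q <- ncol(des$Z)
  C <- crossprod(W)
  ui <- ncol(des$X) + seq_len(q)
  C[ui, ui] <- C[ui, ui] + lambda * diag(q)
  Cinv <- chol2inv(chol(C))
  theta <- drop(Cinv %*% crossprod(W, des$y))
  e <- des$y - drop(W %*% theta)
  h <- rowSums((W %*% Cinv) * W)
  t <- e / sqrt(vc@sigma2e * pmax(1 - h, 1e-8))
  p <- 2 * stats::pnorm(-abs(t))
  list(t = t, p_bonf = pmin(p * n, 1))
}

#' Bonferroni outlier screen on a trait table
#'
#' Per experiment x condition x trait, fits the screening mixed model
#' (replication and blocks-within-replication fixed, genotype random),
#' computes studentized conditional residuals and flags the observation
#' with the smallest Bonferroni-adjusted two-sided p-value; if it falls
#' below \code{alpha} the observation is removed and the model refitted,
#' iterating worst-first until nothing is flagged. Genotype enters as a
#' random (shrunken) effect so that with few replicates the screen can
#' attribute an aberrant value to the plot that carries it rather than
#' splitting it with the genotype's other plots. Groups with too little
#' residual information are skipped with a warning.
#'
#' @param table long-format trait table from [plotsToTraitTable()].
#' @param alpha family-wise significance level (default 0.05); 0 disables
#'   filtering.
#' @param maxIter cap on removals per group.
#' @return A list with elements \code{table} (cleaned) and
#'   \code{outliers} (data.frame of removed records with the studentized
#'   residual and adjusted p-value).
#' @export
bonferroniOutlierFilter <- function(table, alpha = 0.05, maxIter = 50L) {
  removed <- list()
  if (alpha <= 0) {
    return(list(table = table,
                outliers = cbind(table[0, ],
                                 statistic = numeric(), p_bonferroni = numeric())))
  }
  grp <- interaction(table$experiment, table$condition, table$trait,
                     drop = TRUE)
  keep <- rep(TRUE, nrow(table))
  for (g in levels(grp)) {
    idx <- which(grp == g & !is.na(table$value))
    for (iter in seq_len(maxIter)) {
      dat <- table[idx, ]
      scr <- tryCatch(.studentizedScreen(dat), error = function(e) NULL)
      if (is.null(scr)) {
        if (iter == 1L)
          warning("outlier screen skipped for group ", g,
                  ": too few residual degrees of freedom")
        break
      }
      worst <- which.min(scr$p_bonf)
      if (!length(worst) || is.na(scr$p_bonf[worst]) ||
          scr$p_bonf[worst] >= alpha) break
      row <- idx[worst]  # rstudent() order follows row order within dat
      removed[[length(removed) + 1L]] <-
        cbind(table[row, , drop = FALSE],
              statistic = unname(scr$t[worst]),
              p_bonferroni = unname(scr$p_bonf[worst]))
      keep[row] <- FALSE
      idx <- idx[-worst]
    }
  }
  outliers <- if (length(removed)) do.call(rbind, removed)
              else cbind(table[0, ], statistic = numeric(),
                         p_bonferroni = numeric())
  rownames(outliers) <- NULL
  list(table = table[keep, , drop = FALSE], outliers = outliers)
}

#' Percentage reduction of a trait mean under stress
#'
#' @param control trait mean under the control (aerobic) condition.
#' @param stressed trait mean under the stress (anaerobic) condition.
#' @return \code{(control - stressed) / control * 100}; NA with a warning
#'   when the control mean is zero. Negative values (stress benefit) are
#'   reported as-is.
#' @examples
#' percentReduction(0.071, 0.025)  # shoot dry matter, about 64.8
#' @export
percentReduction <- function(control, stressed) {
  out <- (control - stressed) / control * 100
  if (any(control == 0)) {
    warning("control mean of zero: reduction undefined")
    out[control == 0] <- NA_real_
  }
  out
}

#' Stress impact: per-trait percentage reductions under anaerobic stress
#'
#' Computes genotype-level means per condition, averages them per trait,
#' and reports the percentage reduction of the anaerobic mean relative to
#' the aerobic mean.
#'
#' @param table long-format trait table with both conditions present.
#' @param stress,control condition labels (defaults \code{"anaerobic"},
#'   \code{"aerobic"}).
#' @return A data.frame with columns \code{trait}, \code{mean_control},
#'   \code{mean_stress}, \code{reduction_pct} (NA and flagged via warning
#'   when the control mean is zero).
#' @export
stressImpact <- function(table, stress = "anaerobic", control = "aerobic") {
  sub <- table[table$condition %in% c(stress, control) & !is.na(table$value), ]
  gm <- stats::aggregate(value ~ trait + condition + genotype, data = sub,
                         FUN = mean)
  tm <- stats::aggregate(value ~ trait + condition, data = gm, FUN = mean)
  traits <- intersect(.TRAITS, unique(tm$trait))
  mc <- tm$value[match(paste(traits, control), paste(tm$trait, tm$condition))]
  ms <- tm$value[match(paste(traits, stress), paste(tm$trait, tm$condition))]
  data.frame(trait = traits, mean_control = mc, mean_stress = ms,
             reduction_pct = percentReduction(mc, ms),
             stringsAsFactors = FALSE)
}

#' Pearson correlations between traits on genotype-level values
#'
#' Pairwise-complete Pearson correlations between trait columns (typically
#' per-genotype BLUPs). Pairs with fewer than 3 complete observations are
#' reported as NA; the diagonal is exactly 1.
#'
#' @param blupMatrix genotype-by-trait numeric matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
traitCorrelations <- function(blupMatrix) {
  m <- as.matrix(blupMatrix)
  k <- ncol(m)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  complete <- crossprod(!is.na(m))  # pairwise complete counts
  r[complete < 3] <- NA_real_
  diag(r) <- 1
  r
}
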
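make_trial_tables <- function(seed = 61L, ...) {
  trial <- simulateTrial(small_config(seed, ...))
  list(trial = trial, tt = plotsToTraitTable(trial$phenotypes))
}

test_that("identity covariance reduces GEBVs to recentred phenotypic BLUPs", {
  w <- make_trial_tables()
  ids <- sort(unique(w$tt$genotype))
  Ident <- diag(length(ids))
  dimnames(Ident) <- list(ids, ids)
  gid <- new("GenomicRelationshipMatrix", values = Ident, denominator = 1,
             ridge = 0)
  g <- gblupGEBVs(w$tt, gid, environment = "anaerobic",
                  traits = "germ14_pct")
  fit <- fitTrait(w$tt, "germ14_pct", condition = "anaerobic",
                  analysis = "mea")
  expect_equal(gebvs(g)[names(blups(fit)), "germ14_pct"],
               fit@fittedMean + blups(fit), tolerance = 1e-8)
})

test_that("GBLUP equals RR-BLUP marker-effect predictions on small instances", {
  # kinship centred by the generating frequencies (full rank, so the
  # mixed-model-equation route is exact); the oracle uses the same
  # centring, making the two prediction routes algebraically equivalent
  for (s in 1:5) {
    set.seed(s)
    q <- 8L; m <- 40L; reps <- 3L
    gen <- paste0("g", 1:q)
    p <- runif(m, 0.1, 0.9)
    dos <- matrix(rbinom(q * m, 2, rep(p, each = q)),
                  q, m, dimnames = list(gen, paste0("mk", 1:m)))
    Zc <- sweep(dos, 2, 2 * p)
    denom <- 2 * sum(p * (1 - p))
    K <- tcrossprod(Zc) / denom
    n <- q * reps
    X <- cbind(1, rnorm(n))
    Z <- matrix(0, n, q, dimnames = list(NULL, gen))
    Z[cbind(1:n, rep(1:q, reps))] <- 1
    y <- drop(X %*% c(5, 1)) + rnorm(n, sd = 2)
    s2g <- 2; s2e <- 1
    vc <- new("VarianceComponents", sigma2g = s2g, sigma2e = s2e,
              convergence = "converged", nIterations = 1L, loglikTrace = 0,
              method = "profile")
    fit <- solveMME(X, Z, y, K = K, varcomp = vc)
    expect_equal(unname(blups(fit)),
                 unname(oracle_rrblup(X, Z, y, dos, s2g, s2e, p = p)),
                 tolerance = 1e-8)
  }
})

test_that("GEBVs track true breeding values on a simulated panel", {
  w <- make_trial_tables(62L)
  grm <- computeGRM(imputeMissing(w$trial$markers))
  g <- gblupGEBVs(w$tt, grm, environment = "anaerobic",
                  traits = "germ14_pct")
  tbv <- w$trial$genetics$tbv
  r <- cor(gebvs(g)[rownames(tbv), "germ14_pct"], tbv[, "germ14_pct"])
  expect_gt(r, 0.45)
  # mismatched panel: losing >10% of phenotyped genotypes is a hard error
  keep <- rownames(grmValues(grm))[1:40]
  small <- new("GenomicRelationshipMatrix",
               values = grmValues(grm)[keep, keep],
               denominator = grm@denominator, ridge = grm@ridge)
  expect_error(gblupGEBVs(w$tt, small, environment = "anaerobic",
                          traits = "germ14_pct"), "mismatch")
})

test_that("standardisation is exact, idempotent and flags degenerate traits", {
  set.seed(4)
  v <- cbind(germ14_pct = rnorm(20, 50, 10), culm = rep(1.7, 20))
  rownames(v) <- paste0("g", 1:20)
  g <- new("GEBVTable", environment = "anaerobic", values = v,
           standardized = FALSE,
           intercepts = c(germ14_pct = 50, culm = 1.7),
           zeroVarianceTraits = character())
  s <- standardizeGEBVs(g)
  expect_equal(unname(colMeans(gebvs(s))), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(sd(gebvs(s)[, 1])), 1, tolerance = 1e-10)
  expect_true(all(gebvs(s)[, "culm"] == 0))
  expect_equal(s@zeroVarianceTraits, "culm")
  s2 <- standardizeGEBVs(s)
  expect_equal(gebvs(s2)[, "germ14_pct"], gebvs(s)[, "germ14_pct"],
               tolerance = 1e-10)
  expect_error(standardizeGEBVs(
    new("GEBVTable", environment = "anaerobic", values = v[1, , drop = FALSE],
        standardized = FALSE, intercepts = numeric(),
        zeroVarianceTraits = character())), "2 genotypes")
})

test_that("the selection index is the weighted sum of standardised values", {
  set.seed(9)
  v <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("g", 1:5), traitNames()))
  g <- new("GEBVTable", environment = "anaerobic", values = v,
           standardized = TRUE,
           intercepts = setNames(numeric(8), traitNames()),
           zeroVarianceTraits = character())
  w <- defaultIndexWeights()
  idx <- selectionIndex(g, w)
  # brute-force per-genotype weighted sums
  manual <- sapply(rownames(v), function(gt)
    sum(sapply(names(w), function(tr) w[[tr]] * v[gt, tr])))
  expect_equal(idx, manual, tolerance = 1e-12)
  expect_equal(unname(selectionIndex(g, c(germ14_pct = 1))),
               unname(v[, "germ14_pct"]))
  expect_equal(unname(selectionIndex(g, setNames(rep(0, 8), traitNames()))),
               rep(0, 5))
  # a genotype missing a weighted trait gets a missing index
  v2 <- v; v2[2, "culm"] <- NA
  g2 <- g; g2@values <- v2
  idx2 <- selectionIndex(g2, w)
  expect_true(is.na(idx2["g2"]) && !anyNA(idx2[-2]))
  # standardisation absorbs constant trait shifts
  g3 <- g
  g3@standardized <- FALSE
  g4 <- g3
  g4@values[, "germ14_pct"] <- g4@values[, "germ14_pct"] + 50
  expect_equal(selectionIndex(standardizeGEBVs(g3), w),
               selectionIndex(standardizeGEBVs(g4), w), tolerance = 1e-10)
})

test_that("donor selection enforces both thresholds, ordering and check flags", {
  idx <- c(A = 30, B = 24.9, C = 28, D = 28, E = 40)
  germ <- c(A = 75, B = 95, C = 80, D = 71, E = 60)
  dl <- selectDonors(idx, germ, rule = "anaerobic", checks = "C")
  tb <- donorTable(dl)
  expect_equal(tb$genotype, c("E", "A", "C", "D")[-1])  # E fails germination
  expect_true(tb$is_check[tb$genotype == "C"])
  # strict conjunction: B (index 24.9, germ 95) is excluded
  expect_false("B" %in% tb$genotype)
  # ties broken by germination then id
  expect_equal(tb$genotype[tb$selection_index == 28], c("C", "D"))
  # raising thresholds never adds genotypes
  dl2 <- selectDonors(idx, germ, rule = "anaerobic", indexMin = 28,
                      germMin = 75)
  expect_true(all(donorTable(dl2)$genotype %in% tb$genotype))
  # empty input is a valid empty list
  expect_equal(nrow(donorTable(
    selectDonors(numeric(), numeric(), rule = "aerobic"))), 0L)
})

test_that("donor reports are written deterministically with Entry/Check remarks", {
  idx <- c(A = 30, C = 28)
  germ <- c(A = 75, C = 80)
  dl <- selectDonors(idx, germ, rule = "anaerobic", checks = "C")
  d1 <- tempfile(); d2 <- tempfile()
  donorReport(list(dl), d1)
  donorReport(list(dl), d2)
  f1 <- readLines(file.path(d1, "donors_anaerobic.tsv"))
  expect_identical(f1, readLines(file.path(d2, "donors_anaerobic.tsv")))
  expect_equal(length(f1), nrow(donorTable(dl)) + 1L)
  expect_true(any(grepl("C\tanaerobic\t.*Check$", f1)))
})
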
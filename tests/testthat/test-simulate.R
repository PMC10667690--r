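test_that("marker simulation is deterministic, respects missingness, and hits the expected MAF", {
  cfg <- simConfig(rngSeed = 101L)
  m1 <- simulateMarkers(cfg)
  m2 <- simulateMarkers(cfg)
  expect_identical(dosages(m1), dosages(m2))
  expect_false(anyNA(dosages(m1)))  # missingRate = 0

  cfgNA <- simConfig(rngSeed = 101L, missingRate = 0.05)
  expect_true(anyNA(dosages(simulateMarkers(cfgNA))))

  # mean minor-allele frequency under p ~ U(0.05, 0.95), against a
  # Monte-Carlo evaluation of E[min(p, 1-p)]
  p <- alleleFrequencies(m1)
  maf <- mean(pmin(p, 1 - p))
  set.seed(1)
  u <- runif(2e5, 0.05, 0.95)
  expect_lt(abs(maf - mean(pmin(u, 1 - u))), 0.03)
  expect_gt(maf, 0.20)
  expect_lt(maf, 0.30)
})

test_that("simulated panel heterozygosity matches the inbreeding coefficient", {
  m <- simulateMarkers(simConfig(rngSeed = 5L))
  het <- mean(dosages(m) == 1)
  # (1 - F) * 2 E[p(1-p)] with F = 0.95, p ~ U(0.05, 0.95)
  set.seed(2)
  u <- runif(2e5, 0.05, 0.95)
  expect_lt(abs(het - 0.05 * mean(2 * u * (1 - u))), 0.005)
})

test_that("breeding values honour correlation, heritability and marker determinism", {
  # identity genetic correlation -> near-zero TBV cross-correlations
  traits <- traitNames()
  offdiag <- replicate(10, {
    cfg <- simConfig(rngSeed = sample.int(1e6, 1),
                     geneticCorrelation = diag(8) |>
                       (\(x) {dimnames(x) <- list(traits, traits); x})())
    g <- simulateBreedingValues(simulateMarkers(cfg), cfg)
    r <- cor(g$tbv)
    r[upper.tri(r)]
  })
  expect_lt(max(abs(rowMeans(offdiag))), 0.15)

  # zero heritability -> all-zero TBV column; configured variance recovered
  cfg <- simConfig(rngSeed = 42L, traitHeritabilities = c(culm = 0))
  g <- simulateBreedingValues(simulateMarkers(cfg), cfg)
  expect_true(all(g$tbv[, "culm"] == 0))
  expect_equal(unname(apply(g$tbv[, c("germ14_pct", "height21")], 2, sd)),
               unname(cfg@geneticSD[c("germ14_pct", "height21")]),
               tolerance = 1e-10)
  expect_equal(unname(colMeans(g$tbv)), rep(0, 8), tolerance = 1e-10)

  # identical marker rows -> identical TBV rows
  m <- simulateMarkers(cfg)
  d <- dosages(m)
  d["ENT002", ] <- d["ENT001", ]
  g2 <- simulateBreedingValues(markerMatrix(d), cfg)
  expect_equal(g2$tbv["ENT001", ], g2$tbv["ENT002", ])
})

test_that("trial designs satisfy the lattice replication structure", {
  cfg <- simConfig(rngSeed = 9L)
  des <- generateTrialDesign(cfg)
  one <- des[des$experiment == "exp1" & des$condition == "anaerobic" &
               des$replication == "R1", ]
  expect_equal(nrow(one), 224L)
  counts <- table(one$genotype)
  expect_true(all(counts[sprintf("ENT%03d", 1:200)] == 1L))
  expect_true(all(counts[checkIds(cfg)] == 3L))
  expect_true(all(table(paste(des$experiment, des$condition,
                              des$replication, des$block)) == 14L))

  # no-check design: every genotype exactly once per replication
  cfg0 <- simConfig(nEntries = 224L, nChecks = 0L, checkReps = 3L,
                    rngSeed = 2L)
  des0 <- generateTrialDesign(cfg0)
  one0 <- des0[des0$experiment == "exp1" & des0$condition == "anaerobic" &
                 des0$replication == "R1", ]
  expect_true(all(table(one0$genotype) == 1L))

  # violated identity reports the arithmetic
  expect_error(simConfig(nEntries = 199L), "199")
})

test_that("phenotypes reduce to mean + TBV in the noiseless limit and counts stay valid", {
  h1 <- setNames(rep(1, 8), traitNames())
  cfg <- simConfig(nEntries = 48L, nChecks = 4L, checkReps = 3L,
                   blocksPerReplication = 6L, plotsPerBlock = 10L,
                   nMarkers = 100L, traitHeritabilities = h1,
                   blockVariance = 0, replicationEffectSize = 0,
                   environmentEffectSize = 0, rngSeed = 7L)
  trial <- simulateTrial(cfg)
  ph <- trial$phenotypes
  expected <- cfg@traitMeans["height14", ph$condition] +
    trial$genetics$tbv[ph$genotype, "height14"]
  expect_equal(ph$height14_cm, unname(pmax(expected, 0)), tolerance = 1e-10)

  counts <- c(ph$germ14_count, ph$germ21_count)
  expect_true(all(counts >= 0 & counts <= cfg@seedsPerPlot))
  expect_true(all(counts == round(counts)))

  # unknown genotype in design is rejected
  bad <- trial$design
  bad$genotype[1] <- "NOPE"
  expect_error(simulatePhenotypes(bad, trial$genetics, cfg), "NOPE")
})

test_that("flooded 14-DAS germination stays anchored to the study mean", {
  means <- vapply(1:20, function(s) {
    trial <- simulateTrial(simConfig(rngSeed = 1000L + s))
    ph <- trial$phenotypes
    mean(percentGermination(
      ph$germ14_count[ph$condition == "anaerobic"], ph$seeds_sown[1]))
  }, numeric(1))
  expect_lt(abs(mean(means) - 29.4), 5)
})

test_that("fixture writers are deterministic byte for byte", {
  trial <- simulateTrial(small_config(31L))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writePhenotypeCSV(trial$phenotypes, f1)
  writePhenotypeCSV(trial$phenotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
  m1 <- tempfile(); writeDosageCSV(trial$markers, m1)
  back <- readDosageCSV(m1)
  expect_equal(dosages(back), dosages(trial$markers))
})
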
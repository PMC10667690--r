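test_that("design matrices have the declared shapes and nesting", {
  tb <- data.frame(experiment = "e1", condition = "anaerobic",
                   replication = rep(c("R1", "R2"), each = 3),
                   block = "B1", genotype = rep(paste0("g", 1:3), 2),
                   trait = "height14", value = rnorm(6))
  des <- buildDesign(tb, analysis = "sea", blocks = FALSE)
  expect_equal(dim(des$X), c(6L, 2L))
  expect_equal(dim(des$Z), c(6L, 3L))

  # block labels reused across replications yield distinct nested columns
  tb2 <- expand.grid(replication = c("R1", "R2"), block = c("B1", "B2"),
                     genotype = paste0("g", 1:4), stringsAsFactors = FALSE)
  tb2$value <- rnorm(nrow(tb2))
  des2 <- buildDesign(tb2, analysis = "sea")
  expect_equal(qr(des2$X)$rank, ncol(des2$X))  # full rank after aliasing
  expect_equal(ncol(des2$X), 4L)  # intercept + 3 df for rep/block nesting
  expect_true(any(grepl("R2:B", colnames(des2$X))))

  # two environments produce exactly one environment contrast
  tb3 <- tb2
  tb3$environment <- rep(c("anaerobic", "aerobic"), length.out = nrow(tb3))
  des3 <- buildDesign(tb3, analysis = "mea", blocks = FALSE)
  expect_equal(sum(grepl("^env", colnames(des3$X))), 1L)

  # missing responses are dropped and counted
  tb2$value[3] <- NA
  expect_equal(buildDesign(tb2, analysis = "sea")$nDropped, 1L)
  # single-level factors are dropped with a warning, not an error
  expect_warning(buildDesign(tb[tb$replication == "R1", ], analysis = "sea",
                             blocks = FALSE), "single level")
})

test_that("the MME solution equals the dense GLS oracle on random instances", {
  for (s in 1:20) {
    inst <- random_instance(s, withK = s %% 2 == 0)
    vc <- new("VarianceComponents", sigma2g = inst$s2g, sigma2e = inst$s2e,
              convergence = "converged", nIterations = 1L, loglikTrace = 0,
              method = "profile")
    fit <- solveMME(inst$X, inst$Z, inst$y, K = inst$K, varcomp = vc)
    oracle <- oracle_gls(inst$X, inst$Z, inst$y, inst$K, inst$s2g, inst$s2e)
    expect_equal(unname(fixedEffects(fit)), unname(oracle$beta),
                 tolerance = 1e-8)
    expect_equal(unname(blups(fit)), unname(oracle$u), tolerance = 1e-8)
  }
})

test_that("balanced identity-covariance BLUPs equal the closed-form shrinkage", {
  set.seed(7)
  q <- 5L; nrep <- 4L
  gen <- paste0("g", 1:q)
  Z <- matrix(0, q * nrep, q, dimnames = list(NULL, gen))
  Z[cbind(seq_len(q * nrep), rep(1:q, nrep))] <- 1
  X <- matrix(1, q * nrep, 1, dimnames = list(NULL, "(Intercept)"))
  y <- drop(Z %*% rnorm(q, sd = 2)) + rnorm(q * nrep)
  s2g <- 4; s2e <- 1
  vc <- new("VarianceComponents", sigma2g = s2g, sigma2e = s2e,
            convergence = "converged", nIterations = 1L, loglikTrace = 0,
            method = "profile")
  fit <- solveMME(X, Z, y, varcomp = vc)
  gm <- as.numeric(tapply(y, rep(gen, nrep), mean)[gen])
  shrink <- nrep * s2g / (nrep * s2g + s2e)
  expect_equal(unname(blups(fit)), shrink * (gm - mean(y)),
               tolerance = 1e-10)
  # balanced identity-covariance BLUPs average to zero
  expect_lt(abs(mean(blups(fit))), 1e-6)
  # shrinkage bound: PEV never exceeds the genetic variance
  expect_true(all(pev(fit) <= s2g + 1e-10))
  # PEV matches the dense projection-matrix oracle
  expect_equal(unname(pev(fit)),
               unname(oracle_pev(X, Z, diag(q), s2g, s2e)),
               tolerance = 1e-8)
})

test_that("reliability approaches the closed-form shrinkage for panel-sized trials", {
  # MME prediction error includes intercept uncertainty, so reliability
  # sits slightly below n s2g / (n s2g + s2e) and converges to it as the
  # panel grows
  set.seed(17)
  q <- 100L; nrep <- 4L
  Z <- matrix(0, q * nrep, q, dimnames = list(NULL, paste0("g", 1:q)))
  Z[cbind(seq_len(q * nrep), rep(1:q, nrep))] <- 1
  X <- matrix(1, q * nrep, 1, dimnames = list(NULL, "(Intercept)"))
  s2g <- 4; s2e <- 1
  vc <- new("VarianceComponents", sigma2g = s2g, sigma2e = s2e,
            convergence = "converged", nIterations = 1L, loglikTrace = 0,
            method = "profile")
  fit <- solveMME(X, Z, drop(Z %*% rnorm(q, sd = 2)) + rnorm(q * nrep),
                  varcomp = vc)
  shrink <- nrep * s2g / (nrep * s2g + s2e)
  r <- reliability(fit)$perGenotype
  expect_true(all(r <= shrink + 1e-10))
  expect_lt(max(abs(r - shrink)), 0.02)
})

test_that("REML finds the restricted-likelihood optimum (grid oracle)", {
  set.seed(11)
  inst <- random_instance(3, withK = TRUE, q = 4L, reps = 2L)
  vc <- remlFit(inst$X, inst$Z, inst$y, K = inst$K)
  llopt <- remlLoglik(inst$X, inst$Z, inst$y, K = inst$K,
                      sigma2g = vc@sigma2g, sigma2e = vc@sigma2e)
  grid <- matrix(exp(runif(200, log(1e-3), log(50))), ncol = 2)
  llgrid <- apply(grid, 1, function(g)
    remlLoglik(inst$X, inst$Z, inst$y, K = inst$K,
               sigma2g = g[1], sigma2e = g[2]))
  expect_true(all(llopt >= llgrid - 1e-6))
})

test_that("EM-REML agrees with the profiled optimum and its loglik trace is monotone", {
  inst <- random_instance(8, withK = TRUE, q = 8L, reps = 3L)
  vcP <- remlFit(inst$X, inst$Z, inst$y, K = inst$K, method = "profile")
  vcE <- remlFit(inst$X, inst$Z, inst$y, K = inst$K, method = "em",
                 maxIter = 2000L)
  expect_true(all(diff(vcE@loglikTrace) >= -1e-8))
  h2 <- function(vc) vc@sigma2g / (vc@sigma2g + vc@sigma2e)
  expect_equal(h2(vcE), h2(vcP), tolerance = 1e-3)
})

test_that("variance components are recovered in a balanced simulated trial", {
  set.seed(123)
  q <- 200L; nrep <- 2L
  gen <- sprintf("g%03d", 1:q)
  Z <- matrix(0, q * nrep, q, dimnames = list(NULL, gen))
  Z[cbind(seq_len(q * nrep), rep(1:q, nrep))] <- 1
  X <- matrix(1, q * nrep, 1, dimnames = list(NULL, "(Intercept)"))
  est <- t(replicate(20, {
    y <- drop(Z %*% rnorm(q, sd = 2)) + rnorm(q * nrep, sd = 1)
    vc <- remlFit(X, Z, y)
    c(vc@sigma2g, vc@sigma2e)
  }))
  expect_lt(abs(mean(est[, 1]) - 4) / 4, 0.25)
  expect_lt(abs(mean(est[, 2]) - 1) / 1, 0.25)
})

test_that("degenerate and shifted responses behave as contracted", {
  inst <- random_instance(5, withK = FALSE)
  # constant response pins both components at the boundary floor
  vc0 <- remlFit(inst$X, inst$Z, rep(5, length(inst$y)))
  expect_equal(vc0@convergence, "boundary")
  expect_warning(heritability(vc0), "boundary")
  # adding a constant changes the intercept only
  vc1 <- remlFit(inst$X, inst$Z, inst$y)
  fit1 <- solveMME(inst$X, inst$Z, inst$y, varcomp = vc1)
  vc2 <- remlFit(inst$X, inst$Z, inst$y + 100)
  fit2 <- solveMME(inst$X, inst$Z, inst$y + 100, varcomp = vc2)
  expect_equal(vc1@sigma2g, vc2@sigma2g, tolerance = 1e-6)
  expect_equal(vc1@sigma2e, vc2@sigma2e, tolerance = 1e-6)
  expect_equal(blups(fit1), blups(fit2), tolerance = 1e-6)
  expect_equal(fixedEffects(fit2)[["(Intercept)"]] -
                 fixedEffects(fit1)[["(Intercept)"]], 100, tolerance = 1e-6)
})

test_that("shrinkage is monotone in lambda and total at the limit", {
  inst <- random_instance(6, withK = FALSE)
  lambdas <- c(0.1, 1, 10, 100, 1e8)
  mags <- sapply(lambdas, function(l) {
    vc <- new("VarianceComponents", sigma2g = 1, sigma2e = l,
              convergence = "converged", nIterations = 1L, loglikTrace = 0,
              method = "profile")
    abs(blups(solveMME(inst$X, inst$Z, inst$y, varcomp = vc)))
  })
  expect_true(all(diff(t(mags))[, ] <= 1e-10))
  expect_lt(max(mags[, 5]), 1e-5)  # lambda -> Inf drives BLUPs to zero
})

test_that("heritability follows its definition on both bases", {
  vc <- new("VarianceComponents", sigma2g = 2, sigma2e = 2,
            convergence = "converged", nIterations = 1L, loglikTrace = 0,
            method = "profile")
  expect_equal(heritability(vc), 0.5)
  expect_equal(heritability(vc, basis = "entry-mean", nReps = 2), 2 / 3)
  vc0 <- new("VarianceComponents", sigma2g = 0, sigma2e = 2,
             convergence = "converged", nIterations = 1L, loglikTrace = 0,
             method = "profile")
  expect_equal(heritability(vc0), 0)
  expect_warning(r <- reliability(
    solveMME(matrix(1, 4, 1), diag(4), rnorm(4), varcomp = vc0)))
  expect_equal(unname(r$perGenotype), rep(0, 4))
})

test_that("unobserved genotypes carry zero reliability; noiseless fits approach one", {
  set.seed(31)
  q <- 50L
  gen <- paste0("g", seq_len(q))
  n <- 2L * (q - 1L)
  Z <- matrix(0, n, q, dimnames = list(NULL, gen))
  Z[cbind(seq_len(n), rep(seq_len(q - 1L), 2))] <- 1  # last never observed
  X <- matrix(1, n, 1)
  vc <- new("VarianceComponents", sigma2g = 3, sigma2e = 1e-6,
            convergence = "converged", nIterations = 1L, loglikTrace = 0,
            method = "profile")
  r <- reliability(solveMME(X, Z, rnorm(n), varcomp = vc))$perGenotype
  expect_equal(unname(r[q]), 0, tolerance = 1e-6)
  expect_true(all(r[-q] > 0.95))
})

test_that("fitTrait estimates plot-basis heritability near its configured value", {
  trial <- simulateTrial(simConfig(rngSeed = 77L))
  tt <- plotsToTraitTable(trial$phenotypes)
  fit <- fitTrait(tt, "germ14_pct", condition = "anaerobic",
                  experiment = "exp1", analysis = "sea")
  expect_lt(abs(heritability(varianceComponents(fit)) - 0.71), 0.15)
  expect_equal(fit@nObs, 448L)
})
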
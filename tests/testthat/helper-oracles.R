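# Independent oracles kept deliberately naive: they re-derive each
# quantity from its definition (dense algebra, double loops, two-pass
# formulas) and never share code with the implementation they check.

# VanRaden relationships by explicit double loop over genotype pairs.
oracle_grm <- function(d) {
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  n <- nrow(d)
  G <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(ncol(d)))
      s <- s + (d[i, k] - 2 * p[k]) * (d[j, k] - 2 * p[k])
    G[i, j] <- s / denom
  }
  G
}

# Dense GLS / conditional-expectation solution through explicit
# V = s2g Z K Z' + s2e I.
oracle_gls <- function(X, Z, y, K, s2g, s2e) {
  V <- s2g * Z %*% K %*% t(Z) + s2e * diag(length(y))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2g * K %*% t(Z) %*% Vi %*% (y - X %*% beta)
  list(beta = drop(beta), u = drop(u))
}

# Ridge-regression marker-effect predictions (RR-BLUP): the marker-model
# route to GEBVs, with marker-effect variance s2g / denominator. The
# centring frequencies p may be external; they must match the kinship
# being compared against (sample-frequency kinships are singular by
# construction, so exact-equivalence checks centre externally).
oracle_rrblup <- function(X, Z, y, dosages, s2g, s2e,
                          p = colMeans(dosages) / 2) {
  denom <- 2 * sum(p * (1 - p))
  Zc <- sweep(dosages, 2, 2 * p)
  W <- Z %*% Zc               # n x m marker design for the observations
  lambda_a <- s2e / (s2g / denom)
  m <- ncol(W)
  C <- rbind(cbind(t(X) %*% X, t(X) %*% W),
             cbind(t(W) %*% X, t(W) %*% W + lambda_a * diag(m)))
  sol <- solve(C, c(t(X) %*% y, t(W) %*% y))
  alpha <- sol[-(seq_len(ncol(X)))]
  drop(Zc %*% alpha)          # GEBV per panel genotype
}

# Dense prediction-error variance: Var(u-hat - u) through the projection
# matrix P of the marginal model.
oracle_pev <- function(X, Z, K, s2g, s2e) {
  V <- s2g * Z %*% K %*% t(Z) + s2e * diag(nrow(Z))
  Vi <- solve(V)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  G <- s2g * K
  diag(G - G %*% t(Z) %*% P %*% Z %*% G)
}

# Two-pass textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small random mixed-model instance (<= 30 observations).
random_instance <- function(seed, withK = TRUE, q = 6L, reps = 3L) {
  set.seed(seed)
  n <- q * reps
  gen <- paste0("g", seq_len(q))
  X <- cbind(1, rep(c(0, 1), length.out = n))
  colnames(X) <- c("(Intercept)", "x")
  Z <- matrix(0, n, q, dimnames = list(NULL, gen))
  Z[cbind(seq_len(n), rep(seq_len(q), reps))] <- 1
  K <- if (withK) {
    A <- matrix(rnorm(q * 2 * q), q)
    K <- tcrossprod(A) / (2 * q) + diag(q) * 0.2
    dimnames(K) <- list(gen, gen)
    K
  } else diag(q)
  s2g <- runif(1, 0.5, 4)
  s2e <- runif(1, 0.5, 2)
  u <- drop(chol(K) %*% rnorm(q)) * sqrt(s2g)
  y <- drop(X %*% c(10, 1) + Z %*% u + rnorm(n, sd = sqrt(s2e)))
  list(X = X, Z = Z, y = y, K = K, s2g = s2g, s2e = s2e, genotypes = gen)
}

# Reduced synthetic study that keeps the lattice identity
# (48 entries + 4 checks x 3 = 6 blocks x 10 plots).
small_config <- function(seed, ...) {
  simConfig(nEntries = 48L, nChecks = 4L, checkReps = 3L,
            blocksPerReplication = 6L, plotsPerBlock = 10L,
            nMarkers = 200L, rngSeed = seed, ...)
}

# Single-trait long table for outlier-screen experiments: one experiment,
# one condition, q genotypes x 2 replications in b blocks.
outlier_table <- function(seed, q = 50L, b = 5L, sigma = 1) {
  set.seed(seed)
  gen <- sprintf("g%02d", seq_len(q))
  per_block <- q / b
  df <- expand.grid(genotype = gen, replication = c("R1", "R2"),
                    stringsAsFactors = FALSE)
  df$experiment <- "exp1"
  df$condition <- "anaerobic"
  df$block <- NA_character_
  for (r in c("R1", "R2")) {
    idx <- which(df$replication == r)
    df$block[idx] <- paste0("B", rep(seq_len(b), each = per_block))[
      order(sample(length(idx)))]
  }
  geno_eff <- rnorm(q, sd = 2)
  names(geno_eff) <- gen
  block_eff <- rnorm(b * 2, sd = 1)
  names(block_eff) <- as.vector(outer(seq_len(b), c("R1", "R2"),
                                      function(b_, r) paste0(r, ":B", b_)))
  df$trait <- "height14"
  df$value <- 20 + geno_eff[df$genotype] +
    block_eff[paste0(df$replication, ":", df$block)] +
    rnorm(nrow(df), sd = sigma)
  df[c("experiment", "condition", "replication", "block", "genotype",
       "trait", "value")]
}
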
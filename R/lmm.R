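# Linear mixed model engine for the screening trials.
#
# Model: y = X beta + Z u + e,  u ~ N(0, sigma2_g K),  e ~ N(0, sigma2_e I).
# Fixed effects are the intercept, replication, blocks-within-replication
# and (for multi-environment analyses) the environment; the genotype is
# the single random term, with identity covariance for phenotypic BLUPs or
# a genomic relationship matrix for GBLUP.

.VAR_FLOOR <- 1e-10

# Drop aliased columns so X has full column rank (reference-level coding
# plus QR pivoting; e.g. replication indicators are spanned by the
# blocks-within-replication indicators).
.fullRank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) return(X)
  X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
}

#' Build design matrices for the screening mixed models
#'
#' Constructs the fixed design matrix X (intercept, optional environment,
#' replication, blocks-within-replication; reference-level coding with
#' aliased columns dropped to full rank), the genotype indicator matrix Z
#' and the response y. Rows with missing response are dropped and
#' counted. Fixed factors with a single level are dropped with a warning.
#'
#' @param table data.frame with columns \code{replication}, \code{block},
#'   \code{genotype}, \code{value}, and \code{environment} when
#'   \code{analysis = "mea"}; restricted to one trait.
#' @param analysis \code{"sea"} (single experiment: no environment term)
#'   or \code{"mea"} (adds the fixed environment contrast; blocks are
#'   nested within replication within environment).
#' @param genotypes genotype levels defining the columns of Z (defaults to
#'   the sorted observed genotypes; pass the relationship-matrix ids for
#'   genomic evaluation).
#' @param blocks include the blocks-within-replication fixed term
#'   (default TRUE, as the models declare).
#' @return A list with \code{X}, \code{Z}, \code{y}, \code{genotypes},
#'   \code{nDropped}.
#' @export
buildDesign <- function(table, analysis = c("sea", "mea"), genotypes = NULL,
                        blocks = TRUE) {
  analysis <- match.arg(analysis)
  keep <- !is.na(table$value)
  nDropped <- sum(!keep)
  table <- table[keep, , drop = FALSE]
  if (!nrow(table)) stop("no non-missing observations")
  terms <- list()
  if (analysis == "mea") {
    if (is.null(table$environment))
      stop("mea analysis needs an 'environment' column")
    env <- factor(table$environment)
    if (nlevels(env) < 2L)
      warning("environment has a single level; term dropped")
    else terms$env <- env
  }
  repf <- factor(table$replication)
  if (nlevels(repf) < 2L)
    warning("replication has a single level; term dropped")
  else terms$repf <- repf
  if (blocks) {
    blk <- if (analysis == "mea" && !is.null(table$environment))
      paste(table$environment, table$replication, table$block, sep = ":")
    else paste(table$replication, table$block, sep = ":")
    blockf <- factor(blk)
    if (nlevels(blockf) < 2L)
      warning("block has a single level; term dropped")
    else terms$blockf <- blockf
  }
  df <- as.data.frame(terms)
  X <- if (length(terms))
    stats::model.matrix(stats::as.formula(
      paste("~", paste(names(terms), collapse = " + "))), data = df)
  else matrix(1, nrow(table), 1L, dimnames = list(NULL, "(Intercept)"))
  X <- .fullRank(X)
  if (is.null(genotypes)) genotypes <- sort(unique(table$genotype))
  unknown <- setdiff(unique(table$genotype), genotypes)
  if (length(unknown))
    stop("genotypes absent from the requested levels: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  gidx <- match(table$genotype, genotypes)
  Z <- matrix(0, nrow(table), length(genotypes),
              dimnames = list(NULL, genotypes))
  Z[cbind(seq_len(nrow(table)), gidx)] <- 1
  list(X = X, Z = Z, y = table$value, genotypes = genotypes,
       nDropped = nDropped)
}

# Shared spectral pieces for the restricted likelihood of the
# two-component model: eigendecomposition of Z K Z' through the q x q
# matrix L Z' Z L' with K = L' L.
.remlPieces <- function(X, Z, y, K = NULL) {
  n <- length(y)
  p <- ncol(X)
  q <- ncol(Z)
  if (n <= p + 1L) stop("too few observations: n must exceed rank(X) + 1")
  if (is.null(K)) {
    Q <- Z
  } else {
    L <- chol(K)  # K = L'L with upper-triangular chol convention: t(L)%*%L
    Q <- Z %*% t(L)
  }
  ee <- eigen(crossprod(Q), symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  pos <- lam > max(lam, 1) * 1e-12
  U <- Q %*% ee$vectors[, pos, drop = FALSE]
  U <- sweep(U, 2L, sqrt(lam[pos]), `/`)  # orthonormal columns
  list(n = n, p = p, q = q, lam = lam, pos = pos,
       Ux = crossprod(U, X), Uy = drop(crossprod(U, y)),
       XtX = crossprod(X), Xty = drop(crossprod(X, y)),
       yty = sum(y * y))
}

# Profiled REML criterion at variance ratio delta = sigma2_g / sigma2_e.
# Returns the restricted log-likelihood (up to the additive constant) and
# the profiled residual variance.
.remlProfile <- function(pieces, delta) {
  lamp <- pieces$lam[pieces$pos]
  w <- delta * lamp / (1 + delta * lamp)
  A <- pieces$XtX - crossprod(pieces$Ux, w * pieces$Ux)
  b <- pieces$Xty - drop(crossprod(pieces$Ux, w * pieces$Uy))
  cc <- pieces$yty - sum(w * pieces$Uy^2)
  cholA <- chol(A)
  beta <- backsolve(cholA, forwardsolve(t(cholA), b))
  rss <- max(cc - sum(b * beta), .VAR_FLOOR)
  np <- pieces$n - pieces$p
  s2e <- rss / np
  ll <- -0.5 * (np * log(s2e) + sum(log1p(delta * pieces$lam)) +
                  2 * sum(log(diag(cholA))) + np)
  list(ll = ll, s2e = s2e)
}

#' Restricted log-likelihood of the two-component model
#'
#' Evaluates the REML criterion
#' \eqn{-\frac12 [\log|V| + \log|X'V^{-1}X| + y'Py]} (plus the usual
#' constant) for \eqn{V = \sigma^2_g Z K Z' + \sigma^2_e I}, using one
#' spectral decomposition so repeated evaluations are cheap.
#'
#' @param X,Z,y design matrices and response from [buildDesign()].
#' @param K genotype covariance (NULL for identity).
#' @param sigma2g,sigma2e variance components (> 0).
#' @return The restricted log-likelihood (scalar).
#' @export
remlLoglik <- function(X, Z, y, K = NULL, sigma2g, sigma2e) {
  pieces <- .remlPieces(X, Z, y, K)
  .remlLoglikPieces(pieces, sigma2g, sigma2e)
}

.remlLoglikPieces <- function(pieces, sigma2g, sigma2e) {
  delta <- sigma2g / sigma2e
  lamp <- pieces$lam[pieces$pos]
  w <- delta * lamp / (1 + delta * lamp)
  A <- pieces$XtX - crossprod(pieces$Ux, w * pieces$Ux)
  b <- pieces$Xty - drop(crossprod(pieces$Ux, w * pieces$Uy))
  cc <- pieces$yty - sum(w * pieces$Uy^2)
  cholA <- chol(A)
  beta <- backsolve(cholA, forwardsolve(t(cholA), b))
  yPy <- max(cc - sum(b * beta), 0) / sigma2e
  np <- pieces$n - pieces$p
  logdetV <- pieces$n * log(sigma2e) + sum(log1p(delta * pieces$lam))
  logdetA <- 2 * sum(log(diag(cholA))) - pieces$p * log(sigma2e)
  -0.5 * (np * log(2 * pi) + logdetV + logdetA + yPy)
}

#' REML variance components for the screening mixed model
#'
#' Estimates \eqn{(\sigma^2_g, \sigma^2_e)} of
#' \eqn{y \sim N(X\beta,\; \sigma^2_g Z K Z' + \sigma^2_e I)} by restricted
#' maximum likelihood. The default method profiles the restricted
#' likelihood down to the variance ratio and solves the one-dimensional
#' problem exactly (Brent search after one spectral decomposition); the
#' EM variant iterates Henderson's mixed-model-equation updates, whose
#' restricted log-likelihood trace is monotone nondecreasing.
#'
#' @param X,Z,y design matrices and response from [buildDesign()].
#' @param K genotype covariance matrix (NULL for identity); must be
#'   positive definite (add a ridge if needed).
#' @param method \code{"profile"} (default) or \code{"em"}.
#' @param tol relative convergence tolerance (default 1e-8).
#' @param maxIter iteration cap for EM (default 500).
#' @return A [VarianceComponents-class]; \code{convergence} is
#'   \code{"boundary"} when a component is pinned at the lower floor
#'   (e.g. a constant response).
#' @export
remlFit <- function(X, Z, y, K = NULL, method = c("profile", "em"),
                    tol = 1e-8, maxIter = 500L) {
  method <- match.arg(method)
  pieces <- .remlPieces(X, Z, y, K)
  if (method == "profile") .remlFitProfile(pieces, tol)
  else .remlFitEM(X, Z, y, K, pieces, tol, maxIter)
}

.remlFitProfile <- function(pieces, tol) {
  nev <- 0L
  obj <- function(t) {
    nev <<- nev + 1L
    -.remlProfile(pieces, exp(t))$ll
  }
  lo <- -25; hi <- 25
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
  delta <- exp(opt$minimum)
  prof <- .remlProfile(pieces, delta)
  s2e <- max(prof$s2e, .VAR_FLOOR)
  s2g <- max(delta * s2e, 0)
  boundary <- opt$minimum < lo + 0.5 || opt$minimum > hi - 0.5 ||
    prof$s2e <= .VAR_FLOOR * (pieces$n - pieces$p) * 10
  if (opt$minimum < lo + 0.5) s2g <- .VAR_FLOOR
  new("VarianceComponents", sigma2g = s2g, sigma2e = s2e,
      convergence = if (boundary) "boundary" else "converged",
      nIterations = nev,
      loglikTrace = .remlLoglikPieces(pieces, max(s2g, .VAR_FLOOR), s2e),
      method = "profile")
}

# EM-REML through Henderson's mixed-model equations:
#   sigma2_g <- (u' K^-1 u + sigma2_e tr(K^-1 C^uu)) / q
#   sigma2_e <- y'(y - X beta - Z u) / (n - p)
# with C^uu the u-block of the inverse coefficient matrix. The restricted
# log-likelihood is recorded each step and is nondecreasing.
.remlFitEM <- function(X, Z, y, K, pieces, tol, maxIter) {
  n <- pieces$n; p <- pieces$p; q <- pieces$q
  Kinv <- if (is.null(K)) diag(q) else chol2inv(chol(K))
  XtX <- pieces$XtX; Xty <- pieces$Xty; yty <- pieces$yty
  XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z); Zty <- drop(crossprod(Z, y))
  vy <- stats::var(y)
  s2g <- max(vy / 2, .VAR_FLOOR * 10)
  s2e <- max(vy / 2, .VAR_FLOOR * 10)
  trace <- numeric(0)
  conv <- "max-iter"
  it <- 0L
  for (it in seq_len(maxIter)) {
    trace <- c(trace, .remlLoglikPieces(pieces, s2g, s2e))
    lambda <- s2e / s2g
    C <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ + lambda * Kinv))
    Cinv <- chol2inv(chol(C))
    sol <- drop(Cinv %*% c(Xty, Zty))
    beta <- sol[seq_len(p)]
    u <- sol[p + seq_len(q)]
    Cuu <- Cinv[p + seq_len(q), p + seq_len(q)]
    s2g_new <- max((drop(u %*% Kinv %*% u) + s2e * sum(Kinv * Cuu)) / q,
                   .VAR_FLOOR)
    s2e_new <- max((yty - sum(beta * Xty) - sum(u * Zty)) / (n - p),
                   .VAR_FLOOR)
    rel <- max(abs(s2g_new - s2g) / max(s2g, .VAR_FLOOR),
               abs(s2e_new - s2e) / max(s2e, .VAR_FLOOR))
    s2g <- s2g_new; s2e <- s2e_new
    if (rel < tol) { conv <- "converged"; break }
  }
  trace <- c(trace, .remlLoglikPieces(pieces, s2g, s2e))
  if (s2g <= .VAR_FLOOR || s2e <= .VAR_FLOOR) conv <- "boundary"
  new("VarianceComponents", sigma2g = s2g, sigma2e = s2e,
      convergence = conv, nIterations = it, loglikTrace = trace,
      method = "em")
}

#' Solve Henderson's mixed-model equations
#'
#' Solves
#' \deqn{\begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda K^{-1} \end{pmatrix}
#'       \begin{pmatrix} \hat\beta \\ \hat u \end{pmatrix} =
#'       \begin{pmatrix} X'y \\ Z'y \end{pmatrix}}
#' with \eqn{\lambda = \sigma^2_e / \sigma^2_g}, returning fixed-effect
#' estimates, genotype BLUPs and prediction error variances
#' \eqn{PEV_i = \sigma^2_e [C^{-1}]_{u_i u_i}}.
#'
#' @param X,Z,y design matrices and response from [buildDesign()].
#' @param K genotype covariance (NULL for identity); positive definite.
#' @param varcomp a [VarianceComponents-class].
#' @return A [FitResult-class].
#' @export
solveMME <- function(X, Z, y, K = NULL, varcomp) {
  stopifnot(is(varcomp, "VarianceComponents"))
  s2g <- max(varcomp@sigma2g, .VAR_FLOOR)
  s2e <- varcomp@sigma2e
  lambda <- s2e / s2g
  p <- ncol(X); q <- ncol(Z)
  Kinv <- if (is.null(K)) diag(q) else chol2inv(chol(K))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Kinv))
  rhs <- c(drop(crossprod(X, y)), drop(crossprod(Z, y)))
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e) {
    stop(sprintf(
      "singular mixed-model coefficient matrix (reciprocal condition number %.3e)",
      rcond(C)))
  })
  sol <- drop(Cinv %*% rhs)
  beta <- sol[seq_len(p)]
  names(beta) <- colnames(X)
  u <- sol[p + seq_len(q)]
  names(u) <- colnames(Z)
  pev <- s2e * diag(Cinv)[p + seq_len(q)]
  names(pev) <- colnames(Z)
  new("FitResult", fixedEstimates = beta, blups = u,
      pev = pmax(pev, 0), varcomp = varcomp,
      fittedMean = mean(drop(X %*% beta)),
      nObs = length(y), nDropped = 0L)
}

#' Broad-sense heritability from variance components
#'
#' Plot-basis heritability \eqn{H^2 = \sigma^2_g / (\sigma^2_g +
#' \sigma^2_e)} (genetic variance over total variance); the entry-mean
#' basis \eqn{\sigma^2_g / (\sigma^2_g + \sigma^2_e / r)} is available for
#' comparison with replicated-trial reports.
#'
#' @param varcomp a [VarianceComponents-class].
#' @param basis \code{"plot"} (default) or \code{"entry-mean"}.
#' @param nReps effective replications per entry (entry-mean basis only).
#' @return Heritability in [0, 1]; NA with a warning when both components
#'   sit at the boundary floor.
#' @examples
#' vc <- new("VarianceComponents", sigma2g = 2, sigma2e = 2,
#'           convergence = "converged", nIterations = 1L,
#'           loglikTrace = 0, method = "profile")
#' heritability(vc)  # 0.5
#' @export
heritability <- function(varcomp, basis = c("plot", "entry-mean"),
                         nReps = 2) {
  basis <- match.arg(basis)
  s2g <- varcomp@sigma2g
  s2e <- varcomp@sigma2e
  if (s2g <= .VAR_FLOOR && s2e <= .VAR_FLOOR) {
    warning("both variance components at the boundary: heritability undefined")
    return(NA_real_)
  }
  if (s2g <= .VAR_FLOOR) return(0)
  if (basis == "plot") s2g / (s2g + s2e) else s2g / (s2g + s2e / nReps)
}

#' Reliability of genotype BLUPs
#'
#' Squared accuracy \eqn{r^2_i = 1 - PEV_i / \sigma^2_g}, clipped to
#' [0, 1]; genotypes without observations have \eqn{PEV = \sigma^2_g} and
#' thus reliability 0 (identity covariance).
#'
#' @param fit a [FitResult-class].
#' @return A list with \code{perGenotype} (named vector) and \code{mean}.
#'   When \eqn{\sigma^2_g = 0} reliabilities are reported as 0 with a
#'   warning.
#' @export
reliability <- function(fit) {
  s2g <- fit@varcomp@sigma2g
  if (s2g <= .VAR_FLOOR) {
    warning("zero genetic variance: reliability undefined, reported as 0")
    r2 <- setNames(rep(0, length(fit@pev)), names(fit@pev))
  } else {
    r2 <- pmin(pmax(1 - fit@pev / s2g, 0), 1)
  }
  list(perGenotype = r2, mean = mean(r2))
}

#' Fit one trait with the screening mixed model
#'
#' High-level wrapper: subsets the long trait table, constructs the SEA or
#' MEA design, estimates variance components by REML and solves the
#' mixed-model equations.
#'
#' The environment term of an MEA design is taken from the table's
#' \code{environment} column if present, otherwise built from the
#' experiment label (joint per-condition analysis across experiments) or
#' the experiment x condition combination (full across-environment
#' analysis).
#'
#' @param table long trait table ([plotsToTraitTable()]).
#' @param trait trait id to fit.
#' @param condition restrict to one water regime (NULL keeps all).
#' @param experiment restrict to one experiment (NULL keeps all).
#' @param analysis \code{"sea"} or \code{"mea"}.
#' @param K genotype covariance ([GenomicRelationshipMatrix-class] or
#'   matrix; NULL for identity = phenotypic BLUPs).
#' @param method,tol,maxIter passed to [remlFit()].
#' @param blocks include the fixed block term (default TRUE).
#' @return A [FitResult-class].
#' @export
fitTrait <- function(table, trait, condition = NULL, experiment = NULL,
                     analysis = c("sea", "mea"), K = NULL,
                     method = "profile", tol = 1e-8, maxIter = 500L,
                     blocks = TRUE) {
  analysis <- match.arg(analysis)
  sub <- table[table$trait == trait, , drop = FALSE]
  if (!is.null(condition)) sub <- sub[sub$condition %in% condition, ]
  if (!is.null(experiment)) sub <- sub[sub$experiment %in% experiment, ]
  if (!nrow(sub)) stop("no records for trait ", trait)
  if (analysis == "mea" && is.null(sub$environment)) {
    sub$environment <- if (length(unique(sub$condition)) > 1L)
      paste(sub$experiment, sub$condition, sep = "_")
    else sub$experiment
  }
  Kmat <- if (is(K, "GenomicRelationshipMatrix")) K@values else K
  genotypes <- if (!is.null(Kmat)) rownames(Kmat) else NULL
  des <- buildDesign(sub, analysis = analysis, genotypes = genotypes,
                     blocks = blocks)
  vc <- remlFit(des$X, des$Z, des$y, K = Kmat, method = method,
                tol = tol, maxIter = maxIter)
  fit <- solveMME(des$X, des$Z, des$y, K = Kmat, varcomp = vc)
  fit@nDropped <- as.integer(des$nDropped)
  fit
}
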
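---
title: "Models and methods behind anaerGS donor screening"
author: "anaerGS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind anaerGS donor screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Direct-seeded rice fails to establish when early floods cut off oxygen
during germination. Screening programmes sow panels of genotypes —
largely landraces of unknown merit plus a handful of checks of known
tolerance class — under standing floodwater (anaerobic) and moist
control (aerobic) conditions, and score germination (seedling emergence
above the water surface) at 14 and 21 days after seeding together with
seedling height, culm diameter, root length and shoot/root dry matter.
anaerGS implements the statistical chain that turns those plot-level
records plus a ~1000-SNP genotyping panel into ranked donor lists:
mixed-model BLUPs, a genomic relationship matrix, GBLUP breeding values,
a weighted selection index, and threshold-based selection rules.

## Trial design and the phenotype models

The design is a resolvable incomplete-block (alpha) lattice: each
replication consists of 16 crates (blocks) of 14 plots, and with 200
entries appearing once per replication plus 8 checks replicated three
times, a replication is exactly filled (200 + 8×3 = 224 = 16×14). Each
experiment (run) contains both water regimes with 2 replications each.

Two model layers are fitted per trait, both Gaussian linear mixed models
with genotype as the single random term:

* single-experiment analysis (SEA), within one experiment and condition:
  $y = \beta_0 + \beta_1 r + u + b + \epsilon$, with fixed replication
  $r$ and fixed blocks-within-replication $b$;
* multi-environment analysis (MEA), adding a fixed environment term $E$:
  $y = \beta_0 + \beta_1 E + \beta_2 r + \beta_3 B + u + \epsilon$.

The same MEA form serves two data layers: the joint per-condition
analysis (both experiments of one water regime, $E$ = experiment) and
the full across-environment analysis ($E$ = experiment × condition
cell). Blocks are nested within replication within environment; the
environment statement leaves the nesting across environments open, and
nesting fully is the conservative choice. Blocks are kept fixed, exactly
as the model statements declare, although lattice practice often takes
them random; `buildDesign(blocks = FALSE)` drops them.

Fixed factors use reference-level coding with the reference being the
first level in sorted order; columns made redundant by nesting (e.g.
replication indicators spanned by block indicators) are removed by QR
pivoting so the fixed design always has full column rank. This affects
the reporting of fixed effects only, never the BLUPs.

## REML, Henderson's equations, heritability, reliability

Variance components of
$y \sim N(X\beta,\; \sigma^2_g Z K Z' + \sigma^2_e I)$ are estimated by
REML. Because the model has exactly two components, the restricted
likelihood can be profiled down to the variance ratio
$\delta = \sigma^2_g/\sigma^2_e$: after one spectral decomposition of
$Z K Z'$ (computed through the q×q matrix $L Z'Z L'$ with $K = L'L$),
each evaluation costs $O(qp^2)$ and the one-dimensional problem is
solved by Brent search on $\log\delta \in [-25, 25]$. This is the
package default because it is exact, deterministic and fast enough for
the ~80 fits of a full pipeline run. An EM-REML variant
(`remlFit(method = "em")`) iterates the classical mixed-model-equation
updates; its restricted log-likelihood trace is monotone nondecreasing,
which makes it a useful cross-check of the profiled optimum, and both
are verified in the test suite against a dense grid oracle. Variance
components are floored at $10^{-10}$; hitting the floor (e.g. a constant
response) is reported as boundary convergence, never silently.

Given components, Henderson's mixed-model equations give
$\hat\beta, \hat u$ and prediction error variances
$PEV_i = \sigma^2_e [C^{-1}]_{u_iu_i}$. Note that this PEV includes
fixed-effect uncertainty: in tiny balanced toys the reliability
$r^2_i = 1 - PEV_i/\sigma^2_g$ therefore sits slightly below the
textbook $n\sigma^2_g/(n\sigma^2_g+\sigma^2_e)$ and converges to it as
the panel grows; the test suite checks both the exact dense
projection-matrix oracle and the closed form at panel size.
Heritability is reported on the plot basis, literally genetic variance
over total variance, $H^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$; an
entry-mean basis $\sigma^2_g/(\sigma^2_g+\sigma^2_e/r)$ is available via
`heritability(basis = "entry-mean")` because published trial tables are
often consistent with either convention.

## Marker QC and the genomic relationship matrix

Dosages count the alternate allele (VCF GT 0/1 → 1, 1/1 → 2). QC removes
samples first (call rate < 0.66, the pass bar reported for the panel the
package emulates, or heterozygosity > 0.10 — inbred rice is expected
nearly homozygous), then markers (call rate < 0.90 or MAF < 0.01). All
thresholds are arguments. Missing calls are mean-imputed per marker
(2p), which provably leaves allele frequencies unchanged.

The relationship matrix is VanRaden's method 1,
$G = ZZ'/(2\sum_j p_j(1-p_j))$ with $Z$ the 2p-centred dosages and
frequencies estimated from the panel itself. Sample-frequency centring
makes $G$ exactly singular (its rows sum to zero), so a ridge (default
$10^{-6}$) is added to the diagonal before the evaluation equations
invert it. GBLUP with $G$ is algebraically identical to ridge-regression
BLUP on marker effects with $\sigma^2_\alpha = \sigma^2_g$/denominator;
the test suite keeps that equivalence as a permanent oracle (exact on
full-rank kinships with shared centring).

## Outlier screening

Data preparation applies an iterative Bonferroni screen per experiment ×
condition × trait: studentized conditional residuals from the screening
mixed model, worst observation removed if its Bonferroni-adjusted
two-sided p-value falls below alpha (default 0.05), model refitted,
repeated until nothing is flagged. Genotype enters this screen as a
random (shrunken) effect — a deliberate choice: with only two replicates
a fixed-genotype residual splits an aberrant value symmetrically between
the two plots of the genotype and cannot tell which plot carries it,
whereas shrinkage borrows strength across the trial and points at the
shifted observation. The screen skips groups with too little residual
information (with a warning) and is idempotent on its own output.

## GEBVs, the selection index, donor rules

GEBVs are genotype BLUPs from the evaluation model with $K = G$,
recentred by the model's grand fitted fixed mean so germination GEBVs
live on the 0–100% scale regardless of reference coding (the raw
reference-level intercept would be the reference environment cell and
distorts across-environment scales). Before weighting, GEBVs are
standardised per trait within the evaluation environment. This is the
standard selection-index preparation and the package default: the
published index values the package emulates (≈25–117) are incompatible
with weights applied to raw percentage-scale breeding values, which
would reach several hundreds. `runConfig(standardize = FALSE)` disables
it.

The index is $I_g = \sum_i b_i x_{gi}$ with relative economic weights
germination 14 DAS 10, germination 21 DAS 8, shoot dry matter 7,
seedling height 14 DAS 5, root length 5, seedling height 21 DAS 4, root
dry matter 4, culm diameter 3 — one weight set for all rules. Donor
rules keep genotypes with index ≥ 25 and phenotypic germination-21-DAS
BLUP ≥ 70% (anaerobic) or ≥ 80% (aerobic, across); the germination
threshold deliberately applies to phenotypic BLUPs, not GEBVs. Checks
are evaluated, flagged and reported, but never counted as entries.
Whether across-environment GEBVs should come from the MEA fit or from
averaged per-condition fits is ambiguous in practice; the package fits
the MEA model, the more principled pooling.

## The synthetic trial generator

`simConfig()`/`simulateTrial()` generate complete trials with known
ground truth. Defaults encode the study conditions the package models:

* geometry: 200 entries + 8 checks × 3, 14 × 16 lattice, 2 replications,
  2 experiments × 2 conditions, 30 seeds per plot;
* markers: 1000 SNPs, allele frequencies uniform on [0.05, 0.95],
  inbreeding coefficient F = 0.95 so panel heterozygosity is ~2%,
  matching an inbred landrace collection (F = 0 gives a Hardy-Weinberg
  panel);
* trait means per condition from the published across-experiment
  summaries (e.g. flooded 14-DAS germination 29.4%, control 98.3%);
* genetic SDs set once as range/4 of those genotype-level summaries
  (averaged over conditions; germination traits use the flooded-derived
  value because the control is compressed against the 100% ceiling);
* plot-basis heritabilities averaging the two flooded experiments
  (0.71 for 14-DAS germination), residual variances back-solved as
  $\sigma^2_e = \sigma^2_g(1-h^2)/h^2$;
* a positive-definite genetic correlation matrix with strong coupling of
  the two germination scores (0.9), moderate germination–height and
  germination–dry-matter correlations and weak culm-diameter links;
* nuisance structure: centred fixed experiment (±0.1 SD) and replication
  (±0.05 SD) ladders and incomplete-block effects with variance 5% of
  phenotypic, so configured condition means remain grand means.

True breeding values are built from i.i.d. normal marker effects mixed
through the matrix square root of the genetic correlation, and rescaled
so the per-trait TBV variance over the panel equals the configured
genetic variance exactly. Phenotypes add the fixed ladders, block and
residual noise; germination is realised as counts out of 30 (latent
percentage rounded and truncated), other measurements floored at zero.
Randomisation of the lattice is constrained random allocation without
concurrence optimisation.

What the generator does **not** emulate: genotype-by-environment
interaction in the genetic effects (one TBV per trait across
conditions), binomial sampling noise of germination counts beyond
rounding, spatial trends within crates, non-Gaussian trait
distributions, linkage disequilibrium structure among markers, and
population stratification. Passing recovery tests therefore shows the
chain is correct under a Gaussian, LD-free, GxE-free world; it does not
certify behaviour on real data with those features.

## Validation strategy and problem sizes

The test suite separates exact oracles from stochastic recovery. Exact:
mixed-model solutions against a dense GLS implementation on 100 random
instances of ≤30 observations; GBLUP against the ridge-regression
marker-effect route; the relationship matrix against a brute-force
double loop on 6×10 panels and an analytic diagonal case. Stochastic,
under the default synthetic study: mean estimated plot-basis H² for
14-DAS flooded germination over 20 seeds against the configured 0.71;
GEBV–TBV correlation over 10 seeds at configured H² ∈ {0.2, 0.5, 0.8},
checked for level and monotonicity; outlier-screen sensitivity and
false-removal rate over 100 seeds with three planted +10 SD plots in
100-plot trials; and byte-identical donor lists across repeated pipeline
runs of one seed. `scripts/acceptance.R` recomputes all of these from
scratch, plus the printed-arithmetic worked examples on the reference
tables shipped in `inst/extdata/`.

## Known limitations

Traits are fitted independently (no multi-trait REML); residual
variances are homogeneous across environments; no spatial row-column
modelling; no LD pruning or population-structure correction; economic
weights are fixed inputs, not Smith–Hazel optimised; QTL haplotype
calling is out of scope. Reliability inherits whatever the variance
components are, so boundary fits report it as 0 with a flag rather than
a number pretending precision.
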
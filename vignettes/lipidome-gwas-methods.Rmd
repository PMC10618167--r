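---
title: "Methods: multivariate GWAS of lipid species, fine-mapping and disease colocalization"
author: "LipidomeGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate GWAS of lipid species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

LipidomeGWAS implements a complete desk-scale pipeline for genetic
association analysis of a correlated lipidome: phenotype preparation,
trait clustering, univariate and multivariate (canonical-correlation)
association, rare-variant inflation calibration, SNP heritability,
Bayesian fine-mapping with credible sets, locus definition, phenome-wide
endpoint association and credible-set colocalization. A synthetic-cohort
generator with a ground-truth ledger makes every stage verifiable against
planted parameters. This vignette documents the statistical model behind
each stage, the tunable parameters and their defaults, the numerical
choices, and what the verification does and does not establish.

# Phenotype preparation

Lipid species measurements are adjusted for covariates by per-species
ordinary least squares on the complete cases (age, sex, collection site
in the synthetic cohort; arbitrary covariate tables, including genetic
PCs from the GRM module, are accepted). Residuals are inverse-normal
transformed with the Blom offset,
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, average ranks for ties.
Blom is the common convention for GWAS phenotypes; the offset choice is
immaterial beyond the third decimal for $n$ in the thousands. Missing
entries stay missing: association testing always uses per-species
complete cases, and mean imputation is used **only** for the
principal-component test budget below.

The effective number of tests is the smallest number of principal
components of the mean-imputed phenotype matrix explaining more than 90%
of variance. The PCA uses the covariance of the transformed matrix
(after INT the columns have unit variance, so covariance and correlation
PCA nearly coincide; this was a genuinely open choice and is fixed
here). All multiple-testing thresholds are Bonferroni ratios of a base
level (5e-8 genome-wide, 0.05 nominal) and products of counts; with 68
components the genome-wide Bonferroni threshold is 7.352941e-10 and with
11 clusters 4.545455e-9.

# Trait clustering

Multivariate testing needs clusters of correlated but not collinear
traits. The pipeline (i) computes absolute pairwise-complete Pearson
correlations of the INT residuals, (ii) iteratively removes one member
of every pair with $|r| > 0.8$ — the victim is the member with the
larger mean $|r|$ to the remaining traits, ties broken toward the
lexicographically later id, a deterministic rule that keeps the more
distinct trait, (iii) clusters the remaining traits by average-linkage
agglomeration on Euclidean distances between rows of the $|r|$ matrix,
separately within partition groups (e.g. glycerolipids vs the rest), and
(iv) within each cluster iteratively removes the member with the largest
variance inflation factor until all VIF < 5. The dendrogram is cut at an
explicit cluster count — a parameter replacing visual inspection, which
is not reproducible. Cluster membership survives in the output with a
status column (`member`, `removed_pairwise`, `removed_vif`).

# Univariate association

The default per-variant model is ordinary least squares of the prepared
phenotype on dosage with a two-sided Wald p-value from the normal
approximation. The synthetic cohort has unrelated samples, for which a
mixed model is equivalent in expectation; an `lmm` option (one global
variance-component fit on the null model, then per-variant GLS through
the GRM eigen-basis) is provided for relatedness-structured simulations
and agrees with OLS when the GRM is the identity. Variants are filtered
at MAF $\ge$ 0.002 and INFO $\ge$ 0.8 (boundary kept). The genomic
inflation factor is the median 1-df chi-square over 0.4549.

# Multivariate association via canonical correlation

Per-trait effects are standardized to the correlation scale,
$b = \beta / (\sqrt{N}\,\mathrm{se})$. For one variant against a cluster
of $q$ traits with correlation $S_{YY}$, the squared canonical
correlation is $r^2 = b^\top S_{YY}^{-1} b$ and the test statistic is
Bartlett's chi-square
$-(N - 1 - (1 + q + 1)/2)\,\log(1 - r^2)$ with $q$ degrees of freedom
and $N$ the mean univariate sample size at the variant. Bartlett's
factor is the standard CCA asymptotic and reduces to $N r^2$ (the
univariate $z^2$) for small $r$ — the package tests verify equality to a
generic eigen-decomposition CCA at 1e-10 and the $q = 1$ equivalence
within 0.5%.

$S_{YY}$ can be estimated from the phenotypes directly or, as in
summary-statistic practice, as the correlation of the standardized
effect columns across a null-dominated genome (at least 500 variants
required). The estimate is shrunk toward the identity with the smallest
$\alpha$ giving minimum eigenvalue 1e-3; $\alpha$ is reported. The
optimal combination weights $a \propto S_{YY}^{-1} b$ are normalized to
$a^\top S_{YY} a = 1$ and signed so $a^\top b \ge 0$; summing the
cluster traits with these weights gives the linear combination phenotype
(LCP), a univariate trait whose $z^2$ at the lead variant approximates
the multivariate chi-square and which feeds region-wise fine-mapping.

## Rare-variant inflation and permutation calibration

For rare and low-frequency variants the multivariate p-values are
slightly anti-conservative. Two mechanisms survive even in a clean
simulation: the Wald standardization $t/\sqrt{n}$ exceeds the
correlation $r$ by a factor $1/\sqrt{1 - r^2}$, and an estimated
$S_{YY}$ mis-specifies the quadratic form by $O(q/V)$ for $V$ estimation
variants. The calibration permutes the genotype vector (phenotypes
fixed, preserving the trait correlation), recomputes the per-trait
regressions and the CCA chi-square, and sets $\lambda$ to the median
permuted statistic over the theoretical chi-square median; the
correction divides the observed chi-square by $\lambda$ (standard
genomic control, not a p-value remap). The correction is applied to
variants with MAF < 0.05 that reach multivariate but no univariate
genome-wide significance. The package uses 100,000 permutations: at the
study scale ($n = 2000$, $q = 10$, MAF 0.005) the true inflation is
only about 1%, and the Monte-Carlo standard error of a median-based
$\lambda$ at $10^5$ permutations (about 0.002) is what makes it
measurable; the run takes under a minute vectorized.

## Driver traits

A decremental search approximates the central-trait decomposition of
multivariate hits: at each step the trait whose removal increases the
multivariate p-value least is dropped; each subset records
$\mathrm{BIC} = -\chi^2 + |S| \log N$; the minimum-BIC subset on the
path is the optimal set and its members the drivers. The output is
flagged `metaphat_like`: the reference tool's exact subset criterion is
not published in enough detail to clone, and this explicit rule is
deterministic and testable (planted single-trait effects are recovered
as sole drivers in $\ge 90\%$ of simulations).

# SNP heritability

The GRM is $A = ZZ^\top/m$ over LD-pruned variants (window 1000 kb, step
1, $r^2$ 0.7, MAF $\ge$ 0.01, INFO $\ge$ 0.95), with per-variant
standardized dosages; its top eigenvectors serve as genetic PCs. Two
estimators are provided. Haseman–Elston regression regresses
$y_i y_j$ ($i<j$) on $A_{ij}$; its standard error is **not** the naive
pair-regression standard error — pairs sharing a sample are dependent,
which makes that SE under-cover badly at moderate heritability — but
the sampling variance of the quadratic-form estimator,
$2\,\mathrm{tr}(MVMV)$ with $V = \hat h^2 A + (1-\hat h^2)I$, estimated
with 64 Rademacher trace probes under a fixed internal seed. REML fits a
single variance component through the GRM eigen-basis (computed through
the $m \times m$ problem, so cost scales with the variant count) with
the SE from the curvature of the profile log-likelihood. Estimates are
clamped to $[0, 1]$ with a flag; the unclamped value is retained.

Heritability here means the genetic variance share of the
covariate-adjusted trait — the scale on which the pipeline actually
estimates it. Recovery studies use a common-MAF panel so that the GRM
filters do not silently remove causal variants; with rare causal
variants excluded from the GRM the estimate is genuinely attenuated
(incomplete tagging), which is a property of the design, not an
estimator defect.

# Fine-mapping

Per region, z-scores and the signed in-sample dosage correlation matrix
$R$ enter an exhaustive Bayesian scan over all causal configurations
$C$ with $|C| \le K$: under $C$, $z_C \sim N(0, R_C + N\sigma^2 R_C
R_C)$; under the null $z_C \sim N(0, R_C)$; independent-inclusion prior
$\pi^{|C|}(1-\pi)^{m-|C|}$ with $\pi = 1/m$; prior effect SD
$\sigma = 0.05$ per standardized effect (both configurable and logged).
Enumeration is exact — the shotgun search of production fine-mappers is
deliberately replaced by exhaustion at desk scale ($K \le 2$ up to 2000
variants, $K = 3$ up to 200). A non-PSD $R$ is ridge-repaired with 1e-6.
The MAP causal count $k^*$ maximizes the size-wise posterior. Per-signal
credible sets use a swap construction: with the other MAP variants
fixed, each candidate's posterior mass replaces one signal variant,
renormalized; the 95% set is the smallest descending-PIP prefix with
mass 0.95. For $k^* = 1$ this reduces exactly to marginal PIPs. Purity
is the minimum pairwise $r^2$ among members; a set is informative at
purity $\ge$ 0.1; a region with no informative set falls back to the
GWAS lead as representative, as does the MHC region (chr6:25–34 Mb),
which is excluded from fine-mapping outright. The representative is the
top-PIP variant unless a functional variant (severity-ordered consequence
list down to splice-region) sits in the set at $r^2 > 0.95$ with it.

# Locus definition

Lead variants are taken iteratively as the lowest-p uncovered variant;
each opens a $\pm$1.5 Mb region; overlapping regions combine (lowest-p
lead, others secondary); a combined region wider than 6 Mb has its
half-windows multiplied by 0.9 repeatedly, regions rebuilt each time,
until the width is below 6 Mb or the regions separate. After shrinking,
any genome-wide-significant variant left uncovered seeds a further lead
— this outer iteration is what guarantees that every significant variant
ends up inside some region. Representatives from fine-mapping merge into
signals when $r^2 \ge 0.1$ on the same chromosome (connected
components); signal regions are unions of their GWAS regions; overlapping
signal regions combine into non-overlapping loci. A lead is novel iff
$r^2 < 0.1$ with every known variant present in-sample, with a $\pm$1.5
Mb proximity fallback for known variants absent from the data (the
package does not query external LD reference panels; this fallback is
the one deviation from reference-panel-based novelty lookups and is
stated in the output). Loci are named by the gene of a missense
representative if present, else the overlapping or nearest gene of the
lowest-p top variant (tie: the upstream gene).

# Endpoints: PheWAS and colocalization

Binary endpoints with at least 50 cases are tested per variant by
logistic regression (dosage + covariates), two-sided Wald p, with a
Firth-penalized fallback under separation (flagged). Reported tiers are
0.05 and 5e-8 divided by the endpoint count. The effective sample size
is $N_{\mathrm{eff}} = N\theta(1-\theta)$ and is used as the sample size
when endpoint z-scores are fine-mapped — endpoint fine-mapping reuses
the same engine as lipid traits so the colocalization inputs are
coherent. For a lipid credible set and an endpoint credible set, the
colocalization probability is
$\mathrm{CLPP} = \sum_{s \in \cap} \mathrm{PIP}_T(s)\,\mathrm{PIP}_D(s)$
over shared variants, with colocalization called at CLPP > 0.01. The
heatmap-style summary applies the conjunction: endpoint-corrected
genome-wide PheWAS significance AND CLPP > 0.01.

# The synthetic cohort

Genotypes: per LD block and haplotype, a latent AR(1) Gaussian series
(parameter `ldRho`, default 0.8, blocks of 50) thresholded at each
variant's allele-frequency quantile; two haplotypes sum to a genotype.
This gives closed-form target LD cheaply and independence across blocks.
The MAF spectrum is a common/low-frequency/rare mixture (weights
0.5/0.3/0.2, floors at 0.002). Imputation noise shrinks genotypes toward
expected dosage, `d = (1-e) g + 2 e maf`, `e ~ Beta(1, 19)`, and INFO is
the dosage variance over `2 maf (1-maf)` — a filterable INFO column
without imputation machinery. Positions are 1-based on synthetic
chromosomes (10 kb spacing).

Lipidome: species split into contiguous classes sharing a standard
normal factor (loading 0.6); fixed covariate slopes 0.1 (age), 0.2
(sex), 0.05 (site) so that preprocessing has real work to do; planted
effects act on standardized dosages, rescaled so the genetic share of
the covariate-adjusted trait hits the per-species heritability target
(target `NA` keeps the planted slopes literally — used by
effect-recovery tests; target 0 removes genetic effects). Noise absorbs
the remaining variance; an impossible variance budget is a configuration
error. Missingness is MCAR. The default desk-scale shape is 5000
samples, 2000 variants, 18 species in 6 classes; verification studies
state their own sizes (calibration uses 10,000 variants at n = 5000;
heritability recovery 20 seeds at n = 4000 with a 600-variant panel —
sizes chosen so each Monte-Carlo band in the tests is several times
narrower than the property being checked).

Endpoints: liability threshold with logistic errors — identical to a
logistic model, so planted coefficients are exact per-allele log odds
ratios, recoverable by the PheWAS module; the intercept is solved
numerically for the target prevalence; endpoints below 50 expected cases
are flagged excluded.

What the generator does **not** emulate: genotyping/imputation artifacts
beyond the INFO shrinkage, batch and drift structure in the lipid
measurements, population structure and relatedness (the GRM of the
synthetic cohort is near-identity), linkage between blocks, and the
ontology structure of real disease endpoints. Passing tests therefore
establish the correctness and calibration of the statistical machinery
under its stated assumptions, not robustness to those real-data
features.

# Numerical choices and degenerate inputs

Zero-variance genotypes yield p = 1 with a flagged standard error rather
than an error. Perfect collinearity in VIF pruning gives an infinite VIF
and immediate removal. The CCA canonical correlation is clamped at
$1 - 10^{-12}$ before the log. $S_{YY}$ shrinkage and the fine-mapping
ridge repair are logged. All tie-breaks (pair pruning, VIF, LD pruning,
lead variants at equal p) are deterministic and stated in the function
documentation. Every simulation entry point takes a seed and restores
the caller's RNG state; identical configuration and seed give
byte-identical cohorts.

# Known limitations

Exhaustive fine-mapping is exponential in $K$; the region-size budgets
are hard limits, not heuristics. The LCP route inherits the weights of a
single lead variant, so secondary signals within a cluster-region are
only approximately represented. The driver-trait rule is an explicit
approximation, not a clone, of the reference tool. Novelty calls without
an external LD panel can only be as complete as the in-sample variant
set plus the proximity fallback.
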
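#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Planted causal effect
#'
#' Describes one causal variant planted by the synthetic-cohort generator:
#' which variant, which lipid species it affects, the standardized
#' per-allele slopes, and the kind of effect. `multivariate_cancel`
#' effects have opposing signs across traits so that the summed signal is
#' attenuated (only a multivariate test sees the full signal);
#' `rare_large` effects must sit on variants with MAF < 0.05.
#'
#' @slot variantIndex integer index of the causal variant.
#' @slot traitTargets integer indices of the affected species.
#' @slot effectSizes standardized slopes, one per target trait.
#' @slot kind one of `"univariate"`, `"multivariate_cancel"`, `"rare_large"`.
#' @export
setClass("PlantedEffect",
  representation(variantIndex = "integer", traitTargets = "integer",
                 effectSizes = "numeric", kind = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@traitTargets) != length(object@effectSizes))
      msg <- c(msg, "traitTargets and effectSizes must have equal length")
    if (!object@kind %in% c("univariate", "multivariate_cancel", "rare_large"))
      msg <- c(msg, "kind must be univariate, multivariate_cancel or rare_large")
    if (object@kind == "multivariate_cancel" &&
        length(object@effectSizes) >= 2 &&
        !(abs(sum(object@effectSizes)) < max(abs(object@effectSizes))))
      msg <- c(msg, "multivariate_cancel effects must sign-cancel: |sum(beta)| < max|beta|")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a planted effect
#'
#' @param variantIndex index of the causal variant in the simulated panel.
#' @param traitTargets indices of the affected lipid species.
#' @param effectSizes standardized slopes (may have opposing signs).
#' @param kind effect kind; see [PlantedEffect-class].
#' @return A [PlantedEffect-class] object.
#' @examples
#' plantedEffect(5L, c(1L, 2L), c(0.1, -0.1), "multivariate_cancel")
#' @export
plantedEffect <- function(variantIndex, traitTargets, effectSizes,
                          kind = c("univariate", "multivariate_cancel", "rare_large")) {
  new("PlantedEffect", variantIndex = as.integer(variantIndex),
      traitTargets = as.integer(traitTargets),
      effectSizes = as.numeric(effectSizes), kind = match.arg(kind))
}

#' Simulation configuration
#'
#' Full description of a synthetic cohort: genotype panel (blockwise-LD
#' dosages over a realistic MAF spectrum), a class-structured lipidome
#' with controllable per-species heritability, fixed covariate effects,
#' planted causal variants and binary disease endpoints.
#'
#' @slot nSamples,nVariants cohort and panel size.
#' @slot blockSize variants per LD block.
#' @slot ldRho within-block adjacent-variant latent correlation in [0, 1).
#' @slot mafSpectrum data.frame with columns `class`, `weight`, `low`,
#'   `high`: mixture weights and MAF ranges (floor 0.002, ceiling 0.5).
#' @slot nSpecies number of lipid traits.
#' @slot nClasses number of lipid classes the species are split across.
#' @slot classLoading within-class shared-factor loading.
#' @slot h2Targets per-species heritability targets in [0, 1).
#' @slot plantedEffects list of [PlantedEffect-class].
#' @slot endpointSpecs data.frame with columns `endpoint`, `prevalence`,
#'   plus a list-column `sharedVariants` of variant indices and `logOR`
#'   of per-variant liability log-odds.
#' @slot missingRate per-species MCAR missingness fraction in [0, 0.3].
#' @slot nChromosomes number of synthetic chromosomes the blocks are
#'   spread over.
#' @slot posStep base-pair spacing between adjacent variants.
#' @slot seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @export
setClass("SimConfig",
  representation(nSamples = "integer", nVariants = "integer",
                 blockSize = "integer", ldRho = "numeric",
                 mafSpectrum = "data.frame", nSpecies = "integer",
                 nClasses = "integer", classLoading = "numeric",
                 h2Targets = "numeric", plantedEffects = "list",
                 endpointSpecs = "data.frame", missingRate = "numeric",
                 nChromosomes = "integer", posStep = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
    if (object@nVariants < 1L) msg <- c(msg, "nVariants must be >= 1")
    if (object@ldRho < 0 || object@ldRho >= 1)
      msg <- c(msg, "ldRho must be in [0, 1)")
    ms <- object@mafSpectrum
    if (!all(c("weight", "low", "high") %in% names(ms)))
      msg <- c(msg, "mafSpectrum needs columns weight, low, high")
    else if (any(ms$low < 0.002 - 1e-12) || any(ms$high > 0.5) ||
             any(ms$low > ms$high))
      msg <- c(msg, "mafSpectrum ranges must lie within [0.002, 0.5]")
    if (length(object@h2Targets) != object@nSpecies)
      msg <- c(msg, "h2Targets must have one entry per species")
    if (any(object@h2Targets < 0 | object@h2Targets >= 1, na.rm = TRUE))
      msg <- c(msg, "h2Targets must be in [0, 1) (NA = take planted slopes as given)")
    covShare <- sum(covariateSlopes()^2)
    if (any(object@h2Targets + object@classLoading^2 + covShare > 1,
            na.rm = TRUE))
      msg <- c(msg, "h2 target + class factor + covariate variance share exceeds 1")
    if (object@missingRate < 0 || object@missingRate > 0.3)
      msg <- c(msg, "missingRate must be in [0, 0.3]")
    if (nrow(object@endpointSpecs) &&
        (any(object@endpointSpecs$prevalence <= 0) ||
         any(object@endpointSpecs$prevalence >= 1)))
      msg <- c(msg, "endpoint prevalence must be in (0, 1)")
    for (pe in object@plantedEffects) {
      if (any(pe@variantIndex > object@nVariants))
        msg <- c(msg, "planted variant index outside panel")
      if (any(pe@traitTargets > object@nSpecies))
        msg <- c(msg, "planted trait index outside lipidome")
    }
    if (is.null(msg)) TRUE else msg
  })

# fixed standardized covariate slopes shared by the lipidome generator and
# the SimConfig variance-budget check (age, sex, site)
covariateSlopes <- function() c(age = 0.1, sex = 0.2, site = 0.05)

#' Default MAF spectrum: common / low-frequency / rare mixture
#'
#' @return data.frame with mixture weights and MAF ranges. The rare class
#'   is floored at 0.002, the panel-wide inclusion limit.
#' @export
defaultMafSpectrum <- function() {
  data.frame(class = c("common", "low_frequency", "rare"),
             weight = c(0.5, 0.3, 0.2),
             low = c(0.05, 0.01, 0.002),
             high = c(0.5, 0.05, 0.01))
}

#' Construct a simulation configuration
#'
#' Defaults describe a desk-scale cohort: 5000 unrelated samples, 2000
#' variants in AR(1) LD blocks of 50 with latent correlation 0.8 over two
#' chromosomes, and 18 lipid species in 6 classes with a within-class
#' factor loading of 0.6 (within-class correlation about 0.36) and
#' heritability targets of 0.2.
#'
#' @param nSamples,nVariants,blockSize,ldRho,mafSpectrum,nSpecies,nClasses
#'   see [SimConfig-class].
#' @param classLoading,h2Targets,plantedEffects,endpointSpecs,missingRate
#'   see [SimConfig-class].
#' @param nChromosomes,posStep,seed see [SimConfig-class].
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nSamples = 200, nVariants = 100, seed = 7)
#' @export
simConfig <- function(nSamples = 5000, nVariants = 2000, blockSize = 50,
                      ldRho = 0.8, mafSpectrum = defaultMafSpectrum(),
                      nSpecies = 18, nClasses = 6, classLoading = 0.6,
                      h2Targets = rep(0.2, nSpecies),
                      plantedEffects = list(),
                      endpointSpecs = emptyEndpointSpecs(),
                      missingRate = 0.02, nChromosomes = 2,
                      posStep = 10000, seed = 1) {
  new("SimConfig", nSamples = as.integer(nSamples),
      nVariants = as.integer(nVariants), blockSize = as.integer(blockSize),
      ldRho = ldRho, mafSpectrum = mafSpectrum,
      nSpecies = as.integer(nSpecies), nClasses = as.integer(nClasses),
      classLoading = classLoading, h2Targets = h2Targets,
      plantedEffects = plantedEffects, endpointSpecs = endpointSpecs,
      missingRate = missingRate, nChromosomes = as.integer(nChromosomes),
      posStep = as.integer(posStep), seed = as.integer(seed))
}

#' Empty endpoint specification table
#' @return zero-row data.frame in the layout `endpointSpecs` expects.
#' @export
emptyEndpointSpecs <- function() {
  out <- data.frame(endpoint = character(), prevalence = numeric())
  out$sharedVariants <- list()
  out$logOR <- list()
  out
}

#' Build an endpoint specification table
#'
#' @param endpoint character ids.
#' @param prevalence per-endpoint case proportions in (0, 1).
#' @param sharedVariants list of integer vectors: causal variant indices
#'   per endpoint (may be empty for a null endpoint).
#' @param logOR list of numeric vectors: per-variant liability log-odds.
#' @return data.frame usable as `endpointSpecs` in [simConfig()].
#' @export
endpointSpecs <- function(endpoint, prevalence, sharedVariants = NULL,
                          logOR = NULL) {
  n <- length(endpoint)
  if (is.null(sharedVariants)) sharedVariants <- rep(list(integer()), n)
  if (is.null(logOR)) logOR <- rep(list(numeric()), n)
  out <- data.frame(endpoint = endpoint, prevalence = prevalence)
  out$sharedVariants <- sharedVariants
  out$logOR <- logOR
  out
}

#' Ground-truth ledger of a simulated cohort
#'
#' Parameter-recovery tests read planted truth from this object rather
#' than re-deriving it from the data.
#'
#' @slot effects data.frame, one row per (planted effect, trait) pair:
#'   `effect`, `variant`, `trait`, `slope` (realized, after heritability
#'   scaling), `maf` (realized), `kind`.
#' @slot species data.frame: per-species `species`, `h2Target`,
#'   `h2Realized` (empirical genetic variance share).
#' @slot endpoints data.frame: per (endpoint, causal variant) `endpoint`,
#'   `variant`, `logOR` on the liability (logit) scale.
#' @export
setClass("TruthLedger",
  representation(effects = "data.frame", species = "data.frame",
                 endpoints = "data.frame"))

#' Simulated cohort container
#'
#' @slot genotypes a [SummarizedExperiment::RangedSummarizedExperiment]
#'   with assay `"dosage"` (variants x samples) and per-variant `rowRanges`
#'   carrying ref/alt alleles, realized MAF and a simulated INFO score.
#' @slot lipidome numeric matrix, samples x species, raw measurements with
#'   MCAR missingness.
#' @slot species data.frame mapping species to lipid class.
#' @slot covariates data.frame (sample, age, sex, site).
#' @slot endpointStatus integer matrix samples x endpoints (0/1).
#' @slot endpointInfo data.frame: `endpoint`, `prevalence` (target),
#'   `cases`, `excluded` (fewer than 50 expected cases).
#' @slot truth a [TruthLedger-class].
#' @export
setClass("LipidomeCohort",
  representation(genotypes = "ANY", lipidome = "matrix",
                 species = "data.frame", covariates = "data.frame",
                 endpointStatus = "matrix", endpointInfo = "data.frame",
                 truth = "TruthLedger"))

#' Covariate-adjusted, inverse-normal transformed phenotypes
#'
#' @slot residuals samples x species matrix; each column is the INT of the
#'   least-squares residual on the covariates, with missingness preserved.
#' @slot nObs per-species complete-case counts.
#' @slot covariateNames covariate columns that were removed.
#' @export
setClass("PreparedPhenotypes",
  representation(residuals = "matrix", nObs = "integer",
                 covariateNames = "character"))

#' Multiple-testing budget
#'
#' @slot nComponents90 number of principal components of the mean-imputed
#'   phenotype matrix needed to explain more than 90 percent of variance;
#'   the effective number of tests.
#' @slot alphaGw genome-wide significance level (default 5e-8).
#' @slot alphaNominal nominal level (default 0.05).
#' @slot thresholds named numeric vector of derived Bonferroni thresholds.
#' @export
setClass("TestBudget",
  representation(nComponents90 = "integer", alphaGw = "numeric",
                 alphaNominal = "numeric", thresholds = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nComponents90 < 1L) msg <- c(msg, "nComponents90 must be >= 1")
    if (any(object@thresholds <= 0)) msg <- c(msg, "thresholds must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' A pruned cluster of correlated lipid species
#'
#' @slot id cluster identifier.
#' @slot members species ids kept after pairwise and VIF pruning.
#' @slot removedPairwise species dropped by the |r| > 0.8 pair rule.
#' @slot removedVif species dropped by the VIF >= 5 loop.
#' @slot correlation within-cluster correlation submatrix of the members.
#' @export
setClass("TraitCluster",
  representation(id = "character", members = "character",
                 removedPairwise = "character", removedVif = "character",
                 correlation = "matrix"))

#' Single-variant multivariate (canonical correlation) test result
#'
#' @slot variant,cluster identifiers.
#' @slot r canonical correlation in [0, 1).
#' @slot chisq Bartlett chi-square statistic.
#' @slot df degrees of freedom (= cluster size).
#' @slot p raw p-value.
#' @slot pCorrected p after genomic-control division by `lambda`.
#' @slot lambda inflation factor applied (1 when none).
#' @slot weights optimal combination weights a, scaled so a' S_YY a = 1.
#' @slot n mean univariate GWAS sample size used as the chi-square N.
#' @export
setClass("MvTestResult",
  representation(variant = "character", cluster = "character",
                 r = "numeric", chisq = "numeric", df = "integer",
                 p = "numeric", pCorrected = "numeric", lambda = "numeric",
                 weights = "numeric", n = "numeric"))

#' SNP-heritability estimate
#'
#' @slot h2 estimate, clamped to [0, 1].
#' @slot se standard error.
#' @slot method `"haseman_elston"` or `"reml"`.
#' @slot clamped TRUE when the raw estimate fell outside [0, 1].
#' @slot raw the unclamped estimate.
#' @export
setClass("HeritabilityEstimate",
  representation(h2 = "numeric", se = "numeric", method = "character",
                 clamped = "logical", raw = "numeric"))

#' Exhaustive fine-mapping fit for one region
#'
#' @slot variants region variant ids.
#' @slot configs list of integer vectors (causal configurations, including
#'   the null configuration).
#' @slot logBF per-configuration log Bayes factors against the null.
#' @slot posterior normalized configuration posterior probabilities.
#' @slot pip marginal posterior inclusion probability per variant.
#' @slot kMap MAP number of causal variants.
#' @slot kPosterior posterior over the causal count 0..K.
#' @export
setClass("FinemapFit",
  representation(variants = "character", configs = "list",
                 logBF = "numeric", posterior = "numeric", pip = "numeric",
                 kMap = "integer", kPosterior = "numeric"))

#' 95 percent credible set for one association signal
#'
#' @slot signalIndex which of the MAP signals this set describes.
#' @slot variants member variant ids, sorted by descending PIP.
#' @slot pips per-signal posterior inclusion probabilities of the members.
#' @slot mass cumulative posterior mass covered (>= 0.95).
#' @slot purity minimum pairwise LD r-squared among the members.
#' @slot informative purity >= 0.1.
#' @slot representative variant chosen to stand for the signal (top PIP,
#'   or a functional variant in LD r-squared > 0.95 with it).
#' @export
setClass("CredibleSet",
  representation(signalIndex = "integer", variants = "character",
                 pips = "numeric", mass = "numeric", purity = "numeric",
                 informative = "logical", representative = "character"))
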
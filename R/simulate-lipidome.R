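#' @include simulate-genotypes.R
NULL

#' Simulate a class-structured lipidome with planted genetic effects
#'
#' Each lipid species is built as
#' `class factor + genetic effects + covariate effects + noise`,
#' all on a unit-variance scale. Species are split into `nClasses`
#' contiguous classes sharing a standard-normal factor with loading
#' `classLoading`. Genetic effects come from the planted effects in the
#' configuration, acting on standardized dosages; when a species has a
#' finite heritability target the planted slopes are rescaled so the
#' realized genetic variance share of the covariate-adjusted trait
#' equals the target (a species with
#' target 0 receives no genetic effect; a species with target `NA` keeps
#' the planted slopes as given). Species with a positive target but no
#' planted effect receive a polygenic background over 100 random panel
#' variants. Covariates (age, sex, collection site) enter with fixed
#' standardized slopes 0.1, 0.2 and 0.05. Noise absorbs the remaining
#' variance; missingness is MCAR at `missingRate`.
#'
#' @param genotypes the RangedSummarizedExperiment from
#'   [simulateGenotypes()].
#' @param config the same [SimConfig-class].
#' @return list with `lipidome` (samples x species matrix), `species`
#'   (data.frame species/class), `covariates` (data.frame) and `truth`
#'   (a [TruthLedger-class]).
#' @export
simulateLipidome <- function(genotypes, config) {
  stopifnot(is(config, "SimConfig"))
  dos <- SummarizedExperiment::assay(genotypes, "dosage")
  n <- ncol(dos)
  if (n != config@nSamples)
    stop("genotype sample count does not match config")
  for (pe in config@plantedEffects)
    if (pe@variantIndex > nrow(dos))
      stop("planted variant index not present in genotype matrix")
  nsp <- config@nSpecies

  withSeed(subSeed(config@seed, 1L), {
    samples <- colnames(dos)
    age <- stats::rnorm(n)
    sex <- stats::rbinom(n, 1, 0.5)
    site <- sample(c("A", "B", "C"), n, replace = TRUE)
    covariates <- data.frame(sample = samples, age = age, sex = sex,
                             site = site)
    slopes <- covariateSlopes()
    covPart <- slopes["age"] * scaleVec(age) +
      slopes["sex"] * scaleVec(sex) +
      slopes["site"] * scaleVec(as.integer(factor(site)))

    classOf <- ((seq_len(nsp) - 1L) %/% ceiling(nsp / config@nClasses)) + 1L
    factors <- matrix(stats::rnorm(n * config@nClasses), n, config@nClasses)
    lam <- config@classLoading

    # per-species genetic components
    h2 <- config@h2Targets
    peByTrait <- vector("list", nsp)
    for (k in seq_along(config@plantedEffects)) {
      pe <- config@plantedEffects[[k]]
      for (j in seq_along(pe@traitTargets)) {
        t <- pe@traitTargets[j]
        peByTrait[[t]] <- rbind(peByTrait[[t]],
          data.frame(effect = k, variant = pe@variantIndex,
                     slope = pe@effectSizes[j], kind = pe@kind))
      }
    }

    vids <- rownames(dos)
    mafs <- SummarizedExperiment::rowRanges(genotypes)$maf
    sdDos <- apply(dos, 1, stats::sd)

    Y <- matrix(NA_real_, n, nsp)
    effRows <- list()
    h2Realized <- numeric(nsp)
    for (s in seq_len(nsp)) {
      tab <- peByTrait[[s]]
      G <- numeric(n)
      realSlopes <- numeric(0)
      if (!is.null(tab)) {
        Z <- standardizeCols(t(dos[tab$variant, , drop = FALSE]))
        G <- drop(Z %*% tab$slope)
        realSlopes <- tab$slope
        vg <- stats::var(G)
        # the target is the genetic share of the covariate-adjusted trait,
        # so the raw-scale genetic variance is h2 * (1 - covariate share)
        vTarget <- h2[s] * (1 - sum(covariateSlopes()^2))
        if (!is.na(h2[s])) {
          if (h2[s] == 0) {
            G <- numeric(n); realSlopes <- rep(0, nrow(tab))
          } else if (vg > 0) {
            sc <- sqrt(vTarget / vg)
            G <- G * sc; realSlopes <- realSlopes * sc
          }
        }
      } else if (!is.na(h2[s]) && h2[s] > 0) {
        # polygenic background so the heritability target is met
        bgIdx <- sample.int(nrow(dos), min(100L, nrow(dos)))
        w <- stats::rnorm(length(bgIdx))
        Zbg <- standardizeCols(t(dos[bgIdx, , drop = FALSE]))
        G <- drop(Zbg %*% w)
        G <- G * sqrt(h2[s] * (1 - sum(covariateSlopes()^2)) / stats::var(G))
      }
      vg <- stats::var(G)
      resVar <- 1 - vg - lam^2 - sum(covariateSlopes()^2)
      if (resVar <= 0)
        stop("species ", s, ": heritability + shared variance exceeds 1")
      y <- G + lam * factors[, classOf[s]] + covPart +
        stats::rnorm(n, sd = sqrt(resVar))
      # realized heritability on the covariate-adjusted scale
      h2Realized[s] <- vg / (stats::var(y) - stats::var(covPart))
      Y[, s] <- y
      if (!is.null(tab))
        effRows[[s]] <- data.frame(
          effect = tab$effect, variant = vids[tab$variant],
          trait = sprintf("species%02d", s), slope = realSlopes,
          slopeDosage = realSlopes / sdDos[tab$variant],
          maf = mafs[tab$variant], kind = tab$kind)
    }

    if (config@missingRate > 0) {
      miss <- matrix(stats::runif(n * nsp) < config@missingRate, n, nsp)
      Y[miss] <- NA_real_
    }
    speciesIds <- sprintf("species%02d", seq_len(nsp))
    colnames(Y) <- speciesIds
    rownames(Y) <- samples

    effects <- if (length(effRows)) do.call(rbind, effRows) else
      data.frame(effect = integer(), variant = character(),
                 trait = character(), slope = numeric(),
                 slopeDosage = numeric(), maf = numeric(),
                 kind = character())
    rownames(effects) <- NULL
    truth <- new("TruthLedger",
                 effects = effects,
                 species = data.frame(species = speciesIds,
                                      class = paste0("class", classOf),
                                      h2Target = h2,
                                      h2Realized = h2Realized),
                 endpoints = data.frame(endpoint = character(),
                                        variant = character(),
                                        logOR = numeric()))
    list(lipidome = Y,
         species = data.frame(species = speciesIds,
                              class = paste0("class", classOf)),
         covariates = covariates, truth = truth)
  })
}

scaleVec <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate binary disease endpoints sharing causal variants with lipids
#'
#' Cases arise from a liability-threshold model with logistic liability:
#' the linear predictor is the sum of per-variant log-odds times raw
#' dosage, plus an intercept solved numerically so that the expected case
#' proportion equals the target prevalence; case status is then a
#' Bernoulli draw. The planted coefficients are therefore exactly
#' per-allele log odds ratios, recoverable by logistic regression.
#' Endpoints whose expected case count falls below 50 are flagged
#' excluded (the phenome-wide inclusion rule) with a warning.
#'
#' @param genotypes RangedSummarizedExperiment from [simulateGenotypes()].
#' @param config the [SimConfig-class] whose `endpointSpecs` drive the
#'   simulation.
#' @return list with `status` (samples x endpoints 0/1 matrix), `info`
#'   (data.frame endpoint/prevalence/cases/excluded) and `truth` rows for
#'   the endpoint ledger.
#' @export
simulateEndpoints <- function(genotypes, config) {
  stopifnot(is(config, "SimConfig"))
  dos <- SummarizedExperiment::assay(genotypes, "dosage")
  n <- ncol(dos)
  specs <- config@endpointSpecs
  nE <- nrow(specs)
  withSeed(subSeed(config@seed, 2L), {
    status <- matrix(0L, n, nE)
    rownames(status) <- colnames(dos)
    ledger <- list()
    info <- data.frame(endpoint = character(nE), prevalence = numeric(nE),
                       cases = integer(nE), excluded = logical(nE))
    for (e in seq_len(nE)) {
      prev <- specs$prevalence[e]
      vars <- specs$sharedVariants[[e]]
      gam <- specs$logOR[[e]]
      eta <- if (length(vars))
        drop(crossprod(dos[vars, , drop = FALSE], gam)) else numeric(n)
      alpha <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - prev,
                              c(-30, 30))$root
      status[, e] <- stats::rbinom(n, 1, stats::plogis(alpha + eta))
      excl <- n * prev < 50
      if (excl)
        warning("endpoint ", specs$endpoint[e],
                ": fewer than 50 expected cases; flagged excluded")
      info[e, ] <- list(specs$endpoint[e], prev, sum(status[, e]), excl)
      if (length(vars))
        ledger[[e]] <- data.frame(endpoint = specs$endpoint[e],
                                  variant = rownames(dos)[vars],
                                  logOR = gam)
    }
    colnames(status) <- specs$endpoint
    truth <- if (length(ledger)) do.call(rbind, ledger) else
      data.frame(endpoint = character(), variant = character(),
                 logOR = numeric())
    list(status = status, info = info, truth = truth)
  })
}

#' Simulate a full cohort
#'
#' Convenience wrapper running [simulateGenotypes()],
#' [simulateLipidome()] and [simulateEndpoints()] and bundling the result.
#'
#' @param config a [SimConfig-class].
#' @return A [LipidomeCohort-class].
#' @examples
#' cohort <- simulateCohort(simConfig(nSamples = 300, nVariants = 50,
#'                                    nSpecies = 6, nClasses = 2, seed = 11))
#' cohort
#' @export
simulateCohort <- function(config) {
  geno <- simulateGenotypes(config)
  lip <- simulateLipidome(geno, config)
  ep <- simulateEndpoints(geno, config)
  truth <- lip$truth
  truth@endpoints <- ep$truth
  new("LipidomeCohort", genotypes = geno, lipidome = lip$lipidome,
      species = lip$species, covariates = lip$covariates,
      endpointStatus = ep$status, endpointInfo = ep$info, truth = truth)
}

#' Write / read a truth ledger
#'
#' The ledger round-trips through three tab-delimited files with a common
#' prefix (`<prefix>.effects.tsv`, `<prefix>.species.tsv`,
#' `<prefix>.endpoints.tsv`).
#'
#' @param ledger a [TruthLedger-class].
#' @param prefix file path prefix.
#' @return `writeTruthLedger` returns the prefix invisibly;
#'   `readTruthLedger` the reconstructed [TruthLedger-class].
#' @export
writeTruthLedger <- function(ledger, prefix) {
  utils::write.table(ledger@effects, paste0(prefix, ".effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ledger@species, paste0(prefix, ".species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ledger@endpoints, paste0(prefix, ".endpoints.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname writeTruthLedger
#' @export
readTruthLedger <- function(prefix) {
  rd <- function(f, proto) {
    out <- utils::read.delim(f, colClasses = vapply(proto, class, ""))
    out
  }
  empty <- new("TruthLedger",
               effects = data.frame(effect = integer(), variant = character(),
                                    trait = character(), slope = numeric(),
                                    slopeDosage = numeric(), maf = numeric(),
                                    kind = character()),
               species = data.frame(species = character(), class = character(),
                                    h2Target = numeric(), h2Realized = numeric()),
               endpoints = data.frame(endpoint = character(),
                                      variant = character(), logOR = numeric()))
  new("TruthLedger",
      effects = rd(paste0(prefix, ".effects.tsv"), empty@effects),
      species = rd(paste0(prefix, ".species.tsv"), empty@species),
      endpoints = rd(paste0(prefix, ".endpoints.tsv"), empty@endpoints))
}
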
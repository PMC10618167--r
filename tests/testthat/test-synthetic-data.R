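test_that("dosages are bounded and the variant table is complete", {
  for (seed in c(1, 2, 3)) {
    geno <- simulateGenotypes(simConfig(nSamples = 150, nVariants = 60,
                                        blockSize = 15, seed = seed))
    dos <- SummarizedExperiment::assay(geno, "dosage")
    expect_gte(min(dos), 0)
    expect_lte(max(dos), 2)
    vt <- variantTableOf(geno)
    expect_true(all(c("chromosome", "position", "ref", "alt", "maf",
                      "info") %in% names(vt)))
    expect_true(all(vt$position >= 1))
    expect_true(all(vt$info >= 0 & vt$info <= 1))
  }
})

test_that("a fixed-MAF class is realized within binomial error", {
  spec <- commonSpectrum(0.30, 0.30)
  geno <- simulateGenotypes(simConfig(nSamples = 5000, nVariants = 100,
                                      mafSpectrum = spec, seed = 11))
  maf <- SummarizedExperiment::rowRanges(geno)$maf
  expect_true(all(abs(maf - 0.30) < 0.02))
})

test_that("ldRho = 0 gives independent variants; ldRho > 0 matches the AR(1)-implied LD", {
  n <- 5000
  g0 <- simulateGenotypes(simConfig(nSamples = n, nVariants = 60,
                                    blockSize = 15, ldRho = 0, seed = 4))
  d0 <- SummarizedExperiment::assay(g0, "dosage")
  r <- cor(t(d0))
  offdiag <- abs(r[upper.tri(r)])
  expect_lt(mean(offdiag), 3 / sqrt(n))

  # implied adjacent-dosage correlation for thresholded latent AR(1):
  # r = (P(Z1 < t, Z2 < t; rho) - p^2) / (p (1 - p)), computed by
  # numerical integration (independent of the generator's code path)
  rho <- 0.8; maf <- 0.3
  t0 <- qnorm(maf)
  p11 <- integrate(function(z)
    pnorm((t0 - rho * z) / sqrt(1 - rho^2)) * dnorm(z),
    -Inf, t0)$value
  implied <- (p11 - maf^2) / (maf * (1 - maf))
  g1 <- simulateGenotypes(simConfig(nSamples = n, nVariants = 60,
                                    blockSize = 15, ldRho = rho,
                                    mafSpectrum = commonSpectrum(0.3, 0.3),
                                    seed = 5))
  d1 <- SummarizedExperiment::assay(g1, "dosage")
  adj <- sapply(seq(1, 59), function(i)
    if (i %% 15 == 0) NA else cor(d1[i, ], d1[i + 1, ])^2)
  expect_lt(abs(mean(adj, na.rm = TRUE) - implied^2), 0.05)
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- simConfig(nSamples = 120, nVariants = 40, nSpecies = 5,
                   nClasses = 2, seed = 99,
                   endpointSpecs = endpointSpecs("E1", 0.5))
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(dosages(a), dosages(b))
  expect_identical(lipidome(a), lipidome(b))
  expect_identical(endpointStatus(a), endpointStatus(b))
})

test_that("a zero-heritability species shows no association with its planted variant", {
  hits <- 0
  for (seed in 1:8) {
    cfg <- simConfig(nSamples = 800, nVariants = 40, nSpecies = 4,
                     nClasses = 1,
                     mafSpectrum = commonSpectrum(0.2, 0.4),
                     plantedEffects = list(plantedEffect(5L, 1L, 0.4)),
                     h2Targets = c(0, NA, NA, NA), missingRate = 0,
                     seed = seed)
    co <- simulateCohort(cfg)
    y <- lipidome(co)[, 1]
    g <- dosages(co)[5, ]
    tstat <- coef(summary(lm(y ~ g)))[2, 3]
    if (abs(tstat) >= 4) hits <- hits + 1
  }
  expect_lte(hits, 1)
})

test_that("planted slopes with NA heritability target are realized as given", {
  cfg <- simConfig(nSamples = 5000, nVariants = 30, nSpecies = 3,
                   nClasses = 1, classLoading = 0,
                   mafSpectrum = commonSpectrum(0.3, 0.3),
                   plantedEffects = list(plantedEffect(2L, 1L, 0.2)),
                   h2Targets = c(NA, 0, 0), missingRate = 0, seed = 21)
  co <- simulateCohort(cfg)
  led <- truthLedger(co)@effects
  expect_equal(led$slope, 0.2)
  g <- scale(dosages(co)[2, ])
  y <- lipidome(co)[, 1]
  fit <- summary(lm(y ~ g))
  est <- coef(fit)[2, 1]
  ci <- est + c(-2, 2) * coef(fit)[2, 2]
  expect_true(ci[1] <= 0.2 && 0.2 <= ci[2])
})

test_that("missingness rate is realized within binomial error", {
  cfg <- simConfig(nSamples = 2000, nVariants = 20, nSpecies = 6,
                   nClasses = 2, missingRate = 0.1, seed = 31)
  co <- simulateCohort(cfg)
  obsMiss <- colMeans(is.na(lipidome(co)))
  expect_true(all(abs(obsMiss - 0.1) < 0.02))
})

test_that("endpoint prevalence, exclusion rule and null calibration behave", {
  cfg <- simConfig(nSamples = 5000, nVariants = 60, nSpecies = 3,
                   nClasses = 1, seed = 41,
                   endpointSpecs = endpointSpecs(c("E1", "E2"),
                                                 c(0.2, 0.3)))
  co <- simulateCohort(cfg)
  expect_lt(abs(mean(endpointStatus(co)[, "E1"]) - 0.2), 0.02)

  # an endpoint with < 50 expected cases is flagged excluded
  cfgBad <- simConfig(nSamples = 400, nVariants = 20, nSpecies = 3,
                      nClasses = 1, seed = 42,
                      endpointSpecs = endpointSpecs("tiny", 0.05))
  expect_warning(co2 <- simulateCohort(cfgBad), "fewer than 50")
  expect_true(co2@endpointInfo$excluded[1])

  # no causal variants: per-variant logistic p-values are uniform
  y <- endpointStatus(co)[, "E2"]
  dos <- dosages(co)
  pvals <- apply(dos[1:40, ], 1, function(g) {
    f <- glm(y ~ g, family = binomial())
    coef(summary(f))[2, 4]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("a planted endpoint log-OR is recovered by logistic regression", {
  cover <- 0
  for (seed in 1:10) {
    cfg <- simConfig(nSamples = 5000, nVariants = 20, nSpecies = 2,
                     nClasses = 1,
                     mafSpectrum = commonSpectrum(0.3, 0.3), seed = seed,
                     endpointSpecs = endpointSpecs("E1", 0.3, list(3L),
                                                   list(0.5)))
    geno <- simulateGenotypes(cfg)
    ep <- suppressWarnings(simulateEndpoints(geno, cfg))
    g <- SummarizedExperiment::assay(geno, "dosage")[3, ]
    fit <- summary(glm(ep$status[, 1] ~ g, family = binomial()))
    est <- coef(fit)[2, 1]; se <- coef(fit)[2, 2]
    if (est - 1.96 * se <= 0.5 && 0.5 <= est + 1.96 * se)
      cover <- cover + 1
  }
  expect_gte(cover, 9)
})

test_that("sign-canceling planted effects attenuate the unweighted trait sum", {
  worse <- 0
  for (seed in 1:6) {
    cfg <- simConfig(nSamples = 2000, nVariants = 30, nSpecies = 4,
                     nClasses = 1, classLoading = 0,
                     mafSpectrum = commonSpectrum(0.2, 0.4),
                     plantedEffects = list(
                       plantedEffect(4L, c(1L, 2L), c(0.12, -0.12),
                                     "multivariate_cancel")),
                     h2Targets = c(NA, NA, 0, 0), missingRate = 0,
                     seed = seed)
    co <- simulateCohort(cfg)
    g <- dosages(co)[4, ]
    y1 <- lipidome(co)[, 1]; y2 <- lipidome(co)[, 2]
    chi <- function(y) coef(summary(lm(y ~ g)))[2, 3]^2
    if (chi(y1 + y2) < max(chi(y1), chi(y2))) worse <- worse + 1
  }
  expect_gte(worse, 5)
})

test_that("the truth ledger round-trips through file I/O", {
  co <- smallCohort(seed = 3)
  led <- truthLedger(co)
  prefix <- file.path(withr::local_tempdir(), "truth")
  writeTruthLedger(led, prefix)
  back <- readTruthLedger(prefix)
  expect_equal(back@species$h2Realized, led@species$h2Realized,
               tolerance = 1e-12)
  expect_equal(back@effects, led@effects, tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(mafSpectrum = data.frame(class = "x", weight = 1,
                                                  low = 0.0005, high = 0.3)),
               "mafSpectrum")
  expect_error(simConfig(nSpecies = 2, h2Targets = c(0.95, 0.2)),
               "exceeds 1")
  expect_error(plantedEffect(1L, c(1L, 2L), c(0.3, 0.3),
                             "multivariate_cancel"),
               "sign-cancel")
})
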
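test_that("effect standardization follows beta / (sqrt(N) se)", {
  ss <- list(
    t1 = data.frame(variant_id = c("v1", "v2"), beta = c(0.1, 0),
                    standard_error = c(0.02, 0.05), n = c(2500, 2500)),
    t2 = data.frame(variant_id = c("v1", "v2"), beta = c(-0.3, 0.2),
                    standard_error = c(0.1, 0.1), n = c(2500, 2500)))
  std <- standardizeEffects(ss)
  expect_equal(std$bstand["v1", "t1"], 0.1 / (50 * 0.02))
  expect_equal(std$bstand["v2", "t1"], 0)
  expect_equal(std$meanN, c(v1 = 2500, v2 = 2500), ignore_attr = TRUE)

  ssBad <- ss
  ssBad$t1$standard_error[1] <- 0
  expect_warning(out <- standardizeEffects(ssBad), "non-positive se")
  expect_true(is.na(out$bstand["v1", "t1"]))
})

test_that("standardized effects approximate the genotype-phenotype correlation", {
  co <- smallCohort(seed = 23, n = 1000, nSpecies = 4, missingRate = 0)
  prep <- preparePhenotypes(lipidome(co), covariates(co))
  ss <- uvGwasAll(prep, co, mafMin = 0.05, infoMin = 0)
  std <- standardizeEffects(ss)
  vt <- variantTable(co)
  dos <- dosages(co)[match(rownames(std$bstand), vt$variant), ]
  for (j in 1:4) {
    r <- apply(dos, 1, function(g) cor(g, residuals(prep)[, j],
                                       use = "complete.obs"))
    expect_lt(max(abs(std$bstand[, j] - r)), 3 / sqrt(1000))
  }
})

test_that("S_YY estimates from summary stats and phenotypes agree, with PSD repair", {
  cfg <- simConfig(nSamples = 2000, nVariants = 1500, blockSize = 20,
                   nSpecies = 4, nClasses = 1, classLoading = 0.6,
                   h2Targets = rep(0, 4), missingRate = 0, seed = 31)
  co <- simulateCohort(cfg)
  prep <- preparePhenotypes(lipidome(co), covariates(co))
  ss <- uvGwasAll(prep, co, mafMin = 0, infoMin = 0)
  std <- standardizeEffects(ss)
  s1 <- estimateSyy(std, source = "summary_stats")
  s2 <- estimateSyy(residuals(prep), source = "phenotypes")
  expect_lt(max(abs(s1$S - s2$S)), 0.05)

  # independent traits give S_YY close to the identity
  withr::with_seed(32, {
    B <- matrix(rnorm(5000 * 3, sd = 0.02), 5000, 3)
    s0 <- estimateSyy(B, source = "summary_stats")
    expect_lt(max(abs(s0$S - diag(3))), 0.05)
  })

  # duplicated trait: shrinkage restores the eigenvalue floor
  dup <- cbind(residuals(prep), residuals(prep)[, 1])
  sd <- estimateSyy(dup, source = "phenotypes")
  expect_gte(min(eigen(sd$S, only.values = TRUE)$values), 1e-3 - 1e-12)
  expect_gt(sd$alpha, 0)

  expect_error(estimateSyy(std$bstand[1:100, ], source = "summary_stats"),
               "500")
})

test_that("the q = 1 CCA chi-square matches the univariate z-squared at small r", {
  res <- ccaTest(0.05, matrix(1), n = 1000)
  expect_equal(res@df, 1L)
  expect_equal(res@chisq, -997.5 * log(1 - 0.0025), tolerance = 1e-12)
  z2 <- 1000 * 0.05^2
  expect_lt(abs(res@chisq - z2) / z2, 0.005)
})

test_that("the single-SNP test equals a generic canonical-correlation computation", {
  # generic CCA oracle: largest eigenvalue of Sxx^-1 Sxy Syy^-1 Syx
  withr::with_seed(5, {
    for (rep in 1:20) {
      q <- sample(2:5, 1)
      L <- matrix(rnorm(q * q), q)
      S <- cov2cor(L %*% t(L) + diag(q))
      b <- rnorm(q, sd = 0.03)
      res <- ccaTest(b, S, n = 1000)
      eig <- eigen(1 %*% t(b) %*% solve(S) %*% b)$values[1]
      expect_equal(res@r^2, drop(eig), tolerance = 1e-10)
      # weight normalization a' S a = 1 and a'b >= 0
      a <- res@weights
      expect_equal(drop(t(a) %*% S %*% a), 1, tolerance = 1e-10)
      expect_gte(sum(a * b), 0)
    }
  })
  # q = 2 worked example on the identity
  res2 <- ccaTest(c(0.03, 0.04), diag(2), n = 1000)
  expect_equal(res2@r^2, 0.0025, tolerance = 1e-12)
})

test_that("degenerate CCA inputs behave as specified", {
  resNull <- ccaTest(c(0, 0), diag(2), n = 500)
  expect_equal(resNull@r, 0)
  expect_equal(resNull@p, 1)
  expect_error(ccaTest(rep(0.1, 5), diag(5), n = 6), "underdetermined")
})

test_that("permutation lambda is calibrated for common variants and reproducible", {
  withr::with_seed(6, {
    n <- 1500
    Y <- factorTraits(n, 5, loading = 0.5, seed = 61)
    g <- rbinom(n, 2, 0.3)
    a <- permutationLambda(g, Y, nPerm = 10000, seed = 9)
    b <- permutationLambda(g, Y, nPerm = 10000, seed = 9)
    expect_identical(a$chisq, b$chisq)
    expect_gt(a$lambda, 0.95)
    expect_lt(a$lambda, 1.05)
    expect_error(permutationLambda(rep(1, n), Y, nPerm = 1000), "constant")
    expect_error(permutationLambda(g, Y, nPerm = 10), "1000")
  })
})

test_that("lambda correction leaves p unchanged at lambda 1 and never decreases it above 1", {
  res <- ccaTest(c(0.05, 0.02), diag(2), n = 2000, lambda = 1)
  expect_equal(res@pCorrected, res@p)
  res2 <- ccaTest(c(0.05, 0.02), diag(2), n = 2000, lambda = 1.2)
  expect_gte(res2@pCorrected, res2@p)
})

test_that("the calibration trigger follows the MAF and significance rule", {
  expect_true(needsPermutationCalibration(0.01, 1e-9, 1e-3))
  expect_false(needsPermutationCalibration(0.3, 1e-9, 1e-3))
  expect_false(needsPermutationCalibration(0.01, 1e-9, 1e-9))
  expect_false(needsPermutationCalibration(0.01, 1e-7, 1e-3))
})

test_that("the LCP reproduces the multivariate signal as a univariate trait", {
  withr::with_seed(7, {
    n <- 4000
    g <- rbinom(n, 2, 0.3)
    Y <- cbind(0.08 * scale(g) + rnorm(n),
               -0.08 * scale(g) + rnorm(n),
               rnorm(n))
    colnames(Y) <- paste0("t", 1:3)
    S <- cor(Y)
    b <- drop(cor(Y, g))
    res <- ccaTest(b, S, n)
    lcp <- lcpConstruct(Y, res)
    z2 <- coef(summary(lm(lcp ~ g)))[2, 3]^2
    expect_lt(abs(z2 - res@chisq) / res@chisq, 0.1)

    # singleton cluster: the LCP is the trait itself
    single <- lcpConstruct(Y[, 1, drop = FALSE], 2)
    expect_equal(abs(cor(single, Y[, 1])), 1, tolerance = 1e-12)
    expect_error(lcpConstruct(Y, c(0, 0, 0)), "degenerate")
  })
})

test_that("driver decomposition finds the planted traits and walks the full path", {
  found <- 0
  nSeeds <- 8
  for (seed in seq_len(nSeeds)) {
    withr::with_seed(300 + seed, {
      n <- 2000
      g <- rbinom(n, 2, 0.3)
      Y <- sapply(1:5, function(j) rnorm(n))
      Y[, 2] <- Y[, 2] + 0.25 * scale(g)
      colnames(Y) <- paste0("t", 1:5)
      dd <- driverTraits(g, Y)
      expect_equal(nrow(dd$path), 5)
      if (identical(dd$drivers, "t2")) found <- found + 1
    })
  }
  expect_gte(found, round(0.9 * nSeeds) - 1)
})

test_that("two equally planted traits usually share the optimal set", {
  both <- 0
  nSeeds <- 5
  for (seed in seq_len(nSeeds)) {
    withr::with_seed(400 + seed, {
      n <- 2000
      g <- rbinom(n, 2, 0.3)
      Y <- sapply(1:4, function(j) rnorm(n))
      Y[, 1] <- Y[, 1] + 0.2 * scale(g)
      Y[, 3] <- Y[, 3] + 0.2 * scale(g)
      colnames(Y) <- paste0("t", 1:4)
      dd <- driverTraits(g, Y)
      if (all(c("t1", "t3") %in% dd$optimalSet)) both <- both + 1
    })
  }
  expect_gte(both, 4)
})
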
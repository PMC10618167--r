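test_that("enumeration equals an independent brute-force posterior", {
  withr::with_seed(1, {
    for (rep in 1:5) {
      m <- sample(6:12, 1)
      n <- 3000
      G <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.4)), n, m, byrow = TRUE)
      y <- 0.1 * scale(G[, 2]) + rnorm(n)
      z <- zScores(y, G)
      R <- cor(G)
      kMax <- sample(2:3, 1)
      fit <- finemapRegion(z, R, n, finemapConfig(kMax = kMax))
      oracle <- bruteForceFinemap(z, R, n, kMax)
      expect_lt(max(abs(fit@posterior - oracle$post)), 1e-10)
      expect_lt(max(abs(unname(fit@pip) - oracle$pip)), 1e-10)
      expect_equal(sum(fit@posterior), 1, tolerance = 1e-10)
    }
  })
})

test_that("forced and symmetric regions give the expected PIPs", {
  # single variant with |z| = 8: PIP ~ 1, one causal signal
  fit1 <- finemapRegion(c(v = 8), matrix(1), n = 5000,
                        finemapConfig(kMax = 1))
  expect_gt(fit1@pip[[1]], 0.99)
  expect_identical(fit1@kMap, 1L)

  # two variants in perfect LD with equal z: symmetric PIPs ~ 0.5
  R <- matrix(c(1, 1, 1, 1), 2)
  fit2 <- suppressMessages(
    finemapRegion(c(a = 6, b = 6), R, n = 5000, finemapConfig(kMax = 1)))
  expect_equal(unname(fit2@pip[1]), unname(fit2@pip[2]), tolerance = 1e-6)
  expect_equal(unname(fit2@pip[1]), 0.5, tolerance = 0.01)
})

test_that("PIP of the causal variant is monotone in its z-score", {
  withr::with_seed(2, {
    m <- 8
    G <- matrix(rbinom(2000 * m, 2, 0.3), 2000, m)
    R <- cor(G)
    z <- rnorm(m, sd = 0.5)
    last <- -1
    for (zc in c(2, 4, 6, 8)) {
      z[3] <- zc
      fit <- finemapRegion(z, R, 2000, finemapConfig(kMax = 2))
      expect_gte(fit@pip[[3]], last)
      last <- fit@pip[[3]]
    }
  })
})

test_that("credible sets obey the mass, purity and informativeness rules", {
  withr::with_seed(3, {
    n <- 4000
    # one strong causal variant in a 10-variant region with an LD partner
    G <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
    G[, 2] <- ifelse(runif(n) < 0.95, G[, 1], G[, 2])
    y <- 0.12 * scale(G[, 1]) + rnorm(n)
    z <- zScores(y, G)
    R <- cor(G)
    fit <- finemapRegion(z, R, n, finemapConfig(kMax = 2))
    csList <- buildCredibleSets(fit, R)
    expect_gte(length(csList), 1)
    cs <- csList[[1]]
    expect_gte(cs@mass, 0.95)
    expect_identical(order(cs@pips, decreasing = TRUE),
                     seq_along(cs@pips))
    expect_identical(cs@informative, cs@purity >= 0.1)
  })
})

test_that("a sharply concentrated signal yields a single-member credible set", {
  # per-signal PIPs (0.96, 0.03, 0.01): the 95% set is the first variant
  fit <- new("FinemapFit", variants = c("a", "b", "c"),
             configs = list(integer(0), 1L, 2L, 3L),
             logBF = c(0, 10, 6.5, 5.4),
             posterior = c(0.00, 0.96, 0.03, 0.01),
             pip = c(a = 0.96, b = 0.03, c = 0.01), kMap = 1L,
             kPosterior = c(`0` = 0, `1` = 1))
  R <- diag(3); dimnames(R) <- list(c("a", "b", "c"), c("a", "b", "c"))
  cs <- buildCredibleSets(fit, R)[[1]]
  expect_identical(cs@variants, "a")
  expect_equal(cs@purity, 1)
})

test_that("low-LD credible sets are flagged not informative", {
  fit <- new("FinemapFit", variants = c("a", "b"),
             configs = list(integer(0), 1L, 2L),
             logBF = c(0, 5, 4.9),
             posterior = c(0.0, 0.55, 0.45),
             pip = c(a = 0.55, b = 0.45), kMap = 1L,
             kPosterior = c(`0` = 0, `1` = 1))
  R <- matrix(c(1, sqrt(0.05), sqrt(0.05), 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  cs <- buildCredibleSets(fit, R)[[1]]
  expect_identical(cs@variants, c("a", "b"))
  expect_lt(cs@purity, 0.1)
  expect_false(cs@informative)
})

test_that("two independent causal variants are recovered as two informative sets", {
  good <- 0
  nSeeds <- 10
  for (seed in seq_len(nSeeds)) {
    withr::with_seed(500 + seed, {
      n <- 4000
      G <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
      y <- 0.12 * scale(G[, 2]) + 0.12 * scale(G[, 7]) + rnorm(n)
      z <- zScores(y, G)
      R <- cor(G)
      fit <- finemapRegion(z, R, n, finemapConfig(kMax = 2))
      if (fit@kMap == 2) {
        csList <- buildCredibleSets(fit, R)
        v <- lapply(csList, function(cs) cs@variants)
        hit <- any(vapply(v, function(x) "v2" %in% x, TRUE)) &&
               any(vapply(v, function(x) "v7" %in% x, TRUE)) &&
               length(intersect(v[[1]], v[[2]])) == 0 &&
               all(vapply(csList, function(cs) cs@informative, TRUE))
        if (hit) good <- good + 1
      }
    })
  }
  expect_gte(good, 9)
})

test_that("functional variants in high LD replace the top variant as representative", {
  ann <- data.frame(variant = c("a", "b", "c"),
                    class = c("intron_variant", "missense_variant",
                              "missense_variant"))
  R <- matrix(c(1, 0.985, 0.98,
                0.985, 1, 0.97,
                0.98, 0.97, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cs <- makeCredibleSet(c("a", "b", "c"), c(0.7, 0.2, 0.1), purity = 0.95)
  # both functional members exceed r2 = 0.95; the larger r2 wins
  expect_identical(representativeVariant(cs, ann, R), "b")

  annNone <- data.frame(variant = "a", class = "intron_variant")
  expect_identical(representativeVariant(cs, annNone, R), "a")

  # functional member below the LD threshold: top variant stays
  Rlow <- diag(3); dimnames(Rlow) <- dimnames(R)
  expect_identical(representativeVariant(cs, ann, Rlow), "a")
})

test_that("region exclusions follow the MHC rule", {
  expect_false(applyRegionExclusions("chr6", 26e6, 28e6)$finemap)
  expect_true(applyRegionExclusions("chr6", 24.0e6, 24.9e6)$finemap)
  expect_true(applyRegionExclusions("chr6", 26e6, 28e6,
                                    exclusions = data.frame(
                                      chromosome = character(),
                                      start = numeric(),
                                      end = numeric()))$finemap)
})

test_that("single-causal PIPs are loosely calibrated", {
  withr::with_seed(9, {
    n <- 2000
    m <- 8
    total <- 0; causal <- 0
    for (rep in 1:60) {
      G <- matrix(rbinom(n * m, 2, 0.3), n, m)
      cIdx <- sample.int(m, 1)
      y <- 0.09 * scale(G[, cIdx]) + rnorm(n)
      z <- zScores(y, G)
      fit <- finemapRegion(z, cor(G), n, finemapConfig(kMax = 1))
      hi <- which(fit@pip >= 0.8)
      total <- total + length(hi)
      causal <- causal + sum(hi == cIdx)
    }
    expect_gt(total, 5)
    expect_gte(causal / total, 0.7)
  })
})

test_that("credible sets export to the tab-delimited layout", {
  cs <- makeCredibleSet(c("a", "b"), c(0.8, 0.17), purity = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCredibleSets(list(cs), "region1", "trait1", path)
  tab <- read.delim(path)
  expect_identical(names(tab), c("region_id", "trait", "signal_index",
                                 "variant", "pip", "in_cs95", "purity",
                                 "informative", "representative"))
  expect_equal(nrow(tab), 2)
})
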
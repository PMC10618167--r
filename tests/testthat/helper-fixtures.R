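# Shared fixtures, all generated in code.

# a small default cohort used by several files
smallCohort <- function(seed = 7, n = 400, m = 120, nSpecies = 8,
                        missingRate = 0.05, ...) {
  simulateCohort(simConfig(nSamples = n, nVariants = m, blockSize = 20,
                           nSpecies = nSpecies, nClasses = 2,
                           missingRate = missingRate, seed = seed, ...))
}

# single-class common-MAF spectrum (used when every variant must pass the
# GRM filters or have a fixed frequency range)
commonSpectrum <- function(low = 0.05, high = 0.5) {
  data.frame(class = "common", weight = 1, low = low, high = high)
}

variantTableOf <- function(geno) {
  gr <- SummarizedExperiment::rowRanges(geno)
  data.frame(variant = names(gr),
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             position = GenomicRanges::start(gr),
             ref = gr$ref, alt = gr$alt, maf = gr$maf,
             altFreq = gr$altFreq, info = gr$info, row.names = NULL)
}

# correlated multivariate-normal traits with a shared factor
factorTraits <- function(n, q, loading = 0.6, seed = 1) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    sapply(seq_len(q), function(j)
      loading * f + sqrt(1 - loading^2) * rnorm(n))
  })
}

# independent brute-force fine-mapping oracle: direct normalized posterior
# over all configurations, densities computed from scratch
bruteForceFinemap <- function(z, R, n, kMax, sigma = 0.05, priorPi = NULL) {
  m <- length(z)
  if (is.null(priorPi)) priorPi <- 1 / m
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    R <- R + diag(1e-6, m)
  ldmvn <- function(x, S) {
    k <- length(x)
    -0.5 * (k * log(2 * pi) + determinant(S)$modulus +
            drop(t(x) %*% solve(S) %*% x))
  }
  configs <- list(integer(0))
  for (k in seq_len(kMax)) configs <- c(configs,
    utils::combn(m, k, simplify = FALSE))
  lp <- vapply(configs, function(C) {
    prior <- length(C) * log(priorPi) + (m - length(C)) * log(1 - priorPi)
    if (!length(C)) return(prior)
    Rc <- R[C, C, drop = FALSE]
    S1 <- Rc + n * sigma^2 * Rc %*% Rc
    prior + ldmvn(z[C], S1) - ldmvn(z[C], Rc)
  }, 0)
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  pip <- numeric(m)
  for (i in seq_along(configs))
    pip[configs[[i]]] <- pip[configs[[i]]] + post[i]
  list(post = post, pip = pip, configs = configs)
}

# z-scores of simple regression for each column of G
zScores <- function(y, G) {
  apply(G, 2, function(g) {
    f <- stats::lm(y ~ g)
    stats::coef(summary(f))[2, 3]
  })
}

makeCredibleSet <- function(variants, pipsVec, purity = 1, signal = 1L) {
  new("CredibleSet", signalIndex = signal, variants = variants,
      pips = stats::setNames(pipsVec, variants),
      mass = sum(pipsVec), purity = purity,
      informative = purity >= 0.1, representative = variants[1])
}
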
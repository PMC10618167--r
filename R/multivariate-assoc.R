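#' @include AllClasses.R
NULL

#' Standardize univariate effects for summary-statistic CCA
#'
#' Converts each trait's per-variant slope to the correlation scale,
#' `b_stand = beta / (sqrt(N) * se)`, and records the mean analyzed
#' sample size per variant across traits. A record with `se <= 0` is
#' skipped with a warning. For non-degenerate fits `b_stand`
#' approximates the genotype-phenotype Pearson correlation.
#'
#' @param sumstatsList named list of summary-statistic data.frames (one
#'   per trait, from [gwas()]), aligned on `variant_id`.
#' @return list with `bstand` (variants x traits matrix), `meanN`
#'   (per-variant mean sample size) and `variants` (ids).
#' @export
standardizeEffects <- function(sumstatsList) {
  stopifnot(length(sumstatsList) >= 1)
  ids <- sumstatsList[[1]]$variant_id
  for (ss in sumstatsList)
    if (!identical(ss$variant_id, ids))
      stop("summary statistics are not aligned on variant id")
  B <- sapply(sumstatsList, function(ss) {
    bad <- !is.na(ss$standard_error) & ss$standard_error <= 0
    if (any(bad))
      warning(sum(bad), " record(s) with non-positive se skipped")
    out <- ss$beta / (sqrt(ss$n) * ss$standard_error)
    out[bad | is.na(ss$standard_error)] <- NA_real_
    out
  })
  Nmat <- sapply(sumstatsList, function(ss) ss$n)
  rownames(B) <- ids
  list(bstand = B, meanN = rowMeans(Nmat), variants = ids)
}

#' Estimate the trait correlation matrix S_YY for a cluster
#'
#' Either from summary statistics (the Pearson correlation of the
#' standardized effect columns across a null-dominated genome; at least
#' 500 variants required) or directly from the phenotypes
#' (pairwise-complete correlation). The estimate is shrunk toward the
#' identity, `S <- (1 - alpha) S + alpha I`, with the smallest alpha
#' making the minimum eigenvalue at least 1e-3.
#'
#' @param x a standardized-effects matrix (variants x traits) from
#'   [standardizeEffects()], or a samples x traits phenotype matrix.
#' @param source `"summary_stats"` or `"phenotypes"`.
#' @param minEigen eigenvalue floor after shrinkage.
#' @return list with `S` (the shrunk correlation matrix), `alpha` and
#'   `source`.
#' @export
estimateSyy <- function(x, source = c("summary_stats", "phenotypes"),
                        minEigen = 1e-3) {
  source <- match.arg(source)
  if (source == "summary_stats") {
    if (is.list(x) && !is.null(x$bstand)) x <- x$bstand
    if (nrow(x) < 500)
      stop("need at least 500 variants to estimate S_YY from summary statistics")
    S <- stats::cor(x, use = "pairwise.complete.obs")
  } else {
    S <- correlationMatrix(x)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  eMin <- min(ev)
  alpha <- if (eMin >= minEigen) 0 else (minEigen - eMin) / (1 - eMin)
  nm <- dimnames(S)
  S <- (1 - alpha) * S + alpha * diag(nrow(S))
  dimnames(S) <- nm
  list(S = S, alpha = alpha, source = source)
}

#' Canonical-correlation test of one variant against a trait cluster
#'
#' With a single genotype variable the canonical correlation against a
#' trait set with correlation `S_YY` and standardized effect vector `b`
#' is `r^2 = b' S_YY^{-1} b`. The test statistic is Bartlett's
#' chi-square, `-(N - 1 - (1 + q + 1)/2) * log(1 - r^2)` with `q` the
#' cluster size and `N` the mean univariate GWAS sample size, referred
#' to a chi-square with `q` degrees of freedom; for small `r` it reduces
#' to the univariate `N r^2`. The optimal combination weights are
#' `a = S_YY^{-1} b` scaled so `a' S_YY a = 1` and signed so
#' `a' b >= 0`.
#'
#' @param b standardized effect vector (one entry per cluster trait).
#' @param syy trait correlation matrix (or the list from
#'   [estimateSyy()]).
#' @param n mean univariate sample size at the variant.
#' @param variant,cluster identifiers carried into the result.
#' @param lambda genomic-control inflation factor; the chi-square is
#'   divided by it for `pCorrected` (1 = no correction).
#' @return A [MvTestResult-class].
#' @examples
#' ccaTest(c(0.03, 0.04), diag(2), n = 1000)
#' @export
ccaTest <- function(b, syy, n, variant = "variant", cluster = "cluster",
                    lambda = 1) {
  if (is.list(syy)) syy <- syy$S
  q <- length(b)
  stopifnot(nrow(syy) == q)
  if (n <= q + 2) stop("underdetermined: N must exceed cluster size + 2")
  sol <- solve(syy, b)
  r2 <- min(max(sum(b * sol), 0), 1 - 1e-12)
  chisq <- -(n - 1 - (1 + q + 1) / 2) * log(1 - r2)
  p <- stats::pchisq(chisq, df = q, lower.tail = FALSE)
  if (r2 > 0) {
    a <- sol / sqrt(r2)
    if (sum(a * b) < 0) a <- -a
  } else a <- rep(0, q)
  pCorr <- stats::pchisq(chisq / lambda, df = q, lower.tail = FALSE)
  new("MvTestResult", variant = variant, cluster = cluster,
      r = sqrt(r2), chisq = chisq, df = as.integer(q), p = p,
      pCorrected = pCorr, lambda = lambda, weights = a, n = n)
}

#' Multivariate GWAS of a cluster across all variants
#'
#' Vectorized [ccaTest()] over a standardized-effects matrix.
#'
#' @param std output of [standardizeEffects()] restricted to the cluster
#'   traits (or a variants x traits matrix plus `meanN`).
#' @param syy trait correlation (matrix or [estimateSyy()] list).
#' @param cluster cluster id for the output.
#' @param meanN per-variant mean sample size (taken from `std` when it
#'   is a [standardizeEffects()] result).
#' @return data.frame (variant, cluster, r, chisq, df, p, p_corrected,
#'   lambda) plus a `weights` attribute (variants x traits matrix).
#' @export
mvGwas <- function(std, syy, cluster = "cluster", meanN = NULL) {
  if (is.list(syy)) syy <- syy$S
  if (is.list(std) && !is.null(std$bstand)) {
    B <- std$bstand
    meanN <- std$meanN
  } else B <- as.matrix(std)
  if (is.null(meanN)) stop("meanN required")
  q <- ncol(B)
  sol <- t(solve(syy, t(B)))
  r2 <- pmin(pmax(rowSums(B * sol), 0), 1 - 1e-12)
  chisq <- -(meanN - 1 - (1 + q + 1) / 2) * log(1 - r2)
  p <- stats::pchisq(chisq, df = q, lower.tail = FALSE)
  W <- sol / sqrt(pmax(r2, 1e-300))
  W[r2 == 0, ] <- 0
  out <- data.frame(variant = rownames(B), cluster = cluster,
                    r = sqrt(r2), chisq = chisq, df = q, p = p,
                    p_corrected = p, lambda = 1, row.names = NULL)
  attr(out, "weights") <- W
  out
}

#' Permutation-based inflation factor for the multivariate test
#'
#' Permutes the genotype vector (phenotypes fixed, so the trait
#' correlation is preserved), recomputes the per-trait univariate
#' regression, standardizes (`b_stand = t / sqrt(n)`, the Wald form of
#' beta / (sqrt(N) se)), runs the canonical-correlation test, and
#' returns `lambda` = median permuted chi-square over the theoretical
#' chi-square median at `q` degrees of freedom. The correction divides
#' an observed chi-square by lambda (standard genomic control). Intended
#' for variants with MAF below 0.05 that reach the multivariate
#' genome-wide threshold without any univariate support (see
#' [needsPermutationCalibration()]).
#'
#' @param genotype dosage vector.
#' @param phenotypes samples x cluster-traits matrix (complete cases
#'   used).
#' @param syy trait correlation used by the test (matrix or
#'   [estimateSyy()] list); defaults to the complete-case phenotype
#'   correlation.
#' @param nPerm number of permutations (>= 1000; 100,000 gives the
#'   lambda a Monte-Carlo standard error of about 0.002).
#' @param seed RNG seed; the result is reproducible bit-for-bit.
#' @param chunk permutations per memory chunk.
#' @return list with `lambda`, `nPerm`, `seed`, `df`, `chisq` (the
#'   permuted statistics).
#' @export
permutationLambda <- function(genotype, phenotypes, syy = NULL,
                              nPerm = 10000, seed = 1, chunk = 5000) {
  stopifnot(nPerm >= 1000)
  Y <- as.matrix(phenotypes)
  ok <- stats::complete.cases(Y) & !is.na(genotype)
  Y <- Y[ok, , drop = FALSE]
  g <- genotype[ok]
  if (stats::var(g) == 0) stop("constant genotype")
  n <- nrow(Y)
  q <- ncol(Y)
  if (is.null(syy)) syy <- stats::cor(Y)
  if (is.list(syy)) syy <- syy$S
  Ys <- standardizeCols(Y)
  withSeed(seed, {
    chis <- numeric(nPerm)
    done <- 0
    while (done < nPerm) {
      k <- min(chunk, nPerm - done)
      P <- matrix(0, n, k)
      for (j in seq_len(k)) P[, j] <- g[sample.int(n)]
      P <- standardizeCols(P)
      R <- crossprod(Ys, P) / (n - 1)        # q x k correlations
      B <- R * sqrt((n - 2) / n) / sqrt(pmax(1 - R^2, 1e-12))
      sol <- solve(syy, B)
      r2 <- pmin(pmax(colSums(B * sol), 0), 1 - 1e-12)
      chis[done + seq_len(k)] <-
        -(n - 1 - (1 + q + 1) / 2) * log(1 - r2)
      done <- done + k
    }
    list(lambda = stats::median(chis) / stats::qchisq(0.5, df = q),
         nPerm = nPerm, seed = seed, df = q, chisq = chis)
  })
}

#' Trigger rule for the permutation calibration
#'
#' The inflation correction is applied to rare and low-frequency
#' variants (MAF < 0.05) that reach the multivariate genome-wide
#' significance threshold but no univariate genome-wide threshold.
#'
#' @param maf minor-allele frequency.
#' @param pMv multivariate p-value.
#' @param pUvMin minimum univariate p across the cluster traits.
#' @param gws genome-wide level, default 5e-8.
#' @return logical.
#' @export
needsPermutationCalibration <- function(maf, pMv, pUvMin, gws = 5e-8) {
  maf < 0.05 & pMv < gws & pUvMin >= gws
}

#' Linear combination phenotype from optimal CCA weights
#'
#' `y_LCP = sum_j a_j y_j` over samples complete in every cluster trait,
#' re-standardized to mean 0 and variance 1; incomplete rows are NA (and
#' all-missing rows are dropped from the standardization). The weights
#' are taken from the cluster's lead variant's [MvTestResult-class].
#'
#' @param phenotypes samples x cluster-traits matrix.
#' @param weights optimal combination weights (numeric, or an
#'   [MvTestResult-class]).
#' @return numeric vector aligned with the input rows.
#' @export
lcpConstruct <- function(phenotypes, weights) {
  if (is(weights, "MvTestResult")) weights <- weights@weights
  Y <- as.matrix(phenotypes)
  stopifnot(length(weights) == ncol(Y))
  if (all(weights == 0)) stop("degenerate combination: weights all zero")
  ok <- stats::complete.cases(Y)
  out <- rep(NA_real_, nrow(Y))
  v <- drop(Y[ok, , drop = FALSE] %*% weights)
  out[ok] <- (v - mean(v)) / stats::sd(v)
  names(out) <- rownames(Y)
  out
}

#' Driver-trait decomposition of a multivariate association
#'
#' Decremental search: starting from the full cluster, at each step the
#' trait whose removal yields the smallest increase of the multivariate
#' p-value (the least-contributing trait) is dropped, down to a single
#' trait. At each subset S the Bayesian information criterion
#' `BIC(S) = -chisq(S) + |S| log(N)` is recorded; the optimal set is the
#' minimum-BIC subset on the path and its members are the driver traits.
#' The decomposition is an explicit approximation of the
#' MetaPhat-style central-trait search and is flagged `metaphat_like`
#' in the output.
#'
#' @param genotype dosage vector of the variant.
#' @param phenotypes samples x cluster-traits matrix.
#' @return list with `path` (data.frame: step, size, removed, traits,
#'   chisq, p, bic), `optimalSet`, `drivers` and `method =
#'   "metaphat_like"`.
#' @export
driverTraits <- function(genotype, phenotypes) {
  Y <- as.matrix(phenotypes)
  stopifnot(ncol(Y) >= 2)
  ok <- stats::complete.cases(Y) & !is.na(genotype)
  Y <- Y[ok, , drop = FALSE]
  g <- genotype[ok]
  n <- nrow(Y)
  traits <- colnames(Y)
  if (is.null(traits)) traits <- colnames(Y) <- paste0("t", seq_len(ncol(Y)))

  testSet <- function(set) {
    Ys <- standardizeCols(Y[, set, drop = FALSE])
    b <- drop(crossprod(Ys, scaleVec(g))) / (n - 1)
    S <- stats::cor(Y[, set, drop = FALSE])
    res <- ccaTest(b, S, n)
    c(chisq = res@chisq, p = res@p)
  }
  cur <- traits
  path <- list()
  step <- 1L
  st <- testSet(cur)
  path[[step]] <- data.frame(step = step, size = length(cur),
                             removed = NA_character_,
                             traits = paste(cur, collapse = ","),
                             chisq = st["chisq"], p = st["p"],
                             bic = -st["chisq"] + length(cur) * log(n))
  while (length(cur) > 1) {
    cand <- vapply(cur, function(t) testSet(setdiff(cur, t))["p"], 0)
    drop1 <- names(cand)[which.min(cand)]
    cur <- setdiff(cur, drop1)
    st <- testSet(cur)
    step <- step + 1L
    path[[step]] <- data.frame(step = step, size = length(cur),
                               removed = drop1,
                               traits = paste(cur, collapse = ","),
                               chisq = st["chisq"], p = st["p"],
                               bic = -st["chisq"] + length(cur) * log(n))
  }
  path <- do.call(rbind, path)
  rownames(path) <- NULL
  best <- which.min(path$bic)
  optimal <- strsplit(path$traits[best], ",")[[1]]
  list(path = path, optimalSet = optimal, drivers = optimal,
       method = "metaphat_like")
}
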
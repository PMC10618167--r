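#' @include AllClasses.R
NULL

#' Greedy LD pruning
#'
#' Variants are scanned in position order per chromosome. Each candidate
#' is compared with the already-kept variants lying within `windowKb` of
#' it; for any pair with squared correlation above `r2Max` the member
#' with the lower MAF is dropped (tie: the variant at the later
#' position). The scan advances one variant (`step = 1`) at a time, so
#' the result is deterministic.
#'
#' @param dosage variants x samples matrix.
#' @param variantTable data.frame aligned with the rows (columns
#'   `variant`, `chromosome`, `position`, `maf`, `info`).
#' @param windowKb window size in kb, default 1000.
#' @param r2Max pairwise r-squared threshold, default 0.7.
#' @param mafMin,infoMin,missMax inclusion filters applied before
#'   pruning (defaults 0.01, 0.95, 0.03).
#' @param excludeRegions optional data.frame (chromosome, start, end) of
#'   long-range LD regions to drop entirely.
#' @return character vector of kept variant ids, in position order.
#' @export
ldPrune <- function(dosage, variantTable, windowKb = 1000, r2Max = 0.7,
                    mafMin = 0.01, infoMin = 0.95, missMax = 0.03,
                    excludeRegions = NULL) {
  stopifnot(r2Max > 0, r2Max <= 1, windowKb > 0)
  vt <- variantTable
  keepMask <- vt$maf >= mafMin & vt$info >= infoMin
  if (!is.null(excludeRegions) && nrow(excludeRegions)) {
    for (i in seq_len(nrow(excludeRegions)))
      keepMask <- keepMask & !(vt$chromosome == excludeRegions$chromosome[i] &
                               vt$position >= excludeRegions$start[i] &
                               vt$position <= excludeRegions$end[i])
  }
  vt <- vt[keepMask, , drop = FALSE]
  dosage <- dosage[keepMask, , drop = FALSE]
  ord <- order(vt$chromosome, vt$position)
  vt <- vt[ord, , drop = FALSE]
  Z <- standardizeCols(t(dosage[ord, , drop = FALSE]))
  n <- nrow(Z)
  win <- windowKb * 1000
  kept <- character()
  keptIdx <- integer()
  for (i in seq_len(nrow(vt))) {
    ok <- TRUE
    inWin <- keptIdx[vt$chromosome[keptIdx] == vt$chromosome[i] &
                     vt$position[i] - vt$position[keptIdx] <= win]
    j <- length(inWin)
    while (j >= 1) {
      jj <- inWin[j]
      r2 <- (sum(Z[, i] * Z[, jj]) / (n - 1))^2
      if (r2 > r2Max) {
        dropLater <- vt$maf[i] == vt$maf[jj]
        if (vt$maf[i] < vt$maf[jj] || dropLater) { ok <- FALSE; break }
        keptIdx <- setdiff(keptIdx, jj)
        inWin <- setdiff(inWin, jj)
      }
      j <- j - 1
    }
    if (ok) keptIdx <- c(keptIdx, i)
  }
  vt$variant[keptIdx]
}

#' Genetic relationship matrix and genetic principal components
#'
#' `A = Z Z' / m` with the columns of `Z` the per-variant standardized
#' dosages. Monomorphic variants are dropped with a warning. The top
#' `nPcs` eigenvectors are returned as genetic PCs (computed through the
#' small `Z'Z / m` eigenproblem, so the cost is governed by the variant
#' count). For large cohorts the dense matrix can be skipped
#' (`dense = FALSE`); the returned factor `Z` is enough for
#' [estimateH2()].
#'
#' @param dosage variants x samples matrix.
#' @param keptIds variant ids (rownames of `dosage`) to use, e.g. from
#'   [ldPrune()].
#' @param nPcs number of genetic PCs, default 10.
#' @param dense also return the dense samples x samples matrix.
#' @return list with `A` (dense GRM or NULL), `Z` (samples x variants
#'   standardized dosages), `pcs` (samples x nPcs, orthonormal),
#'   `values` (the nonzero GRM eigenvalues) and `ids` (sample ids).
#' @export
computeGrm <- function(dosage, keptIds = rownames(dosage), nPcs = 10,
                       dense = TRUE) {
  sub <- dosage[keptIds, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " monomorphic variant(s) dropped from the GRM")
    sub <- sub[sds > 0, , drop = FALSE]
  }
  if (nrow(sub) < 10) stop("need at least 10 variants after pruning")
  Z <- standardizeCols(t(sub))
  m <- ncol(Z)
  C <- crossprod(Z) / m
  eg <- eigen(C, symmetric = TRUE)
  nz <- eg$values > 1e-10
  U <- Z %*% sweep(eg$vectors[, nz, drop = FALSE], 2,
                   sqrt(m * eg$values[nz]), `/`)
  pcs <- U[, seq_len(min(nPcs, ncol(U))), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  rownames(pcs) <- rownames(Z)
  list(A = if (dense) tcrossprod(Z) / m else NULL,
       Z = Z, pcs = pcs, values = eg$values[nz], ids = rownames(Z))
}

# REML for y = u + e, Var(u) = sg2 * diag(d) in the rotated basis.
# d: eigenvalues, yt: rotated centered phenotype. Returns variance
# components, h2, its standard error from the curvature of the profile
# log-likelihood, and the maximized value.
remlFromEigen <- function(d, yt) {
  d <- pmax(d, 0)
  n <- length(yt)
  prof <- function(h2) {
    v <- h2 * d + (1 - h2)
    s2 <- mean(yt^2 / v)
    0.5 * (n * log(s2) + sum(log(v)) + n)
  }
  opt <- stats::optimize(prof, c(0, 0.9999))
  h2 <- opt$minimum
  v <- h2 * d + (1 - h2)
  s2 <- mean(yt^2 / v)
  eps <- 1e-4
  h0 <- min(max(h2, eps), 1 - 2 * eps)
  info <- (prof(h0 + eps) - 2 * prof(h0) + prof(h0 - eps)) / eps^2
  se <- if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
  list(h2 = h2, se = se, sg2 = s2 * h2, se2 = s2 * (1 - h2),
       negloglik = opt$objective)
}

#' SNP-heritability of one phenotype
#'
#' `method = "haseman_elston"`: the cross-product of the standardized
#' phenotype over all sample pairs `i < j` is regressed on the
#' corresponding GRM entry; the slope estimates h2 and the standard
#' error comes from that regression. `method = "reml"`: a single
#' variance-component REML fit through the GRM eigen-basis, standard
#' error from the curvature of the profile log-likelihood. Estimates are
#' clamped to [0, 1] with a flag. Both are invariant to sign flips and
#' additive shifts of the phenotype.
#'
#' @param phenotype numeric vector (INT residuals); NAs are dropped
#'   together with the matching GRM rows.
#' @param grm output of [computeGrm()] (a dense matrix is also accepted
#'   for `haseman_elston` and `reml`).
#' @param method estimator.
#' @return A [HeritabilityEstimate-class].
#' @export
estimateH2 <- function(phenotype, grm,
                       method = c("haseman_elston", "reml")) {
  method <- match.arg(method)
  if (is.matrix(grm)) grm <- list(A = grm, Z = NULL)
  ok <- !is.na(phenotype)
  y <- phenotype[ok]
  if (stats::sd(y) == 0) stop("zero phenotype variance")
  y <- (y - mean(y)) / stats::sd(y)
  n <- length(y)

  if (method == "haseman_elston") {
    if (!is.null(grm$A)) {
      A <- grm$A[ok, ok, drop = FALSE]
      diagA <- diag(A)
      Amv <- function(v) drop(A %*% v)
      quad <- drop(crossprod(y, Amv(y)))
      oneA1 <- sum(A)
      fro2 <- sum(A^2)
    } else {
      Z <- grm$Z[ok, , drop = FALSE]
      m <- ncol(Z)
      diagA <- rowSums(Z^2) / m
      Amv <- function(v) drop(Z %*% drop(crossprod(Z, v))) / m
      quad <- sum(drop(crossprod(Z, y))^2) / m
      oneA1 <- sum(drop(crossprod(Z, rep(1, n)))^2) / m
      fro2 <- sum(crossprod(Z)^2) / m^2
    }
    trA <- sum(diagA)
    Sx <- (oneA1 - trA) / 2
    Sxx <- (fro2 - sum(diagA^2)) / 2
    Sxy <- (quad - sum(diagA * y^2)) / 2
    P <- n * (n - 1) / 2
    SxxC <- Sxx - Sx^2 / P
    Sy <- (sum(y)^2 - sum(y^2)) / 2
    SxyC <- Sxy - Sx * Sy / P
    slope <- SxyC / SxxC
    raw <- slope
    # sampling variance of the quadratic-form estimator under
    # y ~ N(0, h2 A + (1 - h2) I): var = 2 tr(M V M V) with M the
    # centered off-diagonal GRM over twice the regression denominator;
    # estimated with Rademacher trace probes (pairs sharing a sample are
    # dependent, so the naive pair-regression variance is too small)
    abar <- Sx / P
    a <- min(max(slope, 0), 1)
    Mmv <- function(v) (Amv(v) - diagA * v - abar * (sum(v) - v)) /
      (2 * SxxC)
    Vmv <- function(v) a * Amv(v) + (1 - a) * v
    tr <- withSeed(271828L, {
      probes <- 64L
      acc <- 0
      for (b in seq_len(probes)) {
        u <- sample(c(-1, 1), n, replace = TRUE)
        acc <- acc + sum(u * Mmv(Vmv(Mmv(Vmv(u)))))
      }
      acc / probes
    })
    se <- sqrt(max(2 * tr, 0))
  } else {
    if (!is.null(grm$Z)) {
      Z <- grm$Z[ok, , drop = FALSE]
      m <- ncol(Z)
      C <- crossprod(Z) / m
      eg <- eigen(C, symmetric = TRUE)
      nz <- eg$values > 1e-10
      U <- Z %*% sweep(eg$vectors[, nz, drop = FALSE], 2,
                       sqrt(m * eg$values[nz]), `/`)
      ytNz <- drop(crossprod(U, y))
      rss0 <- sum(y^2) - sum(ytNz^2)
      k0 <- n - length(ytNz)
      # aggregate the null-space components: equal eigenvalue 0, equal
      # contribution rss0 spread over k0 terms
      d <- c(eg$values[nz], rep(0, k0))
      yt <- c(ytNz, rep(sqrt(max(rss0, 0) / max(k0, 1)), k0))
    } else {
      A <- grm$A[ok, ok, drop = FALSE]
      eg <- eigen(A, symmetric = TRUE)
      d <- eg$values
      yt <- drop(crossprod(eg$vectors, y))
    }
    fit <- remlFromEigen(d, yt)
    raw <- fit$h2
    se <- fit$se
  }
  clamped <- raw < 0 || raw > 1
  new("HeritabilityEstimate", h2 = min(max(raw, 0), 1), se = se,
      method = method, clamped = clamped, raw = raw)
}

#' Write a GRM as lower-triangle text plus an id file
#'
#' @param grm output of [computeGrm()] with a dense `A`.
#' @param prefix path prefix; writes `<prefix>.grm.tsv` (i, j, value)
#'   and `<prefix>.ids.txt`.
#' @return the prefix, invisibly.
#' @export
writeGrm <- function(grm, prefix) {
  A <- grm$A
  if (is.null(A)) stop("dense GRM required; rerun computeGrm(dense = TRUE)")
  idx <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  utils::write.table(data.frame(i = idx[, 1], j = idx[, 2],
                                value = A[idx]),
                     paste0(prefix, ".grm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(grm$ids, paste0(prefix, ".ids.txt"))
  invisible(prefix)
}
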
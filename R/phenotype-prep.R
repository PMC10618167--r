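#' @include AllClasses.R
NULL

#' Adjust lipid measurements for covariates
#'
#' Per species, fits ordinary least squares of the measurement on all
#' covariate columns (factors expanded to dummies, intercept included)
#' over that species' non-missing samples, and returns the residuals.
#' Missing entries stay missing. A rank-deficient covariate matrix is an
#' error naming the collinear columns.
#'
#' @param phenotypes samples x species numeric matrix (NA = missing).
#' @param covariates data.frame row-aligned with `phenotypes`; a column
#'   named `sample` is ignored as an identifier.
#' @return residual matrix of the same shape.
#' @export
adjustCovariates <- function(phenotypes, covariates) {
  phenotypes <- as.matrix(phenotypes)
  if (nrow(phenotypes) != nrow(covariates))
    stop("covariate table is not row-aligned with the phenotypes")
  covariates <- covariates[, setdiff(names(covariates), "sample"),
                           drop = FALSE]
  if (anyNA(covariates)) stop("missing covariate values are not supported")
  X <- if (ncol(covariates) == 0) matrix(1, nrow(phenotypes), 1) else
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  out <- phenotypes
  for (j in seq_len(ncol(phenotypes))) {
    ok <- !is.na(phenotypes[, j])
    if (!any(ok)) stop("species ", colnames(phenotypes)[j],
                       ": no complete observations")
    fit <- stats::lm.fit(X[ok, , drop = FALSE], phenotypes[ok, j])
    out[ok, j] <- fit$residuals
  }
  out
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal scores at Blom probabilities,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties.
#' Missing values are preserved; a constant vector is an error.
#'
#' @param x numeric vector.
#' @return transformed vector of the same length.
#' @examples
#' inverseNormalTransform(c(3, 1, 4, 1, 5))
#' @export
inverseNormalTransform <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 3) stop("need at least 3 non-missing values")
  if (length(unique(v)) < 2) stop("degenerate phenotype: constant input")
  r <- rank(v, ties.method = "average")
  x[ok] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  x
}

#' Prepare phenotypes for association testing
#'
#' Covariate adjustment followed by the inverse-normal transform, per
#' species on its complete cases.
#'
#' @inheritParams adjustCovariates
#' @return A [PreparedPhenotypes-class].
#' @export
preparePhenotypes <- function(phenotypes, covariates) {
  res <- adjustCovariates(phenotypes, covariates)
  out <- apply(res, 2, inverseNormalTransform)
  dimnames(out) <- dimnames(res)
  covariates <- covariates[, setdiff(names(covariates), "sample"),
                           drop = FALSE]
  new("PreparedPhenotypes", residuals = out,
      nObs = as.integer(colSums(!is.na(out))),
      covariateNames = colnames(covariates))
}

#' @describeIn preparePhenotypes residual matrix accessor.
#' @param object a [PreparedPhenotypes-class].
#' @param ... unused.
#' @export
setMethod("residuals", "PreparedPhenotypes", function(object, ...)
  object@residuals)

#' Effective number of tests from lipidome principal components
#'
#' Missing entries are replaced by the species mean, the covariance PCA
#' is run, and the effective test count is the smallest number of
#' components whose cumulative explained variance share exceeds 90
#' percent. Derived Bonferroni thresholds are attached: the
#' genome-wide level divided by the component count (the BFS threshold),
#' the nominal level divided by the component count, and any extra
#' corrections requested through `extraDenominators`.
#'
#' @param phenotypes samples x species matrix (typically INT residuals).
#' @param alphaGw genome-wide level, default 5e-8.
#' @param alphaNominal nominal level, default 0.05.
#' @param varShare explained-variance target, default 0.9.
#' @param extraDenominators named list of count vectors; each entry `nm`
#'   adds a threshold `alphaNominal / prod(counts)` named `nm`.
#' @return A [TestBudget-class].
#' @examples
#' m <- matrix(rnorm(300), 100, 3)
#' effectiveTestCount(m)
#' @export
effectiveTestCount <- function(phenotypes, alphaGw = 5e-8,
                               alphaNominal = 0.05, varShare = 0.9,
                               extraDenominators = list()) {
  phenotypes <- as.matrix(phenotypes)
  if (nrow(phenotypes) < 2) stop("need at least 2 samples")
  if (ncol(phenotypes) < 2) stop("need at least 2 species")
  imp <- apply(phenotypes, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  ev <- stats::prcomp(imp, center = TRUE, scale. = FALSE)$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum > varShare)[1]
  thresholds <- c(uv_bfs = alphaGw / k,
                  uv_marginal = alphaNominal / k)
  for (nm in names(extraDenominators))
    thresholds[nm] <- bonferroniThreshold(alphaNominal,
                                          extraDenominators[[nm]])
  new("TestBudget", nComponents90 = as.integer(k), alphaGw = alphaGw,
      alphaNominal = alphaNominal, thresholds = thresholds)
}

#' Bonferroni-style threshold
#'
#' @param alpha base level in (0, 1).
#' @param denominators counts to divide by; the threshold is
#'   `alpha / prod(denominators)`.
#' @return the corrected threshold.
#' @examples
#' bonferroniThreshold(5e-8, 68)        # univariate BFS
#' bonferroniThreshold(0.05, c(85, 68)) # marginal, loci x components
#' @export
bonferroniThreshold <- function(alpha, denominators) {
  stopifnot(alpha > 0, alpha < 1, all(denominators >= 1))
  alpha / prod(denominators)
}

#' Serialize a test budget to a config-style text file
#'
#' @param budget a [TestBudget-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTestBudget <- function(budget, path) {
  lines <- c(sprintf("n_components_90: %d", budget@nComponents90),
             sprintf("alpha_gw: %.10g", budget@alphaGw),
             sprintf("alpha_nominal: %.10g", budget@alphaNominal),
             sprintf("%s: %.10g", names(budget@thresholds),
                     budget@thresholds))
  writeLines(lines, path)
  invisible(path)
}
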
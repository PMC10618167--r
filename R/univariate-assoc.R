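#' @include AllClasses.R
NULL

#' Variant inclusion filter
#'
#' Keeps variants with `MAF >= mafMin` and `INFO >= infoMin` (boundary
#' values kept: the exclusion rules are strict `MAF < 0.002` and
#' `INFO < 0.8`).
#'
#' @param variantTable data.frame with columns `variant`, `maf`, `info`.
#' @param mafMin minor-allele frequency floor, default 0.002.
#' @param infoMin imputation-quality floor, default 0.8.
#' @return character vector of kept variant ids.
#' @export
filterVariants <- function(variantTable, mafMin = 0.002, infoMin = 0.8) {
  stopifnot(mafMin >= 0, mafMin < 0.5, infoMin >= 0, infoMin <= 1)
  need <- c("variant", "maf", "info")
  if (!all(need %in% names(variantTable)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  variantTable$variant[variantTable$maf >= mafMin &
                       variantTable$info >= infoMin]
}

#' Per-variant association of one prepared phenotype
#'
#' `model = "ols"` regresses the phenotype on each variant's dosage
#' (intercept included) over the phenotype's complete cases, with a
#' two-sided Wald p from the normal approximation. `model = "lmm"` fits
#' `y = g b + u + e` with `u ~ N(0, sigma_g^2 GRM)`: the variance
#' components are estimated once on the null model by REML through the
#' GRM eigen-basis, then each variant is tested by generalized least
#' squares in that basis. With unrelated samples (GRM = identity) the two
#' models coincide. A variant with zero dosage variance in the analyzed
#' samples is reported with `p = 1` and `standard_error = NA`.
#'
#' @param phenotype numeric vector, covariate-adjusted and INT (NA =
#'   missing; those samples are dropped).
#' @param dosage variants x samples matrix.
#' @param variantTable data.frame (from [variantTable()]) aligned with
#'   the dosage rows; supplies chromosome, position, alleles, allele
#'   frequency and INFO.
#' @param model `"ols"` or `"lmm"`.
#' @param grm samples x samples relationship matrix (required for
#'   `"lmm"`).
#' @return data.frame of summary statistics with columns chromosome,
#'   base_pair_location, variant_id, effect_allele, other_allele,
#'   effect_allele_frequency, beta, standard_error, p_value, n, info,
#'   sorted by (chromosome, position). The effect allele is the
#'   alternate allele.
#' @export
gwas <- function(phenotype, dosage, variantTable, model = c("ols", "lmm"),
                 grm = NULL) {
  model <- match.arg(model)
  dosage <- as.matrix(dosage)
  stopifnot(length(phenotype) == ncol(dosage),
            nrow(variantTable) == nrow(dosage))
  ok <- !is.na(phenotype)
  y <- phenotype[ok]
  n <- length(y)
  if (n < 3) stop("fewer than 3 complete observations")
  G <- dosage[, ok, drop = FALSE]

  if (model == "ols") {
    gc <- G - rowMeans(G)
    yc <- y - mean(y)
    Sxx <- rowSums(gc^2)
    Sxy <- drop(gc %*% yc)
    Syy <- sum(yc^2)
    beta <- ifelse(Sxx > 0, Sxy / Sxx, 0)
    rss <- pmax(Syy - beta * Sxy, 0)
    se <- ifelse(Sxx > 0, sqrt(rss / (n - 2) / Sxx), NA_real_)
  } else {
    if (is.null(grm)) stop("lmm model requires a GRM")
    A <- grm[ok, ok, drop = FALSE]
    eg <- eigen(A, symmetric = TRUE)
    fit0 <- remlFromEigen(eg$values, drop(crossprod(eg$vectors, y - mean(y))))
    w <- 1 / (fit0$sg2 * pmax(eg$values, 0) + fit0$se2)
    U <- eg$vectors
    yt <- drop(crossprod(U, y))
    u0 <- drop(crossprod(U, rep(1, n)))
    Gt <- G %*% U                       # m x n rotated genotypes
    S00 <- sum(w * u0^2)
    S0y <- sum(w * u0 * yt)
    Sgg <- drop(Gt^2 %*% w)
    S0g <- drop(Gt %*% (w * u0))
    Sgy <- drop(Gt %*% (w * yt))
    det <- S00 * Sgg - S0g^2
    beta <- ifelse(det > 1e-12, (S00 * Sgy - S0g * S0y) / det, 0)
    se <- ifelse(det > 1e-12, sqrt(S00 / det), NA_real_)
    Sxx <- det
  }
  z <- ifelse(is.na(se) | se == 0, 0, beta / se)
  p <- ifelse(Sxx > 0, 2 * stats::pnorm(-abs(z)), 1)

  out <- data.frame(chromosome = variantTable$chromosome,
                    base_pair_location = variantTable$position,
                    variant_id = variantTable$variant,
                    effect_allele = variantTable$alt,
                    other_allele = variantTable$ref,
                    effect_allele_frequency =
                      if ("altFreq" %in% names(variantTable))
                        variantTable$altFreq else variantTable$maf,
                    beta = beta, standard_error = se, p_value = p,
                    n = n, info = variantTable$info)
  out[order(out$chromosome, out$base_pair_location), , drop = FALSE]
}

#' Univariate GWAS of every species in a cohort
#'
#' Applies the variant filter once, prepares nothing (phenotypes are
#' expected already adjusted and transformed), and runs [gwas()] per
#' species on its complete cases.
#'
#' @param prepared a [PreparedPhenotypes-class] (or samples x species
#'   matrix).
#' @param cohort a [LipidomeCohort-class].
#' @param mafMin,infoMin variant filter, see [filterVariants()].
#' @param model,grm passed to [gwas()].
#' @return named list of summary-statistic data.frames, one per species.
#' @export
uvGwasAll <- function(prepared, cohort, mafMin = 0.002, infoMin = 0.8,
                      model = "ols", grm = NULL) {
  Y <- if (is(prepared, "PreparedPhenotypes")) residuals(prepared)
       else as.matrix(prepared)
  vt <- variantTable(cohort)
  keep <- filterVariants(vt, mafMin, infoMin)
  idx <- match(keep, vt$variant)
  dos <- dosages(cohort)[idx, , drop = FALSE]
  vt <- vt[idx, , drop = FALSE]
  out <- lapply(colnames(Y), function(sp)
    gwas(Y[, sp], dos, vt, model = model, grm = grm))
  names(out) <- colnames(Y)
  out
}

#' Genomic inflation factor
#'
#' Median observed 1-df chi-square divided by the theoretical median
#' (about 0.4549).
#'
#' @param p two-sided p-values, or
#' @param chisq 1-df chi-square statistics (exactly one of the two).
#' @param df degrees of freedom of the supplied chi-squares (default 1).
#' @return the inflation factor lambda.
#' @examples
#' lambdaGC(p = runif(1000))
#' @export
lambdaGC <- function(p = NULL, chisq = NULL, df = 1) {
  if (is.null(chisq)) {
    if (is.null(p)) stop("supply p or chisq")
    if (length(p) < 100) stop("need at least 100 values")
    chisq <- stats::qchisq(p, df = df, lower.tail = FALSE)
  } else if (length(chisq) < 100) stop("need at least 100 values")
  stats::median(chisq) / stats::qchisq(0.5, df = df)
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' @param sumstats data.frame from [gwas()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSumstats <- function(sumstats, path) {
  utils::write.table(sumstats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSumstats
#' @export
readSumstats <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
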
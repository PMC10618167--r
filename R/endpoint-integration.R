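#' @include AllClasses.R
NULL

#' Effective case-control sample size
#'
#' `N_eff = N * theta * (1 - theta)`, with `theta` the case proportion.
#' Symmetric in `theta` and `1 - theta`, maximized at 0.5.
#'
#' @param n total sample size.
#' @param theta case proportion in [0, 1].
#' @return effective sample size.
#' @examples
#' neff(1000, 0.5)
#' @export
neff <- function(n, theta) {
  stopifnot(n >= 1, theta >= 0, theta <= 1)
  n * theta * (1 - theta)
}

# Firth-penalized logistic regression (Jeffreys prior), used as the
# fallback under separation.
firthLogistic <- function(X, y, maxIter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XtW <- t(X * W)
    Finfo <- XtW %*% X
    Fi <- solve(Finfo)
    # hat diagonal of sqrt(W) X (X'WX)^-1 X' sqrt(W)
    h <- rowSums((X %*% Fi) * X) * W
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(Fi %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(Fi))
  list(beta = beta, se = se)
}

#' PheWAS: logistic association of variants with binary endpoints
#'
#' Per variant and endpoint, logistic regression of case status on
#' dosage plus covariates with a two-sided Wald p. Endpoints with fewer
#' than 50 cases are excluded with a warning (the phenome-wide inclusion
#' rule). Complete or quasi-complete separation triggers a
#' Firth-penalized fallback, flagged in the output. Two significance
#' tiers are flagged: nominal corrected for the endpoint count
#' (`alphaNominal / nEndpoints`) and genome-wide corrected
#' (`alphaGw / nEndpoints`).
#'
#' @param variantIds variants to test (rownames of the dosage matrix).
#' @param dosage variants x samples matrix.
#' @param endpointStatus samples x endpoints 0/1 matrix.
#' @param covariates data.frame of adjustment covariates (a `sample`
#'   column is ignored); NULL for none.
#' @param alphaNominal,alphaGw base levels (0.05, 5e-8).
#' @return data.frame (variant, endpoint, beta, se, p, n_cases,
#'   firth, sig_nominal_corrected, sig_gws_corrected) with the
#'   thresholds in attributes.
#' @export
phewas <- function(variantIds, dosage, endpointStatus, covariates = NULL,
                   alphaNominal = 0.05, alphaGw = 5e-8) {
  cases <- colSums(endpointStatus)
  keep <- cases >= 50
  if (any(!keep))
    warning("excluded endpoint(s) with fewer than 50 cases: ",
            paste(colnames(endpointStatus)[!keep], collapse = ", "))
  endpointStatus <- endpointStatus[, keep, drop = FALSE]
  nEp <- ncol(endpointStatus)
  thrNom <- alphaNominal / nEp
  thrGws <- alphaGw / nEp
  X0 <- if (is.null(covariates)) NULL else
    stats::model.matrix(~ ., data = as.data.frame(
      covariates[, setdiff(names(covariates), "sample"), drop = FALSE]))[, -1,
                                                                 drop = FALSE]
  rows <- list()
  for (v in variantIds) {
    g <- dosage[v, ]
    for (e in colnames(endpointStatus)) {
      y <- endpointStatus[, e]
      X <- cbind(`(Intercept)` = 1, dosage = g, X0)
      sep <- FALSE
      fit <- withCallingHandlers(
        stats::glm.fit(X, y, family = stats::binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1",
                    conditionMessage(w))) sep <<- TRUE
          invokeRestart("muffleWarning")
        })
      p <- fit$fitted.values
      W <- p * (1 - p)
      Finfo <- crossprod(X * sqrt(W))
      ok <- tryCatch({
        covB <- solve(Finfo)
        beta <- fit$coefficients["dosage"]
        se <- sqrt(covB["dosage", "dosage"])
        !sep && is.finite(se) && se < 100
      }, error = function(e) FALSE)
      if (!ok) {
        ff <- firthLogistic(X, y)
        beta <- ff$beta[2]
        se <- ff$se[2]
        sep <- TRUE
      }
      pv <- 2 * stats::pnorm(-abs(beta / se))
      rows[[length(rows) + 1]] <-
        data.frame(variant = v, endpoint = e, beta = unname(beta),
                   se = unname(se), p = pv, n_cases = sum(y),
                   firth = sep,
                   sig_nominal_corrected = pv < thrNom,
                   sig_gws_corrected = pv < thrGws)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- c(nominal_corrected = thrNom,
                               gws_corrected = thrGws)
  out
}

#' Credible-set colocalization probability (CLPP)
#'
#' The probability of a shared causal variant between a lipid-trait
#' credible set and a disease credible set: the sum over the shared
#' variants of the product of the two per-signal PIPs. Pairs with
#' CLPP above `threshold` (default 0.01) are called colocalized. Both
#' sets are expected to be informative (minimum pairwise LD r-squared
#' at least 0.1); non-informative input raises a warning.
#'
#' @param csTrait,csEndpoint [CredibleSet-class] objects.
#' @param threshold colocalization cutoff, default 0.01.
#' @return list with `clpp`, `colocalized`, `shared` (variant ids).
#' @examples
#' a <- new("CredibleSet", signalIndex = 1L, variants = "v1",
#'          pips = c(v1 = 0.9), mass = 0.95, purity = 1,
#'          informative = TRUE, representative = "v1")
#' b <- new("CredibleSet", signalIndex = 1L, variants = "v1",
#'          pips = c(v1 = 0.8), mass = 0.95, purity = 1,
#'          informative = TRUE, representative = "v1")
#' clpp(a, b)$clpp   # 0.72
#' @export
clpp <- function(csTrait, csEndpoint, threshold = 0.01) {
  if (!csTrait@informative || !csEndpoint@informative)
    warning("colocalization between non-informative credible sets")
  shared <- intersect(csTrait@variants, csEndpoint@variants)
  val <- if (length(shared))
    sum(csTrait@pips[shared] * csEndpoint@pips[shared]) else 0
  list(clpp = val, colocalized = val > threshold, shared = shared)
}

#' Tiered lookup of external (e.g. disease risk) variants in the lipid GWAS
#'
#' For each external variant: if absent from the panel, the in-sample
#' variant with the highest LD r-squared above 0.8 within 500 kb of a
#' supplied proxy source variant is used instead (absent variants
#' without such a proxy are dropped, with a log entry in the output
#' attribute). Effects are aligned to the risk allele, and each
#' (variant, trait) pair is assigned the highest tier it reaches:
#' `gws_corrected` (genome-wide level divided by the test count),
#' `gws`, or `nominal_corrected` (0.05 divided by the test count).
#'
#' @param external data.frame (`variant`, `chromosome`, `position`,
#'   `riskAllele`).
#' @param sumstatsList named list of summary-statistic data.frames
#'   (univariate traits and/or multivariate clusters; for clusters the
#'   columns `p_value` and `variant_id` suffice).
#' @param nTests named numeric: the correction denominator per trait
#'   (e.g. 68 for univariate species, 11 for clusters).
#' @param dosage,variantTable optional panel for proxy resolution.
#' @param alphaNominal,alphaGw base levels.
#' @return data.frame (externalVariant, usedVariant, proxy, trait, beta,
#'   p, tier); attribute `dropped` lists unresolvable variants.
#' @export
variantLookup <- function(external, sumstatsList, nTests,
                          dosage = NULL, variantTable = NULL,
                          alphaNominal = 0.05, alphaGw = 5e-8) {
  rows <- list()
  dropped <- character()
  for (i in seq_len(nrow(external))) {
    ev <- external[i, ]
    used <- ev$variant
    proxy <- FALSE
    present <- any(vapply(sumstatsList, function(ss)
      ev$variant %in% ss$variant_id, TRUE))
    if (!present) {
      if (is.null(dosage) || is.null(variantTable)) {
        dropped <- c(dropped, ev$variant); next
      }
      cand <- which(variantTable$chromosome == ev$chromosome &
                    abs(variantTable$position - ev$position) <= 5e5 &
                    variantTable$variant != ev$variant)
      if (ev$variant %in% variantTable$variant && length(cand)) {
        gi <- dosage[ev$variant, ]
        r2 <- apply(dosage[variantTable$variant[cand], , drop = FALSE], 1,
                    function(g) stats::cor(g, gi)^2)
        if (max(r2) > 0.8) {
          used <- variantTable$variant[cand][which.max(r2)]
          proxy <- TRUE
        } else { dropped <- c(dropped, ev$variant); next }
      } else { dropped <- c(dropped, ev$variant); next }
    }
    for (tr in names(sumstatsList)) {
      ss <- sumstatsList[[tr]]
      j <- match(used, ss$variant_id)
      if (is.na(j)) next
      k <- if (tr %in% names(nTests)) nTests[[tr]] else nTests[[1]]
      beta <- if ("beta" %in% names(ss)) ss$beta[j] else NA_real_
      if (!is.na(beta) && "effect_allele" %in% names(ss) && !proxy &&
          !is.na(ev$riskAllele) && ev$riskAllele == ss$other_allele[j])
        beta <- -beta
      pv <- ss$p_value[j]
      tier <- if (pv < alphaGw / k) "gws_corrected"
        else if (pv < alphaGw) "gws"
        else if (pv < alphaNominal / k) "nominal_corrected"
        else "none"
      rows[[length(rows) + 1]] <-
        data.frame(externalVariant = ev$variant, usedVariant = used,
                   proxy = proxy, trait = tr, beta = beta, p = pv,
                   tier = tier)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(externalVariant = character(), usedVariant = character(),
               proxy = logical(), trait = character(), beta = numeric(),
               p = numeric(), tier = character())
  attr(out, "dropped") <- dropped
  out
}

#' Endpoint-by-trait summary with the colocalization conjunction
#'
#' Flags the (endpoint, trait) combinations that reach the GWS-corrected
#' PheWAS tier AND colocalize (CLPP above the threshold) — the rule used
#' for heatmap-style reporting.
#'
#' @param phewasTable output of [phewas()] with a `trait` column mapping
#'   each variant to its lipidome trait.
#' @param colocTable data.frame (trait, endpoint, clpp).
#' @param clppThreshold default 0.01.
#' @return data.frame (endpoint, trait, phewasHit, colocalized, linked).
#' @export
phewasColocSummary <- function(phewasTable, colocTable,
                               clppThreshold = 0.01) {
  agg <- stats::aggregate(sig_gws_corrected ~ endpoint + trait,
                          data = phewasTable, FUN = any)
  names(agg)[3] <- "phewasHit"
  cl <- stats::aggregate(clpp ~ endpoint + trait, data = colocTable,
                         FUN = max)
  out <- merge(agg, cl, by = c("endpoint", "trait"), all.x = TRUE)
  out$clpp[is.na(out$clpp)] <- 0
  out$colocalized <- out$clpp > clppThreshold
  out$linked <- out$phewasHit & out$colocalized
  out[order(out$endpoint, out$trait), ]
}
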
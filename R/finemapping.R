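#' @include AllClasses.R
NULL

#' Fine-mapping configuration
#'
#' @param kMax maximum causal variants per region (default 3; exhaustive
#'   enumeration is exact but the configuration count grows as
#'   `choose(m, k)`).
#' @param priorSigma prior standard deviation of a standardized causal
#'   effect (default 0.05).
#' @param priorPi per-variant prior inclusion probability; NULL = 1/m.
#' @param mhc excluded region (chromosome, start, end); default the MHC,
#'   chr6:25,000,000-34,000,000.
#' @param functionalR2 LD threshold for substituting a functional variant
#'   as representative (default 0.95).
#' @param budgetK2,budgetK3 maximum region sizes for enumeration at
#'   `kMax <= 2` and `kMax = 3` (defaults 2000 and 200).
#' @return list of settings used by [finemapRegion()].
#' @export
finemapConfig <- function(kMax = 3, priorSigma = 0.05, priorPi = NULL,
                          mhc = list(chromosome = "chr6",
                                     start = 25e6, end = 34e6),
                          functionalR2 = 0.95,
                          budgetK2 = 2000, budgetK3 = 200) {
  stopifnot(kMax >= 1, priorSigma > 0, functionalR2 > 0, functionalR2 <= 1)
  list(kMax = as.integer(kMax), priorSigma = priorSigma, priorPi = priorPi,
       mhc = mhc, functionalR2 = functionalR2,
       budgetK2 = budgetK2, budgetK3 = budgetK3)
}

# log N(z; 0, Sigma) up to the shared (2 pi)^(-k/2) constant
logMvn <- function(z, Sigma) {
  ch <- chol(Sigma)
  -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, z, transpose = TRUE)^2)
}

#' Exhaustive Bayesian fine-mapping of one region
#'
#' Enumerates every causal configuration `C` with `|C| <= kMax`
#' (including the null configuration). Under configuration `C` the
#' z-scores follow `z_C ~ N(0, R_C + N sigma^2 R_C R_C)`; under the null
#' `z_C ~ N(0, R_C)`; the Bayes factor is the likelihood ratio, the
#' prior is independent-inclusion `pi^|C| (1 - pi)^(m - |C|)`, and the
#' posterior is normalized over all enumerated configurations. The
#' marginal PIP of a variant is the summed posterior of the
#' configurations containing it, and the MAP causal count `k*` maximizes
#' the posterior summed within each size. A non-positive-definite LD
#' matrix is ridge-repaired with a 1e-6 diagonal (logged as a message).
#'
#' @param z named z-score vector for the region variants.
#' @param R signed in-sample LD (correlation) matrix, same order.
#' @param n GWAS sample size.
#' @param config from [finemapConfig()].
#' @return A [FinemapFit-class].
#' @export
finemapRegion <- function(z, R, n, config = finemapConfig()) {
  m <- length(z)
  stopifnot(nrow(R) == m, ncol(R) == m)
  if (is.null(names(z))) names(z) <- paste0("v", seq_len(m))
  kMax <- min(config$kMax, m)
  if (kMax >= 3 && m > config$budgetK3)
    stop("region of ", m, " variants exceeds the enumeration budget for K = 3")
  if (kMax <= 2 && m > config$budgetK2)
    stop("region of ", m, " variants exceeds the enumeration budget")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    message("LD matrix not positive definite; ridge-repaired with 1e-6")
    R <- R + diag(1e-6, m)
  }
  pi0 <- if (is.null(config$priorPi)) 1 / m else config$priorPi
  c0 <- n * config$priorSigma^2

  configs <- list(integer(0))
  logBF <- 0
  for (k in seq_len(kMax)) {
    sets <- utils::combn(m, k, simplify = FALSE)
    bf <- vapply(sets, function(C) {
      Rc <- R[C, C, drop = FALSE]
      S1 <- Rc + c0 * (Rc %*% Rc)
      logMvn(z[C], S1) - logMvn(z[C], Rc)
    }, 0)
    configs <- c(configs, sets)
    logBF <- c(logBF, bf)
  }
  sizes <- lengths(configs)
  logPrior <- ifelse(sizes == 0, 0, sizes * log(pi0)) +
    ifelse(sizes == m, 0, (m - sizes) * log1p(-pi0))
  lp <- logBF + logPrior
  post <- exp(lp - max(lp))
  post <- post / sum(post)

  pip <- numeric(m)
  for (i in seq_along(configs)) pip[configs[[i]]] <- pip[configs[[i]]] + post[i]
  names(pip) <- names(z)
  kPost <- vapply(0:kMax, function(k) sum(post[sizes == k]), 0)
  names(kPost) <- as.character(0:kMax)
  new("FinemapFit", variants = names(z), configs = configs,
      logBF = logBF, posterior = post,
      pip = pip, kMap = as.integer(which.max(kPost) - 1L),
      kPosterior = kPost)
}

# canonical key for a configuration (sorted indices)
configKey <- function(C) paste(sort(C), collapse = ",")

#' Per-signal 95 percent credible sets
#'
#' Takes the MAP configuration of size `kStar` (default the MAP causal
#' count). For each of its variants, per-signal PIPs are the posterior
#' masses of the configurations obtained by swapping that variant for
#' each candidate while the other MAP variants stay fixed, renormalized;
#' the credible set is the smallest descending-PIP prefix with mass at
#' least 0.95. Purity is the minimum pairwise LD r-squared among the
#' members (1 for a singleton); a set is informative when purity is at
#' least 0.1. When `kStar = 0` no sets are returned and the caller
#' should fall back to the GWAS lead variant as representative.
#'
#' @param fit a [FinemapFit-class].
#' @param R the region LD matrix (signed correlations).
#' @param kStar number of signals (defaults to `fit@kMap`).
#' @param annotations optional data.frame (`variant`, `class`) used by
#'   [representativeVariant()].
#' @param config from [finemapConfig()] (for the functional-substitution
#'   threshold).
#' @return list of [CredibleSet-class], one per signal.
#' @export
buildCredibleSets <- function(fit, R, kStar = fit@kMap, annotations = NULL,
                              config = finemapConfig()) {
  if (kStar < 1) return(list())
  m <- length(fit@variants)
  sizes <- lengths(fit@configs)
  keys <- vapply(fit@configs, configKey, "")
  postByKey <- stats::setNames(fit@posterior, keys)
  cand <- which(sizes == kStar)
  cstar <- fit@configs[[cand[which.max(fit@posterior[cand])]]]

  out <- vector("list", kStar)
  for (i in seq_along(cstar)) {
    base <- setdiff(cstar, cstar[i])
    swapIdx <- setdiff(seq_len(m), base)
    mass <- vapply(swapIdx, function(v) {
      k <- configKey(c(base, v))
      if (k %in% names(postByKey)) postByKey[[k]] else 0
    }, 0)
    pipSig <- mass / sum(mass)
    ord <- order(pipSig, decreasing = TRUE)
    cum <- cumsum(pipSig[ord])
    take <- seq_len(which(cum >= 0.95)[1])
    memberIdx <- swapIdx[ord[take]]
    members <- fit@variants[memberIdx]
    purity <- if (length(memberIdx) == 1) 1 else
      min((R[memberIdx, memberIdx, drop = FALSE][
        upper.tri(diag(length(memberIdx)))])^2)
    cs <- new("CredibleSet", signalIndex = i, variants = members,
              pips = stats::setNames(pipSig[ord[take]], members),
              mass = cum[length(take)], purity = purity,
              informative = purity >= 0.1,
              representative = members[1])
    if (!is.null(annotations))
      cs@representative <- representativeVariant(cs, annotations, R,
                                                 fit@variants,
                                                 r2Min = config$functionalR2)
    out[[i]] <- cs
  }
  out
}

#' Severity-ordered functional variant classes
#'
#' The consequence classes counted as functional, ordered from most to
#' least severe (the standard Ensembl severity ranking down to
#' splice-region variants).
#'
#' @return character vector.
#' @export
functionalClasses <- function() {
  c("transcript_ablation", "splice_acceptor_variant",
    "splice_donor_variant", "stop_gained", "frameshift_variant",
    "stop_lost", "start_lost", "transcript_amplification",
    "inframe_insertion", "inframe_deletion", "missense_variant",
    "protein_altering_variant", "splice_region_variant")
}

#' Representative variant of a credible set
#'
#' The top-PIP variant, unless the set contains a functional variant
#' (see [functionalClasses()]) in LD `r^2 > r2Min` with it, in which
#' case the functional variant with the largest r-squared is chosen.
#'
#' @param cs a [CredibleSet-class].
#' @param annotations data.frame with columns `variant` and `class`.
#' @param R region LD matrix.
#' @param regionVariants variant ids indexing `R` (defaults to the
#'   matrix dimnames).
#' @param r2Min substitution threshold, default 0.95.
#' @return variant id.
#' @export
representativeVariant <- function(cs, annotations, R,
                                  regionVariants = rownames(R),
                                  r2Min = 0.95) {
  top <- cs@variants[1]
  func <- annotations$variant[annotations$class %in% functionalClasses()]
  inCs <- intersect(func, cs@variants)
  if (!length(inCs)) return(top)
  it <- match(top, regionVariants)
  r2 <- (R[match(inCs, regionVariants), it])^2
  best <- inCs[which.max(r2)]
  if (max(r2) > r2Min) best else top
}

#' Region exclusion decision
#'
#' Regions overlapping an excluded interval (by default the MHC,
#' chr6:25-34 Mb) skip fine-mapping; the GWAS lead variant becomes the
#' sole representative.
#'
#' @param chromosome,start,end the region.
#' @param exclusions data.frame (chromosome, start, end); default the
#'   configured MHC interval.
#' @param config from [finemapConfig()].
#' @return list with `finemap` (logical) and `reason`.
#' @export
applyRegionExclusions <- function(chromosome, start, end,
                                  exclusions = NULL,
                                  config = finemapConfig()) {
  if (is.null(exclusions))
    exclusions <- data.frame(chromosome = config$mhc$chromosome,
                             start = config$mhc$start,
                             end = config$mhc$end)
  if (nrow(exclusions))
    for (i in seq_len(nrow(exclusions)))
      if (chromosome == exclusions$chromosome[i] &&
          start <= exclusions$end[i] && end >= exclusions$start[i])
        return(list(finemap = FALSE, reason = "excluded region overlap"))
  list(finemap = TRUE, reason = "")
}

#' Write credible sets to a tab-delimited file
#'
#' Columns: region_id, trait, signal_index, variant, pip, in_cs95,
#' purity, informative, representative.
#'
#' @param csList list of [CredibleSet-class].
#' @param regionId,trait identifiers repeated per row.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCredibleSets <- function(csList, regionId, trait, path) {
  rows <- do.call(rbind, lapply(csList, function(cs)
    data.frame(region_id = regionId, trait = trait,
               signal_index = cs@signalIndex, variant = cs@variants,
               pip = cs@pips, in_cs95 = TRUE, purity = cs@purity,
               informative = cs@informative,
               representative = cs@representative)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
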
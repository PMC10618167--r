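#' @include AllClasses.R
NULL

#' Accessors for simulated cohorts and pipeline objects
#'
#' `dosages()` returns the variants x samples dosage matrix, `variantTable()`
#' the per-variant annotation as a data.frame (chromosome, position, ref,
#' alt, maf, info), `lipidome()` the samples x species measurement matrix,
#' `covariates()` the covariate table, `endpointStatus()` the samples x
#' endpoints 0/1 matrix and `truthLedger()` the ground-truth ledger.
#'
#' @param x an object.
#' @return the requested component.
#' @name cohort-accessors
#' @aliases dosages variantTable lipidome covariates endpointStatus
#'   truthLedger
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname cohort-accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))
#' @rdname cohort-accessors
#' @export
setGeneric("lipidome", function(x) standardGeneric("lipidome"))
#' @rdname cohort-accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @rdname cohort-accessors
#' @export
setGeneric("endpointStatus", function(x) standardGeneric("endpointStatus"))
#' @rdname cohort-accessors
#' @export
setGeneric("truthLedger", function(x) standardGeneric("truthLedger"))

#' @rdname cohort-accessors
#' @export
setMethod("dosages", "LipidomeCohort", function(x)
  SummarizedExperiment::assay(x@genotypes, "dosage"))

#' @rdname cohort-accessors
#' @export
setMethod("variantTable", "LipidomeCohort", function(x) {
  gr <- SummarizedExperiment::rowRanges(x@genotypes)
  data.frame(variant = names(gr),
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             position = GenomicRanges::start(gr),
             ref = gr$ref, alt = gr$alt, maf = gr$maf, info = gr$info,
             row.names = NULL)
})

#' @rdname cohort-accessors
#' @export
setMethod("lipidome", "LipidomeCohort", function(x) x@lipidome)
#' @rdname cohort-accessors
#' @export
setMethod("covariates", "LipidomeCohort", function(x) x@covariates)
#' @rdname cohort-accessors
#' @export
setMethod("endpointStatus", "LipidomeCohort", function(x) x@endpointStatus)
#' @rdname cohort-accessors
#' @export
setMethod("truthLedger", "LipidomeCohort", function(x) x@truth)

#' Cluster membership accessor
#' @param x a [TraitCluster-class].
#' @return character vector of member species ids.
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname members
#' @export
setMethod("members", "TraitCluster", function(x) x@members)

#' Posterior inclusion probabilities
#' @param x a [FinemapFit-class] or [CredibleSet-class].
#' @return named numeric vector of PIPs.
#' @export
setGeneric("pips", function(x) standardGeneric("pips"))
#' @rdname pips
#' @export
setMethod("pips", "FinemapFit", function(x) x@pip)
#' @rdname pips
#' @export
setMethod("pips", "CredibleSet", function(x) x@pips)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSamples, "samples,", object@nVariants,
      "variants (blocks of", object@blockSize, ", ldRho =", object@ldRho,
      "),", object@nSpecies, "species in", object@nClasses, "classes\n")
  cat("  planted effects:", length(object@plantedEffects),
      "| endpoints:", nrow(object@endpointSpecs),
      "| seed:", object@seed, "\n")
})

setMethod("show", "LipidomeCohort", function(object) {
  cat("LipidomeCohort:", ncol(dosages(object)), "samples x",
      nrow(dosages(object)), "variants;", ncol(object@lipidome),
      "lipid species;", ncol(object@endpointStatus), "endpoints\n")
})

setMethod("show", "TestBudget", function(object) {
  cat("TestBudget: ", object@nComponents90,
      " PCs explain >90% of phenotypic variance\n", sep = "")
  for (nm in names(object@thresholds))
    cat(sprintf("  %-24s %.6e\n", nm, object@thresholds[[nm]]))
})

setMethod("show", "TraitCluster", function(object) {
  cat("TraitCluster ", object@id, ": ", length(object@members),
      " members (", length(object@removedPairwise), " removed pairwise, ",
      length(object@removedVif), " by VIF)\n", sep = "")
})

setMethod("show", "MvTestResult", function(object) {
  cat(sprintf("MvTestResult %s x %s: r = %.4f, chisq = %.3f (df %d), p = %.3g",
              object@variant, object@cluster, object@r, object@chisq,
              object@df, object@p))
  if (object@lambda != 1)
    cat(sprintf(", lambda = %.3f, p_corrected = %.3g",
                object@lambda, object@pCorrected))
  cat("\n")
})

setMethod("show", "HeritabilityEstimate", function(object) {
  cat(sprintf("h2 = %.4f (se %.4f, %s%s)\n", object@h2, object@se,
              object@method, if (object@clamped) ", clamped" else ""))
})

setMethod("show", "FinemapFit", function(object) {
  cat("FinemapFit:", length(object@variants), "variants,",
      length(object@configs), "configurations, MAP k =", object@kMap, "\n")
})

setMethod("show", "CredibleSet", function(object) {
  cat(sprintf("CredibleSet (signal %d): %d variants, mass %.3f, purity %.3f%s; representative %s\n",
              object@signalIndex, length(object@variants), object@mass,
              object@purity,
              if (object@informative) " (informative)" else " (not informative)",
              object@representative))
})
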
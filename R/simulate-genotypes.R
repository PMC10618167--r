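#' @include AllClasses.R
NULL

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# Deterministic sub-stream seeds so the genotype, lipidome and endpoint
# draws are reproducible individually. Kept well below 2^31.
subSeed <- function(seed, offset) (abs(seed) %% 2000000000L) + offset

#' Simulate blockwise-LD genotype dosages
#'
#' Genotypes are built from a Gaussian copula: per haplotype and LD block,
#' a latent AR(1) series with parameter `ldRho` is thresholded at the
#' normal quantile of each variant's allele frequency; the two haplotypes
#' are summed into a 0/1/2 genotype. Blocks are independent, so LD decays
#' as `ldRho^d` on the latent scale within a block and is zero across
#' blocks. Imputation noise is emulated by shrinking each variant's
#' genotype toward its expected dosage, `dosage = (1 - e) * genotype +
#' e * 2 * maf`, with `e` drawn per variant; the INFO score is recorded
#' as the ratio of the dosage variance to `2 * maf * (1 - maf)`, which is
#' the standard imputation-quality summary.
#'
#' @param config a [SimConfig-class].
#' @return A [SummarizedExperiment::RangedSummarizedExperiment] with
#'   assay `"dosage"` (variants x samples, values in [0, 2]) and
#'   `rowRanges` carrying `ref`, `alt`, `maf` (realized minor-allele
#'   frequency of the dosage), `altFreq` and `info`.
#' @examples
#' se <- simulateGenotypes(simConfig(nSamples = 100, nVariants = 20, seed = 3))
#' dim(SummarizedExperiment::assay(se))
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- config@nSamples
  m <- config@nVariants
  withSeed(subSeed(config@seed, 0L), {
    ms <- config@mafSpectrum
    cls <- sample.int(nrow(ms), m, replace = TRUE, prob = ms$weight)
    maf <- stats::runif(m, ms$low[cls], ms$high[cls])
    thr <- stats::qnorm(maf)

    nBlocks <- ceiling(m / config@blockSize)
    block <- rep(seq_len(nBlocks), each = config@blockSize)[seq_len(m)]
    rho <- config@ldRho
    geno <- matrix(0L, nrow = m, ncol = n)
    for (b in seq_len(nBlocks)) {
      idx <- which(block == b)
      k <- length(idx)
      for (h in 1:2) {
        z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k)
        if (rho > 0 && k > 1) {
          s <- sqrt(1 - rho^2)
          for (j in 2:k) z[, j] <- rho * z[, j - 1] + s * z[, j]
        }
        geno[idx, ] <- geno[idx, ] +
          t(sweep(z, 2, thr[idx], `<`) * 1L)
      }
    }

    # imputation-noise emulation; most variants stay above INFO 0.8
    e <- stats::rbeta(m, 1, 19)
    dos <- (1 - e) * geno + e * (2 * maf)

    altFreq <- rowMeans(dos) / 2
    mafReal <- pmin(altFreq, 1 - altFreq)
    v <- apply(dos, 1, stats::var)
    hw <- 2 * mafReal * (1 - mafReal)
    info <- ifelse(hw > 0, pmin(v / hw, 1), 0)

    # contiguous chromosome assignment: first ceiling(nBlocks/C) blocks on
    # chr1, and so on
    perChrom <- ceiling(nBlocks / config@nChromosomes)
    chromOfBlock <- ((seq_len(nBlocks) - 1L) %/% perChrom) + 1L
    chrom <- paste0("chr", chromOfBlock[block])
    pos <- integer(m)
    for (cc in unique(chrom)) {
      ii <- which(chrom == cc)
      pos[ii] <- seq_along(ii) * config@posStep + 1L
    }

    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")

    ids <- sprintf("var%05d", seq_len(m))
    rownames(dos) <- ids
    colnames(dos) <- sprintf("S%05d", seq_len(n))
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = pos, width = 1L),
                                 ref = ref, alt = unname(alt),
                                 maf = mafReal, altFreq = altFreq,
                                 info = info, block = block)
    names(gr) <- ids
    SummarizedExperiment::SummarizedExperiment(
      assays = list(dosage = dos), rowRanges = gr)
  })
}

# standardize columns (samples x k) to mean 0, sd 1; zero-variance columns
# become all-zero
standardizeCols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- Inf
  sweep(sweep(x, 2, mu), 2, sd, `/`)
}
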
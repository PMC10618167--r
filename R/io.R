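#' @include AllClasses.R
NULL

#' Write genotype dosages as a VCF with a per-sample DS field
#'
#' Minimal VCFv4.2 output: one record per variant with `GT:DS`, genotype
#' hard-called from the dosage. Positions are 1-based.
#'
#' @param genotypes RangedSummarizedExperiment from
#'   [simulateGenotypes()].
#' @param path output file (plain text).
#' @return the path, invisibly.
#' @export
writeDosageVcf <- function(genotypes, path) {
  gr <- SummarizedExperiment::rowRanges(genotypes)
  dos <- SummarizedExperiment::assay(genotypes, "dosage")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(dos)),
                     collapse = "\t")), con)
  gtOf <- function(d) c("0/0", "0/1", "1/1")[pmin(pmax(round(d), 0), 2) + 1]
  for (i in seq_len(nrow(dos))) {
    fields <- paste(gtOf(dos[i, ]), sprintf("%.4g", dos[i, ]), sep = ":")
    writeLines(paste(c(as.character(GenomicRanges::seqnames(gr)[i]),
                       GenomicRanges::start(gr)[i], names(gr)[i],
                       gr$ref[i], gr$alt[i], ".", "PASS", ".", "GT:DS",
                       fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF with a DS field
#'
#' Uses VariantAnnotation when available, falling back to a plain-text
#' scan of uncompressed files.
#'
#' @param path VCF file.
#' @return list with `dosage` (variants x samples matrix) and `variants`
#'   (data.frame: variant, chromosome, position, ref, alt).
#' @export
readDosageVcf <- function(path) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path)
    dos <- VariantAnnotation::geno(vcf)$DS
    mode(dos) <- "numeric"
    rr <- SummarizedExperiment::rowRanges(vcf)
    vt <- data.frame(variant = names(rr),
                     chromosome = as.character(GenomicRanges::seqnames(rr)),
                     position = GenomicRanges::start(rr),
                     ref = as.character(rr$REF),
                     alt = vapply(rr$ALT, function(a)
                       as.character(a)[1], ""))
    return(list(dosage = dos, variants = vt))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- strsplit(lines[-1], "\t")
  samples <- hdr[-(1:9)]
  vt <- data.frame(
    variant = vapply(body, `[`, "", 3),
    chromosome = vapply(body, `[`, "", 1),
    position = as.integer(vapply(body, `[`, "", 2)),
    ref = vapply(body, `[`, "", 4),
    alt = vapply(body, `[`, "", 5))
  dos <- t(vapply(body, function(f) {
    fmt <- strsplit(f[9], ":")[[1]]
    di <- which(fmt == "DS")
    vapply(f[-(1:9)], function(x)
      as.numeric(strsplit(x, ":")[[1]][di]), 0, USE.NAMES = FALSE)
  }, numeric(length(samples))))
  dimnames(dos) <- list(vt$variant, samples)
  list(dosage = dos, variants = vt)
}

#' Read / write tab-delimited phenotype and covariate tables
#'
#' First column `sample`, header row of trait or covariate names, `NA`
#' for missing.
#'
#' @param path file path.
#' @return `readPhenotypeTable`: list with `matrix` (samples x traits)
#'   and `samples`; `writePhenotypeTable` the path invisibly.
#' @export
readPhenotypeTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  list(matrix = m, samples = df[[1]])
}

#' @rdname readPhenotypeTable
#' @param m samples x traits matrix with rownames.
#' @export
writePhenotypeTable <- function(m, path) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
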
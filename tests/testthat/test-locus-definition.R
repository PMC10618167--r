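makeStats <- function(pos, p, chrom = "chr1") {
  data.frame(chromosome = chrom, base_pair_location = pos,
             variant_id = sprintf("s%04d", seq_along(pos)), p_value = p)
}

test_that("no genome-wide variant means no regions", {
  ss <- makeStats(seq(1e5, 1e6, by = 1e5), rep(1e-3, 10))
  expect_length(findRegions(ss), 0)
})

test_that("two peaks 2 Mb apart combine into one region with a secondary lead", {
  pos <- seq(1e5, 9e6, by = 1e5)
  p <- rep(0.5, length(pos))
  p[pos == 2e6] <- 1e-12
  p[pos == 4e6] <- 1e-10
  reg <- findRegions(makeStats(pos, p))
  expect_length(reg, 1)
  expect_identical(reg$lead, "s0020")
  expect_identical(reg$secondaryLeads, "s0040")
  expect_equal(GenomicRanges::start(reg), 2e6 - 1.5e6)
  expect_equal(GenomicRanges::end(reg), 4e6 + 1.5e6)
})

test_that("a chained peak set wider than 6 Mb is shrunk below the cap with leads preserved", {
  pos <- seq(1e5, 12e6, by = 1e5)
  p <- rep(0.5, length(pos))
  peaks <- c(2e6, 4e6, 5.5e6, 7e6, 9e6)
  for (i in seq_along(peaks)) p[pos == peaks[i]] <- 10^-(15 - i)
  reg <- findRegions(makeStats(pos, p))
  expect_true(all(GenomicRanges::width(reg) < 6e6))
  leads <- unlist(c(reg$lead,
                    strsplit(reg$secondaryLeads[reg$secondaryLeads != ""],
                             ",")))
  expect_setequal(leads, sprintf("s%04d", peaks / 1e5))
  expect_true(all(reg$halfWindow < 1.5e6))
})

test_that("every genome-wide significant variant lies inside some region", {
  withr::with_seed(4, {
    pos <- sort(sample(seq(1e5, 3e7, by = 1e4), 400))
    p <- runif(400)
    p[sample(400, 25)] <- 10^-runif(25, 8.5, 30)
    ss <- makeStats(pos, p)
    reg <- findRegions(ss)
    sig <- ss[ss$p_value < 5e-8, ]
    covered <- vapply(seq_len(nrow(sig)), function(i)
      any(GenomicRanges::start(reg) <= sig$base_pair_location[i] &
          GenomicRanges::end(reg) >= sig$base_pair_location[i]), TRUE)
    expect_true(all(covered))
  })
})

test_that("multivariate-univariate overlap follows the LD and tier rule", {
  uv <- list(t1 = data.frame(variant_id = c("a", "b"),
                             p_value = c(1e-12, 0.2)))
  expect_true(mvUvOverlap("a", uv, c(a = 1, b = 0.9)))
  # best univariate variant only weakly linked: multivariate-only discovery
  expect_false(mvUvOverlap("lead", uv, c(a = 0.05, b = 0.9)))
  uvNull <- list(t1 = data.frame(variant_id = c("a", "b"),
                                 p_value = c(1e-3, 0.5)))
  expect_false(mvUvOverlap("lead", uvNull, c(a = 1, b = 1)))
})

test_that("signals merge at r2 >= 0.1 within a chromosome and loci are disjoint", {
  reps <- data.frame(variant = c("r1", "r2", "r3"),
                     trait = c("t1", "t2", "t3"),
                     chromosome = c("chr1", "chr1", "chr2"),
                     start = c(1e6, 1.4e6, 5e6),
                     end = c(4e6, 4.4e6, 8e6),
                     position = c(2.5e6, 2.9e6, 6.5e6))
  ld <- diag(3)
  dimnames(ld) <- list(reps$variant, reps$variant)
  ld["r1", "r2"] <- ld["r2", "r1"] <- sqrt(0.2)   # r2 = 0.2: merge
  out <- mergeSignals(reps, ld)
  expect_equal(nrow(out$signals), 2)
  expect_length(out$loci, 2)
  sameSignal <- out$signals[grepl("r1", out$signals$representatives), ]
  expect_true(grepl("r2", sameSignal$representatives))
  expect_equal(sameSignal$start, 1e6)
  expect_equal(sameSignal$end, 4.4e6)

  # different chromosomes never merge even at r2 = 1
  ld2 <- ld; ld2["r1", "r3"] <- ld2["r3", "r1"] <- 1
  out2 <- mergeSignals(reps, ld2)
  expect_equal(nrow(out2$signals), 2)

  # single representative: one signal, one locus
  out3 <- mergeSignals(reps[1, ], matrix(1, 1, 1,
                                         dimnames = list("r1", "r1")))
  expect_equal(nrow(out3$signals), 1)
  expect_length(out3$loci, 1)
})

test_that("merging is idempotent on its own representatives", {
  reps <- data.frame(variant = c("r1", "r2"), trait = c("t1", "t2"),
                     chromosome = "chr1", start = c(1e6, 2e6),
                     end = c(3e6, 4e6), position = c(2e6, 3e6))
  ld <- matrix(c(1, 0.6, 0.6, 1), 2,
               dimnames = list(c("r1", "r2"), c("r1", "r2")))
  once <- mergeSignals(reps, ld)
  reps2 <- data.frame(variant = "r1", trait = "t1,t2",
                      chromosome = "chr1",
                      start = once$signals$start,
                      end = once$signals$end,
                      position = 2e6)
  twice <- mergeSignals(reps2, matrix(1, 1, 1,
                                      dimnames = list("r1", "r1")))
  expect_equal(GenomicRanges::start(twice$loci),
               GenomicRanges::start(once$loci))
  expect_equal(GenomicRanges::end(twice$loci),
               GenomicRanges::end(once$loci))
})

test_that("novelty calls use in-sample LD with the proximity fallback", {
  leads <- data.frame(variant = c("L1", "L2", "L3"),
                      chromosome = "chr1",
                      position = c(1e6, 5e6, 9e6))
  known <- data.frame(variant = c("L1", "K2", "K3"),
                      chromosome = "chr1",
                      position = c(1e6, 5.2e6, 10e6))
  ld <- matrix(sqrt(0.05), 3, 2,
               dimnames = list(leads$variant, c("L1", "K3_absent")))
  ld["L1", "L1"] <- 1
  # K3 absent from ld columns -> proximity fallback applies to it; K2 too
  ld <- ld[, "L1", drop = FALSE]
  out <- callNovelty(leads, known, ld)
  expect_false(out[["L1"]])   # the lead is itself a known variant
  expect_false(out[["L2"]])   # absent known K2 only 0.2 Mb away
  expect_false(out[["L3"]])   # absent known K3 1.0 Mb away (fallback)

  # low LD with all in-sample knowns and no nearby absent known: novel
  known2 <- data.frame(variant = "L1", chromosome = "chr1",
                       position = 1e6)
  out2 <- callNovelty(leads, known2, ld)
  expect_true(out2[["L2"]])
  expect_true(out2[["L3"]])
})

test_that("locus naming prefers missense variants, then overlap, then proximity", {
  genes <- data.frame(chromosome = "chr1",
                      start = c(1e6, 3e6, 5e6),
                      end = c(2e6, 3.5e6, 6e6),
                      strand = c("+", "-", "+"),
                      symbol = c("A", "B", "D"))
  # top variant inside gene A
  tv1 <- data.frame(variant = "v1", chromosome = "chr1", position = 1.5e6,
                    p = 1e-20, class = "intron_variant")
  expect_identical(nameLocus(tv1, genes), "A")

  # intergenic top variant: nearest edge wins (B at 10 kb vs D at 50 kb)
  tv2 <- data.frame(variant = "v2", chromosome = "chr1",
                    position = 3.51e6, p = 1e-15,
                    class = "intergenic_variant")
  expect_identical(nameLocus(tv2, genes), "B")

  # missense among representatives overrides the lower-p intronic lead
  tv3 <- rbind(data.frame(variant = "lead", chromosome = "chr1",
                          position = 1.5e6, p = 1e-30,
                          class = "intron_variant"),
               data.frame(variant = "rep", chromosome = "chr1",
                          position = 5.5e6, p = 1e-10,
                          class = "missense_variant"))
  expect_identical(nameLocus(tv3, genes), "D")

  expect_identical(nameLocus(tv1, genes[0, ]), "NA")
})

test_that("loci export as BED with 0-based half-open coordinates", {
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 2e6),
                                 name = "A", novel = TRUE, minP = 1e-12,
                                 signals = "1", traits = "t1",
                                 leads = "v1")
  bed <- withr::local_tempfile(fileext = ".bed")
  det <- withr::local_tempfile(fileext = ".tsv")
  writeLociBed(loci, bed, det)
  tab <- read.delim(bed, header = FALSE)
  expect_equal(tab$V2, 1e6 - 1)
  expect_equal(tab$V3, 2e6)
  expect_identical(read.delim(det)$locus, "A")
})
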
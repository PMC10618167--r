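#' @include AllClasses.R
NULL

#' Iterative lead-variant GWAS regions
#'
#' Lead variants are picked iteratively as the globally lowest-p variant
#' not yet covered by a region; each lead opens a region of `window` bp
#' on each side and covers its variants; the search stops when no
#' uncovered variant is below `threshold`. Overlapping regions on a
#' chromosome are combined, the combined lead being the lowest-p lead
#' and the others secondary. A combined region wider than `maxWidth`
#' has its leads' half-window shrunk by 10 percent repeatedly, regions
#' being rebuilt after each shrink, until the width drops below
#' `maxWidth` or the shrunk regions no longer overlap. Ties in p are
#' broken by position, then variant id.
#'
#' @param sumstats data.frame with columns `chromosome`,
#'   `base_pair_location`, `variant_id`, `p_value`.
#' @param threshold significance cutoff for leads (5e-8 for the GWS
#'   tier; use the Bonferroni threshold for the BFS tier).
#' @param tier label stored with the regions.
#' @param window half-window in bp, default 1.5 Mb.
#' @param maxWidth maximum combined width, default 6 Mb.
#' @return A [GenomicRanges::GRanges] of regions with metadata columns
#'   `lead`, `leadP`, `secondaryLeads` (comma-joined), `tier`.
#' @export
findRegions <- function(sumstats, threshold = 5e-8, tier = "GWS",
                        window = 1.5e6, maxWidth = 6e6) {
  ss <- sumstats[order(sumstats$p_value, sumstats$base_pair_location,
                       sumstats$variant_id), ]
  emit <- list()
  buildGroups <- function(df, w) {
    # merge overlapping [pos - w, pos + w] intervals per chromosome
    groups <- list()
    for (cc in unique(df$chromosome)) {
      sub <- df[df$chromosome == cc, , drop = FALSE]
      sub <- sub[order(sub$base_pair_location), , drop = FALSE]
      cur <- 1
      start <- sub$base_pair_location[1] - w
      end <- sub$base_pair_location[1] + w
      idx <- 1
      if (nrow(sub) > 1) for (k in 2:nrow(sub)) {
        if (sub$base_pair_location[k] - w <= end) {
          idx <- c(idx, k)
          end <- max(end, sub$base_pair_location[k] + w)
        } else {
          groups[[length(groups) + 1]] <- sub[idx, , drop = FALSE]
          idx <- k
          end <- sub$base_pair_location[k] + w
        }
      }
      groups[[length(groups) + 1]] <- sub[idx, , drop = FALSE]
    }
    groups
  }
  process <- function(df, w) {
    for (g in buildGroups(df, w)) {
      width <- (max(g$base_pair_location) + w) -
               (min(g$base_pair_location) - w) + 1
      if (width >= maxWidth && nrow(g) > 1) {
        process(g, w * 0.9)
      } else {
        ord <- order(g$p_value, g$base_pair_location, g$variant_id)
        emit[[length(emit) + 1]] <<- data.frame(
          chromosome = g$chromosome[1],
          start = max(1, min(g$base_pair_location) - w),
          end = max(g$base_pair_location) + w,
          lead = g$variant_id[ord[1]],
          leadP = g$p_value[ord[1]],
          secondaryLeads = paste(g$variant_id[ord[-1]], collapse = ","),
          halfWindow = w)
      }
    }
  }

  # outer iteration: add the lowest-p variant not covered by the current
  # regions as a new lead and rebuild (the shrink loop can uncover
  # significant variants, which then seed further leads)
  leads <- integer()
  repeat {
    emit <- list()
    if (length(leads)) process(ss[leads, , drop = FALSE], window)
    covered <- rep(FALSE, nrow(ss))
    for (r in emit)
      covered <- covered | (ss$chromosome == r$chromosome &
                            ss$base_pair_location >= r$start &
                            ss$base_pair_location <= r$end)
    cand <- which(!covered & ss$p_value < threshold)
    if (!length(cand)) break
    leads <- c(leads, cand[1])
  }
  if (!length(emit))
    return(GenomicRanges::GRanges(lead = character(), leadP = numeric(),
                                  secondaryLeads = character(),
                                  tier = character()))
  df <- do.call(rbind, emit)
  gr <- GenomicRanges::GRanges(df$chromosome,
                               IRanges::IRanges(df$start, df$end),
                               lead = df$lead, leadP = df$leadP,
                               secondaryLeads = df$secondaryLeads,
                               tier = tier, halfWindow = df$halfWindow)
  sort(gr)
}

#' Was a multivariate region also found by the univariate analyses?
#'
#' TRUE iff some variant in LD (`r^2 > 0.1`) with the multivariate lead
#' reaches the given univariate tier threshold in any cluster member
#' trait.
#'
#' @param lead the multivariate lead variant id.
#' @param uvSumstatsList list of univariate summary-statistic
#'   data.frames for the cluster member traits.
#' @param ldR2 named vector of r-squared values with the lead (names =
#'   variant ids).
#' @param threshold the univariate tier threshold (GWS or BFS).
#' @return logical.
#' @export
mvUvOverlap <- function(lead, uvSumstatsList, ldR2, threshold = 5e-8) {
  linked <- names(ldR2)[ldR2 > 0.1]
  for (ss in uvSumstatsList) {
    hit <- ss$variant_id %in% linked & ss$p_value < threshold
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Merge association signals across traits and build physical loci
#'
#' Representative variants are connected when their LD r-squared is at
#' least 0.1 on the same chromosome; connected components are
#' independent signals; each signal's region is the union of the GWAS
#' regions that contributed its representatives; overlapping signal
#' regions on a chromosome are combined into non-overlapping loci.
#'
#' @param representatives data.frame with one row per (representative,
#'   trait, region): columns `variant`, `trait`, `chromosome`, `start`,
#'   `end`, `position`.
#' @param ld square signed-correlation matrix of the unique
#'   representative variants (dimnames = variant ids); squared
#'   internally.
#' @return list with `signals` (data.frame: signal, representatives,
#'   traits, chromosome, start, end) and `loci`
#'   ([GenomicRanges::GRanges] with metadata `signals`, `traits`).
#' @export
mergeSignals <- function(representatives, ld) {
  reps <- representatives
  vars <- unique(reps$variant)
  L2 <- (as.matrix(ld)[vars, vars, drop = FALSE])^2
  chromOf <- reps$chromosome[match(vars, reps$variant)]
  adj <- L2 >= 0.1 & outer(chromOf, chromOf, `==`)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  sig <- data.frame(variant = vars, signal = comp)
  reps$signal <- sig$signal[match(reps$variant, sig$variant)]
  signals <- do.call(rbind, lapply(split(reps, reps$signal), function(s)
    data.frame(signal = s$signal[1],
               representatives = paste(unique(s$variant), collapse = ","),
               traits = paste(unique(s$trait), collapse = ","),
               chromosome = s$chromosome[1],
               start = min(s$start), end = max(s$end))))
  rownames(signals) <- NULL

  sigGr <- GenomicRanges::GRanges(signals$chromosome,
                                  IRanges::IRanges(signals$start,
                                                   signals$end),
                                  signal = signals$signal)
  loci <- GenomicRanges::reduce(sigGr)
  hits <- GenomicRanges::findOverlaps(sigGr, loci)
  memb <- split(signals$signal[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits))
  traitsOf <- split(signals$traits[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits))
  loci$signals <- vapply(memb, function(x)
    paste(sort(unique(x)), collapse = ","), "")
  loci$traits <- vapply(traitsOf, function(x)
    paste(sort(unique(unlist(strsplit(x, ",")))), collapse = ","), "")
  list(signals = signals, loci = loci)
}

#' Novelty calls for lead variants
#'
#' A lead is novel iff its LD r-squared with every known variant present
#' in the data is below 0.1; for known variants absent from the data the
#' proximity fallback applies: the lead is flagged non-novel if any
#' absent known variant lies within the window on the same chromosome.
#' A locus is novel iff all its leads are novel.
#'
#' @param leads data.frame (`variant`, `chromosome`, `position`).
#' @param known data.frame (`variant`, `chromosome`, `position`); rows
#'   whose variant id appears in the columns of `ld` are treated as
#'   in-sample.
#' @param ld signed-correlation matrix with leads in rows and in-sample
#'   known variants in columns (squared internally); NULL when no known
#'   variant is in-sample.
#' @param window proximity fallback window, default 1.5 Mb.
#' @return logical vector named by lead variant.
#' @export
callNovelty <- function(leads, known, ld = NULL, window = 1.5e6) {
  inSample <- if (is.null(ld)) character() else
    intersect(known$variant, colnames(ld))
  absent <- known[!known$variant %in% inSample, , drop = FALSE]
  out <- logical(nrow(leads))
  for (i in seq_len(nrow(leads))) {
    novel <- TRUE
    if (length(inSample)) {
      r2 <- (ld[leads$variant[i], inSample])^2
      if (any(r2 >= 0.1)) novel <- FALSE
    }
    if (novel && nrow(absent)) {
      near <- absent$chromosome == leads$chromosome[i] &
        abs(absent$position - leads$position[i]) <= window
      if (any(near)) novel <- FALSE
    }
    out[i] <- novel
  }
  stats::setNames(out, leads$variant)
}

#' Name a locus from gene models
#'
#' If any top/representative variant in the locus is a missense variant,
#' the locus is named by that variant's gene (the lowest-p missense
#' variant when there are several); otherwise by the gene overlapping
#' the lowest-p top variant, else the nearest gene by distance to the
#' closer gene edge (tie: the upstream gene, i.e. the one ending before
#' the variant).
#'
#' @param topVariants data.frame (`variant`, `chromosome`, `position`,
#'   `p`, `class`), where `class` is the functional annotation.
#' @param geneModels data.frame (`chromosome`, `start`, `end`, `strand`,
#'   `symbol`).
#' @return gene symbol (or `"NA"` for an empty gene table).
#' @export
nameLocus <- function(topVariants, geneModels) {
  if (is.null(geneModels) || !nrow(geneModels)) return("NA")
  geneFor <- function(chrom, pos) {
    gm <- geneModels[geneModels$chromosome == chrom, , drop = FALSE]
    if (!nrow(gm)) return("NA")
    inside <- gm$start <= pos & gm$end >= pos
    if (any(inside)) return(gm$symbol[which(inside)[1]])
    dist <- pmin(abs(gm$start - pos), abs(gm$end - pos))
    best <- which(dist == min(dist))
    if (length(best) > 1) {
      up <- best[gm$end[best] < pos]
      best <- if (length(up)) up[1] else best[1]
    }
    gm$symbol[best[1]]
  }
  ms <- topVariants[!is.na(topVariants$class) &
                    topVariants$class == "missense_variant", ,
                    drop = FALSE]
  pick <- if (nrow(ms)) ms[which.min(ms$p), ] else
    topVariants[which.min(topVariants$p), ]
  geneFor(pick$chromosome, pick$position)
}

#' Export loci as BED plus a detail table
#'
#' The BED file uses 0-based half-open coordinates (chrom, start0, end,
#' name, score = -log10 of the minimum p, strand "."); the detail file
#' is a TSV (locus, signals, traits, leads, novel).
#'
#' @param loci GRanges from [mergeSignals()] with metadata `name`,
#'   `novel`, `minP`, `leads` attached by the caller.
#' @param bedPath,detailPath output files.
#' @return invisibly, the BED path.
#' @export
writeLociBed <- function(loci, bedPath, detailPath) {
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(loci)),
                    start0 = GenomicRanges::start(loci) - 1L,
                    end1 = GenomicRanges::end(loci),
                    name = loci$name,
                    score = round(-log10(loci$minP), 3),
                    strand = ".")
  utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  detail <- data.frame(locus = loci$name, signals = loci$signals,
                       traits = loci$traits, leads = loci$leads,
                       novel = loci$novel)
  utils::write.table(detail, detailPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(bedPath)
}
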
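#' @include AllClasses.R
NULL

#' Pairwise-complete Pearson correlation matrix of lipid species
#'
#' @param phenotypes samples x species matrix.
#' @param absolute return absolute correlations (the clustering input).
#' @return symmetric matrix with unit diagonal. A pair with fewer than
#'   3 complete observations is an error naming the pair.
#' @export
correlationMatrix <- function(phenotypes, absolute = FALSE) {
  phenotypes <- as.matrix(phenotypes)
  if (ncol(phenotypes) < 2) stop("need at least 2 species")
  obs <- !is.na(phenotypes)
  pairN <- crossprod(obs)
  if (any(pairN < 3)) {
    bad <- sort(which(pairN < 3, arr.ind = TRUE)[1, ])
    stop("fewer than 3 complete observations for pair ",
         colnames(phenotypes)[bad[1]], " / ", colnames(phenotypes)[bad[2]])
  }
  r <- stats::cor(phenotypes, use = "pairwise.complete.obs")
  diag(r) <- 1
  if (absolute) abs(r) else r
}

#' Iteratively prune highly correlated trait pairs
#'
#' Repeatedly takes the pair with the largest absolute correlation above
#' the threshold and drops the member with the larger mean absolute
#' correlation to all remaining traits (tie: the lexicographically later
#' id), until no pair exceeds the threshold.
#'
#' @param correlations square correlation matrix with dimnames.
#' @param threshold pair cutoff, default 0.8.
#' @return list with `kept` and `removed` character vectors (removal
#'   order preserved).
#' @export
pruneHighPairs <- function(correlations, threshold = 0.8) {
  r <- abs(as.matrix(correlations))
  stopifnot(nrow(r) == ncol(r))
  if (is.null(rownames(r)))
    rownames(r) <- colnames(r) <- paste0("t", seq_len(nrow(r)))
  removed <- character()
  repeat {
    rr <- r
    diag(rr) <- 0
    mx <- max(rr)
    if (mx <= threshold) break
    hit <- which(rr == mx, arr.ind = TRUE)[1, ]
    pair <- rownames(rr)[hit]
    meanAbs <- rowMeans(rr[pair, , drop = FALSE]) * ncol(rr) / (ncol(rr) - 1)
    victim <- if (meanAbs[1] > meanAbs[2]) pair[1]
      else if (meanAbs[2] > meanAbs[1]) pair[2]
      else sort(pair)[2]
    removed <- c(removed, victim)
    keep <- setdiff(rownames(r), victim)
    r <- r[keep, keep, drop = FALSE]
  }
  list(kept = rownames(r), removed = removed)
}

#' Average-linkage hierarchical clustering of traits
#'
#' Each trait's feature vector is its row of the absolute correlation
#' matrix; dissimilarity is the Euclidean distance between rows;
#' clustering is average-linkage agglomerative, run independently within
#' each partition group (e.g. glycerolipids vs all other species), and
#' the dendrogram is cut at the requested cluster count per group.
#'
#' @param correlations square (absolute) correlation matrix with dimnames.
#' @param nClusters named integer vector: clusters requested per
#'   partition group (or a single unnamed count when there is one group).
#' @param partition named character vector mapping trait id to group;
#'   NULL puts every trait in one group.
#' @return named list of character vectors of trait ids, one entry per
#'   cluster, named `<group>.<k>` (or `cluster<k>` for a single group).
#' @export
hierarchicalClusters <- function(correlations, nClusters, partition = NULL) {
  r <- abs(as.matrix(correlations))
  ids <- rownames(r)
  if (is.null(partition)) partition <- setNames(rep("all", length(ids)), ids)
  groups <- unique(partition[ids])
  if (length(nClusters) == 1 && is.null(names(nClusters)))
    nClusters <- setNames(rep(nClusters, length(groups)), groups)
  out <- list()
  for (g in groups) {
    gi <- ids[partition[ids] == g]
    k <- nClusters[[g]]
    if (k > length(gi))
      stop("group ", g, ": requested ", k, " clusters for ",
           length(gi), " traits")
    if (length(gi) == 1) {
      cl <- setNames(1L, gi)
    } else {
      d <- stats::dist(r[gi, gi, drop = FALSE], method = "euclidean")
      cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
    }
    for (kk in sort(unique(cl))) {
      nm <- if (identical(groups, "all")) sprintf("cluster%d", kk)
        else sprintf("%s.%d", g, kk)
      out[[nm]] <- gi[cl == kk]
    }
  }
  out
}

# VIF of each member from complete-case least squares on the others
vifValues <- function(phenotypes, ids) {
  if (length(ids) == 1) return(setNames(1, ids))
  X <- phenotypes[, ids, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  vapply(seq_along(ids), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0, USE.NAMES = FALSE) |> setNames(ids)
}

#' Iterative VIF pruning of a trait cluster
#'
#' Removes the member with the largest variance inflation factor
#' (`1 / (1 - R^2)` from regressing it on the other members over complete
#' cases; tie: lexicographically later id) until the maximum VIF is below
#' `vifMax`. A perfectly collinear member has infinite VIF and goes
#' first.
#'
#' @param phenotypes samples x species matrix (INT residuals).
#' @param clusterIds member species ids.
#' @param vifMax threshold, default 5.
#' @param id cluster identifier for the returned object.
#' @return A [TraitCluster-class] (with `removedPairwise` empty; see
#'   [buildClusters()] for the full pipeline).
#' @export
vifPrune <- function(phenotypes, clusterIds, vifMax = 5, id = "cluster1") {
  stopifnot(length(clusterIds) >= 1)
  keep <- sort(clusterIds)
  removedVif <- character()
  repeat {
    v <- vifValues(phenotypes, keep)
    mx <- max(v)
    if (mx < vifMax || length(keep) == 1) break
    worst <- names(v)[v == mx]
    victim <- sort(worst)[length(worst)]
    removedVif <- c(removedVif, victim)
    keep <- setdiff(keep, victim)
  }
  corSub <- if (length(keep) > 1)
    correlationMatrix(phenotypes[, keep, drop = FALSE]) else
    matrix(1, 1, 1, dimnames = list(keep, keep))
  new("TraitCluster", id = id, members = keep,
      removedPairwise = character(), removedVif = removedVif,
      correlation = corSub)
}

#' Build multivariate trait clusters from prepared phenotypes
#'
#' The full clustering pipeline: absolute pairwise correlations,
#' iterative pruning of pairs with |r| above `pairThreshold`,
#' average-linkage hierarchical clustering within partition groups, and
#' iterative VIF pruning within each cluster.
#'
#' @param phenotypes samples x species matrix (INT residuals).
#' @param nClusters clusters per partition group (see
#'   [hierarchicalClusters()]).
#' @param partition trait-to-group mapping, or NULL for one group.
#' @param pairThreshold pairwise |r| cutoff, default 0.8.
#' @param vifMax VIF cutoff, default 5.
#' @return list of [TraitCluster-class] objects.
#' @export
buildClusters <- function(phenotypes, nClusters, partition = NULL,
                          pairThreshold = 0.8, vifMax = 5) {
  r <- correlationMatrix(phenotypes, absolute = TRUE)
  pr <- pruneHighPairs(r, pairThreshold)
  rKept <- r[pr$kept, pr$kept, drop = FALSE]
  part <- if (is.null(partition)) NULL else partition
  cls <- hierarchicalClusters(rKept, nClusters, part)
  out <- list()
  for (nm in names(cls)) {
    tc <- vifPrune(phenotypes, cls[[nm]], vifMax = vifMax, id = nm)
    tc@removedPairwise <- intersect(pr$removed, colnames(phenotypes))
    out[[nm]] <- tc
  }
  out
}

#' Correlation of species with the four standard lipids
#'
#' Per species, the maximum absolute pairwise-complete correlation
#' (maxCor) across HDL-C, LDL-C, total cholesterol and triglycerides;
#' optionally a comparison of group means between a flagged species
#' subset and the rest.
#'
#' @param phenotypes samples x species matrix.
#' @param standardLipids samples x 4 matrix (HDL-C, LDL-C, TC, TG),
#'   row-aligned.
#' @param flagged optional character vector of species ids forming the
#'   first comparison group.
#' @return list with `maxCor` (named per species) and, when `flagged` is
#'   given, `groupMeans` and `difference` of mean maxCor between the
#'   flagged species and the rest.
#' @export
standardLipidProfile <- function(phenotypes, standardLipids,
                                 flagged = NULL) {
  phenotypes <- as.matrix(phenotypes)
  standardLipids <- as.matrix(standardLipids)
  if (nrow(phenotypes) != nrow(standardLipids))
    stop("standard lipid table is not row-aligned")
  r <- abs(stats::cor(phenotypes, standardLipids,
                      use = "pairwise.complete.obs"))
  maxCor <- apply(r, 1, max)
  out <- list(maxCor = maxCor)
  if (!is.null(flagged)) {
    g1 <- maxCor[names(maxCor) %in% flagged]
    g2 <- maxCor[!names(maxCor) %in% flagged]
    out$groupMeans <- c(flagged = mean(g1), rest = mean(g2))
    out$difference <- mean(g1) - mean(g2)
  }
  out
}

#' Write cluster membership to a tab-delimited file
#'
#' Columns: cluster_id, species_id, status (member / removed_pairwise /
#' removed_vif).
#'
#' @param clusters list of [TraitCluster-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeClusterMembership <- function(clusters, path) {
  rows <- do.call(rbind, lapply(clusters, function(tc) {
    rbind(data.frame(cluster_id = tc@id, species_id = tc@members,
                     status = "member"),
          if (length(tc@removedVif))
            data.frame(cluster_id = tc@id, species_id = tc@removedVif,
                       status = "removed_vif"))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
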
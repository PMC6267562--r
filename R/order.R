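#' Pairwise shared-spacer counts between samples
#'
#' Counts, for every pair of samples, how many spacers they share, where
#' "the same spacer" means "in the same similarity cluster". Counts are
#' multiset overlaps: if sample i carries a cluster 3 times and sample j
#' twice, they share 2. All loci of a sample are pooled (strain-level
#' comparison).
#'
#' @param ss a \linkS4class{SpacerSet}
#' @param clustering a \linkS4class{SpacerClustering} of its spacers
#' @return a \linkS4class{SharedSpacerMatrix}
#' @export
sharedSpacerMatrix <- function(ss, clustering) {
  asg <- clusterAssignment(clustering)
  ids <- spacerIds(ss)
  if (!all(ids %in% names(asg)))
    stop("clustering does not cover every spacer in the dataset")
  samples <- sampleIds(ss)
  cl <- unname(asg[ids])
  counts <- table(factor(spacerInfo(ss)$sample_id, levels = samples),
                  factor(cl, levels = cSort(unique(cl))))
  counts <- matrix(as.integer(counts), nrow = length(samples),
                   dimnames = dimnames(counts))
  n <- length(samples)
  shared <- matrix(0L, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n))
    for (j in seq_len(n))
      shared[i, j] <- sum(pmin(counts[i, ], counts[j, ]))
  new("SharedSpacerMatrix", sampleIds = samples, counts = counts,
      shared = shared)
}

#' Bray-Curtis dissimilarity from shared-spacer counts
#'
#' `D[i,j] = 1 - 2 C[i,j] / (S_i + S_j)` with `C` the shared count and `S`
#' the samples' total spacer counts: 0 for identical spacer multisets, 1 for
#' samples sharing nothing.
#'
#' @param ssm a \linkS4class{SharedSpacerMatrix}
#' @return symmetric numeric matrix with zero diagonal, values in `[0, 1]`
#' @export
brayCurtis <- function(ssm) {
  tot <- diag(ssm@shared)
  if (any(tot == 0))
    stop("sample without spacers: ",
         ssm@sampleIds[which(tot == 0)[1]], " (dissimilarity undefined)")
  D <- 1 - 2 * ssm@shared / outer(tot, tot, `+`)
  dimnames(D) <- list(ssm@sampleIds, ssm@sampleIds)
  D
}

#' Strain display order from UPGMA of a dissimilarity matrix
#'
#' Average-linkage (UPGMA) agglomeration of the Bray-Curtis matrix; the
#' left-to-right leaf order of the resulting guide tree gives the row order
#' of the figure, so strains with similar spacer content end up adjacent.
#' Ties are broken deterministically: when several merges are equally close,
#' the pair whose members appeared earliest in the input is merged first,
#' and in each merge the subtree containing the earlier-input sample is
#' placed on the left. With all distances equal this reduces to input order.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal
#' @param sampleIds sample ids in input order (defaults to rownames of D)
#' @return a \linkS4class{StrainOrdering} with the guide tree attached
#' @export
upgmaOrder <- function(D, sampleIds = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(sampleIds)) stop("sample ids required")
  if (!isSymmetric(unname(D), tol = 1e-12)) stop("D must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  if (n == 1) {
    return(new("StrainOrdering", orderedSamples = sampleIds, tree = NULL,
               source = "upgma"))
  }
  # active clusters: negative = leaf index, positive = merge row
  act <- as.list(-seq_len(n))
  size <- rep(1L, n)
  rank <- seq_len(n)          # smallest input rank of any member
  d <- D
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  leaves <- as.list(seq_len(n))  # leaf sets in left-to-right order
  alive <- seq_len(n)
  for (step in seq_len(n - 1)) {
    # find min distance among alive pairs; tie -> smallest (rank_i, rank_j)
    da <- d[alive, alive, drop = FALSE]
    ut <- upper.tri(da)
    mn <- min(da[ut])
    cand <- which(ut & da <= mn + 1e-12, arr.ind = TRUE)
    ra <- rank[alive[cand[, 1]]]; rb <- rank[alive[cand[, 2]]]
    pick <- order(pmin(ra, rb), pmax(ra, rb))[1]
    a <- alive[cand[pick, 1]]; b <- alive[cand[pick, 2]]
    if (rank[b] < rank[a]) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(act[[a]], act[[b]])
    height[step] <- d[a, b]
    # UPGMA update: unweighted average over member pairs
    for (k in alive) {
      if (k == a || k == b) next
      d[a, k] <- d[k, a] <- (size[a] * d[a, k] + size[b] * d[b, k]) /
        (size[a] + size[b])
    }
    act[[a]] <- step
    size[a] <- size[a] + size[b]
    rank[a] <- min(rank[a], rank[b])
    leaves[[a]] <- c(leaves[[a]], leaves[[b]])  # earlier-rank subtree left
    alive <- setdiff(alive, b)
  }
  ord <- leaves[[alive]]
  tree <- structure(list(merge = merge, height = height, order = ord,
                         labels = sampleIds, method = "average",
                         dist.method = "bray-curtis",
                         call = match.call()),
                    class = "hclust")
  new("StrainOrdering", orderedSamples = sampleIds[ord], tree = tree,
      source = "upgma")
}

#' Strain order from a custom list
#'
#' Orders samples following a plain-text list (one sample id per line, `#`
#' comments allowed) -- e.g. by sampling date, site, or serotype. Samples
#' missing from the list are appended in input order with a warning; unknown
#' ids in the list are skipped with a warning.
#'
#' @param ss a \linkS4class{SpacerSet}
#' @param listPath path to the list file
#' @return a \linkS4class{StrainOrdering}
#' @export
customOrder <- function(ss, listPath) {
  lines <- readLines(listPath, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty sample list: ", listPath)
  samples <- sampleIds(ss)
  unknown <- setdiff(lines, samples)
  if (length(unknown))
    warning("unknown sample id(s) in list, skipped: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  keep <- unique(lines[lines %in% samples])
  rest <- setdiff(samples, keep)
  if (length(rest))
    warning("sample(s) absent from list, appended in input order: ",
            paste(rest, collapse = ", "), call. = FALSE)
  new("StrainOrdering", orderedSamples = c(keep, rest), tree = NULL,
      source = "custom")
}

#' Strain order as given in the input
#'
#' @param ss a \linkS4class{SpacerSet}
#' @return a \linkS4class{StrainOrdering} preserving input order
#' @export
inputOrder <- function(ss) {
  new("StrainOrdering", orderedSamples = sampleIds(ss), tree = NULL,
      source = "input_order")
}

#' Export the UPGMA guide tree as Newick
#'
#' @param ordering a \linkS4class{StrainOrdering} with a tree
#' @param path output path
#' @return invisibly, `path`
#' @export
writeGuideTree <- function(ordering, path) {
  tr <- guideTree(ordering)
  if (is.null(tr)) stop("ordering carries no guide tree")
  ape::write.tree(ape::as.phylo(tr), file = path)
  invisible(path)
}
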
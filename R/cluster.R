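#' Cluster spacers by transitive closure of pairwise similarity
#'
#' Two spacers are considered the same spacer when their reduced adjusted
#' mismatch score is at most `cutoff` (default 2, allowing for occasional
#' sequencing errors or point mutations). Similarity is then closed
#' transitively: if A is similar to B and B to C, then A, B and C form one
#' cluster, even if A and C differ by more than the cutoff. Clusters are the
#' connected components of the similarity graph, computed with union-find;
#' unlinked spacers are singleton clusters. The cluster id is the
#' lexicographically smallest member id (C collation), so ids are stable
#' across reruns and appends.
#'
#' @param pairs data.frame from [alignAllPairs()] (or any table with columns
#'   `id1`, `id2`, `adjusted`); may be pre-filtered to pairs at or below the
#'   cutoff
#' @param allIds character vector of every spacer id in the dataset
#' @param cutoff maximum adjusted mismatches for two spacers to be linked
#' @return a \linkS4class{SpacerClustering}
#' @export
clusterSpacers <- function(pairs, allIds, cutoff = 2) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  if (anyDuplicated(allIds)) stop("duplicated spacer id in allIds")
  unknown <- setdiff(unique(c(pairs$id1, pairs$id2)), allIds)
  if (length(unknown))
    stop("spacer referenced in pairs but absent from allIds: ", unknown[1])
  n <- length(allIds)
  parent <- seq_len(n)
  findRoot <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  edges <- pairs[pairs$adjusted <= cutoff, c("id1", "id2"), drop = FALSE]
  e1 <- match(edges$id1, allIds); e2 <- match(edges$id2, allIds)
  for (k in seq_along(e1)) {
    r1 <- findRoot(e1[k]); r2 <- findRoot(e2[k])
    if (r1 != r2) parent[max(r1, r2)] <- min(r1, r2)
  }
  comp <- vapply(seq_len(n), findRoot, integer(1))
  members <- split(allIds, comp)
  ids <- vapply(members, cMin, character(1))
  names(members) <- ids
  members <- members[cSort(ids)]
  members <- lapply(members, cSort)
  assignment <- setNames(rep(names(members), lengths(members)),
                         unlist(members, use.names = FALSE))
  assignment <- assignment[allIds]
  new("SpacerClustering", cutoff = as.numeric(cutoff),
      assignment = assignment, clusters = members)
}

#' Write cluster membership as TSV
#'
#' @param clustering a \linkS4class{SpacerClustering}
#' @param path output path
#' @return invisibly, `path`
#' @export
writeClusterTable <- function(clustering, path) {
  asg <- clusterAssignment(clustering)
  sz <- clusterSizes(clustering)
  df <- data.frame(spacer_id = names(asg), cluster_id = unname(asg),
                   cluster_size = unname(sz[asg]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
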
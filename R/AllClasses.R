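#' @import methods
#' @importFrom stats setNames
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")

#' SpacerSet: a dataset of CRISPR spacers
#'
#' Container for all spacers of a dataset, one row per spacer, holding the
#' identity fields recovered from CRISPRDetect-style GFF3 (or a spacer FASTA)
#' and the spacer sequence stored 5'->3' in array orientation. Sample order
#' reflects input order; it is preserved because downstream tie-breaking
#' (UPGMA, cluster ids) relies on it being deterministic.
#'
#' @slot spacers data.frame with columns `sample_id`, `locus_num`,
#'   `spacer_num`, `start`, `end`, `length`, `strand`, `sequence`. Rows are
#'   ordered by sample (input order), then locus, then spacer number.
#' @slot sampleOrder character, sample ids in input order.
#' @slot provenance named character, sample id -> source path ("" if unknown).
#'
#' @export
setClass("SpacerSet",
  representation(spacers = "data.frame",
                 sampleOrder = "character",
                 provenance = "character"))

setValidity("SpacerSet", function(object) {
  df <- object@spacers
  need <- c("sample_id", "locus_num", "spacer_num", "start", "end",
            "length", "strand", "sequence")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  if (!all(df$end >= df$start)) return("end < start for some spacer")
  if (!all(df$length == df$end - df$start + 1))
    return("length != end - start + 1 for some spacer")
  if (!all(df$length == nchar(df$sequence)))
    return("stored sequence length disagrees with length field")
  if (!all(df$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  bad <- grepl(paste0("[^", paste(IUPAC_CHARS, collapse = ""), "]"), df$sequence)
  if (any(bad)) return("sequence contains non-IUPAC characters")
  ids <- paste(df$sample_id, df$locus_num, df$spacer_num, sep = "|")
  if (anyDuplicated(ids))
    return(paste("duplicated spacer identity:", ids[duplicated(ids)][1]))
  if (!setequal(object@sampleOrder, unique(df$sample_id)))
    return("sampleOrder does not match the samples present")
  # spacer numbers 1..n consecutive within each locus
  sp <- split(df$spacer_num, paste(df$sample_id, df$locus_num, sep = "|"))
  ok <- vapply(sp, function(v) identical(sort(v), seq_along(v)), logical(1))
  if (!all(ok)) return("spacer numbers are not 1..n within some locus")
  TRUE
})

#' SpacerClustering: partition of spacers into similarity clusters
#'
#' Clusters are the connected components of the pairwise-similarity graph at
#' the given adjusted-mismatch cutoff (transitive closure). The id of a
#' cluster is the lexicographically smallest member identity, which keeps ids
#' stable across reruns and under appends.
#'
#' @slot cutoff numeric scalar, adjusted-mismatch threshold used.
#' @slot assignment named character, spacer id -> cluster id.
#' @slot clusters named list, cluster id -> character vector of member ids.
#'
#' @export
setClass("SpacerClustering",
  representation(cutoff = "numeric",
                 assignment = "character",
                 clusters = "list"))

setValidity("SpacerClustering", function(object) {
  if (length(object@cutoff) != 1 || object@cutoff < 0)
    return("cutoff must be a single value >= 0")
  memb <- unlist(object@clusters, use.names = FALSE)
  if (length(memb) != length(object@assignment) ||
      anyDuplicated(memb) || !setequal(memb, names(object@assignment)))
    return("clusters do not form a partition of the assigned spacers")
  if (any(lengths(object@clusters) == 0)) return("empty cluster")
  for (cid in names(object@clusters)) {
    mem <- object@clusters[[cid]]
    if (!all(object@assignment[mem] == cid))
      return("assignment and clusters disagree")
    if (cMin(mem) != cid)
      return("cluster id is not its lexicographically smallest member")
  }
  TRUE
})

#' ColorStore: persistent cluster-to-color assignment
#'
#' Maps each cluster to a two-color code: a 3-digit HEX square color and a
#' 3-digit HEX diamond color. One member sequence per cluster is kept as a
#' representative so that appended datasets can re-link clusters and keep
#' their colors. The gray-out code (white square #fff, light-gray diamond
#' #ccc) is reserved and never assigned; square colors are unique across
#' clusters.
#'
#' @slot entries data.frame with columns `cluster_id`, `representative`,
#'   `square`, `diamond`.
#' @slot cutoff numeric, the clustering cutoff the store was built at.
#' @slot seed integer seed used for color draws (NA if none recorded).
#'
#' @export
setClass("ColorStore",
  representation(entries = "data.frame", cutoff = "numeric", seed = "integer"))

GRAY_SQUARE <- "#fff"
GRAY_DIAMOND <- "#ccc"

setValidity("ColorStore", function(object) {
  df <- object@entries
  need <- c("cluster_id", "representative", "square", "diamond")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  hex <- "^#[0-9a-f]{3}$"
  if (!all(grepl(hex, df$square)) || !all(grepl(hex, df$diamond)))
    return("colors must be 3-digit lowercase HEX (#abc)")
  if (anyDuplicated(df$cluster_id)) return("duplicated cluster_id")
  if (anyDuplicated(df$square)) return("square colors must be unique")
  if (any(df$square == GRAY_SQUARE))
    return("the reserved gray-out square #fff may not be assigned")
  if (any(df$square == df$diamond))
    return("square and diamond of a cluster must differ")
  TRUE
})

#' SharedSpacerMatrix: pairwise shared-spacer counts between samples
#'
#' Per-sample cluster abundance vectors and the symmetric matrix of shared
#' spacer counts, where the number shared between two samples is the multiset
#' overlap sum over clusters of min(count_i, count_j).
#'
#' @slot sampleIds character, samples in input order.
#' @slot counts integer matrix, samples x clusters.
#' @slot shared integer matrix, samples x samples.
#'
#' @export
setClass("SharedSpacerMatrix",
  representation(sampleIds = "character", counts = "matrix", shared = "matrix"))

setValidity("SharedSpacerMatrix", function(object) {
  C <- object@shared
  n <- length(object@sampleIds)
  if (!identical(dim(C), c(n, n))) return("shared matrix dimension mismatch")
  if (!isSymmetric(unname(C))) return("shared matrix must be symmetric")
  tot <- rowSums(object@counts)
  if (!all(diag(C) == tot))
    return("diagonal must equal each sample's total spacer count")
  lim <- outer(tot, tot, pmin)
  if (any(C > lim)) return("shared count exceeds a sample total")
  TRUE
})

#' StrainOrdering: display order of the samples
#'
#' The row order used when drawing the figure: the left-to-right leaf order
#' of a UPGMA guide tree over Bray-Curtis dissimilarities, a user-supplied
#' list, or plain input order.
#'
#' @slot orderedSamples character, permutation of the dataset's samples.
#' @slot tree the guide tree as an `hclust` object, or NULL.
#' @slot source one of "upgma", "custom", "input_order".
#'
#' @export
setClass("StrainOrdering",
  representation(orderedSamples = "character", tree = "ANY", source = "character"))

setValidity("StrainOrdering", function(object) {
  if (!object@source %in% c("upgma", "custom", "input_order"))
    return("source must be upgma, custom or input_order")
  if (anyDuplicated(object@orderedSamples)) return("duplicated sample in ordering")
  if (object@source == "upgma" && !is.null(object@tree)) {
    tr <- object@tree
    if (!inherits(tr, "hclust")) return("upgma ordering requires an hclust tree")
    if (!identical(tr$labels[tr$order], object@orderedSamples))
      return("orderedSamples must equal the tree's left-to-right leaf order")
  }
  if (object@source == "upgma" && is.null(object@tree) &&
      length(object@orderedSamples) > 1)
    return("upgma ordering of >1 sample requires the guide tree")
  TRUE
})

#' SvgScene: resolved figure geometry
#'
#' Fully laid-out figure: one colored square + centered diamond per spacer,
#' sample name labels, and canvas size. Coordinates are in SVG user units.
#'
#' @slot cells data.frame with columns `spacer_id`, `x`, `y`, `size`,
#'   `square`, `diamond`, `label` (character, NA when no overlay).
#' @slot labels data.frame with columns `x`, `y`, `text`.
#' @slot width,height numeric canvas size.
#' @slot opts list of the render options used.
#'
#' @export
setClass("SvgScene",
  representation(cells = "data.frame", labels = "data.frame",
                 width = "numeric", height = "numeric", opts = "list"))
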
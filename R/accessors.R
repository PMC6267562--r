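#' @describeIn SpacerSet-class spacer metadata + sequence as a data.frame
#' @export
setMethod("spacerInfo", "SpacerSet", function(x) x@spacers)

#' @describeIn SpacerSet-class spacer sequences as a named
#'   \link[Biostrings]{DNAStringSet} (names are spacer ids)
#' @export
setMethod("spacerSeqs", "SpacerSet", function(x) {
  s <- Biostrings::DNAStringSet(x@spacers$sequence)
  names(s) <- spacerIds(x)
  s
})

#' @describeIn SpacerSet-class sample ids in input order
#' @export
setMethod("sampleIds", "SpacerSet", function(x) x@sampleOrder)

#' @describeIn SpacerSet-class number of spacers
#' @export
setMethod("nSpacers", "SpacerSet", function(x) nrow(x@spacers))

#' @describeIn SpacerSet-class spacer identities `sample|locus<k>|spacer<j>`
#' @export
setMethod("spacerIds", "SpacerSet", function(x) {
  with(x@spacers, spacerId(sample_id, locus_num, spacer_num))
})

setMethod("show", "SpacerSet", function(object) {
  df <- object@spacers
  cat("SpacerSet with", nrow(df), "spacers across",
      length(object@sampleOrder), "samples\n")
  if (nrow(df)) {
    nl <- nrow(unique(df[, c("sample_id", "locus_num")]))
    cat("  loci:", nl,
        " spacer length:", min(df$length), "-", max(df$length), "nt\n")
  }
})

#' @describeIn SpacerClustering-class named character, spacer id -> cluster id
#' @param x a \linkS4class{SpacerClustering}
#' @export
setMethod("clusterAssignment", "SpacerClustering", function(x) x@assignment)

#' @describeIn SpacerClustering-class list of member ids per cluster
#' @export
setMethod("clusterMembers", "SpacerClustering", function(x) x@clusters)

#' @describeIn SpacerClustering-class named integer vector of cluster sizes
#' @export
setMethod("clusterSizes", "SpacerClustering", function(x) lengths(x@clusters))

#' @describeIn SpacerClustering-class the adjusted-mismatch cutoff used
#' @export
setMethod("mismatchCutoff", "SpacerClustering", function(x) x@cutoff)

setMethod("show", "SpacerClustering", function(object) {
  sz <- lengths(object@clusters)
  cat("SpacerClustering:", length(object@assignment), "spacers in",
      length(object@clusters), "clusters (cutoff", object@cutoff, ")\n")
  if (length(sz))
    cat("  cluster sizes: ", sum(sz == 1), " singletons, largest ",
        max(sz), "\n", sep = "")
})

#' @describeIn ColorStore-class the cluster/representative/color table
#' @param x a \linkS4class{ColorStore}
#' @export
setMethod("colorTable", "ColorStore", function(x) x@entries)

setMethod("show", "ColorStore", function(object) {
  cat("ColorStore with", nrow(object@entries), "cluster color pairs",
      "(cutoff", object@cutoff,
      if (!is.na(object@seed)) paste0(", seed ", object@seed) else "", ")\n")
})

#' @describeIn StrainOrdering-class samples in display (row) order
#' @param x a \linkS4class{StrainOrdering}
#' @export
setMethod("orderedSamples", "StrainOrdering", function(x) x@orderedSamples)

#' @describeIn StrainOrdering-class the UPGMA guide tree (`hclust`) or NULL
#' @export
setMethod("guideTree", "StrainOrdering", function(x) x@tree)

setMethod("show", "StrainOrdering", function(object) {
  cat("StrainOrdering (", object@source, "): ",
      paste(object@orderedSamples, collapse = ", "), "\n", sep = "")
})

setMethod("show", "SvgScene", function(object) {
  cat("SvgScene:", nrow(object@cells), "cells,", nrow(object@labels),
      "labels, canvas", object@width, "x", object@height, "\n")
})
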
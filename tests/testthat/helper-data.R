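# Shared test helpers: small in-code datasets and independent oracles.

randDna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# substitute position i of x with a different base
substituteAt <- function(x, i, to = NULL) {
  ch <- strsplit(x, "")[[1]]
  if (is.null(to)) to <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  ch[i] <- to
  paste(ch, collapse = "")
}

# Build a SpacerSet from a named list: sample -> list of sequence vectors
# (one vector per locus). Coordinates are synthesized consistently.
makeSpacerSet <- function(loci, strand = "+") {
  rows <- list()
  for (s in names(loci)) {
    pos <- 100L
    for (l in seq_along(loci[[s]])) {
      seqs <- loci[[s]][[l]]
      for (k in seq_along(seqs)) {
        len <- nchar(seqs[k])
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, locus_num = l, spacer_num = k,
          start = pos, end = pos + len - 1L, length = len,
          strand = strand, sequence = seqs[k], stringsAsFactors = FALSE)
        pos <- pos + len + 30L
      }
      pos <- pos + 500L
    }
  }
  SpacerSet(do.call(rbind, rows), sampleOrder = names(loci))
}

# Independent connected-components oracle: boolean transitive closure of the
# adjacency matrix by Floyd-Warshall-style sweeps, then component labels.
closureComponents <- function(adj) {
  n <- nrow(adj)
  R <- adj | diag(TRUE, n)
  for (k in seq_len(n)) R <- R | (R[, k] %o% R[k, ])
  labels <- integer(n)
  for (i in seq_len(n)) labels[i] <- which(R[i, ])[1]
  labels
}

# partition equality up to relabeling
samePartition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

swAlign <- function(a, b) crisprCanvas:::.sw_align(a, b)
bruteAlign <- function(a, b) crisprCanvas:::.brute_local_align(a, b)
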
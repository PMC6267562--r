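#' Specification for a synthetic CRISPRDetect-style dataset
#'
#' Parameters of the seeded generator used for testing and demonstration.
#' It emulates the structure of real CRISPR typing datasets: several
#' samples, 1-3 CRISPR loci each, a handful to a few dozen spacers per
#' locus, ~28-38 nt spacers, and groups of samples ("sharing pools") whose
#' loci end in a common ancestral block of 3'-terminal spacers -- the old,
#' conserved end of the array -- while novel spacers accumulate at the 5'
#' end. Shared spacers can diverge by per-nucleotide substitutions
#' (`mutationRate`), and whole loci can sit on the minus strand
#' (`strandFlipProb`) to exercise orientation normalization.
#'
#' @param nSamples number of samples
#' @param lociPerSample integer range (min, max) of loci per sample
#' @param spacersPerLocus integer range (min, max) of spacers per locus
#' @param spacerLengthMean,spacerLengthSd spacer length distribution (nt);
#'   lengths are clamped to 28-38
#' @param nSharedPools number of disjoint sharing pools samples are assigned
#'   to (round-robin)
#' @param sharedFraction fraction of each first locus taken from the pool's
#'   ancestral 3' block
#' @param mutationRate per-nucleotide substitution probability applied to
#'   each sample's copy of a shared spacer
#' @param strandFlipProb probability that a locus is annotated on the minus
#'   strand
#' @param seed RNG seed; the generator is fully deterministic given the spec
#' @return list of class `FixtureSpec`
#' @export
fixtureSpec <- function(nSamples = 6, lociPerSample = c(1, 2),
                        spacersPerLocus = c(3, 10),
                        spacerLengthMean = 32, spacerLengthSd = 2,
                        nSharedPools = 2, sharedFraction = 0.5,
                        mutationRate = 0.02, strandFlipProb = 0.3,
                        seed = 1) {
  stopifnot(nSamples >= 1, all(lociPerSample >= 1), all(spacersPerLocus >= 1),
            spacerLengthMean > 0, nSharedPools >= 1,
            mutationRate >= 0, mutationRate <= 1,
            strandFlipProb >= 0, strandFlipProb <= 1)
  structure(list(nSamples = nSamples, lociPerSample = lociPerSample,
                 spacersPerLocus = spacersPerLocus,
                 spacerLengthMean = spacerLengthMean,
                 spacerLengthSd = spacerLengthSd,
                 nSharedPools = nSharedPools,
                 sharedFraction = sharedFraction,
                 mutationRate = mutationRate,
                 strandFlipProb = strandFlipProb, seed = seed),
            class = "FixtureSpec")
}

randSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutateSeq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit)
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# sample() treats a length-1 integer as 1:x; draw from a (min, max) range
rangeDraw <- function(range) {
  v <- seq(range[1], range[2])
  if (length(v) == 1) v else sample(v, 1)
}

drawLen <- function(spec) {
  max(28, min(38, round(stats::rnorm(1, spec$spacerLengthMean,
                                     spec$spacerLengthSd))))
}

#' Simulate a spacer dataset in memory
#'
#' Runs the generator of [fixtureSpec()] without touching disk. Returns the
#' dataset together with its ground truth: the generative cluster of every
#' spacer (shared spacers carry their ancestral id, unique spacers their
#' own) and the true shared-spacer count matrix between samples.
#'
#' @param spec a [fixtureSpec()]
#' @return list with elements `spacerSet` (\linkS4class{SpacerSet}), `truth`
#'   (named character, spacer id -> generative cluster), `pools` (named
#'   integer, sample -> pool), `sharedCounts` (integer matrix)
#' @export
simulateSpacerSet <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  withSeed(spec$seed, {
    samples <- sprintf("sample%02d", seq_len(spec$nSamples))
    pools <- setNames(((seq_len(spec$nSamples) - 1) %% spec$nSharedPools) + 1,
                      samples)
    # ancestral 3'-terminal arrays, one per pool
    ancLen <- max(spec$spacersPerLocus)
    anc <- lapply(seq_len(spec$nSharedPools), function(p)
      vapply(seq_len(ancLen), function(i) randSeq(drawLen(spec)), ""))
    rows <- list(); truth <- character(0)
    for (s in samples) {
      nLoci <- rangeDraw(spec$lociPerSample)
      pos <- 1000L
      for (l in seq_len(nLoci)) {
        n <- rangeDraw(spec$spacersPerLocus)
        seqs <- character(n); tcl <- character(n)
        if (l == 1) {
          # locus 1 ends in the pool's ancestral block; novelty at the 5' end
          t <- max(1, min(ancLen, round(n * spec$sharedFraction)))
          ancIdx <- seq(ancLen - t + 1, ancLen)
          for (k in seq_len(n - t)) {
            seqs[k] <- randSeq(drawLen(spec))
            tcl[k] <- paste0("unique|", s, "|L", l, "|", k)
          }
          for (k in seq_len(t)) {
            j <- n - t + k
            seqs[j] <- mutateSeq(anc[[pools[s]]][ancIdx[k]], spec$mutationRate)
            tcl[j] <- paste0("pool", pools[s], "|anc", ancIdx[k])
          }
        } else {
          for (k in seq_len(n)) {
            seqs[k] <- randSeq(drawLen(spec))
            tcl[k] <- paste0("unique|", s, "|L", l, "|", k)
          }
        }
        strand <- if (stats::runif(1) < spec$strandFlipProb) "-" else "+"
        lens <- nchar(seqs)
        # physical left-to-right genomic order: array order on +, reversed on -
        ordPhys <- if (strand == "+") seq_len(n) else rev(seq_len(n))
        starts <- integer(n); ends <- integer(n)
        p <- pos
        for (k in ordPhys) {
          p <- p + 30L  # leading direct repeat
          starts[k] <- p
          ends[k] <- p + lens[k] - 1L
          p <- ends[k] + 1L
        }
        pos <- p + 530L  # trailing repeat + inter-locus gap
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, locus_num = l, spacer_num = seq_len(n),
          start = starts, end = ends, length = lens, strand = strand,
          sequence = seqs, stringsAsFactors = FALSE)
        truth <- c(truth, setNames(tcl, spacerId(s, l, seq_len(n))))
      }
    }
    df <- do.call(rbind, rows)
    ss <- SpacerSet(df, sampleOrder = samples)
    # true shared counts: multiset overlap of generative clusters
    counts <- table(factor(spacerInfo(ss)$sample_id, levels = samples),
                    truth[spacerIds(ss)])
    n <- length(samples)
    shared <- matrix(0L, n, n, dimnames = list(samples, samples))
    for (i in seq_len(n)) for (j in seq_len(n))
      shared[i, j] <- sum(pmin(counts[i, ], counts[j, ]))
    list(spacerSet = ss, truth = truth, pools = pools, sharedCounts = shared)
  })
}

gffAttr <- function(...) paste(..., sep = ";")

#' Write a simulated dataset as CRISPRDetect-style GFF3 files
#'
#' Materializes [simulateSpacerSet()] on disk: one GFF3 per sample with a
#' `repeat_region` feature per locus, `binding_site` child features for the
#' spacers (sequence carried in the `Note` attribute as the forward genomic
#' strand, length in the score field) and `direct_repeat` features for
#' realism, plus ground-truth TSVs (`truth_clusters.tsv`,
#' `truth_shared.tsv`). Optionally writes the pseudo-genome FASTA so the
#' coordinate-slicing parser path can be exercised.
#'
#' @param spec a [fixtureSpec()]
#' @param outDir output directory (created if needed)
#' @param writeGenome also write `genome.fasta`
#' @return invisibly, list with `gff` (paths), `truthClusters`,
#'   `truthShared`, `genome` (path or NULL), and the `simulation` itself
#' @export
generateFixture <- function(spec, outDir, writeGenome = FALSE) {
  sim <- simulateSpacerSet(spec)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  df <- spacerInfo(sim$spacerSet)
  gffPaths <- character(0)
  genome <- list()
  for (s in sampleIds(sim$spacerSet)) {
    sub <- df[df$sample_id == s, , drop = FALSE]
    lines <- c("##gff-version 3")
    glen <- max(sub$end) + 200L
    chars <- rep("A", glen)  # backbone; repeats/spacers overwrite below
    for (l in sort(unique(sub$locus_num))) {
      loc <- sub[sub$locus_num == l, , drop = FALSE]
      strand <- loc$strand[1]
      lines <- c(lines, paste(
        s, "CRISPRDetect", "repeat_region", min(loc$start) - 30L,
        max(loc$end) + 30L, ".", strand, ".",
        gffAttr(sprintf("ID=CRISPR%d_%s", l, s),
                sprintf("Note=CRISPR array with %d spacers", nrow(loc))),
        sep = "\t"))
      rep_seq <- "GTTTTAGAGCTATGCTGTTTTGAATGGTC"
      for (k in order(loc$start)) {
        fwd <- if (strand == "-") revComp(loc$sequence[k]) else loc$sequence[k]
        lines <- c(lines,
          paste(s, "CRISPRDetect", "direct_repeat",
                loc$start[k] - 30L, loc$start[k] - 1L, "30", strand, ".",
                gffAttr(sprintf("ID=DR%d_%d_%s", l, loc$spacer_num[k], s),
                        sprintf("Parent=CRISPR%d_%s", l, s)),
                sep = "\t"),
          paste(s, "CRISPRDetect", "binding_site",
                loc$start[k], loc$end[k], loc$length[k], strand, ".",
                gffAttr(sprintf("ID=SP%d_%d_%s", l, loc$spacer_num[k], s),
                        sprintf("Parent=CRISPR%d_%s", l, s),
                        sprintf("Note=%s", fwd)),
                sep = "\t"))
        substr_range <- seq(loc$start[k], loc$end[k])
        chars[substr_range] <- strsplit(fwd, "")[[1]]
        rstart <- loc$start[k] - 30L
        chars[seq(rstart, rstart + 29L)] <-
          strsplit(substr(paste0(rep_seq, "G"), 1, 30), "")[[1]]
      }
    }
    path <- file.path(outDir, paste0(s, ".gff3"))
    writeLines(lines, path)
    gffPaths <- c(gffPaths, path)
    genome[[s]] <- paste(chars, collapse = "")
  }
  truthPath <- file.path(outDir, "truth_clusters.tsv")
  utils::write.table(
    data.frame(spacer_id = names(sim$truth), truth_cluster = unname(sim$truth)),
    truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
  sharedPath <- file.path(outDir, "truth_shared.tsv")
  utils::write.table(as.data.frame(as.table(sim$sharedCounts),
                                   responseName = "shared"),
                     sharedPath, sep = "\t", quote = FALSE, row.names = FALSE)
  genomePath <- NULL
  if (writeGenome) {
    genomePath <- file.path(outDir, "genome.fasta")
    gs <- Biostrings::DNAStringSet(unlist(genome))
    Biostrings::writeXStringSet(gs, genomePath, width = 80L)
  }
  invisible(list(gff = gffPaths, truthClusters = truthPath,
                 truthShared = sharedPath, genome = genomePath,
                 simulation = sim))
}
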
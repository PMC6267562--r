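#' Construct a SpacerSet from a spacer table
#'
#' Builds and validates a \linkS4class{SpacerSet}. Rows may be given in any
#' order; they are sorted by sample (first appearance unless `sampleOrder` is
#' given), locus number, then spacer number.
#'
#' @param spacers data.frame with columns `sample_id`, `locus_num`,
#'   `spacer_num`, `start`, `end`, `length`, `strand`, `sequence`. `length`
#'   is filled from the sequence when missing.
#' @param sampleOrder optional character giving the sample display/input
#'   order; defaults to order of first appearance.
#' @param provenance optional named character, sample id -> source path.
#' @return a \linkS4class{SpacerSet}
#' @export
SpacerSet <- function(spacers, sampleOrder = NULL, provenance = NULL) {
  spacers$sequence <- toupper(spacers$sequence)
  if (is.null(spacers$length)) spacers$length <- nchar(spacers$sequence)
  for (col in c("locus_num", "spacer_num", "start", "end", "length"))
    spacers[[col]] <- as.integer(spacers[[col]])
  if (is.null(sampleOrder)) sampleOrder <- unique(spacers$sample_id)
  ord <- order(match(spacers$sample_id, sampleOrder),
               spacers$locus_num, spacers$spacer_num)
  spacers <- spacers[ord, , drop = FALSE]
  rownames(spacers) <- NULL
  if (is.null(provenance))
    provenance <- setNames(rep("", length(sampleOrder)), sampleOrder)
  new("SpacerSet", spacers = spacers, sampleOrder = sampleOrder,
      provenance = provenance)
}

SPACER_TYPES <- c("binding_site", "Spacer")
SEQ_ATTR_KEYS <- c("Note", "sequence", "seq", "spacer_sequence")

# Cheap structural validation so malformed lines are reported with their
# file and line number (rtracklayer's own errors name neither).
validateGffLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body) == 0)
    stop("empty GFF3 file (no feature lines): ", path, call. = FALSE)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf != 9]
  if (length(bad))
    stop("malformed GFF3 line (expected 9 tab-separated fields) at ",
         path, ":", bad[1], call. = FALSE)
  invisible(TRUE)
}

extractSeqAttr <- function(mcols_df, i) {
  for (key in SEQ_ATTR_KEYS) {
    if (!key %in% names(mcols_df)) next
    v <- mcols_df[[key]][[i]]
    v <- unlist(v, use.names = FALSE)
    v <- v[!is.na(v)]
    v <- v[grepl("^[ACGTNRYSWKMBDHVacgtnryswkmbdhv]+$", v)]
    if (length(v)) return(toupper(v[1]))
  }
  NA_character_
}

#' Read CRISPRDetect-style GFF3 into a SpacerSet
#'
#' Parses one or more GFF3 files as produced by CRISPRDetect. Each
#' `repeat_region` feature defines a CRISPR locus; its spacers are features
#' of type `binding_site` or `Spacer` located inside it. Loci are numbered
#' per sample in file order starting at 1; spacers are numbered 5'->3' along
#' the array (ascending genomic coordinates on the + strand, descending on
#' the - strand), and minus-strand sequences are reverse-complemented so the
#' stored sequence is always in array orientation.
#'
#' Spacer sequences are taken from a feature attribute (keys `Note`,
#' `sequence`, `seq` or `spacer_sequence`, holding the forward genomic
#' strand sequence); when absent, they are sliced from `genome`, a companion
#' genome FASTA. One of the two sources must be available for every spacer.
#'
#' @param paths character vector of GFF3 file paths.
#' @param genome optional path to a genome FASTA (or a named
#'   \link[Biostrings]{DNAStringSet}) used to slice spacer sequences by
#'   coordinates when the GFF3 carries no sequence attribute.
#' @return a \linkS4class{SpacerSet}; the sample id is the GFF3 seqname
#'   (field 1) and sample order follows file order.
#' @export
readCrisprGff <- function(paths, genome = NULL) {
  if (length(paths) == 0) stop("no input files given")
  if (!is.null(genome) && !methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::readDNAStringSet(genome)
  rows <- list()
  sampleOrder <- character(0)
  provenance <- character(0)
  for (path in paths) {
    validateGffLines(path)
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    isLocus <- as.character(mc$type) == "repeat_region"
    isSpacer <- as.character(mc$type) %in% SPACER_TYPES
    if (!any(isLocus))
      stop("no repeat_region feature in ", path, call. = FALSE)
    seqn <- as.character(GenomicRanges::seqnames(gr))
    locusIdx <- which(isLocus)
    # per-sample locus counter, samples in file order
    locusNum <- integer(length(gr))
    cnt <- integer(0)
    for (li in locusIdx) {
      s <- seqn[li]
      cnt[s] <- if (is.na(cnt[s])) 1L else cnt[s] + 1L
      locusNum[li] <- cnt[s]
      if (!s %in% sampleOrder) {
        sampleOrder <- c(sampleOrder, s)
        provenance[s] <- path
      }
    }
    st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
    strnd <- as.character(GenomicRanges::strand(gr))
    for (si in which(isSpacer)) {
      parent <- locusIdx[seqn[locusIdx] == seqn[si] &
                         st[locusIdx] <= st[si] & en[locusIdx] >= en[si]]
      if (length(parent) == 0)
        stop("spacer at ", path, " ", seqn[si], ":", st[si], "-", en[si],
             " lies in no repeat_region", call. = FALSE)
      parent <- parent[1]
      seq <- extractSeqAttr(mc, si)
      if (is.na(seq) && !is.null(genome) && seqn[si] %in% names(genome))
        seq <- as.character(Biostrings::subseq(genome[[seqn[si]]], st[si], en[si]))
      if (is.na(seq))
        stop("no recoverable sequence for spacer ", seqn[si], ":", st[si],
             "-", en[si], " in ", path,
             " (no sequence attribute and no genome FASTA)", call. = FALSE)
      spStrand <- strnd[si]
      if (!spStrand %in% c("+", "-")) spStrand <- strnd[parent]
      if (!spStrand %in% c("+", "-")) spStrand <- "+"
      if (spStrand == "-") seq <- revComp(seq)
      len <- en[si] - st[si] + 1L
      if (nchar(seq) != len)
        warning("spacer ", seqn[si], ":", st[si], "-", en[si],
                ": sequence length ", nchar(seq),
                " disagrees with coordinates (", len, "); using the sequence",
                call. = FALSE)
      score <- mc$score[si]
      if (!is.null(score) && !is.na(score) && score > 0 && score != nchar(seq))
        warning("spacer ", seqn[si], ":", st[si], "-", en[si],
                ": length field ", score, " disagrees with sequence length ",
                nchar(seq), "; using the sequence", call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = seqn[si], locus_num = locusNum[parent],
        spacer_num = NA_integer_, start = st[si], end = en[si],
        length = nchar(seq),
        strand = spStrand, sequence = seq, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no spacer features found")
  df <- do.call(rbind, rows)
  # number spacers 5'->3' within each locus
  out <- lapply(split(df, paste(df$sample_id, df$locus_num, sep = "\r")),
    function(d) {
      up <- d$strand[1] == "+"
      d <- d[order(d$start, decreasing = !up), , drop = FALSE]
      d$spacer_num <- seq_len(nrow(d))
      d
    })
  df <- do.call(rbind, out)
  # end must stay >= start; coordinates are kept as read. If the sequence
  # won over a disagreeing length field, refit end so invariants hold.
  df$end <- df$start + df$length - 1L
  ss <- SpacerSet(df, sampleOrder = sampleOrder, provenance = provenance)
  lc <- table(spacerInfo(ss)$sample_id[!duplicated(
    paste(spacerInfo(ss)$sample_id, spacerInfo(ss)$locus_num))])
  if (length(unique(as.integer(lc))) > 1)
    message("note: samples carry differing numbers of CRISPR loci (",
            paste0(names(lc), "=", as.integer(lc), collapse = ", "),
            "); check locus numbering consistency before comparing loci")
  ss
}

#' Write the dataset-wide spacer FASTA
#'
#' One record per spacer, ordered by sample (input order), locus, spacer
#' number. The header encodes all identity fields with `|` as delimiter
#' (illegal in sample names): `sample|locus<k>|spacer<j>|start|end|length|strand`.
#' This file is the hand-editable restart point of the pipeline and is also
#' suitable for protospacer homology searches.
#'
#' @param ss a \linkS4class{SpacerSet}
#' @param path output file path
#' @return invisibly, `path`
#' @export
writeSpacerFasta <- function(ss, path) {
  if (nSpacers(ss) == 0) stop("empty dataset")
  df <- spacerInfo(ss)
  headers <- paste(df$sample_id, paste0("locus", df$locus_num),
                   paste0("spacer", df$spacer_num), df$start, df$end,
                   df$length, df$strand, sep = "|")
  seqs <- Biostrings::DNAStringSet(df$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a spacer FASTA back into a SpacerSet
#'
#' Restart path: reads a FASTA written by [writeSpacerFasta()] (possibly
#' hand-edited to fix locus splits or mis-extracted spacers) and rebuilds the
#' dataset, sufficient for all downstream stages without the original GFF3.
#'
#' @param path spacer FASTA path with headers
#'   `sample|locus<k>|spacer<j>|start|end|length|strand`
#' @return a \linkS4class{SpacerSet}
#' @export
readSpacerFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  hdr <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 7)
  if (length(bad))
    stop("header does not follow sample|locus<k>|spacer<j>|start|end|length|strand: '",
         hdr[bad[1]], "'", call. = FALSE)
  m <- do.call(rbind, parts)
  locus <- suppressWarnings(as.integer(sub("^locus", "", m[, 2])))
  spacer <- suppressWarnings(as.integer(sub("^spacer", "", m[, 3])))
  if (anyNA(locus) || anyNA(spacer) ||
      !all(grepl("^locus[0-9]+$", m[, 2])) ||
      !all(grepl("^spacer[0-9]+$", m[, 3])))
    stop("header does not follow the locus<k>/spacer<j> scheme: '",
         hdr[which(is.na(locus) | is.na(spacer))[1]], "'", call. = FALSE)
  df <- data.frame(sample_id = m[, 1], locus_num = locus, spacer_num = spacer,
                   start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                   length = as.integer(m[, 6]), strand = m[, 7],
                   sequence = as.character(seqs), stringsAsFactors = FALSE)
  ids <- spacerId(df$sample_id, df$locus_num, df$spacer_num)
  if (anyDuplicated(ids))
    stop("duplicated spacer identity in FASTA: ", ids[duplicated(ids)][1],
         call. = FALSE)
  prov <- setNames(rep(path, length(unique(df$sample_id))), unique(df$sample_id))
  SpacerSet(df, provenance = prov)
}

#' Flag spacers with outlying lengths
#'
#' A spacer much longer than the dataset average usually means the upstream
#' CRISPR miner fused a repeat and a spacer; much shorter suggests a
#' mis-split. Flags every spacer whose length is strictly greater than
#' `factor` times the dataset mean, or strictly less than the mean divided by
#' `factor`. Lengths landing exactly on a boundary are not flagged.
#'
#' @param ss a \linkS4class{SpacerSet}
#' @param factor ratio defining "much longer/shorter" (default 1.5)
#' @return data.frame of flagged spacers with columns `sample_id`,
#'   `locus_num`, `spacer_num`, `length`, `mean_length`, `message`;
#'   zero rows when nothing is flagged.
#' @export
checkSpacerLengths <- function(ss, factor = 1.5) {
  if (nSpacers(ss) == 0) stop("empty dataset")
  if (factor <= 1) stop("factor must be > 1")
  df <- spacerInfo(ss)
  m <- mean(df$length)
  hit <- df$length > factor * m | df$length < m / factor
  out <- df[hit, c("sample_id", "locus_num", "spacer_num", "length")]
  out$mean_length <- rep(m, nrow(out))
  out$message <- sprintf(
    "spacer %s length %d nt deviates more than %gx from the dataset mean %.1f nt; check for repeat/spacer mis-splits",
    spacerId(out$sample_id, out$locus_num, out$spacer_num),
    out$length, factor, m)
  rownames(out) <- NULL
  out
}
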
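#' Adjusted number of nucleotide mismatches
#'
#' Extends the mismatch + gap count of a local alignment with the unaligned
#' query overhang, so a short partial alignment is penalized over the full
#' query length:
#' `adjusted = query_length - (alignment_length - mismatches - gaps)`,
#' i.e. the query length minus the number of matched columns. Two spacers
#' aligned end-to-end without errors score 0; every query position that is
#' not a match adds 1.
#'
#' @param queryLength query spacer length (nt)
#' @param alignmentLength columns in the local alignment
#' @param mismatches mismatch columns
#' @param gaps gap columns
#' @return the adjusted mismatch count (never negative)
#' @export
adjustedMismatches <- function(queryLength, alignmentLength, mismatches, gaps) {
  args <- cbind(queryLength, alignmentLength, mismatches, gaps)
  if (any(args < 0)) stop("all arguments must be >= 0")
  if (any(alignmentLength < mismatches + gaps))
    stop("alignment_length must be >= mismatches + gaps")
  if (any(alignmentLength - gaps > queryLength))
    stop("alignment cannot cover more query residues than exist (alignment_length - gaps > query_length)")
  as.integer(queryLength - (alignmentLength - mismatches - gaps))
}

DEFAULT_SCORING <- list(match = 5L, mismatch = -4L, gapOpen = -12L, gapExt = -4L)

checkSeq <- function(x, what) {
  if (length(x) != 1 || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty nucleotide string")
  toupper(x)
}

#' Optimal local alignment of two spacers
#'
#' Smith-Waterman local alignment with affine gaps (match +5, mismatch -4,
#' gap open -12, gap extend -4 per residue; sensitivity comparable to
#' fasta36's DNA defaults). `a` is the query. Among equal-scoring optimal
#' alignments, the one with the most matched columns and then the fewest gap
#' columns is reported, making the adjusted mismatch count canonical.
#' Ambiguity codes (including N) score as mismatches against every base.
#' Sequences are assumed orientation-normalized upstream; only the forward
#' strand is aligned.
#'
#' @param a query sequence (character)
#' @param b subject sequence (character)
#' @param scoring list with `match`, `mismatch`, `gapOpen`, `gapExt`
#' @return one-row data.frame with columns `query_length`,
#'   `alignment_length`, `mismatches`, `gaps`, `score`, `adjusted`
#' @export
alignPair <- function(a, b, scoring = DEFAULT_SCORING) {
  a <- checkSeq(a, "a"); b <- checkSeq(b, "b")
  r <- .sw_align(a, b, scoring$match, scoring$mismatch,
                 scoring$gapOpen, scoring$gapExt)
  data.frame(query_length = nchar(a),
             alignment_length = r$alignment_length,
             mismatches = r$mismatches, gaps = r$gaps, score = r$score,
             adjusted = adjustedMismatches(nchar(a), r$alignment_length,
                                           r$mismatches, r$gaps))
}

#' All-vs-all spacer similarity
#'
#' Aligns every unordered pair of spacers and reduces the two query
#' directions of the adjusted mismatch count to a single symmetric score:
#' the minimum of the two, so a good hit in either direction links the pair.
#' Since the optimal local alignment itself is symmetric, the reduced score
#' equals `min(length_a, length_b) - matched_columns`. Identical sequences
#' are deduplicated before alignment; this changes nothing in the output.
#'
#' @param ss a \linkS4class{SpacerSet}, or a named character vector of
#'   sequences (names are spacer ids)
#' @param scoring see [alignPair()]
#' @param maxAdjusted optional: drop pairs with reduced adjusted score above
#'   this value from the output (the full all-vs-all is still computed)
#' @return data.frame with one row per unordered pair: `id1`, `id2`,
#'   `alignment_length`, `mismatches`, `gaps`, `score`, `adjusted1` (id1 as
#'   query), `adjusted2`, `adjusted` (reduced symmetric score)
#' @export
alignAllPairs <- function(ss, scoring = DEFAULT_SCORING, maxAdjusted = NULL) {
  if (methods::is(ss, "SpacerSet")) {
    seqs <- setNames(spacerInfo(ss)$sequence, spacerIds(ss))
  } else {
    seqs <- ss
    if (is.null(names(seqs))) stop("sequences must be named by spacer id")
  }
  if (length(seqs) < 1) stop("need at least one spacer")
  seqs <- toupper(seqs)
  uniq <- unique(unname(seqs))
  grp <- match(seqs, uniq)
  nu <- length(uniq)
  ulen <- nchar(uniq)
  res <- vector("list", if (nu > 1) nu * (nu - 1) / 2 else 0)
  k <- 0L
  if (nu > 1) {
    for (i in seq_len(nu - 1)) {
      for (j in seq(i + 1, nu)) {
        r <- .sw_align(uniq[i], uniq[j], scoring$match, scoring$mismatch,
                       scoring$gapOpen, scoring$gapExt)
        k <- k + 1L
        res[[k]] <- c(i, j, r$alignment_length, r$mismatches, r$gaps,
                      r$score, r$matches)
      }
    }
  }
  um <- if (k) do.call(rbind, res) else matrix(numeric(0), ncol = 7)
  # expand unique-pair results to all spacer pairs (including duplicate pairs)
  ids <- names(seqs)
  n <- length(ids)
  if (n < 2) {
    i1 <- integer(0); i2 <- integer(0)
  } else {
    i1 <- rep(seq_len(n - 1), times = (n - 1):1)
    i2 <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)),
                 use.names = FALSE)
  }
  g1 <- grp[i1]; g2 <- grp[i2]
  lo <- pmin(g1, g2); hi <- pmax(g1, g2)
  same <- lo == hi
  out <- data.frame(id1 = ids[i1], id2 = ids[i2],
                    alignment_length = integer(length(i1)),
                    mismatches = integer(length(i1)),
                    gaps = integer(length(i1)),
                    score = integer(length(i1)),
                    adjusted1 = integer(length(i1)),
                    adjusted2 = integer(length(i1)),
                    adjusted = integer(length(i1)),
                    stringsAsFactors = FALSE)
  if (any(same)) {
    # duplicate sequence vs itself: pure-ACGT sequences align end-to-end
    # perfectly; sequences carrying ambiguity codes (which never match) go
    # through the aligner like any other pair
    gsame <- sort(unique(g1[same]))
    selfStats <- matrix(0L, nrow = nu, ncol = 5,
                        dimnames = list(NULL, c("alen", "mm", "gaps", "score", "matches")))
    for (g in gsame) {
      if (grepl("^[ACGT]+$", uniq[g])) {
        selfStats[g, ] <- c(ulen[g], 0L, 0L, scoring$match * ulen[g], ulen[g])
      } else {
        r <- .sw_align(uniq[g], uniq[g], scoring$match, scoring$mismatch,
                       scoring$gapOpen, scoring$gapExt)
        selfStats[g, ] <- c(r$alignment_length, r$mismatches, r$gaps,
                            r$score, r$matches)
      }
    }
    gs <- g1[same]
    out$alignment_length[same] <- selfStats[gs, "alen"]
    out$mismatches[same] <- selfStats[gs, "mm"]
    out$gaps[same] <- selfStats[gs, "gaps"]
    out$score[same] <- selfStats[gs, "score"]
    adj <- ulen[gs] - selfStats[gs, "matches"]
    out$adjusted1[same] <- adj; out$adjusted2[same] <- adj
    out$adjusted[same] <- adj
  }
  if (any(!same) && k) {
    key <- (lo[!same] - 1) * nu - lo[!same] * (lo[!same] - 1) / 2 + (hi[!same] - lo[!same])
    rows <- um[key, , drop = FALSE]
    matches <- rows[, 7]
    out$alignment_length[!same] <- rows[, 3]
    out$mismatches[!same] <- rows[, 4]
    out$gaps[!same] <- rows[, 5]
    out$score[!same] <- rows[, 6]
    out$adjusted1[!same] <- nchar(seqs[i1][!same]) - matches
    out$adjusted2[!same] <- nchar(seqs[i2][!same]) - matches
    out$adjusted[!same] <- pmin(out$adjusted1[!same], out$adjusted2[!same])
  }
  if (!is.null(maxAdjusted)) out <- out[out$adjusted <= maxAdjusted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Import fasta36 tabular hits as pair similarities
#'
#' Adapter for users who prefer running fasta36 externally: reads BLAST-like
#' tabular output (`fasta36 -m 8`: query, subject, %identity, alignment
#' length, mismatches, gap openings, qstart, qend, sstart, send, evalue,
#' bitscore) and applies the adjusted-mismatch formula. Gap columns are
#' recovered from the identity fraction
#' (`gaps = alignment_length - mismatches - identities`), and self hits are
#' dropped. Hits in both query directions are reduced to the minimum
#' adjusted score per unordered pair; pairs without any hit are assigned an
#' adjusted score of `Inf` (fasta36 simply reports no alignment for them).
#'
#' @param path tabular output file
#' @param queryLengths named integer vector, spacer id -> length (e.g.
#'   `setNames(spacerInfo(ss)$length, spacerIds(ss))`)
#' @return data.frame with columns `id1`, `id2`, `adjusted` (reduced)
#' @export
readFasta36Hits <- function(path, queryLengths) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("expected >= 6 tabular columns (fasta36 -m 8)")
  q <- tab[[1]]; s <- tab[[2]]
  keep <- q != s
  tab <- tab[keep, , drop = FALSE]; q <- q[keep]; s <- s[keep]
  if (any(!q %in% names(queryLengths)))
    stop("query id missing from queryLengths: ", setdiff(q, names(queryLengths))[1])
  alen <- tab[[4]]; mm <- tab[[5]]
  ident <- round(tab[[3]] / 100 * alen)
  gaps <- pmax(0, alen - mm - ident)
  adj <- adjustedMismatches(queryLengths[q], alen, mm, gaps)
  a <- pmin(q, s); b <- pmax(q, s)
  agg <- tapply(adj, paste(a, b, sep = "\r"), min)
  keys <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(id1 = vapply(keys, `[`, "", 1), id2 = vapply(keys, `[`, "", 2),
             adjusted = as.integer(agg), stringsAsFactors = FALSE, row.names = NULL)
}
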
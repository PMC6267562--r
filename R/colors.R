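HEX3 <- sprintf("#%03x", 0:4095)
GRAY_SQUARE_IDX <- which(HEX3 == "#fff")

#' Assign two-color HEX codes to spacer clusters
#'
#' Every cluster receives a pair of random 3-digit HEX colors: one for the
#' square and one for the centered diamond. Square colors are unique across
#' clusters and `#fff` is reserved (with diamond `#ccc`) for the gray-out
#' display, so the color space holds at most 4095 clusters; a candidate
#' diamond equal to its square is rejected as it would hide the diamond.
#'
#' With a `prior` store (append mode), clusters are first re-linked to the
#' previous run: each prior representative sequence is aligned against the
#' current spacer sequences, and a cluster containing a spacer within
#' `cutoff` of a prior representative inherits that prior color pair. When
#' appended spacers bridge several prior clusters, the merged cluster
#' inherits from the prior cluster supported by most current members (ties:
#' lexicographically smallest prior cluster id). Fresh colors are drawn only
#' for clusters without a prior match, so existing figures keep their colors.
#'
#' @param clustering a \linkS4class{SpacerClustering}
#' @param spacers the \linkS4class{SpacerSet} that was clustered (or a named
#'   character vector of sequences by spacer id); used for representatives
#' @param seed integer seed for the color draws; if NULL a random seed is
#'   drawn and reported, so the run can be reproduced
#' @param prior a \linkS4class{ColorStore} from a previous run, or NULL
#' @return a \linkS4class{ColorStore}
#' @export
assignColors <- function(clustering, spacers, seed = NULL, prior = NULL) {
  if (methods::is(spacers, "SpacerSet"))
    spacers <- setNames(spacerInfo(spacers)$sequence, spacerIds(spacers))
  members <- clusterMembers(clustering)
  missing <- setdiff(unlist(members, use.names = FALSE), names(spacers))
  if (length(missing))
    stop("no sequence for clustered spacer ", missing[1])
  cids <- cSort(names(members))
  reps <- setNames(unname(spacers[cids]), cids)  # sequence of the id-giving member
  entries <- data.frame(cluster_id = cids, representative = reps,
                        square = NA_character_, diamond = NA_character_,
                        stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(prior) && nrow(colorTable(prior)) > 0) {
    pt <- colorTable(prior)
    # locate each prior representative in the current dataset
    uniqSeq <- unique(unname(spacers))
    hitCluster <- character(nrow(pt))
    for (i in seq_len(nrow(pt))) {
      adj <- vapply(uniqSeq, function(u) {
        if (u == pt$representative[i] && grepl("^[ACGT]+$", u)) return(0L)
        r <- .sw_align(pt$representative[i], u, DEFAULT_SCORING$match,
                       DEFAULT_SCORING$mismatch, DEFAULT_SCORING$gapOpen,
                       DEFAULT_SCORING$gapExt)
        as.integer(min(nchar(pt$representative[i]), nchar(u)) - r$matches)
      }, integer(1))
      best <- which(adj <= clustering@cutoff)
      if (length(best)) {
        # the matching sequences must all lie in one cluster (they are within
        # the cutoff of a common sequence only if edges link them -- if they
        # ended up in different clusters the prior rep bridges none of them
        # directly; pick the cluster of the best-scoring sequence)
        bi <- best[which.min(adj[best])]
        sp <- names(spacers)[match(uniqSeq[bi], spacers)]
        hitCluster[i] <- unname(clusterAssignment(clustering)[sp])
      }
    }
    matched <- hitCluster != ""
    if (any(matched)) {
      support <- integer(sum(matched))
      pm <- pt[matched, , drop = FALSE]
      hc <- hitCluster[matched]
      for (cid in unique(hc)) {
        sel <- which(hc == cid)
        if (length(sel) == 1) {
          pick <- sel
        } else {
          # merged cluster: count current members within cutoff of each rep
          memSeq <- spacers[members[[cid]]]
          supp <- vapply(sel, function(s) {
            sum(vapply(memSeq, function(u) {
              r <- .sw_align(pm$representative[s], u, DEFAULT_SCORING$match,
                             DEFAULT_SCORING$mismatch, DEFAULT_SCORING$gapOpen,
                             DEFAULT_SCORING$gapExt)
              (min(nchar(pm$representative[s]), nchar(u)) - r$matches) <=
                clustering@cutoff
            }, logical(1)))
          }, integer(1))
          ord <- order(-supp, pm$cluster_id[sel], method = "radix")
          pick <- sel[ord[1]]
        }
        j <- match(cid, entries$cluster_id)
        entries$square[j] <- pm$square[pick]
        entries$diamond[j] <- pm$diamond[pick]
      }
    }
  }
  todo <- which(is.na(entries$square))
  if (length(todo)) {
    if (is.null(seed)) {
      seed <- sample.int(.Machine$integer.max, 1)
      message("no color seed given; drew seed ", seed,
              " (pass it to reproduce these colors)")
    }
    seed <- as.integer(seed)
    usedSquares <- match(entries$square[!is.na(entries$square)], HEX3)
    free <- setdiff(seq_along(HEX3), c(GRAY_SQUARE_IDX, usedSquares))
    if (length(todo) > length(free))
      stop("3-digit HEX color space exhausted (", length(todo),
           " new clusters, ", length(free), " free square colors); ",
           "consider a gray-out display mode")
    withSeed(seed, {
      for (j in todo) {
        si <- free[sample.int(length(free), 1)]
        free <- setdiff(free, si)
        repeat {
          di <- sample.int(length(HEX3), 1)
          if (di != si) break
        }
        entries$square[j] <- HEX3[si]
        entries$diamond[j] <- HEX3[di]
      }
    })
  }
  new("ColorStore", entries = entries, cutoff = clustering@cutoff,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Resolve per-spacer display colors, with optional graying
#'
#' Turns the cluster colors into one display color per spacer and applies a
#' gray-out mode: `none` colors everything; `gray_unique` grays spacers
#' whose cluster has a single member, so only spacers seen at least twice
#' stay colored; `gray_shared` grays spacers whose cluster has two or more
#' members, highlighting the unique ones. Grayed spacers all get the
#' reserved white square / light-gray diamond.
#'
#' @param clustering a \linkS4class{SpacerClustering}
#' @param colors a \linkS4class{ColorStore} covering every cluster
#' @param mode one of "none", "gray_unique", "gray_shared"
#' @return data.frame with columns `spacer_id`, `square`, `diamond`,
#'   `grayed`
#' @export
applyGrayMode <- function(clustering, colors,
                          mode = c("none", "gray_unique", "gray_shared")) {
  mode <- match.arg(mode)
  asg <- clusterAssignment(clustering)
  ct <- colorTable(colors)
  j <- match(unname(asg), ct$cluster_id)
  if (anyNA(j))
    stop("cluster without a color: ", unname(asg)[which(is.na(j))[1]])
  sz <- clusterSizes(clustering)[unname(asg)]
  grayed <- switch(mode,
    none = rep(FALSE, length(asg)),
    gray_unique = unname(sz) == 1,
    gray_shared = unname(sz) >= 2)
  df <- data.frame(spacer_id = names(asg),
                   square = ct$square[j], diamond = ct$diamond[j],
                   grayed = grayed, stringsAsFactors = FALSE, row.names = NULL)
  df$square[df$grayed] <- GRAY_SQUARE
  df$diamond[df$grayed] <- GRAY_DIAMOND
  df
}

#' Write / read a color store as TSV
#'
#' The store is a plain TSV (`cluster_id`, `representative`, `square`,
#' `diamond`) with a `#` header line recording the cutoff and seed, suitable
#' for rerunning the pipeline on an appended dataset while keeping colors.
#'
#' @param store a \linkS4class{ColorStore}
#' @param path file path
#' @return `writeColorStore`: invisibly `path`; `readColorStore`: a
#'   \linkS4class{ColorStore}
#' @export
writeColorStore <- function(store, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# crisprCanvas color store\tcutoff=%g\tseed=%s\n",
              store@cutoff,
              if (is.na(store@seed)) "NA" else as.character(store@seed)),
      file = con)
  utils::write.table(colorTable(store), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeColorStore
#' @export
readColorStore <- function(path) {
  first <- readLines(path, n = 1)
  cutoff <- 2; seed <- NA_integer_
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("cutoff=([0-9.]+)", first))[[1]]
    if (length(m) == 2) cutoff <- as.numeric(m[2])
    m <- regmatches(first, regexec("seed=([0-9]+)", first))[[1]]
    if (length(m) == 2) seed <- as.integer(m[2])
  }
  # comment.char must stay disabled: the HEX values themselves contain '#'
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                          skip = if (startsWith(first, "#")) 1 else 0,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  new("ColorStore", entries = df, cutoff = cutoff, seed = seed)
}
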
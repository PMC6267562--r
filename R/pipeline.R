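#' Run the full CRISPR array comparison pipeline
#'
#' Single entry point tying all stages together: parse the input (GFF3
#' files, a directory of them, or a spacer FASTA restart file), run the
#' spacer-length sanity check, align all spacer pairs, cluster at the
#' mismatch cutoff, assign or re-use colors, order the strains, and write
#' the artifacts: the dataset-wide spacer FASTA, the color store, the SVG
#' figure, and optionally the guide tree (Newick) and a cluster table.
#' Warnings (outlier spacer lengths, differing locus counts) are collected
#' and summarized; they never abort the run.
#'
#' @param input character: one or more GFF3 paths, a directory containing
#'   `.gff3`/`.gff` files, or a spacer FASTA written by [writeSpacerFasta()]
#'   (detected by extension `.fasta`/`.fa`/`.fna`); a FASTA input skips
#'   parsing, supporting the manual-fix-and-restart loop
#' @param outDir output directory, created if needed
#' @param cutoff adjusted-mismatch cutoff for clustering (default 2)
#' @param sortMode "tree" (Bray-Curtis + UPGMA, default), "list" (custom
#'   list, requires `listPath`), or "input"
#' @param listPath sample list for `sortMode = "list"`
#' @param grayMode "none", "unique" (gray out singleton-cluster spacers) or
#'   "shared" (gray out spacers seen at least twice)
#' @param seed integer seed for color assignment
#' @param colorStorePath path to a color store from a previous run (append
#'   mode); newly written store goes to `outDir` regardless
#' @param genome optional genome FASTA for GFF3 inputs without sequence
#'   attributes
#' @param lengthLabels overlay spacer lengths on grayed cells
#' @param opts render geometry from [renderOptions()]
#' @param writeNewick also write the UPGMA guide tree (tree mode only)
#' @param writeClusters also write a spacer-to-cluster TSV
#' @param verbose print a stage-by-stage log and the warning summary
#' @return invisibly, a list with the computed objects (`spacerSet`,
#'   `clustering`, `colors`, `ordering`, `scene`), the artifact `paths`,
#'   and the collected `warnings` (character)
#' @export
runPipeline <- function(input, outDir, cutoff = 2,
                        sortMode = c("tree", "list", "input"),
                        listPath = NULL,
                        grayMode = c("none", "unique", "shared"),
                        seed = NULL, colorStorePath = NULL, genome = NULL,
                        lengthLabels = FALSE, opts = NULL,
                        writeNewick = FALSE, writeClusters = FALSE,
                        verbose = TRUE) {
  sortMode <- match.arg(sortMode)
  grayMode <- match.arg(grayMode)
  if (sortMode == "list" && is.null(listPath))
    stop("sortMode 'list' requires listPath")
  if (is.null(opts))
    opts <- renderOptions(showLengthLabels = lengthLabels)
  else if (lengthLabels) opts$showLengthLabels <- TRUE
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  warns <- character(0)

  # --- input stage ------------------------------------------------------
  if (length(input) == 1 && dir.exists(input))
    input <- cSort(list.files(input, pattern = "\\.gff3?$", full.names = TRUE))
  if (length(input) == 0) stop("input stage: no input files found")
  ext <- tolower(tools::file_ext(input[1]))
  if (ext %in% c("fasta", "fa", "fna")) {
    say("input: spacer FASTA restart from ", input[1])
    ss <- readSpacerFasta(input[1])
  } else {
    say("input: parsing ", length(input), " GFF3 file(s)")
    ss <- withCallingHandlers(
      readCrisprGff(input, genome = genome),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        warns <<- c(warns, sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  }
  say("  ", nSpacers(ss), " spacers in ", length(sampleIds(ss)), " samples")

  lengthFlags <- checkSpacerLengths(ss)
  warns <- c(warns, lengthFlags$message)

  # --- align + cluster --------------------------------------------------
  say("align: all-vs-all local alignment of ",
      length(unique(spacerInfo(ss)$sequence)), " unique sequences")
  pairs <- alignAllPairs(ss)
  clustering <- clusterSpacers(pairs, spacerIds(ss), cutoff = cutoff)
  say("cluster: ", length(clusterMembers(clustering)),
      " clusters at cutoff ", cutoff)

  # --- colors -----------------------------------------------------------
  prior <- NULL
  if (!is.null(colorStorePath) && file.exists(colorStorePath)) {
    say("colors: appending to store ", colorStorePath)
    prior <- readColorStore(colorStorePath)
  }
  colors <- assignColors(clustering, ss, seed = seed, prior = prior)
  display <- applyGrayMode(clustering, colors,
                           mode = switch(grayMode, none = "none",
                                         unique = "gray_unique",
                                         shared = "gray_shared"))

  # --- order ------------------------------------------------------------
  ordering <- switch(sortMode,
    tree = {
      say("order: Bray-Curtis + UPGMA guide tree")
      upgmaOrder(brayCurtis(sharedSpacerMatrix(ss, clustering)),
                 sampleIds(ss))
    },
    list = {
      say("order: custom list ", listPath)
      withCallingHandlers(customOrder(ss, listPath),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    },
    input = inputOrder(ss))

  # --- render + artifacts ----------------------------------------------
  scene <- layoutScene(ss, ordering, display, opts)
  paths <- list(
    svg = file.path(outDir, "crispr_arrays.svg"),
    fasta = file.path(outDir, "spacers.fasta"),
    colors = file.path(outDir, "color_store.tsv"))
  writeSvg(scene, paths$svg)
  writeSpacerFasta(ss, paths$fasta)
  writeColorStore(colors, paths$colors)
  if (writeNewick && !is.null(guideTree(ordering))) {
    paths$newick <- file.path(outDir, "guide_tree.nwk")
    writeGuideTree(ordering, paths$newick)
  }
  if (writeClusters) {
    paths$clusters <- file.path(outDir, "clusters.tsv")
    writeClusterTable(clustering, paths$clusters)
  }
  say("render: wrote ", paths$svg)
  if (length(warns)) {
    say("---- manual inspection summary (", length(warns), " warnings) ----")
    for (w in warns) say("  * ", w)
  } else {
    say("no warnings")
  }
  invisible(list(spacerSet = ss, clustering = clustering, colors = colors,
                 ordering = ordering, scene = scene, paths = paths,
                 warnings = warns))
}
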
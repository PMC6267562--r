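#' Render options for the CRISPR array figure
#'
#' Geometry and display switches of the SVG output. Defaults (20-unit cells,
#' 2-unit gaps, 30-unit gap between locus columns) follow the proportions of
#' typical published CRISPR array figures; all of them are plain parameters.
#'
#' @param cell square edge length, SVG user units
#' @param gap spacing between cells within a locus
#' @param columnGap spacing between locus columns
#' @param rowGap vertical spacing between sample rows
#' @param margin canvas margin
#' @param showLengthLabels draw the spacer length (nt) over grayed cells --
#'   an exploratory aid for spotting loci that belong to different
#'   CRISPR-Cas systems
#' @param labelAllCells extend length labels to colored cells too
#' @param reverseColumns place locus 1 leftmost instead of rightmost
#' @param fontFamily,fontSize text style for sample names (fonts are
#'   referenced, not embedded; figures are meant for post-editing in a
#'   vector graphics editor)
#' @return list of class options, passed to [layoutScene()]
#' @export
renderOptions <- function(cell = 20, gap = 2, columnGap = 30, rowGap = 6,
                          margin = 10, showLengthLabels = FALSE,
                          labelAllCells = FALSE, reverseColumns = FALSE,
                          fontFamily = "Helvetica", fontSize = 11) {
  stopifnot(cell > 0, gap >= 0, columnGap >= 0, rowGap >= 0, margin >= 0)
  list(cell = cell, gap = gap, columnGap = columnGap, rowGap = rowGap,
       margin = margin, showLengthLabels = showLengthLabels,
       labelAllCells = labelAllCells, reverseColumns = reverseColumns,
       fontFamily = fontFamily, fontSize = fontSize)
}

#' Lay out the CRISPR array figure
#'
#' Computes the full scene geometry: one row per sample in display order,
#' one column per locus number present in the dataset with locus 1 as the
#' rightmost data column (older loci further left), each locus right-aligned
#' within its column so the conserved 3'-terminal spacers line up
#' vertically across strains, and the sample name at the rightmost end of
#' the row. Spacers run 5'->3' left to right within a locus. Samples lacking
#' a locus leave that column empty. When length labels are enabled the
#' spacer length is drawn over each grayed cell (or every cell with
#' `labelAllCells`).
#'
#' @param ss a \linkS4class{SpacerSet}
#' @param ordering a \linkS4class{StrainOrdering} covering every sample
#' @param display per-spacer colors from [applyGrayMode()]
#' @param opts options from [renderOptions()]
#' @return an \linkS4class{SvgScene}
#' @export
layoutScene <- function(ss, ordering, display, opts = renderOptions()) {
  df <- spacerInfo(ss)
  df$spacer_id <- spacerIds(ss)
  miss <- setdiff(df$spacer_id, display$spacer_id)
  if (length(miss)) stop("spacer without display color: ", miss[1])
  samples <- orderedSamples(ordering)
  if (!setequal(samples, sampleIds(ss)))
    stop("ordering does not cover the dataset's samples")
  j <- match(df$spacer_id, display$spacer_id)
  df$square <- display$square[j]
  df$diamond <- display$diamond[j]
  df$grayed <- display$grayed[j]

  lociNums <- sort(unique(df$locus_num), decreasing = !opts$reverseColumns)
  pitch <- opts$cell + opts$gap
  if (length(lociNums)) {
    # width of each locus column = widest locus with that number
    perLocus <- tapply(df$spacer_num, df$locus_num, max)
    colWidth <- setNames(as.numeric(perLocus[as.character(lociNums)]) * pitch -
                           opts$gap, lociNums)
    # left x of each column, in display order
    colLeft <- opts$margin + cumsum(c(0, head(unname(colWidth), -1) +
                                        opts$columnGap))
    names(colLeft) <- lociNums
    colRight <- colLeft + colWidth
  } else {
    colRight <- numeric(0)
  }

  cells <- vector("list", length(samples))
  labels <- data.frame(x = numeric(length(samples)),
                       y = numeric(length(samples)),
                       text = samples, stringsAsFactors = FALSE)
  rowPitch <- opts$cell + opts$rowGap
  for (r in seq_along(samples)) {
    y <- opts$margin + (r - 1) * rowPitch
    rows <- df[df$sample_id == samples[r], , drop = FALSE]
    if (nrow(rows)) {
      n <- ave(rows$spacer_num, rows$locus_num, FUN = max)
      right <- colRight[as.character(rows$locus_num)]
      x <- right - (n - rows$spacer_num + 1) * opts$cell -
        (n - rows$spacer_num) * opts$gap
      lab <- rep(NA_character_, nrow(rows))
      if (opts$showLengthLabels) {
        want <- if (opts$labelAllCells) rep(TRUE, nrow(rows)) else rows$grayed
        lab[want] <- as.character(rows$length[want])
      }
      cells[[r]] <- data.frame(spacer_id = rows$spacer_id, x = x, y = y,
                               size = opts$cell, square = rows$square,
                               diamond = rows$diamond, label = lab,
                               stringsAsFactors = FALSE)
    }
    labels$x[r] <- max(colRight) + opts$columnGap / 2
    labels$y[r] <- y + opts$cell / 2 + opts$fontSize * 0.35
  }
  cells <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
  if (is.null(cells))
    cells <- data.frame(spacer_id = character(0), x = numeric(0),
                        y = numeric(0), size = numeric(0),
                        square = character(0), diamond = character(0),
                        label = character(0), stringsAsFactors = FALSE)
  labelSpace <- if (nrow(labels))
    max(nchar(labels$text)) * opts$fontSize * 0.62 else 0
  width <- (if (length(colRight)) max(colRight) else opts$margin) +
    opts$columnGap / 2 + labelSpace + opts$margin
  height <- opts$margin * 2 +
    (if (length(samples)) length(samples) * rowPitch - opts$rowGap else 0)
  if (length(samples) == 0) labels <- labels[0, , drop = FALSE]
  new("SvgScene", cells = cells, labels = labels, width = width,
      height = height, opts = opts)
}

#' Write a scene to an SVG file
#'
#' Emits SVG 1.1: one `rect` per spacer square, one 4-vertex `polygon` per
#' diamond (vertices at the square's edge midpoints), and `text` elements
#' for labels. Element order and number formatting are fixed, so identical
#' scenes produce byte-identical files on any platform -- which also makes
#' the output friendly to version control and to manual editing in Inkscape
#' or Illustrator.
#'
#' @param scene an \linkS4class{SvgScene}
#' @param path output path
#' @return invisibly, `path`
#' @export
writeSvg <- function(scene, path) {
  opts <- scene@opts
  out <- c(sprintf('<?xml version="1.0" encoding="UTF-8"?>'),
           sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
                   fmtNum(scene@width), fmtNum(scene@height),
                   fmtNum(scene@width), fmtNum(scene@height)))
  cells <- scene@cells
  for (i in seq_len(nrow(cells))) {
    x <- cells$x[i]; y <- cells$y[i]; s <- cells$size[i]
    out <- c(out,
      sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#000" stroke-width="0.5"/>',
              fmtNum(x), fmtNum(y), fmtNum(s), fmtNum(s), cells$square[i]),
      sprintf('<polygon points="%s,%s %s,%s %s,%s %s,%s" fill="%s"/>',
              fmtNum(x + s / 2), fmtNum(y),
              fmtNum(x + s), fmtNum(y + s / 2),
              fmtNum(x + s / 2), fmtNum(y + s),
              fmtNum(x), fmtNum(y + s / 2), cells$diamond[i]))
    if (!is.na(cells$label[i]))
      out <- c(out,
        sprintf('<text x="%s" y="%s" font-family="%s" font-size="%s" text-anchor="middle" fill="#333">%s</text>',
                fmtNum(x + s / 2),
                fmtNum(y + s / 2 + opts$fontSize * 0.3),
                xmlEscape(opts$fontFamily), fmtNum(opts$fontSize * 0.8),
                xmlEscape(cells$label[i])))
  }
  lab <- scene@labels
  for (i in seq_len(nrow(lab)))
    out <- c(out,
      sprintf('<text x="%s" y="%s" font-family="%s" font-size="%s">%s</text>',
              fmtNum(lab$x[i]), fmtNum(lab$y[i]),
              xmlEscape(opts$fontFamily), fmtNum(opts$fontSize),
              xmlEscape(lab$text[i])))
  out <- c(out, "</svg>")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}
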
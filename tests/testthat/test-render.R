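colorEverything <- function(ss, seed = 4) {
  cl <- clusterSpacers(alignAllPairs(ss), spacerIds(ss))
  store <- assignColors(cl, ss, seed = seed)
  list(clustering = cl, store = store,
       display = applyGrayMode(cl, store, "none"))
}

test_that("loci are right-aligned: rightmost cells share x, short rows indent", {
  set.seed(81)
  ss <- makeSpacerSet(list(A = list(replicate(3, randDna(30))),
                           B = list(replicate(5, randDna(30)))))
  parts <- colorEverything(ss)
  sc <- layoutScene(ss, inputOrder(ss), parts$display)
  cells <- sc@cells
  cells$sample <- sub("\\|.*$", "", cells$spacer_id)
  rightA <- max(cells$x[cells$sample == "A"])
  rightB <- max(cells$x[cells$sample == "B"])
  expect_equal(rightA, rightB)
  # the 3-spacer row starts 2 cells further right
  opts <- sc@opts
  expect_equal(min(cells$x[cells$sample == "A"]) -
                 min(cells$x[cells$sample == "B"]),
               2 * (opts$cell + opts$gap))
  # 5'->3' left to right within the locus
  a <- cells[cells$sample == "A", ]
  expect_true(all(diff(a$x[order(as.integer(sub(".*spacer", "", a$spacer_id)))]) > 0))
})

test_that("shared 3'-terminal spacers share x position and colors across rows", {
  set.seed(82)
  tail3 <- randDna(30)
  ss <- makeSpacerSet(list(A = list(c(randDna(30), randDna(30), tail3)),
                           B = list(c(randDna(30), tail3))))
  parts <- colorEverything(ss)
  sc <- layoutScene(ss, inputOrder(ss), parts$display)
  cells <- sc@cells
  last <- cells[grepl("spacer3$", cells$spacer_id) & grepl("^A", cells$spacer_id) |
                grepl("spacer2$", cells$spacer_id) & grepl("^B", cells$spacer_id), ]
  expect_equal(length(unique(last$x)), 1)
  expect_equal(length(unique(last$square)), 1)
  expect_equal(length(unique(last$diamond)), 1)
})

test_that("locus 1 is the rightmost column and missing loci leave gaps", {
  set.seed(83)
  ss <- makeSpacerSet(list(A = list(replicate(3, randDna(30)),
                                    replicate(4, randDna(30))),
                           B = list(replicate(3, randDna(30)))))
  parts <- colorEverything(ss)
  sc <- layoutScene(ss, inputOrder(ss), parts$display)
  cells <- sc@cells
  locus <- as.integer(sub(".*\\|locus([0-9]+)\\|.*", "\\1", cells$spacer_id))
  expect_gt(min(cells$x[locus == 1]), max(cells$x[locus == 2]))
  # B has no locus 2: all its cells sit in the locus-1 column
  bcells <- cells[grepl("^B", cells$spacer_id), ]
  expect_true(all(bcells$x >= min(cells$x[locus == 1])))
  expect_equal(nrow(bcells), 3)
  # flag reverses the column order
  sc2 <- layoutScene(ss, inputOrder(ss), parts$display,
                     renderOptions(reverseColumns = TRUE))
  cells2 <- sc2@cells
  locus2 <- as.integer(sub(".*\\|locus([0-9]+)\\|.*", "\\1", cells2$spacer_id))
  expect_lt(min(cells2$x[locus2 == 1]), max(cells2$x[locus2 == 2]))
})

test_that("rows follow the strain ordering and labels sit right of the cells", {
  set.seed(84)
  ss <- makeSpacerSet(list(A = list(randDna(30)), B = list(randDna(30)),
                           C = list(randDna(30))))
  parts <- colorEverything(ss)
  ord <- new("StrainOrdering", orderedSamples = c("C", "A", "B"),
             tree = NULL, source = "custom")
  sc <- layoutScene(ss, ord, parts$display)
  expect_equal(sc@labels$text, c("C", "A", "B"))
  expect_true(all(diff(sc@labels$y) > 0))
  expect_true(all(sc@labels$x > max(sc@cells$x + sc@cells$size)))
})

test_that("length labels appear on grayed cells only, unless extended", {
  set.seed(85)
  a <- randDna(30)
  ss <- makeSpacerSet(list(A = list(c(a, a, randDna(33)))))
  cl <- clusterSpacers(alignAllPairs(ss), spacerIds(ss))
  store <- assignColors(cl, ss, seed = 4)
  disp <- applyGrayMode(cl, store, "gray_unique")
  sc <- layoutScene(ss, inputOrder(ss), disp,
                    renderOptions(showLengthLabels = TRUE))
  expect_equal(sum(!is.na(sc@cells$label)), 1)
  expect_equal(sc@cells$label[!is.na(sc@cells$label)], "33")
  scAll <- layoutScene(ss, inputOrder(ss), disp,
                       renderOptions(showLengthLabels = TRUE,
                                     labelAllCells = TRUE))
  expect_equal(sum(!is.na(scAll@cells$label)), 3)
})

test_that("every spacer gets exactly one cell; missing colors are an error", {
  set.seed(86)
  ss <- makeSpacerSet(list(A = list(replicate(4, randDna(30))),
                           B = list(replicate(6, randDna(30)))))
  parts <- colorEverything(ss)
  sc <- layoutScene(ss, inputOrder(ss), parts$display)
  expect_setequal(sc@cells$spacer_id, spacerIds(ss))
  expect_error(layoutScene(ss, inputOrder(ss), parts$display[-1, ]),
               "without display color")
})

test_that("SVG structure: one rect + polygon per cell, labels as text", {
  set.seed(87)
  ss <- makeSpacerSet(list(A = list(randDna(30))))
  parts <- colorEverything(ss)
  sc <- layoutScene(ss, inputOrder(ss), parts$display)
  path <- withr::local_tempfile(fileext = ".svg")
  writeSvg(sc, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:rect", ns), 1)
  expect_length(xml2::xml_find_all(doc, "//d1:polygon", ns), 1)
  expect_length(xml2::xml_find_all(doc, "//d1:text", ns), 1)
  # diamond vertices at the square's edge midpoints
  rect <- xml2::xml_find_first(doc, "//d1:rect", ns)
  x <- as.numeric(xml2::xml_attr(rect, "x"))
  y <- as.numeric(xml2::xml_attr(rect, "y"))
  s <- as.numeric(xml2::xml_attr(rect, "width"))
  pts <- xml2::xml_attr(xml2::xml_find_first(doc, "//d1:polygon", ns), "points")
  got <- do.call(rbind, lapply(strsplit(strsplit(pts, " ")[[1]], ","),
                               as.numeric))
  want <- rbind(c(x + s / 2, y), c(x + s, y + s / 2),
                c(x + s / 2, y + s), c(x, y + s / 2))
  expect_equal(got, want)
})

test_that("identical scenes write byte-identical SVG, matching the golden file", {
  ss <- makeSpacerSet(list(
    strainA = list(c("ACGTACGTACGTACGTACGTACGTACGTAC",
                     "TTGCATTGCATTGCATTGCATTGCATTGCA")),
    strainB = list(c("ACGTACGTACGTACGTACGTACGTACGTAC"))))
  cl <- clusterSpacers(alignAllPairs(ss), spacerIds(ss))
  store <- assignColors(cl, ss, seed = 123)
  disp <- applyGrayMode(cl, store, "gray_unique")
  sc <- layoutScene(ss, inputOrder(ss), disp,
                    renderOptions(showLengthLabels = TRUE))
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  writeSvg(sc, p1)
  writeSvg(sc, p2)
  expect_identical(readBin(p1, "raw", 1e6), readBin(p2, "raw", 1e6))
  golden <- test_path("golden-scene.svg")
  expect_identical(readLines(p1), readLines(golden))
})

test_that("an empty scene is still a well-formed SVG", {
  sc <- new("SvgScene",
            cells = data.frame(spacer_id = character(0), x = numeric(0),
                               y = numeric(0), size = numeric(0),
                               square = character(0), diamond = character(0),
                               label = character(0)),
            labels = data.frame(x = numeric(0), y = numeric(0),
                                text = character(0)),
            width = 20, height = 20, opts = renderOptions())
  path <- withr::local_tempfile(fileext = ".svg")
  writeSvg(sc, path)
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "svg")
  expect_length(xml2::xml_children(doc), 0)
})
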
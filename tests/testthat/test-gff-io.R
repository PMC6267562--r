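test_that("parsing maps repeat_region/binding_site structure onto loci and spacers", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "s1.gff3")
  writeLines(c(
    "##gff-version 3",
    "S1\tCRISPRDetect\trepeat_region\t100\t400\t.\t+\t.\tID=CRISPR1_S1",
    "S1\tCRISPRDetect\tbinding_site\t130\t159\t30\t+\t.\tID=sp1;Parent=CRISPR1_S1;Note=ACGTACGTACGTACGTACGTACGTACGTAC",
    "S1\tCRISPRDetect\tbinding_site\t190\t219\t30\t+\t.\tID=sp2;Parent=CRISPR1_S1;Note=TTTTACGTACGTACGTACGTACGTACGTAC",
    "S1\tCRISPRDetect\tbinding_site\t250\t279\t30\t+\t.\tID=sp3;Parent=CRISPR1_S1;Note=GGGGACGTACGTACGTACGTACGTACGTAC"
  ), gff)
  ss <- readCrisprGff(gff)
  df <- spacerInfo(ss)
  expect_equal(nSpacers(ss), 3)
  expect_equal(unique(df$locus_num), 1L)
  expect_equal(df$spacer_num, 1:3)
  expect_equal(df$sequence[1], "ACGTACGTACGTACGTACGTACGTACGTAC")
})

test_that("minus-strand spacers are reverse-complemented into array orientation", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "s1.gff3")
  writeLines(c(
    "##gff-version 3",
    "S1\tCRISPRDetect\trepeat_region\t100\t400\t.\t-\t.\tID=CRISPR1_S1",
    "S1\tCRISPRDetect\tbinding_site\t130\t135\t6\t-\t.\tID=sp1;Parent=CRISPR1_S1;Note=AAACCC"
  ), gff)
  ss <- readCrisprGff(gff)
  expect_equal(spacerInfo(ss)$sequence, "GGGTTT")
  expect_equal(spacerInfo(ss)$strand, "-")
})

test_that("minus-strand arrays are numbered 5'->3' (descending coordinates)", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "s1.gff3")
  writeLines(c(
    "##gff-version 3",
    "S1\tCRISPRDetect\trepeat_region\t100\t400\t.\t-\t.\tID=CRISPR1_S1",
    "S1\tCRISPRDetect\tbinding_site\t130\t135\t6\t-\t.\tID=sp1;Parent=CRISPR1_S1;Note=AAATTT",
    "S1\tCRISPRDetect\tbinding_site\t200\t205\t6\t-\t.\tID=sp2;Parent=CRISPR1_S1;Note=CCCGGG"
  ), gff)
  df <- spacerInfo(readCrisprGff(gff))
  # the downstream-most feature (higher start) is the array's first spacer
  expect_equal(df$start[df$spacer_num == 1], 200)
  expect_equal(df$start[df$spacer_num == 2], 130)
})

test_that("sequences can be sliced from a companion genome FASTA", {
  dir <- withr::local_tempdir()
  fx <- generateFixture(fixtureSpec(nSamples = 2, seed = 5),
                        file.path(dir, "fx"), writeGenome = TRUE)
  # strip the Note attributes so only coordinates remain
  for (g in fx$gff) {
    lines <- readLines(g)
    writeLines(sub(";Note=[ACGT]+$", "", lines), g)
  }
  expect_error(readCrisprGff(fx$gff), "no recoverable sequence")
  ss <- readCrisprGff(fx$gff, genome = fx$genome)
  expect_identical(spacerInfo(ss)$sequence,
                   spacerInfo(fx$simulation$spacerSet)$sequence)
})

test_that("fixture features are counted by the parser exactly (seed 1, 4x2x10)", {
  dir <- withr::local_tempdir()
  spec <- fixtureSpec(nSamples = 4, lociPerSample = c(2, 2),
                      spacersPerLocus = c(10, 10), seed = 1)
  fx <- generateFixture(spec, dir)
  # independent count: raw binding_site lines in the files
  nRaw <- sum(vapply(fx$gff, function(g)
    sum(grepl("\tbinding_site\t", readLines(g))), integer(1)))
  expect_equal(nRaw, 80L)
  expect_equal(nSpacers(readCrisprGff(fx$gff)), 80L)
})

test_that("malformed and degenerate GFF3 inputs produce named errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3", "S1\tonly\tthree"), bad)
  expect_error(readCrisprGff(bad), "bad\\.gff3:2")
  empty <- file.path(dir, "empty.gff3")
  writeLines("##gff-version 3", empty)
  expect_error(readCrisprGff(empty), "empty GFF3")
  noseq <- file.path(dir, "noseq.gff3")
  writeLines(c(
    "##gff-version 3",
    "S1\tsrc\trepeat_region\t100\t200\t.\t+\t.\tID=c1",
    "S1\tsrc\tbinding_site\t110\t120\t11\t+\t.\tID=sp1;Parent=c1"
  ), noseq)
  expect_error(readCrisprGff(noseq), "no recoverable sequence")
})

test_that("spacer FASTA round-trips every identity field and sequence", {
  set.seed(11)
  ss <- makeSpacerSet(list(
    A = list(replicate(4, randDna(30)), replicate(3, randDna(32))),
    B = list(replicate(5, randDna(29)))))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeSpacerFasta(ss, path)
  back <- readSpacerFasta(path)
  expect_identical(spacerInfo(back), spacerInfo(ss))
  expect_identical(sampleIds(back), sampleIds(ss))
  # header scheme: 7 pipe-delimited fields per record
  heads <- grep("^>", readLines(path), value = TRUE)
  expect_true(all(lengths(strsplit(heads, "|", fixed = TRUE)) == 7))
})

test_that("spacer FASTA reader rejects broken headers and duplicates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">S1|locus1|spacer1|1|6|6|+", "ACGTAC",
               ">S1|locus1|spacer1|10|15|6|+", "ACGTAC"), path)
  expect_error(readSpacerFasta(path), "duplicated spacer identity")
  writeLines(c(">S1|weird", "ACGTAC"), path)
  expect_error(readSpacerFasta(path), "header")
})

test_that("a hand-merged locus reads back as one concatenated locus", {
  set.seed(12)
  ss <- makeSpacerSet(list(A = list(replicate(3, randDna(30)),
                                    replicate(2, randDna(30)))))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeSpacerFasta(ss, path)
  lines <- readLines(path)
  # user merges locus 2 into locus 1 by renumbering the headers
  lines <- sub("^>A\\|locus2\\|spacer1\\|", ">A|locus1|spacer4|", lines)
  lines <- sub("^>A\\|locus2\\|spacer2\\|", ">A|locus1|spacer5|", lines)
  writeLines(lines, path)
  back <- readSpacerFasta(path)
  df <- spacerInfo(back)
  expect_equal(unique(df$locus_num), 1L)
  expect_equal(df$spacer_num, 1:5)
})

test_that("length outliers are flagged with strict boundaries", {
  # all equal -> nothing flagged
  ss <- makeSpacerSet(list(A = list(replicate(10, randDna(30)))))
  expect_equal(nrow(checkSpacerLengths(ss)), 0)
  # 9 x 30 nt + one 62 nt: mean 33.2, 1.5x = 49.8 < 62 -> exactly one flag
  ss <- makeSpacerSet(list(A = list(c(replicate(9, randDna(30)), randDna(62)))))
  flags <- checkSpacerLengths(ss)
  expect_equal(nrow(flags), 1)
  expect_equal(flags$length, 62)
  expect_equal(flags$mean_length, 33.2)
  # boundary: 5 x 30 + one 50 -> mean 100/3, 1.5x = 50 exactly -> no flag
  ss <- makeSpacerSet(list(A = list(c(replicate(5, randDna(30)), randDna(50)))))
  expect_equal(nrow(checkSpacerLengths(ss)), 0)
  # short side: strictly below mean/1.5 flags
  ss <- makeSpacerSet(list(A = list(c(replicate(9, randDna(33)), randDna(12)))))
  expect_equal(nrow(checkSpacerLengths(ss)), 1)
})

test_that("flag count is invariant under sample permutation", {
  set.seed(13)
  loci <- list(A = list(replicate(5, randDna(30))),
               B = list(c(replicate(4, randDna(30)), randDna(70))),
               C = list(replicate(6, randDna(31))))
  f1 <- checkSpacerLengths(makeSpacerSet(loci))
  f2 <- checkSpacerLengths(makeSpacerSet(loci[c(3, 1, 2)]))
  expect_equal(nrow(f1), nrow(f2))
  expect_setequal(f1$message, f2$message)
})

test_that("strand normalization holds for any generated fixture", {
  dir <- withr::local_tempdir()
  spec <- fixtureSpec(nSamples = 4, strandFlipProb = 0.5, seed = 21)
  fx <- generateFixture(spec, dir)
  ss <- readCrisprGff(fx$gff)
  expect_identical(spacerInfo(ss)$sequence,
                   spacerInfo(fx$simulation$spacerSet)$sequence)
  expect_true(any(spacerInfo(ss)$strand == "-"))
})
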
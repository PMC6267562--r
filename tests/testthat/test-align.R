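test_that("the adjusted mismatch formula and its preconditions hold", {
  expect_equal(adjustedMismatches(30, 30, 0, 0), 0L)
  expect_equal(adjustedMismatches(30, 30, 2, 0), 2L)
  # unaligned overhang counts as mismatch
  expect_equal(adjustedMismatches(32, 28, 0, 0), 4L)
  expect_error(adjustedMismatches(30, 10, 8, 4), "mismatches \\+ gaps")
  expect_error(adjustedMismatches(10, 20, 0, 2), "more query residues")
  expect_error(adjustedMismatches(-1, 0, 0, 0), ">= 0")
})

test_that("alignPair reports the optimal local alignment", {
  a <- "ACGTACGTACGTACGTACGTACGTACGTAC"
  r <- alignPair(a, a)
  expect_equal(r$alignment_length, 30)
  expect_equal(r$mismatches, 0)
  expect_equal(r$gaps, 0)
  expect_equal(r$adjusted, 0)
  set.seed(31)
  b <- substituteAt(a, 15)
  expect_equal(alignPair(a, b)$adjusted, 1)
  expect_error(alignPair("", a), "non-empty")
})

test_that("strands are not searched both ways", {
  set.seed(32)
  a <- randDna(30)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  expect_gt(alignPair(a, rc)$adjusted, 2)
})

test_that("aligner matches the exhaustive substring-enumeration oracle", {
  set.seed(33)
  for (i in 1:150) {
    a <- randDna(sample(5:14, 1), alphabet = c("A", "C", "G", "T", "N"))
    b <- randDna(sample(5:14, 1), alphabet = c("A", "C", "G", "T", "N"))
    x <- swAlign(a, b); y <- bruteAlign(a, b)
    expect_equal(x$score, y$score)
    expect_equal(x$matches, y$matches)
    expect_equal(x$gaps, y$gaps)
  }
  # spacer-sized sequences, related and unrelated
  for (i in 1:10) {
    a <- randDna(30)
    b <- if (i %% 2) randDna(30) else substituteAt(substituteAt(a, 5), 20)
    x <- swAlign(a, b); y <- bruteAlign(a, b)
    expect_equal(x$score, y$score)
    expect_equal(x$matches, y$matches)
  }
})

test_that("aligner score agrees with Biostrings local alignment", {
  mat <- matrix(-4L, 16, 16,
                dimnames = list(Biostrings::DNA_ALPHABET[1:16],
                                Biostrings::DNA_ALPHABET[1:16]))
  diag(mat)[1:4] <- 5L
  set.seed(34)
  for (i in 1:40) {
    a <- randDna(30); b <- randDna(30)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 12, gapExtension = 4)
    expect_equal(swAlign(a, b)$score, Biostrings::score(pa))
  }
})

test_that("Eq-style identity holds for every emitted pair similarity", {
  set.seed(35)
  ss <- makeSpacerSet(list(A = list(replicate(6, randDna(sample(28:36, 1)))),
                           B = list(replicate(5, randDna(sample(28:36, 1))))))
  pairs <- alignAllPairs(ss)
  lens <- setNames(spacerInfo(ss)$length, spacerIds(ss))
  expect_equal(pairs$adjusted1,
               unname(lens[pairs$id1]) -
                 (pairs$alignment_length - pairs$mismatches - pairs$gaps))
  expect_equal(pairs$adjusted2,
               unname(lens[pairs$id2]) -
                 (pairs$alignment_length - pairs$mismatches - pairs$gaps))
  expect_equal(pairs$adjusted, pmin(pairs$adjusted1, pairs$adjusted2))
  expect_true(all(pairs$alignment_length >= pairs$mismatches + pairs$gaps))
  expect_true(all(pairs$adjusted >= 0))
})

test_that("reduced pair score is symmetric in the two query directions", {
  set.seed(36)
  a <- randDna(30); b <- randDna(34)
  lab <- min(30, 34) - swAlign(a, b)$matches
  lba <- min(34, 30) - swAlign(b, a)$matches
  expect_equal(lab, lba)
})

test_that("all-vs-all links identical spacers and only near-identical pairs", {
  set.seed(37)
  a <- randDna(30)
  ss <- makeSpacerSet(list(A = list(c(a, a, a, a))))
  pairs <- alignAllPairs(ss)
  expect_equal(nrow(pairs), choose(4, 2))
  expect_true(all(pairs$adjusted == 0))
  # A, A with one substitution, unrelated: exactly one pair within cutoff 2
  b <- substituteAt(a, 12)
  ss <- makeSpacerSet(list(A = list(c(a, b, randDna(30)))))
  pairs <- alignAllPairs(ss)
  expect_equal(sum(pairs$adjusted <= 2), 1)
})

test_that("deduplication does not change all-vs-all results", {
  set.seed(38)
  base <- replicate(4, randDna(30))
  seqs <- setNames(c(base, base[c(1, 2)], substituteAt(base[1], 3)),
                   paste0("s", 1:7))
  fast <- alignAllPairs(seqs)
  # naive path: align every pair directly
  ids <- names(seqs)
  for (r in seq_len(nrow(fast))) {
    x <- seqs[[fast$id1[r]]]; y <- seqs[[fast$id2[r]]]
    direct <- swAlign(x, y)
    expect_equal(fast$score[r], direct$score)
    expect_equal(fast$adjusted[r],
                 min(nchar(x), nchar(y)) - direct$matches)
  }
})

test_that("extra substitutions never decrease the reduced adjusted score", {
  set.seed(39)
  for (rep in 1:25) {
    a <- randDna(30)
    b <- a
    positions <- sample(30, 6)
    prev <- 0
    for (p in positions) {
      b <- substituteAt(b, p)
      adj <- min(30, 30) - swAlign(a, b)$matches
      expect_gte(adj, prev)
      prev <- adj
    }
  }
})

test_that("fasta36 tabular hits map onto adjusted mismatch scores", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  # two hits (both directions) + a self hit that must be ignored
  writeLines(c(
    "sp1\tsp2\t93.33\t30\t2\t0\t1\t30\t1\t30\t1e-10\t50",
    "sp2\tsp1\t93.33\t30\t2\t0\t1\t30\t1\t30\t1e-10\t50",
    "sp1\tsp1\t100.00\t30\t0\t0\t1\t30\t1\t30\t1e-12\t60",
    "sp1\tsp3\t100.00\t25\t0\t0\t6\t30\t1\t25\t1e-8\t40"
  ), sep = "\n", tab)
  hits <- readFasta36Hits(tab, c(sp1 = 30L, sp2 = 30L, sp3 = 25L))
  expect_equal(nrow(hits), 2)
  h12 <- hits$adjusted[hits$id1 == "sp1" & hits$id2 == "sp2"]
  expect_equal(h12, 2L)  # 30 - (30 - 2 - 0)
  h13 <- hits$adjusted[hits$id1 == "sp1" & hits$id2 == "sp3"]
  expect_equal(h13, 5L)  # 25-nt perfect alignment, 5 nt overhang
})
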
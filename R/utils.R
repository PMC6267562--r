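# Locale-independent (C collation) sorting, so cluster ids and tie-breaks
# are identical across platforms.
cSort <- function(x) sort(x, method = "radix")

cMin <- function(x) cSort(x)[1]

spacerId <- function(sample_id, locus_num, spacer_num) {
  paste0(sample_id, "|locus", locus_num, "|spacer", spacer_num)
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run code with a temporarily seeded RNG, restoring global RNG state after.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Stable numeric formatting for SVG output: integers verbatim, otherwise two
# decimals with trailing zeros trimmed.
fmtNum <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, sprintf("%d", as.integer(round(x))),
         sub("\\.?0+$", "", sprintf("%.2f", x)))
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
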
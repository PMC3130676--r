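# Shared fixtures and small utilities for the suite. The gallery is built
# once per test run; synthetic networks are generated on demand.

.fixtures <- NULL
gallery <- function() {
  if (is.null(.fixtures)) .fixtures <<- fixture_gallery()
  .fixtures
}

# plain Rand index between two labelings (same names/order)
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

# write a tiny TSV (vectors of lines) to a temp file
tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# the three toy input files used by the parsing tests
toy_files <- function() {
  list(
    ppi = tmp_tsv(c("# toy PPI", "a1\tb1", "b1\tc1", "a1\tc1")),
    sim = tmp_tsv(c("P1\tP2\t0.9", "P1\tP3\t0.3")),
    assoc = tmp_tsv(c("P1\tA1", "P2\tB1")))
}

quiet_synth <- function(...) suppressWarnings(suppressMessages(
  synth_hetnet(synthetic_spec(...))))

# brute-force one-sided ("greater") Fisher p-value by hypergeometric
# tail summation; independent of stats::fisher.test
fisher_tail_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  sum(probs[xs >= a])
}
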
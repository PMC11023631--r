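# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (rle, dhyper) wherever they stand as a second
# route against an implementation.

# Character-by-character left-to-right maximal-run scanner.
brute_split <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bases <- character(0)
  lengths <- integer(0)
  starts <- integer(0)
  i <- 1L
  while (i <= length(ch)) {
    j <- i
    while (j < length(ch) && ch[j + 1L] == ch[i]) j <- j + 1L
    bases <- c(bases, ch[i])
    lengths <- c(lengths, j - i + 1L)
    starts <- c(starts, i)
    i <- j + 1L
  }
  data.frame(base = bases, start = starts, end = starts + lengths - 1L,
             length = lengths, stringsAsFactors = FALSE)
}

# Expected counts of maximal runs of each exact length 1..n over ALL 4^n
# sequences, weighted by prod(p) per sequence (exhaustive enumeration).
enum_expected_counts <- function(n, p = rep(0.25, 4)) {
  grid <- as.matrix(expand.grid(rep(list(1:4), n)))
  w <- apply(matrix(p[grid], nrow(grid)), 1L, prod)
  acc <- numeric(n)
  for (i in seq_len(nrow(grid))) {
    acc <- acc + w[i] * tabulate(rle(grid[i, ])$lengths, n)
  }
  acc / sum(w)
}

# Two-sided Fisher exact p-value by brute-force summation over all tables
# with the observed margins, using exact binomial coefficients (no dhyper).
fisher_oracle_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  if (m1 + m2 == 0) return(NA_real_)
  x <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, x) * choose(m2, k - x)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# A minimal Freebayes-dialect VCF writer for hand-built test records.
write_test_vcf <- function(lines, file = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=ctg,length=100000>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"alt obs\">",
    "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"ref obs\">",
    "##INFO=<ID=SAF,Number=A,Type=Integer,Description=\"alt fwd\">",
    "##INFO=<ID=SAR,Number=A,Type=Integer,Description=\"alt rev\">",
    "##INFO=<ID=SRF,Number=1,Type=Integer,Description=\"ref fwd\">",
    "##INFO=<ID=SRR,Number=1,Type=Integer,Description=\"ref rev\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t"))
  writeLines(c(hdr, lines), file)
  file
}
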
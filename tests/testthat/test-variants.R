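test_that("variant classification follows the SNV/MNV/indel contract", {
  expect_equal(classify_variant("A", "G"), "SNV")
  expect_equal(classify_variant("AT", "GC"), "MNV")
  expect_equal(classify_variant("A", "AA"), "indel")
  expect_equal(classify_variant("AAT", "A"), "indel")
  expect_equal(classify_variant(c("A", "AT"), c("T", "A")), c("SNV", "indel"))
  expect_error(classify_variant("", "A"), "empty")
})

test_that("Freebayes-style VCF records parse with per-allele counts", {
  f <- write_test_vcf(c(
    "ctg\t100\t.\tA\tG\t.\t.\tDP=10600;AO=32;RO=10568;SAF=15;SAR=17;SRF=5284;SRR=5284",
    "ctg\t200\t.\tC\tT,G\t.\t.\tDP=9000;AO=40,10;RO=8950;SAF=22,4;SAR=18,6;SRF=4475;SRR=4475"))
  rec <- parse_variants(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$freq[1], 32 / (32 + 10568))
  expect_equal(rec$alt[2:3], c("T", "G"))
  expect_equal(rec$ao[2:3], c(40L, 10L))
  expect_equal(rec$alt_fwd[2:3], c(22L, 4L))
  expect_equal(rec$ro[2:3], c(8950L, 8950L))
  expect_true(all(rec$has_strand))

  depth <- parse_variants(f, freq_mode = "depth")
  expect_equal(depth$freq[1], 32 / 10600)
})

test_that("records without strand counts are kept but flagged", {
  f <- write_test_vcf(c(
    "ctg\t10\t.\tA\tG\t.\t.\tDP=1000;AO=30;RO=970",
    "ctg\t20\t.\tC\tA\t.\t.\tDP=1000;AO=25;RO=975;SAF=12;SAR=13;SRF=490;SRR=485"))
  expect_warning(rec <- parse_variants(f), "strand")
  expect_equal(rec$has_strand, c(FALSE, TRUE))
  expect_warning(kept <- strand_balance_filter(rec, filter_config()), "untested")
  expect_equal(nrow(kept), 2L)  # untestable record survives strand filtering
})

test_that("an empty VCF body yields an empty record table, not an error", {
  f <- write_test_vcf(character(0))
  rec <- parse_variants(f)
  expect_equal(nrow(rec), 0L)
  expect_true(all(c("contig", "pos", "ref", "alt", "freq") %in% names(rec)))
})

test_that("frequency filter keeps records at or above the threshold", {
  rec <- data.frame(pos = 1:3, freq = c(0.0009, 0.001, 0.005), dp = 10000)
  kept <- frequency_filter(rec, filter_config(min_freq = 0.001))
  expect_equal(kept$pos, 2:3)  # 0.0009 removed, exact boundary 0.001 kept
  rem <- removed_variants(kept)
  expect_equal(rem$pos, 1L)
  expect_equal(rem$reason, "low_freq")
})

test_that("strand-balance Fisher test matches hand-checked cases", {
  # extreme imbalance against a balanced reference baseline: removed
  p_bad <- strand_fisher_p(20, 0, 5000, 5000)
  expect_lt(p_bad, 1e-4)
  # perfectly balanced: kept
  expect_gt(strand_fisher_p(16, 16, 5000, 5000), 0.99)
  # margins too small to detect imbalance: p = 1
  expect_equal(strand_fisher_p(1, 0, 1, 0), 1)
  # all-zero table is undefined
  expect_true(is.na(strand_fisher_p(0, 0, 0, 0)))

  rec <- data.frame(pos = 1:3, freq = 0.002, dp = 10100,
                    alt_fwd = c(20L, 16L, 1L), alt_rev = c(0L, 16L, 0L),
                    ref_fwd = c(5000L, 5000L, 1L), ref_rev = c(5000L, 5000L, 0L),
                    has_strand = TRUE)
  kept <- strand_balance_filter(rec, filter_config())
  expect_equal(kept$pos, 2:3)
  expect_equal(removed_variants(kept)$reason, "strand_bias")
})

test_that("the exact test agrees with brute-force summation and fisher.test", {
  set.seed(17)
  for (i in 1:80) {
    t <- as.integer(sample(0:12, 4, replace = TRUE))
    if (sum(t) == 0) next
    p <- strand_fisher_p(t[1], t[2], t[3], t[4])
    expect_equal(p, fisher_oracle_p(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
    expect_equal(p,
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("frequency and strand filters commute and account for every record", {
  g <- simulate_integrase_gene(seed = 21)
  sim <- simulate_variants(g, slippage_model(strand_bias_fraction = 0.25),
                           seed = 22)
  cfg <- filter_config()
  a <- suppressWarnings(strand_balance_filter(frequency_filter(sim$variants, cfg), cfg))
  b <- suppressWarnings(frequency_filter(strand_balance_filter(sim$variants, cfg), cfg))
  key <- function(d) sort(paste(d$pos, d$ref, d$alt))
  expect_equal(key(a), key(b))

  rem <- removed_variants(a)
  expect_equal(nrow(a) + nrow(rem), nrow(sim$variants))
  expect_true(all(table(c(paste(a$pos, a$alt), paste(rem$pos, rem$alt))) == 1))
})
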
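test_that("planted runs come out flank-guarded at exactly the stated length", {
  s <- generate_cds(300, planted_runs = data.frame(base = "A", length = 8,
                                                   start = 58),
                    seed = 12)
  r <- split_runs(s)
  hit <- r[r$start == 58 & r$base == "A", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length, 8L)
  expect_equal(hit$end, 65L)

  expect_identical(s, generate_cds(300, planted_runs = data.frame(
    base = "A", length = 8, start = 58), seed = 12))
  expect_false(identical(s, generate_cds(300, planted_runs = data.frame(
    base = "A", length = 8, start = 58), seed = 13)))

  expect_error(generate_cds(20, planted_runs = data.frame(
    base = c("A", "A"), length = c(4, 4), start = c(3, 8))), "overlap")
  expect_error(generate_cds(20, planted_runs = data.frame(
    base = "A", length = 30, start = 1)))
})

test_that("orf_mode produces a clean reading frame", {
  for (seed in 1:5) {
    g <- generate_cds(300, orf_mode = TRUE, seed = seed)
    expect_equal(substr(g, 1, 3), "ATG")
    expect_true(substr(g, 298, 300) %in% c("TAA", "TAG", "TGA"))
    internal <- substring(g, seq(4, 294, 3), seq(6, 296, 3))
    expect_false(any(internal %in% c("TAA", "TAG", "TGA")))
  }
  expect_error(generate_cds(100, orf_mode = TRUE), "divisible")
  expect_error(generate_cds(300, orf_mode = TRUE, planted_runs = data.frame(
    base = "A", length = 6, start = 2)), "start or stop")
})

test_that("the canonical integrase-like gene has the intIA hotspot layout", {
  g <- simulate_integrase_gene(seed = 4)
  r <- split_runs(g)
  long <- r[r$length >= 6, ]
  expect_equal(long$start, c(58L, 401L, 700L))
  expect_equal(long$length, c(8L, 7L, 6L))
  expect_equal(long$base, c("A", "T", "A"))
  expect_lte(max(r$length[r$start != 58 & r$start != 401 & r$start != 700]), 5L)
  expect_equal(substr(g, 1, 3), "ATG")
})

test_that("group panel policies enforce their run-length contracts", {
  mi <- generate_group_panel(10, length = 600, policy = "MI-like", seed = 51)
  expect_equal(unique(mi$group), "MI-like")
  expect_true(all(vapply(mi$seq, function(s) max(split_runs(s)$length),
                         numeric(1)) <= 5))

  sci <- generate_group_panel(10, length = 600, policy = "SCI-like", seed = 52)
  n_long <- sum(vapply(sci$seq, function(s) sum(split_runs(s)$length >= 7),
                       numeric(1)))
  expect_gte(n_long, 10)

  expect_identical(sci, generate_group_panel(10, length = 600,
                                             policy = "SCI-like", seed = 52))
  expect_false(anyDuplicated(rbind(sci, mi)$id) > 0)
})

test_that("unconstrained panels match the i.i.d. closed form", {
  panel <- generate_group_panel(300, length = 300, policy = "iid", seed = 61)
  sp <- pooled_spectrum(panel$seq)
  expected <- iid_expected_spectrum(rep(0.25, 4), 300) * 300
  # near-Poisson counts: compare where the expectation is appreciable
  check <- expected >= 20
  dev <- abs(sp$counts[check] - expected[check])
  expect_true(all(dev <= 5 * sqrt(expected[check])))
})

test_that("simulated variants follow the slippage model and its ground truth", {
  g <- simulate_integrase_gene(seed = 71)
  m <- slippage_model()
  expect_equal(slippage_rate(m, 1:3), pmin(1e-5 * 4^(0:2), 0.5))
  sim <- simulate_variants(g, m, seed = 72)
  expect_equal(nrow(sim$variants), nrow(sim$truth))
  expect_equal(sim$variants$pos, sim$truth$pos)
  expect_true(all(sim$variants$alt_fwd + sim$variants$alt_rev == sim$variants$ao))
  expect_true(all(sim$variants$ao >= 1))

  slips <- sim$truth$mechanism == "slippage"
  expect_true(all(!is.na(sim$truth$run_start[slips])))
  expect_true(all(is.na(sim$truth$run_start[!slips])))
  # the 8xA run carries the highest slippage rate, hence the top frequency
  i8 <- which(sim$truth$run_length == 8)
  expect_equal(sim$truth$run_start[i8], 58L)
  expect_equal(max(sim$variants$freq[slips]), sim$variants$freq[i8])

  expect_identical(simulate_variants(g, m, seed = 72)$variants, sim$variants)
})

test_that("planted strand-biased artifacts are caught by the strand filter", {
  g <- simulate_integrase_gene(seed = 81)
  m <- slippage_model(strand_bias_fraction = 1)  # every variant an artifact
  sim <- simulate_variants(g, m, seed = 82)
  expect_true(all(sim$variants$alt_fwd == 0 | sim$variants$alt_rev == 0))
  cfg <- filter_config()
  strong <- sim$variants[sim$variants$freq >= cfg$min_freq, , drop = FALSE]
  kept <- strand_balance_filter(strong, cfg)
  # every surviving record is individually non-significant by the exact test
  expect_true(all(kept$strand_p >= cfg$strand_alpha))
  # high-count artifacts (>= 30 reads on one strand) can never survive
  expect_true(all(kept$ao < 30))
})

test_that("simulated VCFs round-trip through the parser", {
  g <- simulate_integrase_gene(seed = 91)
  sim <- simulate_variants(g, slippage_model(), seed = 92)
  f <- tempfile(fileext = ".vcf")
  write_variants_vcf(sim$variants, f)
  back <- parse_variants(f)
  for (col in c("pos", "ref", "alt", "vtype", "ao", "ro", "alt_fwd",
                "alt_rev", "ref_fwd", "ref_rev", "dp")) {
    expect_equal(back[[col]], sim$variants[[col]], ignore_attr = TRUE)
  }
  expect_equal(back$freq, sim$variants$freq)
})
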
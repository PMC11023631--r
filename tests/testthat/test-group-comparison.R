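make_panel <- function(seqs, group, ids = NULL) {
  data.frame(id = ids %||% sprintf("%s_%d", group, seq_along(seqs)),
             seq = seqs, group = group, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group frequencies: observed side matches pooled spectra", {
  gf <- group_frequencies(make_panel("ATTTAACC", "solo"), n_reps = 20, seed = 1)
  expect_equal(gf$obs_freq[1:3], c(0.25, 0.5, 0.25))
  expect_equal(sum(gf$obs_freq), 1)
  expect_equal(sum(gf$theo_freq), 1)
})

test_that("homogeneous sequences have observed == theoretical exactly", {
  gf <- group_frequencies(make_panel(c("AAAA", "TTTTTT"), "mono"),
                          n_reps = 30, seed = 2)
  expect_equal(gf$obs_count, round(gf$theo_count))
  expect_equal(gf$obs_freq, gf$theo_freq)
})

test_that("unlabeled sequences are rejected with their ids", {
  p <- make_panel(c("ACGT", "GGTA"), "g")
  p$group[2] <- NA
  expect_error(group_frequencies(p), "g_2")
})

test_that("theoretical spectra do not depend on panel row order", {
  p <- make_panel(c("ACGGTTACCA", "TTGACCGTAA", "AGGGTCATCA"), "g")
  a <- group_frequencies(p, n_reps = 40, seed = 5)
  b <- group_frequencies(p[c(3, 1, 2), ], n_reps = 40, seed = 5)
  expect_equal(a$theo_count, b$theo_count)
})

test_that("enrichment ratios carry explicit status flags", {
  freqs <- data.frame(group = rep(c("A", "B"), each = 3),
                      length_bin = rep(1:3, 2),
                      obs_count = c(10, 0, 5, 10, 4, 0),
                      obs_freq = c(10, 0, 5, 10, 4, 0) / c(15, 15, 15, 14, 14, 14),
                      theo_count = rep(1, 6),
                      theo_freq = rep(1 / 3, 6))
  er <- enrichment_ratio(freqs, "A", "B")
  expect_equal(er$obs_status, c("finite", "zero_numerator",
                                "undefined_zero_denominator"))
  expect_true(is.infinite(er$obs_ratio[3]))
  expect_equal(er$theo_ratio, rep(1, 3))

  # self-comparison: every finite ratio is exactly 1
  self <- enrichment_ratio(freqs, "A", "A")
  expect_equal(self$obs_ratio[c(1, 3)], c(1, 1))
  expect_equal(self$obs_status[2], "undefined_zero_denominator")  # 0/0

  bad <- freqs[!(freqs$group == "B" & freqs$length_bin == 3), ]
  expect_error(enrichment_ratio(bad, "A", "B"), "mismatched")
  expect_error(enrichment_ratio(freqs, "A", "C"), "not found")
})

test_that("ratios are antisymmetric under group exchange", {
  set.seed(31)
  p <- rbind(generate_group_panel(5, length = 300, policy = "iid",
                                  seed = 71, group = "A"),
             generate_group_panel(5, length = 300, policy = "iid",
                                  seed = 72, group = "B"))
  gf <- group_frequencies(p, n_reps = 30, seed = 73)
  ab <- enrichment_ratio(gf, "A", "B")
  ba <- enrichment_ratio(gf, "B", "A")
  fin <- ab$obs_status == "finite" & ba$obs_status == "finite"
  expect_equal(ab$obs_ratio[fin], 1 / ba$obs_ratio[fin])
  fin_t <- ab$theo_status == "finite" & ba$theo_status == "finite"
  expect_equal(ab$theo_ratio[fin_t], 1 / ba$theo_ratio[fin_t])
})

test_that("same-composition panels give near-unity ratios at high-count bins", {
  p <- rbind(generate_group_panel(20, length = 500, policy = "iid",
                                  seed = 81, group = "A"),
             generate_group_panel(20, length = 500, policy = "iid",
                                  seed = 82, group = "B"))
  gf <- group_frequencies(p, n_reps = 30, seed = 83)
  er <- enrichment_ratio(gf, "A", "B")
  # bins with expected pooled count >= 100 are tightly concentrated
  expected <- iid_expected_spectrum(rep(0.25, 4), 500) * 20
  stable <- er$length_bin[expected >= 100]
  expect_true(all(er$obs_ratio[stable] > 0.8 & er$obs_ratio[stable] < 1.25))
  expect_true(all(er$theo_ratio[stable] > 0.9 & er$theo_ratio[stable] < 1.1))
})

test_that("pseudo-counts make undefined ratios finite (non-canonical mode)", {
  freqs <- data.frame(group = rep(c("A", "B"), each = 2),
                      length_bin = rep(1:2, 2),
                      obs_count = c(10, 2, 12, 0),
                      obs_freq = c(10, 2, 12, 0) / c(12, 12, 12, 12),
                      theo_count = c(9, 1, 11, 1),
                      theo_freq = c(9, 1, 11, 1) / c(10, 10, 12, 12))
  raw <- enrichment_ratio(freqs, "A", "B")
  expect_equal(raw$obs_status[2], "undefined_zero_denominator")
  pc <- enrichment_ratio(freqs, "A", "B", pseudocount = 1)
  expect_true(all(is.finite(pc$obs_ratio)))
})
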
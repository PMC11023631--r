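test_that("array normalization maps the envelope onto [0,1]", {
  ann <- array_annotation("s1", data.frame(start = 1000, end = 2000),
                          data.frame(start = 1500, end = 1600,
                                     orientation = "+"),
                          integrase_side = "left")
  m <- normalize_map(ann)
  expect_equal(m$is_elements$start, 0.5)
  expect_equal(m$is_elements$end, 0.6)
  expect_equal(m$parts$start, 0)
  expect_equal(m$parts$end, 1)
  expect_equal(m$is_elements$orientation, "+")
})

test_that("a right-hand integrase reflects coordinates and orientations", {
  ann <- array_annotation("s1", data.frame(start = 1000, end = 2000),
                          data.frame(start = 1500, end = 1600,
                                     orientation = "+"),
                          integrase_side = "right")
  m <- normalize_map(ann)
  expect_equal(m$is_elements$start, 0.4)
  expect_equal(m$is_elements$end, 0.5)
  expect_equal(m$is_elements$orientation, "-")
  # unknown orientation survives reflection as unknown
  ann2 <- array_annotation("s2", data.frame(start = 0, end = 10),
                           data.frame(start = 2, end = 4,
                                      orientation = "unknown"),
                           integrase_side = "right")
  expect_equal(normalize_map(ann2)$is_elements$orientation, "unknown")
})

test_that("integrase side can be derived from its coordinates", {
  a <- array_annotation("s", data.frame(start = 0, end = 1000),
                        integrase = c(10, 100))
  expect_equal(a$integrase_side, "left")
  b <- array_annotation("s", data.frame(start = 0, end = 1000),
                        integrase = c(900, 990))
  expect_equal(b$integrase_side, "right")
})

test_that("split arrays flag the interspace gap", {
  ann <- array_annotation("s1",
                          data.frame(start = c(0, 600), end = c(400, 1000)),
                          integrase_side = "left")
  m <- normalize_map(ann)
  expect_equal(m$gaps$start, 0.4)
  expect_equal(m$gaps$end, 0.6)
})

test_that("IS elements outside the envelope are rejected, listing offenders", {
  expect_error(
    array_annotation("s1", data.frame(start = 1000, end = 2000),
                     data.frame(start = 2500, end = 2600, orientation = "+"),
                     integrase_side = "left"),
    "\\[2500,2600\\]")
})

test_that("reflection is involutive and reverses interval order", {
  set.seed(91)
  for (i in 1:20) {
    starts <- sort(runif(4, 0, 0.9))
    ann <- array_annotation(
      "s", data.frame(start = 0, end = 1),
      data.frame(start = starts, end = starts + 0.05,
                 orientation = sample(c("+", "-", "unknown"), 4, TRUE)),
      integrase_side = "left")
    m <- normalize_map(ann)
    twice <- reflect_map(reflect_map(m))
    expect_lt(max(abs(twice$is_elements$start - m$is_elements$start)), 1e-12)
    expect_lt(max(abs(twice$is_elements$end - m$is_elements$end)), 1e-12)
    expect_equal(twice$is_elements$orientation, m$is_elements$orientation)
    refl <- reflect_map(m)
    expect_equal(order(refl$is_elements$start),
                 rev(order(m$is_elements$start)))
  }
})

test_that("inversion segments follow the inverted-repeat convention", {
  seg <- inversion_segment(list(start = 100, end = 200, orientation = "+"),
                           list(start = 900, end = 1000, orientation = "-"))
  expect_equal(seg$status, "inverted_repeat")
  expect_equal(seg$segment_start, 201)
  expect_equal(seg$segment_end, 899)
  expect_equal(seg$segment_length, 699)

  # argument order does not matter
  seg2 <- inversion_segment(list(start = 900, end = 1000, orientation = "-"),
                            list(start = 100, end = 200, orientation = "+"))
  expect_equal(seg2$segment_length, 699)

  expect_equal(inversion_segment(list(start = 1, end = 5, orientation = "+"),
                                 list(start = 10, end = 20, orientation = "+"))$status,
               "direct_repeat")
  expect_equal(inversion_segment(list(start = 1, end = 5, orientation = "unknown"),
                                 list(start = 10, end = 20, orientation = "-"))$status,
               "indeterminate")
  expect_error(inversion_segment(list(start = 1, end = 15, orientation = "+"),
                                 list(start = 10, end = 20, orientation = "-")),
               "overlap")
})

test_that("long-format array tables round-trip into annotations", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("strain\tfeature_type\tstart\tend\tstrand",
               "s1\tSCI_part\t1000\t2000\t+",
               "s1\tIS\t1500\t1600\t+",
               "s1\tintegrase\t900\t990\t+"), f)
  anns <- read_array_table(f)
  expect_equal(names(anns), "s1")
  expect_equal(anns$s1$integrase_side, "left")
  m <- normalize_map(anns$s1)
  expect_equal(m$is_elements$start, 0.5)
})
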
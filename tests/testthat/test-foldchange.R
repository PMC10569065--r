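test_that("the worked fold-change example matches the frozen hand computation", {
  # log10 a = {-1.0, -1.2, -0.8, -1.0}: mean -1.0, var 0.08/3
  # log10 b = {-2.3, -2.6, -2.5, -2.4}: mean -2.45, var 0.05/3
  # ratio = 10^1.45, se = sqrt((0.08/3 + 0.05/3)/4) = 0.1040833
  a <- 10^c(-1.0, -1.2, -0.8, -1.0)
  b <- 10^c(-2.3, -2.6, -2.5, -2.4)
  fc <- logFoldChange(a, b)
  # independent arithmetic from the stated formulas
  seHand <- sqrt((0.08 / 3 + 0.05 / 3) / 4)
  expect_equal(foldRatio(fc), 10^1.45, tolerance = 1e-12)
  expect_equal(foldSeLog10(fc), seHand, tolerance = 1e-12)
  expect_equal(foldInterval(fc), 10^1.45 * 10^c(-seHand, seHand),
               tolerance = 1e-12)
  # four-decimal frozen values
  expect_equal(round(foldRatio(fc), 4), 28.1838)
  expect_equal(round(foldSeLog10(fc), 4), 0.1041)
  expect_equal(round(foldInterval(fc), 4), c(22.1777, 35.8165))
  expect_equal(fc@tStat, 1.45 / seHand, tolerance = 1e-9)
  expect_equal(round(fc@tStat, 4), 13.9311)
  expect_lt(fc@pValue, 0.001)
  # Welch test cross-check against the reference implementation
  tt <- t.test(log10(a), log10(b))
  expect_equal(fc@tStat, unname(tt$statistic))
  expect_equal(fc@pValue, tt$p.value)
})

test_that("identical groups give a null estimate", {
  x <- c(0.2, 0.3, 0.25, 0.28)
  fc <- logFoldChange(x, x)
  expect_equal(foldRatio(fc), 1)
  expect_equal(fc@tStat, 0)
})

test_that("zero-variance arithmetic is exact", {
  fc <- logFoldChange(c(0.1, 0.1), c(0.01, 0.01))
  expect_equal(foldRatio(fc), 10)
  expect_equal(foldSeLog10(fc), 0)
  expect_equal(foldInterval(fc), c(10, 10))
})

test_that("fold changes are antisymmetric with a geometric interval", {
  set.seed(11)
  for (i in 1:10) {
    a <- 10^rnorm(4, -1, 0.3); b <- 10^rnorm(5, -2, 0.2)
    ab <- logFoldChange(a, b); ba <- logFoldChange(b, a)
    expect_equal(foldRatio(ab) * foldRatio(ba), 1, tolerance = 1e-12)
    expect_equal(ab@ciHigh / ab@ratio, ab@ratio / ab@ciLow,
                 tolerance = 1e-12)
    expect_true(ab@ciLow <= ab@ratio && ab@ratio <= ab@ciHigh)
  }
})

test_that("invalid replicate sets are rejected", {
  expect_error(logFoldChange(c(1, 2), c(3, -1)), "> 0")
  expect_error(logFoldChange(1, c(1, 2)), "at least 2")
})

test_that("the file interface round-trips a two-column TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(group = rep(c("wt", "mut"), each = 3),
                   efficiency = c(0.5, 0.4, 0.6, 0.01, 0.02, 0.015))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fc <- foldChangeFromFile(path)
  ref <- logFoldChange(df$efficiency[1:3], df$efficiency[4:6])
  expect_equal(foldRatio(fc), foldRatio(ref))
})
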
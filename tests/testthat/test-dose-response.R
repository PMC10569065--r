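test_that("predicted response hits its asymptotes and midpoint", {
  m <- doseResponseModel(Emin = 1, Emax = 109, K = 1.5, n = 1)
  expect_equal(predictResponse(m, 1.5), (1 + 109) / 2)
  expect_equal(predictResponse(m, 0), 1)
  expect_equal(predictResponse(m, 1e9 * 1.5), 109, tolerance = 1e-12)
  expect_equal(predictResponse(m, 1e-9 * 1.5), 1, tolerance = 1e-12)

  # independent erf evaluation at c = 15 (log10(c/K) = 1)
  skip_if_not_installed("pracma")
  expect_equal(predictResponse(m, 15), 1 + 108 * (1 + pracma::erf(1)) / 2)
  expect_equal(predictResponse(m, 15), 100.5058, tolerance = 1e-4)

  lit <- doseResponseModel(Emin = 5, Emax = 20, K = 1, convention = "literal")
  expect_equal(predictResponse(lit, 1), 5)       # literal: Y(K) = Emin
  expect_equal(predictResponse(lit, 0), -10)     # 2 Emin - Emax
  expect_equal(predictResponse(lit, 1e9), 20, tolerance = 1e-9)

  # monotone non-decreasing in c for both conventions
  cs <- 10^seq(-4, 4, length.out = 200)
  for (mm in list(m, lit))
    expect_true(all(diff(predictResponse(mm, cs)) >= 0))

  expect_error(doseResponseModel(10, 5, 1), "Emax")
  expect_error(doseResponseModel(1, 5, -1), "K")
})

test_that("noiseless data are refit to machine precision", {
  m <- doseResponseModel(Emin = 2, Emax = 80, K = 0.3, n = 1.2)
  d <- simulateDoseResponse(m, doseDesign(0.3), replicates = 1,
                            noiseCV = 0, seed = 1)
  f <- fitDoseResponse(d)
  expect_true(f@converged)
  expect_equal(fittedK(f), 0.3, tolerance = 1e-4)
  expect_equal(fittedEmax(f), 80, tolerance = 1e-4)
  expect_equal(fittedModel(f)@Emin, 2, tolerance = 1e-4)
  expect_equal(fittedModel(f)@n, 1.2, tolerance = 1e-4)
  expect_lt(f@rss, 1e-10)
  expect_equal(length(f@warnings), 0)

  # a zero-concentration row is pinned to the Emin limit, not dropped
  d0 <- rbind(data.frame(concentration_uM = 0, replicate = 1, value = 2), d)
  f0 <- fitDoseResponse(d0)
  expect_equal(fittedK(f0), 0.3, tolerance = 1e-4)
})

test_that("degenerate designs are rejected or flagged", {
  m <- doseResponseModel(1, 100, 0.5)
  few <- simulateDoseResponse(m, c(0.1, 0.5, 2), seed = 1)
  expect_error(fitDoseResponse(few), "4 distinct concentrations")

  # strictly rising data with no plateau: identifiability warning
  rising <- data.frame(concentration_uM = rep(c(0.01, 0.1, 1, 10), each = 2),
                       value = rep(c(1, 3, 10, 30), each = 2) * c(1, 1.02))
  fr <- fitDoseResponse(rising)
  expect_true(fr@converged)
  expect_gt(length(fr@warnings), 0)
})

test_that("halfmax and literal conventions are equivalent up to plateau remapping", {
  mh <- doseResponseModel(10, 100, 0.5)
  d <- simulateDoseResponse(mh, doseDesign(0.5), replicates = 1,
                            noiseCV = 0, seed = 3)
  fl <- fitDoseResponse(d, convention = "literal")
  expect_lt(fl@rss, 1e-8)
  expect_equal(fl@model@Emin, (10 + 100) / 2, tolerance = 1e-3)
  expect_equal(fl@model@Emax, 100, tolerance = 1e-3)
  expect_equal(fl@model@K, 0.5, tolerance = 1e-3)
})

test_that("K comparison propagates log-scale errors", {
  m <- doseResponseModel(1, 80, 1.5)
  d <- simulateDoseResponse(m, doseDesign(1.5), seed = 4)
  f <- fitDoseResponse(d)
  same <- compareK(f, f)
  expect_equal(same$ratio, 1)
  expect_equal(same$seLog10, sqrt(2) * seLog10K(f))

  # zero-SE arithmetic: ratio 5, degenerate CI
  fa <- f; fa@model@K <- 1.5; fa@se["log10K"] <- 0
  fb <- f; fb@model@K <- 0.3; fb@se["log10K"] <- 0
  cmp <- compareK(fa, fb)
  expect_equal(cmp$ratio, 5)
  expect_equal(cmp$ciLow, 5)
  expect_equal(cmp$ciHigh, 5)

  bad <- f; bad@converged <- FALSE
  expect_error(compareK(f, bad), "converged")
})

test_that("the ON-cell threshold fraction counts 10-fold-over-background cells", {
  expect_equal(thresholdFraction(rep(3, 10), background = 3), 0)
  expect_equal(thresholdFraction(rep(60, 4), background = 3), 1)
  expect_equal(thresholdFraction(c(5, 15, 20, 9, 11), background = 1), 0.6)
  expect_equal(thresholdFraction(c(5, 15, 20, 9, 11), background = 1,
                                 fold = 20), 0.2)
  expect_error(thresholdFraction(1:3, background = 0), "background")
})
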
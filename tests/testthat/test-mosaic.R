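test_that("congruence profile flags donor windows and spares the reference region", {
  sim <- smallMosaic(seed = 401)
  wts <- windowTreeSet(sim$alignment)
  prof <- congruenceProfile(wts, sim$speciesTree)
  p <- congruenceTable(prof)
  donorW <- p$start >= 1000 & p$end <= 3500
  speciesW <- p$end <= 1000 | p$start >= 3500
  expect_gt(mean(p$flagged[donorW]), 0.9)
  # flagged windows fall inside the donor segment +/- one window width
  expect_true(all(p$start[p$flagged] >= 1000 - 500 &
                    p$end[p$flagged] <= 3500 + 500))
  expect_lt(mean(p$flagged[speciesW & p$start < 500]), 0.2)

  # reference scored against itself: all zero scores, no flags
  ref <- sim$speciesTree
  wtsRef <- wts
  for (i in seq_along(wtsRef@trees)) wtsRef@trees[[i]] <- ref
  profRef <- congruenceProfile(wtsRef, ref)
  expect_true(all(congruenceTable(profRef)$kScore == 0))
  expect_false(any(congruenceTable(profRef)$flagged))

  expect_error(congruenceProfile(wts, ape::rtree(5)), "leaf set")
})

test_that("a homogeneous locus yields no flags and a single segment", {
  for (seed in c(402, 403)) {
    sim <- smallMosaic(seed = seed, donor = FALSE)
    res <- scanAlignment(sim$alignment, sim$speciesTree,
                         clusterRegion = FALSE)
    expect_equal(sum(congruenceTable(res$profile)$flagged), 0)
    expect_equal(sum(res$call$segments$status == "incongruent"), 0)
    expect_equal(length(res$call$breakpoints), 0)
  }
})

test_that("segmentation isolates a divergent middle block between identical flanks", {
  # constructed fixture: identical trees in two flank blocks, a
  # different tree in the middle block
  sp <- simulateSpeciesTree(8, seed = 404)
  part <- randomAllelePartition(sp$tip.label, seed = 405)
  dn <- deriveDonorTree(sp, part, 0.4)
  win <- makeWindows(1500, width = 100, step = 100)
  trees <- c(replicate(5, sp, simplify = FALSE),
             replicate(5, dn, simplify = FALSE),
             replicate(5, sp, simplify = FALSE))
  wts <- methods::new("WindowTreeSet", windows = win, trees = trees,
                      skipped = rep(FALSE, 15),
                      skipReason = rep("", 15),
                      leaves = sort(sp$tip.label))
  seg <- segmentWindows(windowSimilarityMatrix(wts))
  st <- segmentTable(seg)
  expect_equal(nrow(st), 3)
  expect_equal(st$startBp, c(0L, 500L, 1000L))
  expect_equal(st$endBp, c(500L, 1000L, 1500L))
})

test_that("mosaic calls find the donor segment, breakpoints and both alleles", {
  sim <- smallMosaic(seed = 406, nStrains = 16)
  res <- scanAlignment(sim$alignment, sim$speciesTree)
  regions <- res$call$regions
  expect_equal(sum(regions$status == "incongruent"), 1)
  bp <- res$call$breakpoints
  expect_equal(length(bp), 2)
  expect_lt(abs(bp[1] - 1000), 250)
  expect_lt(abs(bp[2] - 3500), 250)
  expect_equal(nAlleleClusters(res$alleles), 2)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(
    alleleClusters(res$alleles),
    sim$partition[names(alleleClusters(res$alleles))]), 1)
})

test_that("segment vote thresholds produce mixed status", {
  sim <- smallMosaic(seed = 407)
  wts <- windowTreeSet(sim$alignment)
  prof <- congruenceProfile(wts, sim$speciesTree)
  # force one segment covering everything: half flagged -> mixed
  prof@profile$flagged <- rep(c(TRUE, FALSE),
                              length.out = nrow(prof@profile))
  sm <- windowSimilarityMatrix(wts)
  seg <- methods::new("Segmentation",
                      segments = data.frame(
                        segment = 1L, firstWindow = 0L,
                        lastWindow = nrow(prof@profile) - 1L,
                        startBp = 0L, endBp = 4500L,
                        nWindows = nrow(prof@profile)),
                      breakpoints = numeric(0),
                      windowSegment = rep(1L, nrow(prof@profile)))
  call <- callMosaic(prof, seg)
  expect_equal(call$segments$status, "mixed")

  # all windows flagged: a single incongruent segment, no internal
  # breakpoints
  prof@profile$flagged <- rep(TRUE, nrow(prof@profile))
  call2 <- callMosaic(prof, seg)
  expect_equal(call2$segments$status, "incongruent")
  expect_equal(length(call2$breakpoints), 0)
})

test_that("allele clustering recovers the simulated partition and respects nulls", {
  skip_if_not_installed("mclust")
  for (seed in c(408, 409, 410)) {
    sim <- smallMosaic(seed = seed, nStrains = 16)
    al <- clusterAlleles(sim$alignment, c(1000, 3500))
    expect_equal(nAlleleClusters(al), 2)
    expect_equal(mclust::adjustedRandIndex(
      alleleClusters(al), sim$partition[names(alleleClusters(al))]), 1)
    # cluster 1 is the larger (or equal-size) one
    expect_gte(sum(alleleClusters(al) == 1), sum(alleleClusters(al) == 2))
  }
  # region simulated on the species tree only: one cluster
  simNull <- smallMosaic(seed = 411, donor = FALSE, nStrains = 16)
  expect_equal(nAlleleClusters(clusterAlleles(simNull$alignment,
                                              c(1000, 3500))), 1)
  # identical sequences: one cluster, zero heights
  flat <- rep("ACGT", 50)
  seqs <- structure(rep(paste(rep("ACGT", 50), collapse = ""), 5),
                    names = paste0("s", 1:5))
  alFlat <- clusterAlleles(seqs, c(0, 200))
  expect_equal(nAlleleClusters(alFlat), 1)
  expect_true(all(alFlat@heights == 0))
  expect_error(clusterAlleles(seqs, c(0, 50)), "shorter than")
})
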
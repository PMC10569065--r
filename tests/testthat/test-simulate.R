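test_that("species tree simulation yields binary trees with the requested depth", {
  tr <- simulateSpeciesTree(4, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 4)
  expect_true(all(tr$edge.length > 0))
  # unrooted interpretation of a rooted binary 4-leaf tree: 5 splits
  expect_equal(nrow(treeBipartitions(tr)), 5)

  tr2 <- simulateSpeciesTree(10, seed = 7, depth = 0.25)
  depths <- ape::node.depth.edgelength(tr2)[1:10]
  expect_equal(mean(depths), 0.25, tolerance = 1e-12)

  expect_identical(ape::write.tree(simulateSpeciesTree(8, seed = 42)),
                   ape::write.tree(simulateSpeciesTree(8, seed = 42)))
  expect_error(simulateSpeciesTree(3, seed = 1), ">= 4")
})

test_that("donor tree carries the A-vs-B split at the requested divergence", {
  sp <- simulateSpeciesTree(24, seed = 5)
  part <- randomAllelePartition(sp$tip.label, seed = 6)
  dn <- deriveDonorTree(sp, part, donorDivergence = 0.3)
  expect_setequal(dn$tip.label, sp$tip.label)
  bip <- treeBipartitions(dn)
  aSide <- paste(sort(names(part)[part == "A"]), collapse = ",")
  bSide <- paste(sort(names(part)[part == "B"]), collapse = ",")
  hit <- bip$side %in% c(aSide, bSide)
  expect_true(any(hit))
  expect_equal(bip$length[hit], 0.3, tolerance = 1e-9)
  # random partition is discordant with the species tree
  expect_gt(rfDistance(dn, sp), 0)

  # partition matching a species clade: that split contributes 0 to RF
  spl <- treeBipartitions(sp)
  internal <- spl[spl$internal & spl$length > 0, ]
  cladeLabs <- strsplit(internal$side[1], ",")[[1]]
  if (length(cladeLabs) < 2 || length(sp$tip.label) - length(cladeLabs) < 2)
    cladeLabs <- strsplit(internal$side[2], ",")[[1]]
  partC <- structure(ifelse(sp$tip.label %in% cladeLabs, "A", "B"),
                     names = sp$tip.label)
  dnC <- deriveDonorTree(sp, partC, donorDivergence = 0.3)
  keysC <- treeBipartitions(dnC)$side
  keysS <- treeBipartitions(sp)$side
  abKey <- internal$side[internal$side ==
                           paste(sort(cladeLabs), collapse = ",")]
  expect_true(abKey %in% keysC)   # the A|B split is shared, so its RF
  expect_true(abKey %in% keysS)   # contribution is zero

  single <- structure(rep("A", 24), names = sp$tip.label)
  expect_error(deriveDonorTree(sp, single, 0.3), "both alleles")
})

test_that("evolved alignments obey the Jukes-Cantor expectation and layout", {
  # two leaves at total path distance 0.3: expected p = 0.75(1 - e^-0.4)
  two <- ape::read.tree(text = "(x:0.15,y:0.15);")
  layout <- segmentLayout("seg", 10000, "species")
  aln <- evolveAlignment(two, two, layout, seed = 99)
  m <- mosaicscan:::alignmentToIntMatrix(aln)
  pObs <- mean(m[1, ] != m[2, ])
  pExp <- 0.75 * (1 - exp(-0.4))
  expect_equal(pExp, 0.24726, tolerance = 1e-4)
  se <- sqrt(pExp * (1 - pExp) / 10000)
  expect_lt(abs(pObs - pExp), 3 * se)

  # zero branch lengths: all sequences identical
  sp <- simulateSpeciesTree(5, seed = 3)
  sp0 <- sp; sp0$edge.length[] <- 0
  aln0 <- evolveAlignment(sp0, sp0, segmentLayout("s", 200, "species"),
                          seed = 4)
  expect_equal(length(unique(as.character(aln0))), 1)

  # length conservation and determinism
  lay <- segmentLayout(c("a", "b", "c"), c(1000, 2500, 1000),
                       c("species", "donor", "species"))
  part <- randomAllelePartition(sp$tip.label, seed = 8, nA = 2)
  dn <- deriveDonorTree(sp, part, 0.2)
  a1 <- evolveAlignment(sp, dn, lay, seed = 12)
  a2 <- evolveAlignment(sp, dn, lay, seed = 12)
  expect_equal(unique(Biostrings::width(a1)), 4500)
  expect_identical(as.character(a1), as.character(a2))
  expect_equal(S4Vectors::metadata(a1)$layout$end, c(1000L, 3500L, 4500L))

  mism <- sp; mism$tip.label[1] <- "zz"
  expect_error(evolveAlignment(sp, mism, lay, seed = 1), "leaf set")
})

test_that("dose-response simulation is unbiased, floored and reproducible", {
  m <- doseResponseModel(Emin = 1, Emax = 109, K = 1.5)
  conc <- doseDesign(1.5)
  noiseless <- simulateDoseResponse(m, conc, replicates = 2, noiseCV = 0,
                                    seed = 1)
  expect_equal(noiseless$value,
               rep(predictResponse(m, conc), each = 2))

  d1 <- simulateDoseResponse(m, conc, seed = 5)
  d2 <- simulateDoseResponse(m, conc, seed = 5)
  expect_identical(d1, d2)
  expect_true(all(d1$value >= 0))

  # CLT check: 1000 replicates at one concentration
  big <- simulateDoseResponse(m, 1.5, replicates = 1000, noiseCV = 0.1,
                              seed = 77)
  mu <- predictResponse(m, 1.5)
  expect_lt(abs(mean(big$value) - mu), 3 * 0.1 * mu / sqrt(1000))

  expect_error(simulateDoseResponse(m, conc, noiseCV = -0.1, seed = 1),
               "noiseCV")
  expect_error(simulateDoseResponse(m, rev(conc), seed = 1), "ascending")
})

test_that("efficiency simulation hits the requested geometric ratio", {
  g0 <- simulateEfficiencies(trueRatio = 30, log10SD = 0, nPerGroup = 4,
                             seed = 2)
  expect_equal(10^(mean(log10(g0$a)) - mean(log10(g0$b))), 30,
               tolerance = 1e-12)

  # null case with many replicates
  gNull <- simulateEfficiencies(trueRatio = 1, log10SD = 0.2,
                                nPerGroup = 200, seed = 3)
  expect_equal(foldRatio(logFoldChange(gNull$a, gNull$b)), 1,
               tolerance = 0.15)

  # median over simulations is near truth (geometric mean is unbiased
  # on the log scale)
  med <- stats::median(vapply(1:500, function(i) {
    g <- simulateEfficiencies(30, 0.2, 4, seed = 10000 + i)
    foldRatio(logFoldChange(g$a, g$b))
  }, numeric(1)))
  expect_equal(med, 30, tolerance = 0.1 * 30)

  expect_error(simulateEfficiencies(-2, seed = 1), "trueRatio")
  expect_identical(simulateEfficiencies(5, seed = 9),
                   simulateEfficiencies(5, seed = 9))
})
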
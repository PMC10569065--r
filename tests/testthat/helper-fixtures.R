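# Shared fixtures and independent oracles.

# quartet ((A,B),(C,D)) with all branches `len`
quartetTree <- function(len = 0.1, labels = c("A", "B", "C", "D")) {
  txt <- sprintf("((%s:%f,%s:%f):%f,%s:%f,%s:%f);",
                 labels[1], len, labels[2], len, len,
                 labels[3], len, labels[4], len)
  ape::read.tree(text = txt)
}

# random tree with positive branch lengths; cophenetic gives an additive
# distance matrix
randomAdditiveCase <- function(nTaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(nTaxa, br = function(n) stats::runif(n, 0.05, 0.5))
  tr$tip.label <- sprintf("t%02d", seq_len(nTaxa))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Oracle: grid search for the scale factor minimizing the branch-length
# score between K * comparison and reference, over the union of
# bipartitions (branch vectors shared with the implementation; the
# minimization itself is independent of the closed form).
gridSearchK <- function(reference, comparison, kMax = 5, step = 1e-4) {
  br <- mosaicscan:::bipartitionLengths(reference)
  bc <- mosaicscan:::bipartitionLengths(comparison)
  keys <- union(names(br), names(bc))
  r <- structure(numeric(length(keys)), names = keys); cc <- r
  r[names(br)] <- br; cc[names(bc)] <- bc
  ks <- seq(0, kMax, by = step)
  diff2 <- (outer(ks, cc) -
              matrix(r, length(ks), length(r), byrow = TRUE))^2
  score <- sqrt(rowSums(diff2))
  i <- which.min(score)
  list(k = ks[i], score = score[i])
}

# Oracle: least-squares branch lengths of a fixed topology for a
# distance matrix; X[pair, edge] = 1 iff the edge lies on the leaf path,
# derived from the edge bipartitions.
lsTopologyFit <- function(topology, d) {
  labs <- topology$tip.label
  d <- d[labs, labs]
  bip <- mosaicscan::treeBipartitions(topology)
  sides <- strsplit(bip$side, ",", fixed = TRUE)
  pairs <- t(utils::combn(length(labs), 2))
  X <- matrix(0, nrow(pairs), length(sides))
  for (e in seq_along(sides)) {
    inSide <- labs %in% sides[[e]]
    X[, e] <- xor(inSide[pairs[, 1]], inSide[pairs[, 2]])
  }
  dv <- d[pairs]
  fit <- stats::lm.fit(X, dv)
  list(rss = sum(fit$residuals^2), lengths = fit$coefficients)
}

# Oracle: exhaustive search over all unrooted topologies (via
# phangorn::allTrees), scoring each by least-squares RSS.
exhaustiveLsSearch <- function(d) {
  labs <- rownames(d)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  rss <- vapply(topos, function(tp) lsTopologyFit(tp, d)$rss, numeric(1))
  topos[[which.min(rss)]]
}

# topology-only RF (unit branch lengths so nothing is excluded)
topoRF <- function(t1, t2) {
  u <- function(t) { t$edge.length <- rep(1, nrow(t$edge)); t }
  mosaicscan::rfDistance(u(t1), u(t2))
}

# small mosaic simulation for unit tests (cheaper than the default)
smallMosaic <- function(seed, donor = TRUE, nStrains = 12,
                        donorDivergence = 0.3) {
  layout <- segmentLayout(
    name = c("left", "mid", "right"),
    length = c(1000, 2500, 1000),
    tree = c("species", if (donor) "donor" else "species", "species"))
  simulateMosaicAlignment(nStrains = nStrains,
                          donorDivergence = donorDivergence,
                          layout = layout, seed = seed)
}
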
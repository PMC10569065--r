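#' Simulate a species tree under a pure-birth process
#'
#' Draws a Yule (pure-birth) tree and rescales its branch lengths so that
#' the mean root-to-tip depth equals \code{depth} substitutions per site.
#' The returned tree is binary with positive branch lengths; leaves are
#' labeled \code{s01, s02, ...}.
#'
#' @param nLeaves number of leaves, \code{>= 4}.
#' @param seed integer RNG seed; the same seed reproduces the same tree.
#' @param depth target mean root-to-tip depth (substitutions/site,
#'   default 0.1).
#' @return an unrooted-interpretable \code{phylo} object (stored rooted,
#'   as drawn; all downstream comparisons are on unrooted bipartitions).
#' @export
#' @examples
#' tr <- simulateSpeciesTree(8, seed = 1)
simulateSpeciesTree <- function(nLeaves, seed, depth = 0.1) {
  stopIfNot(length(nLeaves) == 1 && nLeaves >= 4,
            "'nLeaves' must be a single integer >= 4")
  stopIfNot(depth > 0, "'depth' must be > 0")
  seed <- checkSeed(seed)
  tr <- withr::with_seed(seed, ape::rphylo(n = nLeaves, birth = 1, death = 0))
  tr$tip.label <- sprintf("s%02d", seq_len(nLeaves))
  d <- mean(rootToTipDepths(tr))
  tr$edge.length <- tr$edge.length * depth / d
  tr
}

#' @noRd
rootToTipDepths <- function(tree) {
  nt <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  depths[seq_len(nt)]
}

#' Build a donor tree with a deep two-allele split
#'
#' Constructs the tree followed by a horizontally transferred segment:
#' its deepest split separates the allele-A strains from the allele-B
#' strains regardless of species relationships, with the internal branch
#' carrying the full between-allele divergence. Within each allele group
#' the subtopology (and branch lengths) mirror the species tree restricted
#' to that group; alternatively each group can receive a fresh random
#' subtopology.
#'
#' @param speciesTree a \code{phylo} whose every leaf is labeled by
#'   \code{partition}.
#' @param partition named character vector (or factor) mapping every leaf
#'   label to \code{"A"} or \code{"B"}; both alleles must contain at least
#'   two strains.
#' @param donorDivergence branch length (subs/site) of the A-vs-B split,
#'   \code{> 0}.
#' @param withinGroup \code{"species"} (default: mirror the restricted
#'   species subtree) or \code{"random"} (fresh Yule subtopology per
#'   group, same mean depth; requires \code{seed}).
#' @param seed RNG seed, used only for \code{withinGroup = "random"}.
#' @return a \code{phylo} on the same leaf set whose bipartition set
#'   contains the A-vs-B split with length \code{donorDivergence}.
#' @export
deriveDonorTree <- function(speciesTree, partition,
                            donorDivergence,
                            withinGroup = c("species", "random"),
                            seed = NULL) {
  withinGroup <- match.arg(withinGroup)
  labs <- speciesTree$tip.label
  partition <- structure(as.character(partition), names = names(partition))
  stopIfNot(all(labs %in% names(partition)),
            "'partition' must label every leaf of 'speciesTree'")
  part <- partition[labs]
  stopIfNot(all(part %in% c("A", "B")),
            "allele labels must be \"A\" or \"B\"")
  nA <- sum(part == "A"); nB <- sum(part == "B")
  stopIfNot(nA >= 2 && nB >= 2,
            "both alleles must contain at least two strains")
  stopIfNot(donorDivergence > 0, "'donorDivergence' must be > 0")

  subTree <- function(group) {
    tips <- labs[part == group]
    if (withinGroup == "species") {
      ape::keep.tip(speciesTree, tips)
    } else {
      tr <- ape::rphylo(n = length(tips), birth = 1, death = 0)
      tr$tip.label <- sample(tips)
      target <- mean(rootToTipDepths(ape::keep.tip(speciesTree, tips)))
      if (target > 0)
        tr$edge.length <- tr$edge.length * target / mean(rootToTipDepths(tr))
      tr
    }
  }
  build <- function() {
    a <- subTree("A"); b <- subTree("B")
    nwk <- function(tr) sub(";\\s*$", "", ape::write.tree(tr))
    half <- donorDivergence / 2
    txt <- sprintf("(%s:%.10f,%s:%.10f);", nwk(a), half, nwk(b), half)
    ape::read.tree(text = txt)
  }
  if (withinGroup == "random") {
    stopIfNot(!is.null(seed), "'seed' is required for withinGroup = \"random\"")
    withr::with_seed(checkSeed(seed), build())
  } else {
    build()
  }
}

#' Split strains into two allele groups
#'
#' Convenience constructor of an allele partition: a random balanced
#' split of the leaf labels into alleles A and B (deterministic for a
#' fixed seed). Such a partition is generally discordant with the species
#' tree, emulating a donor lineage unrelated to the species phylogeny.
#'
#' @param labels character leaf labels (>= 4).
#' @param seed integer RNG seed.
#' @param nA size of allele group A (default: half, rounded down).
#' @return named character vector over \code{c("A", "B")}.
#' @export
randomAllelePartition <- function(labels, seed, nA = length(labels) %/% 2) {
  stopIfNot(length(labels) >= 4, "need at least 4 strains")
  stopIfNot(nA >= 2 && length(labels) - nA >= 2,
            "both alleles must contain at least two strains")
  seed <- checkSeed(seed)
  aSet <- withr::with_seed(seed, sample(labels, nA))
  structure(ifelse(labels %in% aSet, "A", "B"), names = labels)
}
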
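#' Segment layout of a simulated mosaic locus
#'
#' Orders the segments of the simulated locus and assigns each to the
#' tree it evolves along: \code{"species"} (vertical descent) or
#' \code{"donor"} (the horizontally transferred history).
#'
#' @param name unique segment names.
#' @param length segment lengths in bp, all \code{> 0}.
#' @param tree per segment, \code{"species"} or \code{"donor"}.
#' @return data.frame with columns \code{name}, \code{length},
#'   \code{tree}, \code{start}, \code{end} (0-based half-open).
#' @export
segmentLayout <- function(name, length, tree) {
  stopIfNot(length(name) == length(length) && length(name) == length(tree),
            "'name', 'length' and 'tree' must have equal length")
  stopIfNot(!anyDuplicated(name), "segment names must be unique")
  stopIfNot(all(length >= 1 & length == round(length)),
            "segment lengths must be positive integers")
  stopIfNot(all(tree %in% c("species", "donor")),
            "'tree' entries must be \"species\" or \"donor\"")
  end <- cumsum(length)
  data.frame(name = name, length = as.integer(length), tree = tree,
             start = as.integer(end - length), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Default layout of the simulated app-like operon
#'
#' Six segments emulating a peptide-permease operon plus its downstream
#' gene: appD (1000 bp), appF (900), appC (900), appA (1600), appB (900)
#' and yjbA (500), with appA + appB (2500 bp) evolving along the donor
#' tree and everything else along the species tree. Gene order and
#' lengths are illustrative defaults; any layout built with
#' [segmentLayout()] can be substituted.
#'
#' @return a segment layout data.frame (total length 5800 bp).
#' @export
defaultAppLayout <- function() {
  segmentLayout(
    name   = c("appD", "appF", "appC", "appA", "appB", "yjbA"),
    length = c(1000, 900, 900, 1600, 900, 500),
    tree   = c("species", "species", "species", "donor", "donor", "species")
  )
}

# Evolve L iid sites under Jukes-Cantor along a (rooted) phylo: the root
# sequence is uniform over {A,C,G,T}; along a branch of length t each
# site substitutes with probability (3/4)(1 - exp(-4t/3)), moving to one
# of the three alternative bases uniformly. Returns an integer matrix
# (tips x sites). Consumes the current RNG stream.
#' @noRd
evolveSegment <- function(tree, L) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  seqs <- matrix(NA_integer_, nrow = nn, ncol = L)
  po <- ape::reorder.phylo(tree, "postorder")
  root <- nt + 1L
  seqs[root, ] <- sample.int(4L, L, replace = TRUE)
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  lens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  for (i in seq_len(nrow(edges))) {
    parent <- edges[i, 1L]; child <- edges[i, 2L]
    p <- 0.75 * (1 - exp(-4 * lens[i] / 3))
    s <- seqs[parent, ]
    mut <- stats::runif(L) < p
    nmut <- sum(mut)
    if (nmut > 0)
      s[mut] <- ((s[mut] - 1L + sample.int(3L, nmut, replace = TRUE)) %% 4L) + 1L
    seqs[child, ] <- s
  }
  out <- seqs[seq_len(nt), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Evolve a mosaic alignment along discordant trees
#'
#' Simulates an aligned nucleotide locus segment by segment: each segment
#' evolves site-independently under the Jukes-Cantor model along either
#' the species tree or the donor tree, and segments are concatenated in
#' layout order. No indels are introduced, so the output is already
#' aligned.
#'
#' @param speciesTree,donorTree \code{phylo} objects on the same leaf set.
#' @param layout a segment layout from [segmentLayout()].
#' @param seed integer RNG seed; output is reproducible for a fixed seed.
#' @param rateScale multiplier applied to all branch lengths (default 1).
#' @return a \code{DNAStringSet} of equal-length gap-free sequences, one
#'   per leaf, with the layout attached as \code{metadata(x)$layout}.
#' @export
#' @examples
#' sp <- simulateSpeciesTree(6, seed = 1)
#' dn <- deriveDonorTree(sp, randomAllelePartition(sp$tip.label, seed = 2),
#'                       donorDivergence = 0.3)
#' aln <- evolveAlignment(sp, dn, defaultAppLayout(), seed = 3)
evolveAlignment <- function(speciesTree, donorTree, layout, seed,
                            rateScale = 1) {
  stopIfNot(setequal(speciesTree$tip.label, donorTree$tip.label),
            "species and donor trees must share one leaf set")
  stopIfNot(all(c("name", "length", "tree") %in% names(layout)) &&
              nrow(layout) >= 1,
            "'layout' must come from segmentLayout()")
  stopIfNot(rateScale > 0, "'rateScale' must be > 0")
  seed <- checkSeed(seed)
  labs <- speciesTree$tip.label
  trees <- list(species = speciesTree, donor = donorTree)
  if (rateScale != 1)
    trees <- lapply(trees, function(tr) {
      tr$edge.length <- tr$edge.length * rateScale; tr
    })
  mats <- withr::with_seed(seed, lapply(seq_len(nrow(layout)), function(i) {
    tr <- trees[[layout$tree[i]]]
    evolveSegment(tr, layout$length[i])[labs, , drop = FALSE]
  }))
  full <- do.call(cbind, mats)
  out <- Biostrings::DNAStringSet(intMatrixToStrings(full))
  names(out) <- labs
  S4Vectors::metadata(out)$layout <- segmentLayout(layout$name, layout$length,
                                                   layout$tree)
  out
}

#' Simulate the complete mosaic-locus study set
#'
#' One call generating everything the scan pipeline consumes, with ground
#' truth attached: a pure-birth species tree, a random two-allele
#' partition, the derived donor tree, and the mosaic alignment evolved
#' along them under the default layout.
#'
#' @param nStrains number of strains (default 24).
#' @param donorDivergence between-allele divergence in subs/site
#'   (default 0.3).
#' @param layout segment layout (default [defaultAppLayout()]); set every
#'   segment to \code{"species"} for a null, donor-free locus.
#' @param seed integer RNG seed.
#' @param depth mean root-to-tip depth of the species tree (default 0.1).
#' @return list with elements \code{alignment}, \code{speciesTree},
#'   \code{donorTree} (NULL if the layout has no donor segment),
#'   \code{partition}, \code{layout}.
#' @export
simulateMosaicAlignment <- function(nStrains = 24, donorDivergence = 0.3,
                                    layout = defaultAppLayout(), seed,
                                    depth = 0.1) {
  seed <- checkSeed(seed)
  nextSeed <- function(s) as.integer((as.numeric(s) + 1) %% 2147483647)
  sp <- simulateSpeciesTree(nStrains, seed = seed, depth = depth)
  part <- randomAllelePartition(sp$tip.label, seed = nextSeed(seed))
  dn <- NULL
  if (any(layout$tree == "donor"))
    dn <- deriveDonorTree(sp, part, donorDivergence)
  aln <- evolveAlignment(sp, if (is.null(dn)) sp else dn, layout,
                         seed = nextSeed(nextSeed(seed)))
  list(alignment = aln, speciesTree = sp, donorTree = dn,
       partition = part, layout = S4Vectors::metadata(aln)$layout)
}
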
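# Bipartition (split) extraction from unrooted trees. Every edge of a
# tree induces a split of the leaf set; splits are canonicalized by the
# side NOT containing the lexicographically first leaf label, and edges
# inducing the same split (the two root edges of a rooted binary tree)
# are aggregated by summing their lengths.

# Named numeric vector: canonical split key -> branch length. Keys join
# the sorted labels of the canonical side with "\r" (never in labels).
#' @noRd
bipartitionLengths <- function(tree) {
  labs <- tree$tip.label
  nt <- length(labs)
  first <- labs[order(labs)[1]]
  po <- ape::reorder.phylo(tree, "postorder")
  if (is.null(po$edge.length))  # topology-only tree: unit lengths
    po$edge.length <- rep(1, nrow(po$edge))
  nn <- nt + tree$Nnode
  inside <- matrix(FALSE, nn, nt)
  inside[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    inside[par, ] <- inside[par, ] | inside[ch, ]
  }
  firstIdx <- match(first, labs)
  keys <- character(nrow(po$edge))
  sizes <- integer(nrow(po$edge))
  for (k in seq_len(nrow(po$edge))) {
    side <- inside[po$edge[k, 2], ]
    if (side[firstIdx]) side <- !side
    keys[k] <- paste(sort(labs[side]), collapse = "\r")
    sizes[k] <- sum(side)
  }
  lens <- tapply(po$edge.length, keys, sum)
  out <- as.numeric(lens)
  names(out) <- names(lens)
  attr(out, "sizes") <- sizes[match(names(lens), keys)]
  attr(out, "nLeaves") <- nt
  out
}

#' Bipartitions (splits) of a tree
#'
#' One bipartition per edge of the unrooted interpretation of the tree:
#' terminal edges give singleton-vs-rest splits, internal edges give
#' internal splits. Splits are canonicalized by the side not containing
#' the lexicographically first leaf; edges inducing the same split (the
#' two root edges of a rooted binary tree) are merged with summed length.
#'
#' @param tree a \code{phylo}.
#' @return data.frame with columns \code{side} (comma-joined labels of
#'   the canonical side), \code{length}, \code{internal} (TRUE when both
#'   sides have >= 2 leaves).
#' @export
treeBipartitions <- function(tree) {
  b <- bipartitionLengths(tree)
  sizes <- attr(b, "sizes")
  nt <- attr(b, "nLeaves")
  data.frame(
    side = gsub("\r", ",", names(b), fixed = TRUE),
    length = as.numeric(b),
    internal = sizes >= 2 & (nt - sizes) >= 2,
    stringsAsFactors = FALSE
  )
}

# Internal split keys with positive length (zero-length internal edges
# are treated as unresolved / polytomies).
#' @noRd
internalSplitKeys <- function(b, tol = 0) {
  sizes <- attr(b, "sizes")
  nt <- attr(b, "nLeaves")
  internal <- sizes >= 2 & (nt - sizes) >= 2
  names(b)[internal & b > tol]
}

#' Robinson-Foulds distance between two trees
#'
#' The number of internal bipartitions present in exactly one of the two
#' trees. Internal branches of length zero are excluded (treated as
#' polytomies), so topologically collapsed resolutions are not counted.
#'
#' @param t1,t2 \code{phylo} objects on identical leaf sets.
#' @return a non-negative integer.
#' @export
rfDistance <- function(t1, t2) {
  stopIfNot(setequal(t1$tip.label, t2$tip.label),
            "trees must have identical leaf sets")
  s1 <- internalSplitKeys(bipartitionLengths(t1))
  s2 <- internalSplitKeys(bipartitionLengths(t2))
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
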
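#' K tree score between two trees
#'
#' Branch-length-aware tree comparison: the comparison tree is rescaled
#' by the factor K* that minimizes the squared branch-length difference
#' to the reference, and the score is the remaining root-sum-of-squares.
#' Branches are matched by bipartition (terminal branches by leaf label);
#' over the union of bipartitions, with missing branches given length 0,
#' \deqn{K^* = \sum b_c b_r / \sum b_c^2} (0 when the denominator is 0)
#' and \deqn{score = \sqrt{\sum (K^* b_c - b_r)^2}.}
#' The score is 0 iff the trees are identical up to a global scale; it is
#' asymmetric in its arguments (the comparison tree is the one rescaled)
#' and does not satisfy the triangle inequality.
#'
#' @param reference,comparison \code{phylo} objects on identical leaf
#'   sets (no pruning is attempted; a mismatch is an error).
#' @return list with elements \code{kFactor}, \code{kScore},
#'   \code{rfDistance} (zero-length-excluded internal splits, both
#'   directions), \code{nSharedBipartitions}, \code{nUniqueRef},
#'   \code{nUniqueComp}.
#' @export
#' @examples
#' t1 <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,C:0.1,D:0.1);")
#' kTreeScore(t1, t1)  # kFactor 1, kScore 0
kTreeScore <- function(reference, comparison) {
  stopIfNot(setequal(reference$tip.label, comparison$tip.label),
            "trees must have identical leaf sets")
  br <- bipartitionLengths(reference)
  bc <- bipartitionLengths(comparison)
  keys <- union(names(br), names(bc))
  r <- structure(numeric(length(keys)), names = keys)
  cc <- r
  r[names(br)] <- br
  cc[names(bc)] <- bc
  denom <- sum(cc^2)
  kFactor <- if (denom > 0) sum(cc * r) / denom else 0
  kScore <- sqrt(sum((kFactor * cc - r)^2))
  sr <- internalSplitKeys(br)
  sc <- internalSplitKeys(bc)
  list(
    kFactor = kFactor,
    kScore = kScore,
    rfDistance = length(setdiff(sr, sc)) + length(setdiff(sc, sr)),
    nSharedBipartitions = length(intersect(names(br), names(bc))),
    nUniqueRef = length(setdiff(names(br), names(bc))),
    nUniqueComp = length(setdiff(names(bc), names(br)))
  )
}
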
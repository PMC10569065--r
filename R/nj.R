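# Neighbor joining with a fully specified deterministic contract:
# Q-matrix criterion, exact ties broken by the lexicographically smallest
# pair of cluster labels (a cluster is labeled by its smallest leaf
# label), and negative branch-length estimates clamped to zero with a
# flag. This keeps window trees bit-reproducible across platforms.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining. At each step the pair
#' minimizing \code{Q(i,j) = (n-2) d(i,j) - r(i) - r(j)} is joined; exact
#' ties are broken by the lexicographically smallest label pair; negative
#' estimated branch lengths are clamped to 0 and recorded in the
#' \code{"clamped"} attribute of the result. The output is unrooted
#' (basal trifurcation).
#'
#' @param d a labeled symmetric numeric matrix of distances, or the list
#'   returned by [jcDistanceMatrix()]; at least 3 taxa.
#' @return a \code{phylo}; \code{attr(, "clamped")} is TRUE if any branch
#'   was clamped.
#' @export
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' njTree(d)$edge.length  # 0.05 0.15 0.25
njTree <- function(d) {
  if (is.list(d) && !is.matrix(d)) d <- d$d
  stopIfNot(is.matrix(d) && nrow(d) == ncol(d), "'d' must be square")
  n0 <- nrow(d)
  stopIfNot(n0 >= 3, "neighbor joining needs at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- sprintf("t%d", seq_len(n0))

  active <- seq_len(n0)          # node ids: tips 1..n0, internals n0+1..
  minlab <- labs                 # cluster label = smallest leaf label
  D <- d
  nextId <- n0 + 1L
  edges <- matrix(0, nrow = 2 * n0 - 3, ncol = 3)  # a, b, length
  ne <- 0L
  clamped <- FALSE
  addEdge <- function(a, b, len) {
    if (len < 0) { clamped <<- TRUE; len <- 0 }
    ne <<- ne + 1L
    edges[ne, ] <<- c(a, b, len)
  }

  while (length(active) > 3) {
    n <- length(active)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    minQ <- min(Q)
    cand <- which(Q == minQ & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      key1 <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
      key2 <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
      cand <- cand[order(key1, key2)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    addEdge(nextId, active[i], vi)
    addEdge(nextId, active[j], vj)
    dNew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    newlab <- min(minlab[c(i, j)])
    minlab <- c(minlab[keep], newlab)
    active <- c(active[keep], nextId)
    nextId <- nextId + 1L
  }

  # final three-point star
  center <- nextId
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  addEdge(center, active[1], v1)
  addEdge(center, active[2], v2)
  addEdge(center, active[3], v3)

  tree <- edgesToPhylo(edges[seq_len(ne), , drop = FALSE], nTips = n0,
                       tipLabels = labs, root = center)
  attr(tree, "clamped") <- clamped
  tree
}

# Build an ape phylo from an undirected edge list (a, b, length) on node
# ids where tips are 1..nTips; orients edges away from `root` and
# renumbers internal nodes in preorder starting at nTips + 1.
#' @noRd
edgesToPhylo <- function(edges, nTips, tipLabels, root) {
  nn <- max(edges[, 1:2])
  adj <- vector("list", nn)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, edges[k, 3]))
    adj[[b]] <- rbind(adj[[b]], c(a, edges[k, 3]))
  }
  newId <- integer(nn)
  newId[seq_len(nTips)] <- seq_len(nTips)
  nextInternal <- nTips + 1L
  edgeOut <- matrix(0L, nrow(edges), 2)
  lenOut <- numeric(nrow(edges))
  ne <- 0L
  # iterative preorder DFS: number internal nodes and record edges as
  # (parent, node) when each node is visited -> cladewise edge order
  stack <- list(c(root, 0, NA_real_))
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- cur[1]; parent <- cur[2]; plen <- cur[3]
    if (node > nTips) {
      newId[node] <- nextInternal
      nextInternal <- nextInternal + 1L
    }
    if (parent != 0) {
      ne <- ne + 1L
      edgeOut[ne, ] <- c(parent, node)  # original ids; remapped below
      lenOut[ne] <- plen
    }
    nb <- adj[[node]]
    if (is.null(nb)) next
    for (k in rev(seq_len(nrow(nb)))) {
      child <- nb[k, 1]
      if (child == parent) next
      stack[[length(stack) + 1]] <- c(child, node, nb[k, 2])
    }
  }
  edgeOut <- matrix(newId[edgeOut], ncol = 2)
  tree <- list(edge = edgeOut, edge.length = lenOut,
               tip.label = tipLabels,
               Nnode = as.integer(nextInternal - nTips - 1L))
  class(tree) <- "phylo"
  tree
}
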
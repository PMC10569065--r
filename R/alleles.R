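#' Cluster strains into alleles within an alignment region
#'
#' Builds a Jukes-Cantor distance matrix over the whole region (not
#' windowed: the allele statement is region-level, and whole-region
#' distances use the most data per strain pair), runs average-linkage
#' hierarchical clustering, and cuts the dendrogram below every
#' deep-split merge: scanning the merge heights from the top, a merge
#' counts as a deep split while it stands at least
#' \code{heightRatio} times higher than the next merge below it. One
#' cluster is returned when the deepest merge is not a deep split. The
#' ratio criterion is scale-free: it fires on a divergent-donor split
#' that towers over the within-group tree depth, but not on the graded
#' merge-height continuum a vertically inherited region produces.
#' Clusters are labeled by decreasing size (largest = 1).
#'
#' @param alignment a \code{DNAStringSet} or named character vector
#'   (>= 4 strains).
#' @param region length-2 numeric, 0-based half-open bp interval within
#'   the alignment.
#' @param minRegionWidth minimum region width in bp (default 100; shorter
#'   regions carry too little signal for a clustering claim).
#' @param heightRatio minimum ratio between successive top merge heights
#'   for a deep split (default 2).
#' @return an [AlleleAssignment-class]; \code{gapStatistic} holds the
#'   ratio of the two deepest merge heights.
#' @export
clusterAlleles <- function(alignment, region, minRegionWidth = 100,
                           heightRatio = 2) {
  m <- alignmentToIntMatrix(alignment)
  stopIfNot(nrow(m) >= 4, "need at least 4 strains")
  stopIfNot(length(region) == 2 && region[1] >= 0 &&
              region[2] <= ncol(m) && region[1] < region[2],
            "'region' must be a bp interval within the alignment")
  stopIfNot(region[2] - region[1] >= minRegionWidth,
            sprintf("region shorter than %d bp", minRegionWidth))
  sub <- m[, (region[1] + 1L):region[2], drop = FALSE]
  d <- jcDistanceMatrix(sub)$d
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  h <- hc$height
  nh <- length(h)
  nClusters <- 1L
  i <- nh
  while (i >= 1) {
    below <- if (i >= 2) h[i - 1] else 0
    deep <- h[i] > 0 && (below <= 0 || h[i] / below >= heightRatio)
    if (!deep) break
    nClusters <- nClusters + 1L
    i <- i - 1L
  }
  gapStat <- if (nh >= 2 && h[nh - 1] > 0) h[nh] / h[nh - 1]
             else if (h[nh] > 0) Inf else 0
  cl <- if (nClusters > 1) stats::cutree(hc, k = nClusters) else
    structure(rep(1L, nrow(m)), names = rownames(m))
  # relabel by decreasing cluster size (ties: first appearance)
  sizes <- table(cl)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- structure(seq_along(ord), names = names(sizes)[ord])
  clusters <- structure(as.integer(relabel[as.character(cl)]),
                        names = names(cl))
  methods::new("AlleleAssignment",
               region = as.numeric(region), clusters = clusters,
               nClusters = as.integer(nClusters), heights = h,
               gapStatistic = as.numeric(gapStat))
}

#' Write allele assignments as TSV
#'
#' @param alleles an [AlleleAssignment-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAlleleAssignment <- function(alleles, path) {
  df <- data.frame(strain = names(alleles@clusters),
                   cluster = as.integer(alleles@clusters))
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
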
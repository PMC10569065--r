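# Accessors for the S4 containers.

#' Window table of a scan object
#' @param x a [WindowTreeSet-class] or [SimilarityMatrix-class].
#' @return data.frame with columns index, start, end.
#' @export
scanWindows <- function(x) x@windows

#' Per-window trees
#' @param x a [WindowTreeSet-class].
#' @return list of \code{phylo} (NULL where skipped).
#' @export
windowTrees <- function(x) x@trees

#' Skip flags of a window tree set
#' @param x a [WindowTreeSet-class].
#' @return logical vector.
#' @export
skippedWindows <- function(x) x@skipped

#' Score matrix of a similarity object
#' @param x a [SimilarityMatrix-class].
#' @return numeric matrix (NA at masked windows).
#' @export
similarityScores <- function(x) x@scores

#' Per-window congruence table
#' @param x a [CongruenceProfile-class].
#' @return data.frame with kScore, rf, rfFraction, z, flagged per window.
#' @export
congruenceTable <- function(x) x@profile

#' Segment table of a segmentation
#' @param x a [Segmentation-class].
#' @return data.frame of segments.
#' @export
segmentTable <- function(x) x@segments

#' Breakpoints of a segmentation (bp)
#' @param x a [Segmentation-class].
#' @return numeric vector.
#' @export
segmentBreakpoints <- function(x) x@breakpoints

#' Cluster assignment of an allele clustering
#' @param x an [AlleleAssignment-class].
#' @return named integer vector (1 = largest cluster).
#' @export
alleleClusters <- function(x) x@clusters

#' Number of allele clusters
#' @param x an [AlleleAssignment-class].
#' @return integer.
#' @export
nAlleleClusters <- function(x) x@nClusters

#' Fold-change estimate fields
#' @param x a [FoldChangeEstimate-class].
#' @return \code{foldRatio}: the geometric-mean ratio;
#'   \code{foldInterval}: c(low, high) geometric +/- 1 SE bounds;
#'   \code{foldSeLog10}: the log10-scale SE.
#' @export
foldRatio <- function(x) x@ratio

#' @rdname foldRatio
#' @export
foldInterval <- function(x) c(x@ciLow, x@ciHigh)

#' @rdname foldRatio
#' @export
foldSeLog10 <- function(x) x@seLog10
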
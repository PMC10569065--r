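#' Full mosaic scan of an alignment against a reference tree
#'
#' Wires the whole pipeline: sliding-window neighbor-joining trees,
#' per-window congruence with the reference tree, the all-pairs K-score
#' similarity matrix, contiguity-constrained segmentation, segment status
#' calls with breakpoints, and allele clustering of the strains inside
#' the widest incongruent region (when one exists).
#'
#' @param alignment a \code{DNAStringSet} or named character vector.
#' @param referenceTree a \code{phylo} on the strain set (the species
#'   tree, e.g. from a core-genome alignment).
#' @param width,step window parameters in bp (defaults 500 / 50).
#' @param zThreshold,rfThresholdFraction incongruence thresholds (see
#'   [congruenceProfile()]).
#' @param maxSegments segmentation cap (see [segmentWindows()]).
#' @param clusterRegion if TRUE (default), cluster alleles inside the
#'   widest incongruent region.
#' @return list with \code{windows} ([WindowTreeSet-class]),
#'   \code{profile}, \code{similarity}, \code{segmentation}, \code{call}
#'   (see [callMosaic()]), and \code{alleles} (an
#'   [AlleleAssignment-class] or NULL).
#' @export
#' @examples
#' sim <- simulateMosaicAlignment(nStrains = 12, seed = 1)
#' res <- scanAlignment(sim$alignment, sim$speciesTree)
#' res$call$regions
scanAlignment <- function(alignment, referenceTree, width = 500, step = 50,
                          zThreshold = 2.0, rfThresholdFraction = 0.4,
                          maxSegments = 8, clusterRegion = TRUE) {
  wts <- windowTreeSet(alignment, width = width, step = step)
  prof <- congruenceProfile(wts, referenceTree, zThreshold = zThreshold,
                            rfThresholdFraction = rfThresholdFraction)
  sim <- windowSimilarityMatrix(wts)
  seg <- segmentWindows(sim, maxSegments = maxSegments)
  call <- callMosaic(prof, seg)
  alleles <- NULL
  inc <- call$regions[call$regions$status == "incongruent", , drop = FALSE]
  if (clusterRegion && nrow(inc) > 0) {
    widest <- inc[which.max(inc$endBp - inc$startBp), ]
    # a window overlapping the true boundary by any amount can be
    # flagged, so the called region overstates the transferred segment
    # by up to one window width per side; type alleles on the core
    region <- c(widest$startBp, widest$endBp)
    core <- c(region[1] + width, region[2] - width)
    if (core[2] - core[1] < 100) core <- region
    alleles <- clusterAlleles(alignment, core)
  }
  list(windows = wts, profile = prof, similarity = sim,
       segmentation = seg, call = call, alleles = alleles)
}

#' Write the scan report files
#'
#' Emits a TSV of segment calls (start_bp, end_bp, status, mean_z,
#' mean_rf), a TSV of allele assignments when present, and a JSON summary
#' (n_segments, n_incongruent_regions, breakpoints, n_clusters).
#'
#' @param scan the list returned by [scanAlignment()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix (default \code{"scan"}).
#' @return named character vector of the written paths, invisibly.
#' @export
writeScanReport <- function(scan, dir, prefix = "scan") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(segments = file.path(dir, paste0(prefix, "_segments.tsv")),
             summary = file.path(dir, paste0(prefix, "_summary.json")))
  segs <- scan$call$segments
  utils::write.table(
    data.frame(start_bp = segs$startBp, end_bp = segs$endBp,
               status = segs$status, mean_z = segs$meanZ,
               mean_rf = segs$meanRfFraction),
    file = paths[["segments"]], sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(scan$alleles)) {
    paths[["alleles"]] <- file.path(dir, paste0(prefix, "_alleles.tsv"))
    writeAlleleAssignment(scan$alleles, paths[["alleles"]])
  }
  summary <- list(
    n_segments = nrow(segs),
    n_incongruent_regions =
      sum(scan$call$regions$status == "incongruent"),
    breakpoints = scan$call$breakpoints,
    n_clusters = if (is.null(scan$alleles)) NA_integer_
                 else scan$alleles@nClusters
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}
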
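#' Contiguity-constrained segmentation of scan windows
#'
#' Groups adjacent windows into segments of shared phylogenetic history
#' by agglomerative merging on the window similarity matrix: every
#' non-skipped window starts as its own segment, and the adjacent pair
#' with the smallest mean between-segment K score is merged repeatedly.
#' Merging stops when the next merge's score exceeds
#' \code{mean + 2 SD} of all already-accepted merge scores (a jump in
#' dissimilarity marks a region boundary), or at a single segment; if
#' more than \code{maxSegments} remain at the stop, merging continues to
#' \code{maxSegments}.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param maxSegments maximum number of segments (default 8).
#' @return a [Segmentation-class]; breakpoints are the bp midpoints
#'   between the centers of the windows flanking each segment boundary.
#' @export
segmentWindows <- function(sim, maxSegments = 8) {
  ok <- which(!sim@mask)
  stopIfNot(length(ok) >= 1, "all windows are skipped")
  S <- sim@scores[ok, ok, drop = FALSE]
  nw <- length(ok)
  segs <- as.list(seq_len(nw))          # contiguous runs of ok-indices
  accepted <- numeric(0)

  betweenScore <- function(a, b) mean(S[segs[[a]], segs[[b]], drop = FALSE])

  while (length(segs) > 1) {
    ns <- length(segs)
    scores <- vapply(seq_len(ns - 1), function(i) betweenScore(i, i + 1),
                     numeric(1))
    i <- which.min(scores)
    nextScore <- scores[i]
    if (ns <= maxSegments && length(accepted) >= 2) {
      lim <- mean(accepted) + 2 * stats::sd(accepted) +
        1e-9 * max(S, na.rm = TRUE)
      if (nextScore > lim) break
    }
    segs[[i]] <- c(segs[[i]], segs[[i + 1]])
    segs[[i + 1]] <- NULL
    accepted <- c(accepted, nextScore)
  }

  win <- sim@windows
  firstW <- vapply(segs, function(s) ok[min(s)], integer(1))
  lastW <- vapply(segs, function(s) ok[max(s)], integer(1))
  segDf <- data.frame(
    segment = seq_along(segs),
    firstWindow = win$index[firstW],
    lastWindow = win$index[lastW],
    startBp = win$start[firstW],
    endBp = win$end[lastW],
    nWindows = vapply(segs, length, integer(1))
  )
  center <- function(w) (win$start[w] + win$end[w]) / 2
  bp <- numeric(0)
  if (length(segs) > 1)
    bp <- vapply(seq_len(length(segs) - 1), function(i) {
      (center(lastW[i]) + center(firstW[i + 1])) / 2
    }, numeric(1))
  wseg <- rep(NA_integer_, nrow(win))
  for (i in seq_along(segs)) wseg[ok[segs[[i]]]] <- i
  methods::new("Segmentation", segments = segDf, breakpoints = bp,
               windowSegment = wseg)
}

#' Call congruent / incongruent / mixed status per segment
#'
#' Combines the per-window incongruence flags with a segmentation: a
#' segment is \code{incongruent} when more than
#' \code{incongruentFraction} of its windows are flagged,
#' \code{congruent} when fewer than \code{congruentFraction} are, and
#' \code{mixed} otherwise (an intermediate phylogeny, e.g. a segment
#' containing a recombination transition). An incongruent call must
#' additionally be supported by a run of at least \code{minRun}
#' consecutive flagged windows (isolated flagged windows are noise, not
#' a transferred segment). Adjacent segments of equal status are merged
#' into maximal regions.
#'
#' Breakpoints are reported where the per-window flags transition
#' between unflagged and flagged around each supported flagged run: each
#' breakpoint is the bp midpoint between the centers of the two adjacent
#' windows of different status.
#'
#' @param profile a [CongruenceProfile-class].
#' @param seg a [Segmentation-class] over the same windows.
#' @param incongruentFraction,congruentFraction window-vote thresholds
#'   (defaults 0.8 / 0.2).
#' @param minRun minimum number of consecutive flagged windows
#'   supporting an incongruent call (default 3).
#' @return list with \code{segments} (data.frame: segment, status,
#'   fractionFlagged, startBp, endBp, meanZ, meanRfFraction),
#'   \code{regions} (maximal same-status runs with startBp/endBp), and
#'   \code{breakpoints} (bp positions of flag transitions flanking the
#'   supported flagged runs).
#' @export
callMosaic <- function(profile, seg, incongruentFraction = 0.8,
                       congruentFraction = 0.2, minRun = 3) {
  prof <- profile@profile
  stopIfNot(nrow(prof) == length(seg@windowSegment),
            "profile and segmentation cover different windows")
  okIdx <- which(!prof$skipped)
  flags <- prof$flagged[okIdx]
  # maximal flagged runs of length >= minRun (over non-skipped windows)
  runsF <- rle(flags)
  hiF <- cumsum(runsF$lengths)
  loF <- hiF - runsF$lengths + 1
  supported <- which(runsF$values & runsF$lengths >= minRun)
  supportedWindows <- integer(0)
  for (r in supported)
    supportedWindows <- c(supportedWindows, okIdx[loF[r]:hiF[r]])

  segDf <- seg@segments
  ns <- nrow(segDf)
  frac <- meanZ <- meanRf <- numeric(ns)
  hasSupport <- logical(ns)
  for (i in seq_len(ns)) {
    w <- which(seg@windowSegment == i)
    frac[i] <- mean(prof$flagged[w])
    meanZ[i] <- mean(prof$z[w][is.finite(prof$z[w])])
    meanRf[i] <- mean(prof$rfFraction[w])
    hasSupport[i] <- any(w %in% supportedWindows)
  }
  status <- ifelse(frac > incongruentFraction & hasSupport, "incongruent",
                   ifelse(frac < congruentFraction, "congruent", "mixed"))
  segments <- data.frame(
    segment = segDf$segment, status = status, fractionFlagged = frac,
    startBp = segDf$startBp, endBp = segDf$endBp,
    meanZ = meanZ, meanRfFraction = meanRf
  )
  # breakpoints at flag transitions flanking each supported run
  center <- (prof$start + prof$end) / 2
  bp <- numeric(0)
  for (r in supported) {
    if (loF[r] > 1) {
      a <- okIdx[loF[r] - 1]; b <- okIdx[loF[r]]
      bp <- c(bp, (center[a] + center[b]) / 2)
    }
    if (hiF[r] < length(okIdx)) {
      a <- okIdx[hiF[r]]; b <- okIdx[hiF[r] + 1]
      bp <- c(bp, (center[a] + center[b]) / 2)
    }
  }
  # maximal runs of equal segment status
  runs <- rle(status)
  hi <- cumsum(runs$lengths)
  lo <- hi - runs$lengths + 1
  regions <- data.frame(
    region = seq_along(runs$values), status = runs$values,
    startBp = segDf$startBp[lo], endBp = segDf$endBp[hi],
    nSegments = runs$lengths
  )
  list(segments = segments, regions = regions, breakpoints = sort(bp))
}
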
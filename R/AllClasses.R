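#' @import methods
NULL

#' Erf dose-response model of peptide import
#'
#' Parameters of the error-function dose-response curve used to describe
#' reporter expression as a function of signalling-peptide concentration:
#' an expression floor \code{Emin}, a plateau \code{Emax}, a half-maximal
#' concentration \code{K} (uM) and a log10-scale width \code{n}.
#'
#' Two conventions are supported. Under \code{"halfmax"} (default) the
#' response is \deqn{Y = Emin + (Emax - Emin) (1 + erf(log10(c/K)/n))/2,}
#' so that \code{Y(K)} is the midpoint between floor and plateau, matching
#' the meaning of a half-maximal concentration. Under \code{"literal"} the
#' curve is \deqn{Y = Emin + (Emax - Emin) erf(log10(c/K)/n),} in which the
#' floor is reached only as c -> 0 through negative erf values
#' (\code{Y(0) = 2 Emin - Emax}) and \code{Y(K) = Emin}.
#'
#' @slot Emin numeric expression floor (AU), \code{>= 0}.
#' @slot Emax numeric expression plateau (AU), \code{>= Emin}.
#' @slot K numeric half-maximal concentration (uM), \code{> 0}.
#' @slot n numeric log10 width (dimensionless), \code{> 0}.
#' @slot convention \code{"halfmax"} or \code{"literal"}.
#'
#' @seealso [doseResponseModel()], [predictResponse()], [fitDoseResponse()]
#' @exportClass DoseResponseModel
setClass("DoseResponseModel",
  representation(
    Emin = "numeric", Emax = "numeric", K = "numeric", n = "numeric",
    convention = "character"
  )
)

setValidity("DoseResponseModel", function(object) {
  msg <- character()
  if (length(object@Emin) != 1 || !is.finite(object@Emin) || object@Emin < 0)
    msg <- c(msg, "'Emin' must be a single finite value >= 0")
  if (length(object@Emax) != 1 || !is.finite(object@Emax) ||
      object@Emax < object@Emin)
    msg <- c(msg, "'Emax' must be a single finite value >= Emin")
  if (length(object@K) != 1 || !is.finite(object@K) || object@K <= 0)
    msg <- c(msg, "'K' must be a single finite value > 0")
  if (length(object@n) != 1 || !is.finite(object@n) || object@n <= 0)
    msg <- c(msg, "'n' must be a single finite value > 0")
  if (length(object@convention) != 1 ||
      !object@convention %in% c("halfmax", "literal"))
    msg <- c(msg, "'convention' must be \"halfmax\" or \"literal\"")
  if (length(msg)) msg else TRUE
})

#' Result of a dose-response fit
#'
#' Holds the fitted [DoseResponseModel-class], per-parameter standard
#' errors (on the optimized scale for K and n: \code{log10K} and
#' \code{logn}), the residual sum of squares over per-concentration means,
#' a convergence flag and identifiability warnings.
#'
#' @slot model the fitted [DoseResponseModel-class].
#' @slot se named numeric standard errors:
#'   \code{Emin}, \code{dE} (= Emax - Emin), \code{log10K}, \code{logn}.
#' @slot rss residual sum of squares at the optimum.
#' @slot converged logical.
#' @slot warnings character vector of identifiability flags (may be empty).
#' @slot data the per-concentration means the fit used (data.frame with
#'   columns \code{concentration_uM}, \code{mean}).
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  representation(
    model = "DoseResponseModel", se = "numeric", rss = "numeric",
    converged = "logical", warnings = "character", data = "data.frame"
  )
)

#' Geometric-mean fold change with logarithmic standard error
#'
#' The ratio of geometric means of two replicate sets, its standard error
#' on the log10 scale, the geometric +/- 1 SE interval
#' (\code{ratio * 10^(+/- seLog10)}), and a Welch t-test on the log10
#' values.
#'
#' @slot ratio geometric-mean ratio (group a over group b), \code{> 0}.
#' @slot seLog10 standard error of \code{log10(ratio)}.
#' @slot ciLow,ciHigh geometric bounds \code{ratio / 10^seLog10} and
#'   \code{ratio * 10^seLog10}.
#' @slot tStat,pValue Welch t statistic and two-sided p-value on log10
#'   replicates.
#' @slot n1,n2 replicate counts.
#' @exportClass FoldChangeEstimate
setClass("FoldChangeEstimate",
  representation(
    ratio = "numeric", seLog10 = "numeric", ciLow = "numeric",
    ciHigh = "numeric", tStat = "numeric", pValue = "numeric",
    n1 = "integer", n2 = "integer"
  )
)

setValidity("FoldChangeEstimate", function(object) {
  msg <- character()
  if (object@ratio <= 0) msg <- c(msg, "'ratio' must be > 0")
  if (object@seLog10 < 0) msg <- c(msg, "'seLog10' must be >= 0")
  if (!(object@ciLow <= object@ratio && object@ratio <= object@ciHigh))
    msg <- c(msg, "interval must bracket the ratio")
  if (length(msg)) msg else TRUE
})

#' Per-window neighbor-joining trees over a sliding scan
#'
#' One tree per alignment window (or a skip flag with a reason, e.g. too
#' few comparable sites for some pair), plus the window table itself.
#'
#' @slot windows data.frame with columns \code{index}, \code{start},
#'   \code{end} (0-based half-open alignment coordinates).
#' @slot trees list of \code{phylo} objects, \code{NULL} where skipped.
#' @slot skipped logical, one per window.
#' @slot skipReason character, "" where not skipped.
#' @slot leaves common leaf label set of all trees.
#' @exportClass WindowTreeSet
setClass("WindowTreeSet",
  representation(
    windows = "data.frame", trees = "list", skipped = "logical",
    skipReason = "character", leaves = "character"
  )
)

setValidity("WindowTreeSet", function(object) {
  n <- nrow(object@windows)
  if (length(object@trees) != n || length(object@skipped) != n ||
      length(object@skipReason) != n)
    return("one tree (or skip flag) is required per window")
  TRUE
})

#' All-pairs window tree similarity (K tree score) matrix
#'
#' Square matrix of symmetrized K tree scores between window trees, the
#' object behind a window-by-window similarity heatmap. Entry (i, j) is
#' the mean of the score with window i as reference and with window j as
#' reference; the diagonal is zero; skipped windows are masked with NA.
#'
#' @slot scores numeric matrix, one row/column per window.
#' @slot windows the window table (as in [WindowTreeSet-class]).
#' @slot mask logical; TRUE where the window was skipped.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(scores = "matrix", windows = "data.frame", mask = "logical")
)

#' Per-window congruence with a reference tree
#'
#' For every non-skipped window: the K tree score and Robinson-Foulds
#' distance to the reference tree, a robust z-score of the K score
#' (median/MAD over all windows), and an incongruence flag. A window is
#' flagged when both the branch-length signal (robust z above
#' \code{zThreshold}) and the topological signal (RF distance above
#' \code{rfThresholdFraction} of its maximum \code{2(n-3)}) fire.
#'
#' @slot profile data.frame with columns \code{index}, \code{start},
#'   \code{end}, \code{kScore}, \code{rf}, \code{rfFraction}, \code{z},
#'   \code{flagged}.
#' @slot zThreshold,rfThresholdFraction the thresholds used.
#' @exportClass CongruenceProfile
setClass("CongruenceProfile",
  representation(
    profile = "data.frame", zThreshold = "numeric",
    rfThresholdFraction = "numeric"
  )
)

#' Contiguous segmentation of scan windows
#'
#' Ordered, non-overlapping runs of adjacent windows produced by
#' contiguity-constrained agglomerative merging of the window similarity
#' matrix, with breakpoint positions (bp) between adjacent segments.
#'
#' @slot segments data.frame with columns \code{segment}, \code{firstWindow},
#'   \code{lastWindow}, \code{startBp}, \code{endBp}, \code{nWindows}.
#' @slot breakpoints numeric bp positions between adjacent segments
#'   (midpoints between flanking window centers).
#' @slot windowSegment integer segment id per non-skipped window.
#' @exportClass Segmentation
setClass("Segmentation",
  representation(
    segments = "data.frame", breakpoints = "numeric",
    windowSegment = "integer"
  )
)

#' Allele clusters of strains within an alignment region
#'
#' @slot region numeric length-2 bp interval (0-based half-open).
#' @slot clusters named integer cluster index per strain (1 = largest).
#' @slot nClusters integer.
#' @slot heights merge heights of the underlying average-linkage tree.
#' @slot gapStatistic ratio of the two deepest merge heights (the
#'   deep-split cut criterion).
#' @exportClass AlleleAssignment
setClass("AlleleAssignment",
  representation(
    region = "numeric", clusters = "integer", nClusters = "integer",
    heights = "numeric", gapStatistic = "numeric"
  )
)

setValidity("AlleleAssignment", function(object) {
  if (object@nClusters < 1L) return("'nClusters' must be >= 1")
  if (is.null(names(object@clusters))) return("'clusters' must be named")
  TRUE
})
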
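#' Per-window congruence with a reference tree
#'
#' Scores every non-skipped window tree against a reference (species)
#' tree with the K tree score and the Robinson-Foulds distance, converts
#' the K scores to robust z-scores against a congruent baseline, and
#' flags a window as incongruent when both signals fire: robust
#' z above \code{zThreshold} AND normalized RF
#' (\code{rf / (2 (n - 3))}) above \code{rfThresholdFraction}. Requiring
#' both a branch-length and a topological signal avoids flagging windows
#' that merely evolve faster or slower under the same history.
#'
#' The baseline location and scale are estimated by quantile matching on
#' the lower tail of the K-score distribution (the 5th and 25th
#' percentiles, mapped to their standard-normal positions). Because the
#' K score is anchored at zero for windows agreeing with the reference,
#' the congruent windows form the lowest part of the distribution; the
#' lower-tail estimator stays uncontaminated even when a transferred
#' segment covers close to half of the scanned windows (a whole-operon
#' transfer easily does), where a median/MAD baseline over all windows
#' would absorb the incongruent mode. Under a homogeneous locus the
#' estimator matches the full distribution, keeping the nominal meaning
#' of the z threshold.
#'
#' @param wts a [WindowTreeSet-class].
#' @param reference a \code{phylo} sharing the leaf set of the windows.
#' @param zThreshold robust z cutoff (default 2.0).
#' @param rfThresholdFraction normalized RF cutoff in `[0, 1]`
#'   (default 0.4).
#' @return a [CongruenceProfile-class].
#' @export
congruenceProfile <- function(wts, reference, zThreshold = 2.0,
                              rfThresholdFraction = 0.4) {
  stopIfNot(setequal(reference$tip.label, wts@leaves),
            "reference tree must share the window leaf set")
  n <- length(wts@leaves)
  ok <- !wts@skipped
  k <- rep(NA_real_, length(ok))
  rf <- rep(NA_integer_, length(ok))
  for (i in which(ok)) {
    cmp <- kTreeScore(reference, wts@trees[[i]])
    k[i] <- cmp$kScore
    rf[i] <- cmp$rfDistance
  }
  q <- stats::quantile(k[ok], c(0.05, 0.25), names = FALSE)
  sigma <- (q[2] - q[1]) / (stats::qnorm(0.25) - stats::qnorm(0.05))
  mu <- q[2] - stats::qnorm(0.25) * sigma
  z <- rep(NA_real_, length(ok))
  if (sigma > 0) {
    z[ok] <- (k[ok] - mu) / sigma
  } else {
    z[ok] <- ifelse(k[ok] > mu, Inf, 0)
  }
  rfFrac <- rf / (2 * (n - 3))
  flagged <- !is.na(z) & z > zThreshold & rfFrac > rfThresholdFraction
  prof <- data.frame(
    index = wts@windows$index, start = wts@windows$start,
    end = wts@windows$end, kScore = k, rf = rf, rfFraction = rfFrac,
    z = z, skipped = wts@skipped, flagged = flagged
  )
  methods::new("CongruenceProfile", profile = prof,
               zThreshold = zThreshold,
               rfThresholdFraction = rfThresholdFraction)
}
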
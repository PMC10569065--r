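#' Geometric-mean fold change with logarithmic standard error
#'
#' The fold change of group a over group b as the ratio of geometric
#' means, \code{ratio = 10^(mean(log10 a) - mean(log10 b))}, with its
#' standard error on the log10 scale,
#' \code{seLog10 = sqrt(s_a^2/n_a + s_b^2/n_b)} (s = sample SD of the
#' log10 values), the geometric +/- 1 SE interval
#' \code{ratio 10^(+/- seLog10)}, and a Welch two-sided t-test on the
#' log10 replicates. Suited to ratio-scale quantities such as
#' sporulation efficiencies, whose replicate noise is multiplicative.
#'
#' @param a,b numeric vectors of positive values, each of length
#'   \code{>= 2}.
#' @return a [FoldChangeEstimate-class].
#' @export
#' @examples
#' logFoldChange(c(0.1, 0.08, 0.12), c(0.004, 0.003, 0.005))
logFoldChange <- function(a, b) {
  stopIfNot(length(a) >= 2 && length(b) >= 2,
            "both groups need at least 2 replicates")
  stopIfNot(all(a > 0) && all(b > 0), "all values must be > 0")
  la <- log10(a); lb <- log10(b)
  ratio <- 10^(mean(la) - mean(lb))
  se <- sqrt(stats::var(la) / length(la) + stats::var(lb) / length(lb))
  if (se > 0) {
    tt <- stats::t.test(la, lb, var.equal = FALSE)
    tStat <- unname(tt$statistic); pValue <- tt$p.value
  } else {
    # degenerate zero-variance groups: t is 0 (equal means) or +/- Inf
    delta <- mean(la) - mean(lb)
    tStat <- if (delta == 0) 0 else sign(delta) * Inf
    pValue <- if (delta == 0) 1 else 0
  }
  methods::new("FoldChangeEstimate",
               ratio = ratio, seLog10 = se,
               ciLow = ratio / 10^se, ciHigh = ratio * 10^se,
               tStat = tStat, pValue = pValue,
               n1 = length(a), n2 = length(b))
}

#' Read a two-column group/efficiency TSV and compute the fold change
#'
#' The file must have a header and two columns: group (exactly two
#' levels; the first level in file order is the numerator) and
#' efficiency.
#'
#' @param path TSV path.
#' @return a [FoldChangeEstimate-class].
#' @export
foldChangeFromFile <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopIfNot(ncol(df) >= 2, "expected columns: group, efficiency")
  groups <- unique(df[[1]])
  stopIfNot(length(groups) == 2, "expected exactly two groups")
  logFoldChange(df[[2]][df[[1]] == groups[1]],
                df[[2]][df[[1]] == groups[2]])
}
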
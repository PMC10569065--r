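#' Simulate replicate dose-response measurements
#'
#' Generates noisy reporter-expression replicates from a
#' [DoseResponseModel-class]: at each concentration, \code{replicates}
#' values \code{Y (1 + eps)} with \code{eps ~ Normal(0, noiseCV)},
#' floored at 0. Emulates per-day biological repeats of a flow-cytometry
#' mean whose noise scales with the signal.
#'
#' @param model a [DoseResponseModel-class].
#' @param concentrations peptide concentrations in uM, \code{>= 0},
#'   sorted ascending.
#' @param replicates replicates per concentration, \code{>= 1}.
#' @param noiseCV multiplicative coefficient of variation, \code{>= 0}.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{concentration_uM},
#'   \code{replicate}, \code{value}.
#' @export
#' @examples
#' m <- doseResponseModel(Emin = 1, Emax = 79, K = 0.12, n = 1)
#' simulateDoseResponse(m, doseDesign(0.12), seed = 1)
simulateDoseResponse <- function(model, concentrations, replicates = 3,
                                 noiseCV = 0.1, seed) {
  stopIfNot(methods::is(model, "DoseResponseModel"), "'model' must be a DoseResponseModel")
  stopIfNot(all(concentrations >= 0), "'concentrations' must be >= 0")
  stopIfNot(!is.unsorted(concentrations),
            "'concentrations' must be sorted ascending")
  stopIfNot(replicates >= 1, "'replicates' must be >= 1")
  stopIfNot(length(noiseCV) == 1 && noiseCV >= 0, "'noiseCV' must be >= 0")
  seed <- checkSeed(seed)
  y <- predictResponse(model, concentrations)
  n <- length(concentrations) * replicates
  eps <- withr::with_seed(seed, stats::rnorm(n, mean = 0, sd = noiseCV))
  out <- data.frame(
    concentration_uM = rep(concentrations, each = replicates),
    replicate = rep(seq_len(replicates), times = length(concentrations)),
    value = pmax(0, rep(y, each = replicates) * (1 + eps))
  )
  out
}

#' Default log-spaced concentration design bracketing K
#'
#' Eight concentrations spaced evenly in log10 from \code{K 10^-1.75} to
#' \code{K 10^1.75} (roughly K/56 to 56 K), bracketing both plateaus of
#' the response.
#'
#' @param K half-maximal concentration (uM).
#' @param nPoints number of concentrations (default 8).
#' @param span half-width of the design in log10 units (default 1.75).
#' @return numeric vector of concentrations, ascending.
#' @export
doseDesign <- function(K, nPoints = 8, span = 1.75) {
  stopIfNot(K > 0, "'K' must be > 0")
  10^seq(log10(K) - span, log10(K) + span, length.out = nPoints)
}

#' Simulate two groups of sporulation efficiencies
#'
#' Log-normal replicate efficiencies with a known geometric-mean ratio:
#' group 1 log10-values are Normal(m, log10SD) and group 2 values are
#' Normal(m - log10(trueRatio), log10SD), so the expected geometric-mean
#' fold change of group 1 over group 2 is \code{trueRatio}.
#'
#' @param trueRatio true geometric fold change, \code{> 0}.
#' @param log10SD replicate standard deviation on the log10 scale,
#'   \code{>= 0}.
#' @param nPerGroup replicates per group, \code{>= 2}.
#' @param seed integer RNG seed.
#' @param baselineLog10 mean log10 efficiency of group 1 (default
#'   \code{log10(0.5)}, a typical wild-type sporulation efficiency).
#' @return list with numeric vectors \code{a} and \code{b} of positive
#'   efficiencies.
#' @export
simulateEfficiencies <- function(trueRatio, log10SD = 0.2, nPerGroup = 4,
                                 seed, baselineLog10 = log10(0.5)) {
  stopIfNot(length(trueRatio) == 1 && trueRatio > 0, "'trueRatio' must be > 0")
  stopIfNot(log10SD >= 0, "'log10SD' must be >= 0")
  stopIfNot(nPerGroup >= 2, "'nPerGroup' must be >= 2")
  seed <- checkSeed(seed)
  z <- withr::with_seed(seed, stats::rnorm(2 * nPerGroup, 0, log10SD))
  list(
    a = 10^(baselineLog10 + z[seq_len(nPerGroup)]),
    b = 10^(baselineLog10 - log10(trueRatio) + z[nPerGroup + seq_len(nPerGroup)])
  )
}
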
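setMethod("show", "DoseResponseModel", function(object) {
  cat(sprintf(
    "Erf dose-response model (%s convention)\n  Emin = %.4g AU, Emax = %.4g AU, K = %.4g uM, n = %.4g\n",
    object@convention, object@Emin, object@Emax, object@K, object@n))
})

setMethod("show", "DoseResponseFit", function(object) {
  m <- object@model
  cat(sprintf(
    "Dose-response fit (%s convention)\n  K = %.4g uM (SE log10 K = %.3g)\n  Emax = %.4g AU, Emin = %.4g AU, n = %.4g\n  RSS = %.4g over %d concentrations\n",
    m@convention, m@K, object@se["log10K"], m@Emax, m@Emin, m@n,
    object@rss, nrow(object@data)))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "FoldChangeEstimate", function(object) {
  cat(sprintf(
    "Fold change %.3g (%.3g-%.3g, geometric +/- 1 SE; se_log10 = %.3g)\n  Welch t = %.3g, p = %.3g (n = %d, %d)\n",
    object@ratio, object@ciLow, object@ciHigh, object@seLog10,
    object@tStat, object@pValue, object@n1, object@n2))
})

setMethod("show", "WindowTreeSet", function(object) {
  cat(sprintf(
    "WindowTreeSet: %d windows (%d skipped) over %d strains\n",
    nrow(object@windows), sum(object@skipped), length(object@leaves)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf(
    "SimilarityMatrix: %d x %d window K scores (%d masked)\n",
    nrow(object@scores), ncol(object@scores), sum(object@mask)))
})

setMethod("show", "CongruenceProfile", function(object) {
  p <- object@profile
  cat(sprintf(
    "CongruenceProfile: %d windows, %d flagged incongruent (z > %.2g & RF fraction > %.2g)\n",
    nrow(p), sum(p$flagged, na.rm = TRUE), object@zThreshold,
    object@rfThresholdFraction))
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: %d segments", nrow(object@segments)))
  if (length(object@breakpoints))
    cat(sprintf(", boundaries at %s bp",
                paste(round(object@breakpoints), collapse = ", ")))
  cat("\n")
})

setMethod("show", "AlleleAssignment", function(object) {
  cat(sprintf(
    "AlleleAssignment: %d cluster(s) over %d strains in [%d, %d) bp (gap statistic %.3g)\n",
    object@nClusters, length(object@clusters), object@region[1],
    object@region[2], object@gapStatistic))
})
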
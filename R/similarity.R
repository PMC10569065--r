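#' Build neighbor-joining trees over sliding windows
#'
#' Runs the sliding-window scan substrate: for each window a Jukes-Cantor
#' distance matrix with pairwise deletion is built from the window's
#' columns and a neighbor-joining tree is inferred. A window is skipped
#' (flagged with a reason, never silently dropped) when some sequence
#' pair has fewer than \code{minComparableFraction} of the window's sites
#' comparable.
#'
#' @param alignment a \code{DNAStringSet} or named character vector of
#'   equal-length sequences (>= 4 strains).
#' @param width,step window parameters in bp (defaults 500 / 50; see
#'   [makeWindows()]).
#' @param minComparableFraction minimum fraction of comparable sites per
#'   pair (default 0.5) below which the window is skipped.
#' @param pCap,dMax Jukes-Cantor saturation cap (see [jcCorrect()]).
#' @return a [WindowTreeSet-class].
#' @export
windowTreeSet <- function(alignment, width = 500, step = 50,
                          minComparableFraction = 0.5,
                          pCap = 0.74999, dMax = 5.0) {
  m <- alignmentToIntMatrix(alignment)
  stopIfNot(nrow(m) >= 4, "need at least 4 strains")
  stopIfNot(!is.null(rownames(m)), "sequences must be named")
  win <- makeWindows(ncol(m), width = width, step = step)
  nw <- nrow(win)
  stopIfNot(nw >= 1, "alignment shorter than one window")
  trees <- vector("list", nw)
  skipped <- logical(nw)
  reason <- character(nw)
  for (i in seq_len(nw)) {
    sub <- m[, (win$start[i] + 1L):win$end[i], drop = FALSE]
    pd <- pDistance(sub)
    minCmp <- min(pd$comparable[upper.tri(pd$comparable)])
    if (minCmp < minComparableFraction * width) {
      skipped[i] <- TRUE
      reason[i] <- sprintf(
        "window %d [%d,%d): a pair has only %d/%d comparable sites",
        win$index[i], win$start[i], win$end[i], minCmp, width)
      next
    }
    d <- matrix(jcCorrect(pd$p, pCap, dMax), nrow(sub), nrow(sub),
                dimnames = dimnames(pd$p))
    diag(d) <- 0
    trees[[i]] <- njTree(d)
  }
  methods::new("WindowTreeSet", windows = win, trees = trees,
               skipped = skipped, skipReason = reason,
               leaves = sort(rownames(m)))
}

#' All-pairs window similarity matrix of K tree scores
#'
#' For every ordered pair of non-skipped windows (i, j) the K tree score
#' is computed with window i's tree as reference; the stored value is the
#' symmetrized mean of the (i, j) and (j, i) scores, giving one
#' similarity value per window pair (small = similar histories). With
#' \code{mode = "reference"} each window is instead scored against a
#' single reference tree and a per-window vector is returned.
#'
#' @param wts a [WindowTreeSet-class] with >= 2 non-skipped windows.
#' @param mode \code{"allpairs"} (default) or \code{"reference"}.
#' @param reference a \code{phylo}, required for
#'   \code{mode = "reference"}.
#' @return a [SimilarityMatrix-class] (allpairs), or a numeric vector of
#'   scores with NA at skipped windows (reference).
#' @export
windowSimilarityMatrix <- function(wts, mode = c("allpairs", "reference"),
                                   reference = NULL) {
  mode <- match.arg(mode)
  ok <- which(!wts@skipped)
  if (mode == "reference") {
    stopIfNot(!is.null(reference), "'reference' tree required")
    out <- rep(NA_real_, length(wts@trees))
    for (i in ok) out[i] <- kTreeScore(reference, wts@trees[[i]])$kScore
    return(out)
  }
  stopIfNot(length(ok) >= 2, "need at least 2 non-skipped windows")
  blist <- lapply(wts@trees[ok], bipartitionLengths)
  keys <- unique(unlist(lapply(blist, names)))
  B <- matrix(0, nrow = length(ok), ncol = length(keys),
              dimnames = list(NULL, keys))
  for (i in seq_along(blist)) B[i, names(blist[[i]])] <- blist[[i]]
  G <- tcrossprod(B)
  gd <- diag(G)
  # score^2 with row i as reference, column j as comparison
  denom <- matrix(gd, nrow = length(ok), ncol = length(ok), byrow = TRUE)
  s2 <- outer(gd, rep(1, length(ok))) - ifelse(denom > 0, G^2 / denom, 0)
  # identical trees give s2 = x - x^2/x, which may round to ~1e-17
  # instead of 0; snap anything far below branch-length resolution
  s2[s2 < 1e-10 * max(gd)] <- 0
  s <- sqrt(s2)
  sym <- (s + t(s)) / 2
  diag(sym) <- 0
  nw <- length(wts@trees)
  full <- matrix(NA_real_, nw, nw)
  full[ok, ok] <- sym
  methods::new("SimilarityMatrix", scores = full, windows = wts@windows,
               mask = wts@skipped)
}

#' Write a similarity matrix as square TSV keyed by window starts
#'
#' @param sim a [SimilarityMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  m <- sim@scores
  starts <- sim@windows$start
  dimnames(m) <- list(starts, starts)
  df <- data.frame(window_start = starts, m, check.names = FALSE)
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
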
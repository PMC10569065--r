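# Jukes-Cantor distances with pairwise deletion and a saturation cap.

#' Jukes-Cantor correction of a p-distance
#'
#' \code{d = -(3/4) log(1 - (4/3) p)}. The correction diverges at
#' p = 0.75; for \code{p >= pCap} the distance is capped at \code{dMax}
#' and flagged saturated by the callers.
#'
#' @param p proportion of differing sites among comparable sites.
#' @param pCap saturation threshold (default 0.74999).
#' @param dMax capped distance (default 5.0 subs/site).
#' @return corrected distance(s) in substitutions/site.
#' @export
jcCorrect <- function(p, pCap = 0.74999, dMax = 5.0) {
  d <- p
  d[] <- dMax
  ok <- which(p < pCap)
  d[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  d
}

#' Pairwise Jukes-Cantor distance matrix of an alignment
#'
#' For every pair of sequences, the p-distance is computed over sites
#' where both sequences carry an unambiguous base (A/C/G/T; pairwise
#' deletion of gaps and ambiguity codes) and corrected to a
#' Jukes-Cantor distance. Pairs at or beyond the saturation threshold
#' are capped at \code{dMax} and flagged.
#'
#' @param alignment a \code{DNAStringSet}, named character vector, or an
#'   integer matrix from the internal encoding; at least 3 sequences.
#' @param pCap,dMax saturation cap (see [jcCorrect()]).
#' @return list with components \code{d} (symmetric numeric matrix,
#'   labeled), \code{saturated} (logical matrix), \code{comparable}
#'   (integer matrix of comparable-site counts per pair).
#' @export
jcDistanceMatrix <- function(alignment, pCap = 0.74999, dMax = 5.0) {
  m <- if (is.matrix(alignment) && is.integer(alignment)) alignment
       else alignmentToIntMatrix(alignment)
  n <- nrow(m)
  stopIfNot(n >= 3, "need at least 3 sequences")
  pd <- pDistance(m)
  if (any(pd$comparable[upper.tri(pd$comparable)] == 0)) {
    idx <- which(pd$comparable == 0 & upper.tri(pd$comparable), arr.ind = TRUE)[1, ]
    stop(sprintf("no comparable sites between '%s' and '%s'",
                 rownames(m)[idx[1]], rownames(m)[idx[2]]), call. = FALSE)
  }
  p <- pd$p
  saturated <- p >= pCap
  diag(saturated) <- FALSE
  d <- matrix(jcCorrect(p, pCap, dMax), n, n, dimnames = dimnames(p))
  diag(d) <- 0
  list(d = d, saturated = saturated, comparable = pd$comparable)
}

# p-distance with pairwise deletion via per-base indicator cross-products:
# matches(i,j) = sum_b I_b I_b', comparable(i,j) = V V'.
#' @noRd
pDistance <- function(m) {
  n <- nrow(m)
  valid <- !is.na(m)
  storage.mode(valid) <- "double"
  comparable <- tcrossprod(valid)
  matches <- matrix(0, n, n)
  for (b in 1:4) {
    ind <- !is.na(m) & m == b
    storage.mode(ind) <- "double"
    matches <- matches + tcrossprod(ind)
  }
  p <- ifelse(comparable > 0, (comparable - matches) / comparable, NA_real_)
  diag(p) <- 0
  labs <- rownames(m)
  dimnames(p) <- list(labs, labs)
  cmpInt <- comparable
  storage.mode(cmpInt) <- "integer"
  dimnames(cmpInt) <- dimnames(p)
  list(p = p, comparable = cmpInt)
}

#' Write a distance matrix as square TSV
#'
#' @param d a labeled square numeric matrix (e.g.
#'   \code{jcDistanceMatrix(x)$d}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
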
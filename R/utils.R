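# Shared internal helpers.

#' Gauss error function
#'
#' \code{erf(x) = 2 Phi(x sqrt(2)) - 1}, evaluated through the normal CDF.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
#' @examples erf(1) # 0.8427008
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' @noRd
stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' @noRd
checkSeed <- function(seed) {
  stopIfNot(length(seed) == 1 && is.finite(seed) && seed == round(seed),
            "'seed' must be a single integer")
  as.integer(seed)
}

# Alignment as an integer matrix (strains x sites): A=1, C=2, G=3, T=4,
# anything else (gap, N, ...) = NA. Accepts a DNAStringSet or a named
# character vector of equal-length sequences.
#' @noRd
alignmentToIntMatrix <- function(alignment) {
  if (methods::is(alignment, "DNAStringSet")) {
    w <- Biostrings::width(alignment)
    stopIfNot(length(unique(w)) == 1, "sequences must have equal length")
    chars <- as.matrix(alignment)
  } else {
    seqs <- toupper(as.character(alignment))
    stopIfNot(length(unique(nchar(seqs))) == 1,
              "sequences must have equal length")
    chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(chars) <- names(alignment)
  }
  m <- matrix(match(chars, c("A", "C", "G", "T")), nrow = nrow(chars),
              dimnames = list(rownames(chars), NULL))
  m
}

#' @noRd
intMatrixToStrings <- function(m) {
  bases <- c("A", "C", "G", "T")
  apply(m, 1, function(row) paste(bases[row], collapse = ""))
}
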
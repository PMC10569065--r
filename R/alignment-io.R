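#' Read a nucleotide alignment from multi-FASTA
#'
#' Reads an aligned multi-FASTA, uppercases the sequences and validates
#' that all records have equal length and unique identifiers.
#'
#' @param path path to a FASTA file.
#' @return a \code{DNAStringSet}, one record per strain.
#' @export
readAlignment <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("not a parseable FASTA file: ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1) {
    bad <- names(x)[w != w[1]][1]
    stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                 bad, w[names(x) == bad][1], w[1]), call. = FALSE)
  }
  if (anyDuplicated(names(x)))
    stop("duplicate sequence identifiers in ", path, call. = FALSE)
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- names(x)
  out
}

#' Write an alignment as multi-FASTA
#'
#' @param alignment a \code{DNAStringSet} (or named character vector).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(alignment, path) {
  if (!methods::is(alignment, "DNAStringSet"))
    alignment <- Biostrings::DNAStringSet(toupper(as.character(alignment)))
  Biostrings::writeXStringSet(alignment, filepath = path, width = 80)
  invisible(path)
}

#' Write the segment-truth sidecar of a simulated alignment
#'
#' TSV with one row per layout segment: name, start, end (0-based
#' half-open) and the tree it evolved along.
#'
#' @param layout a segment layout data.frame ([segmentLayout()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSegmentTruth <- function(layout, path) {
  utils::write.table(
    layout[, c("name", "start", "end", "tree")],
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a tree as Newick
#'
#' Branch lengths are written with 6-decimal precision.
#'
#' @param tree a \code{phylo}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path) {
  tr <- tree
  tr$edge.length <- round(tr$edge.length, 6)
  ape::write.tree(tr, file = path)
  invisible(path)
}
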
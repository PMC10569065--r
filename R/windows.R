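#' Sliding windows over an alignment
#'
#' Windows of fixed width advancing by a fixed step over 0-based
#' half-open alignment coordinates: starts 0, step, 2 step, ... with
#' \code{start + width <= L}. A trailing partial window is dropped, so
#' the count is \code{floor((L - width)/step) + 1} when \code{L >= width}
#' and 0 otherwise.
#'
#' @param alignmentLength alignment length L in bp, \code{>= 1}.
#' @param width window width in bp (default 500).
#' @param step step between window starts in bp (default 50);
#'   \code{width >= step >= 1}.
#' @return data.frame with columns \code{index} (0-based), \code{start},
#'   \code{end}; zero rows when \code{L < width}.
#' @export
#' @examples
#' nrow(makeWindows(1000))  # 11
makeWindows <- function(alignmentLength, width = 500, step = 50) {
  stopIfNot(length(alignmentLength) == 1 && alignmentLength >= 1,
            "'alignmentLength' must be a single value >= 1")
  stopIfNot(step >= 1 && width >= step,
            "window parameters must satisfy width >= step >= 1")
  if (alignmentLength < width)
    return(data.frame(index = integer(), start = integer(), end = integer()))
  n <- floor((alignmentLength - width) / step) + 1
  starts <- as.integer((seq_len(n) - 1) * step)
  data.frame(index = seq_len(n) - 1L, start = starts,
             end = as.integer(starts + width))
}
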
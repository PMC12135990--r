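#' Stride/offset reduction of an accepted pool
#'
#' Keeps positions \code{offset+1, offset+1+stride, ...} (1-based within
#' the accepted pool): the offset is the number of frames skipped before
#' the first kept frame.  The kept count is
#' \code{floor((poolSize - offset - 1) / stride) + 1}.  Extracted frames
#' retain their original model numbers.
#'
#' @param poolSize number of accepted frames, or a [ConformerPool-class]
#'   (then a reduced pool is returned instead of positions).
#' @param stride keep every stride-th frame, default 10.
#' @param offset frames skipped before the first kept one, default 0; must
#'   be smaller than the pool size.
#' @return Integer positions within the accepted pool, or a reduced
#'   [ConformerPool-class] when \code{poolSize} is a pool.
#' @examples
#' length(reducePool(15707, stride = 7, offset = 5))  # 2244
#' @export
reducePool <- function(poolSize, stride = 10, offset = 0) {
  if (is(poolSize, "ConformerPool")) {
    pool <- poolSize
    pos <- reducePool(nFrames(pool), stride, offset)
    return(new("ConformerPool", template = pool@template,
               coords = pool@coords[, , pos, drop = FALSE],
               modelNumbers = pool@modelNumbers[pos],
               rg = pool@rg[pos], acceptanceLog = pool@acceptanceLog))
  }
  stopifnot(poolSize >= 1, stride >= 1)
  if (offset >= poolSize)
    stop("offset (", offset, ") must be smaller than the pool size (",
         poolSize, ")")
  as.integer(seq.int(offset + 1L, poolSize, by = stride))
}

#' Compare Rg histograms of the full and reduced pools
#'
#' Builds histograms on shared 1 Angstrom (by default) bins spanning both
#' pools, normalizes each to unit mass, and reports the total-variation
#' distance \code{0.5 * sum(|h_full - h_reduced|)} in [0, 1].  The metric
#' is advisory: the reduction is judged by the user, no hard threshold.
#'
#' @param rgFull,rgReduced per-frame Rg values (Angstrom) of the two pools.
#' @param binWidth histogram bin width in Angstrom, default 1.
#' @return list with \code{breaks}, \code{histFull}, \code{histReduced}
#'   (unit-mass bin frequencies) and \code{tvDistance}.
#' @export
rgHistogramCompare <- function(rgFull, rgReduced, binWidth = 1) {
  if (!length(rgFull) || !length(rgReduced))
    stop("both Rg lists must be non-empty")
  lo <- floor(min(rgFull, rgReduced) / binWidth) * binWidth
  hi <- ceiling(max(rgFull, rgReduced) / binWidth + 1e-9) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  hf <- hist(rgFull, breaks = breaks, plot = FALSE)$counts
  hr <- hist(rgReduced, breaks = breaks, plot = FALSE)$counts
  hf <- hf / sum(hf); hr <- hr / sum(hr)
  list(breaks = breaks, histFull = hf, histReduced = hr,
       tvDistance = 0.5 * sum(abs(hf - hr)))
}

#' Augment a selection with adjacent original frames
#'
#' Preselection operates on a strided pool, so models flanking a selected
#' frame in the original accepted-pool ordering were never considered.
#' This adds the k frames on both sides of every selected frame (clipped
#' to the pool), deduplicated and sorted; k may not exceed half the stride
#' (beyond that, neighbourhoods of adjacent kept frames would overlap the
#' next kept frame itself).
#'
#' @param selectedFrames frame numbers within the accepted pool ordering.
#' @param k adjacent frames on each side, \code{0 <= k <= floor(stride/2)}.
#' @param stride the stride used for the reduction.
#' @param poolSize accepted-pool size for clipping.
#' @return Sorted unique frame numbers; always a superset of the selection.
#' @export
augmentAdjacent <- function(selectedFrames, k, stride, poolSize) {
  stopifnot(k >= 0, length(selectedFrames) >= 1)
  if (k > floor(stride / 2))
    stop("adjacent frame count k = ", k,
         " cannot be greater than half the stride (floor(", stride,
         "/2) = ", floor(stride / 2), ")")
  if (any(selectedFrames < 1) || any(selectedFrames > poolSize))
    stop("selected frames must lie in [1, poolSize]")
  out <- unique(sort(unlist(lapply(selectedFrames, function(f)
    (f - k):(f + k)))))
  out[out >= 1 & out <= poolSize]
}

#' @importFrom graphics hist
NULL
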
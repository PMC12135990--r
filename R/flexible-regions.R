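#' Detect flexible regions from per-residue confidence
#'
#' Finds maximal runs of at least \code{minRun} consecutive residues whose
#' confidence (e.g. AlphaFold pLDDT) is strictly below \code{threshold}.
#' A residue exactly at the threshold is not flexible.  Runs touching the
#' chain termini are eligible (a disordered tail is a region).
#'
#' @param confidence numeric vector of per-residue values in 0-100, in
#'   sequence order (see [confidence()]).
#' @param threshold confidence cutoff, default 60.
#' @param minRun minimal run length, default 5.
#' @return An \code{IRanges} of 1-based inclusive residue ranges, sorted,
#'   non-overlapping.
#' @examples
#' conf <- c(rep(90, 10), rep(50, 6), rep(90, 10))
#' detectFlexibleRegions(conf, threshold = 60)  # 11-16
#' @export
detectFlexibleRegions <- function(confidence, threshold = 60, minRun = 5) {
  if (!length(confidence)) stop("confidence list must be non-empty")
  if (threshold <= 0 || threshold > 100)
    stop("threshold must be in (0, 100]")
  low <- confidence < threshold
  runs <- rle(low)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= minRun
  IRanges(start = starts[keep], end = ends[keep])
}

#' Validate a structure alignment range against flexible regions
#'
#' The range used to superpose sampled conformers must lie inside the chain
#' and must not intersect any flexible region (aligning on moving residues
#' would be meaningless).
#'
#' @param regions \code{IRanges} of flexible regions.
#' @param alignRange an \code{IRanges} of length 1 or \code{c(start, end)}.
#' @param nResidues chain length in residues.
#' @return \code{TRUE} invisibly on success, otherwise an error naming the
#'   offending region.
#' @export
validateAlignmentRange <- function(regions, alignRange, nResidues) {
  ar <- .as_range(alignRange)
  if (start(ar) < 1 || end(ar) > nResidues)
    stop("alignment range ", start(ar), "-", end(ar),
         " lies outside the sequence [1, ", nResidues, "]")
  if (length(regions)) {
    hits <- findOverlaps(ar, regions)
    if (length(hits)) {
      off <- regions[subjectHits(hits)[1]]
      stop("alignment range ", start(ar), "-", end(ar),
           " overlaps flexible region ", start(off), "-", end(off),
           "; choose a non-flexible range")
    }
  }
  invisible(TRUE)
}

#' Build flexible regions from manual start/end pairs
#'
#' The manual-entry path for structures without confidence values: the same
#' validation applies as for detected regions (sorted, disjoint, within the
#' chain).
#'
#' @param starts,ends 1-based inclusive residue bounds, one pair per region.
#' @param nResidues chain length in residues.
#' @return An \code{IRanges}.
#' @export
manualRegions <- function(starts, ends, nResidues) {
  stopifnot(length(starts) == length(ends))
  if (any(starts < 1) || any(ends > nResidues) || any(starts > ends))
    stop("each region must satisfy 1 <= start <= end <= ", nResidues)
  rg <- IRanges(start = as.integer(starts), end = as.integer(ends))
  rg <- rg[order(start(rg))]
  if (length(rg) > 1 && any(start(rg)[-1] <= end(rg)[-length(rg)]))
    stop("regions must be non-overlapping")
  rg
}
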
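#' Select a weighted ensemble by non-negative least squares
#'
#' Finds non-negative weights \eqn{w} minimizing
#' \eqn{\|W (A w - b)\|_2}, where the columns of A are the per-model
#' calculated profiles on the experimental grid, b the experimental values
#' and \eqn{W = diag(1/\sigma)} when SD weighting is requested and the
#' experimental curve carries SDs (otherwise identity).  Columns enter
#' unscaled; the weights absorb the overall scale.  Only models with
#' strictly positive weight are reported, with percent contributions
#' summing to 100.  The normalized chi-square of the fitted sum uses an
#' \eqn{N - m} denominator (m = number of positive weights; no extra scale
#' factor is fitted).
#'
#' @param profiles numeric matrix, one column per model, rows on the
#'   experimental grid; column names (or \code{modelNumbers}) key the
#'   models.
#' @param experimental a [ScatteringCurve-class] or [PofR-class] on the
#'   same grid.
#' @param useSdWeighting apply 1/SD weights; falls back to unweighted with
#'   a warning when the experimental curve has no SDs.
#' @param modelNumbers integer keys for the columns; defaults to column
#'   names, else 1..m.
#' @param rg optional per-model Rg (Angstrom) used to fill the ensemble's
#'   weighted Rg.
#' @return An [EnsembleFit-class].
#' @export
nnlsSelect <- function(profiles, experimental, useSdWeighting = FALSE,
                       modelNumbers = NULL, rg = NULL) {
  profiles <- as.matrix(profiles)
  is_pr <- is(experimental, "PofR")
  grid <- if (is_pr) experimental@r else experimental@q
  b <- if (is_pr) experimental@p else experimental@intensity
  if (nrow(profiles) != length(grid))
    stop("profiles and experimental curve do not share a grid (",
         nrow(profiles), " rows vs ", length(grid), " points)")
  if (is.null(modelNumbers)) {
    modelNumbers <- if (!is.null(colnames(profiles)))
      as.integer(colnames(profiles)) else seq_len(ncol(profiles))
  }
  stopifnot(length(modelNumbers) == ncol(profiles))
  sds <- experimental@sd
  wvec <- rep(1, length(b))
  if (useSdWeighting) {
    if (length(sds)) {
      if (any(sds <= 0)) stop("all SDs must be > 0 for 1/SD weighting")
      wvec <- 1 / sds
    } else {
      warning("SD weighting requested but the experimental curve has no ",
              "SDs; falling back to unweighted NNLS")
    }
  }
  sol <- nnls(profiles * wvec, b * wvec)
  w <- sol$x
  pos <- which(w > 0)
  if (!length(pos)) stop("NNLS selected no models (all weights zero)")
  fitted <- as.vector(profiles %*% w)
  n <- length(b); m <- length(pos)
  sig <- if (length(sds)) sds else rep(1, n)
  nchi2 <- sum(((b - fitted) / sig)^2) / max(n - m, 1)
  ord <- order(modelNumbers[pos])
  pos <- pos[ord]
  recon <- new("ScatteringCurve",
               q = if (is_pr) grid else grid, intensity = fitted)
  wrg <- if (!is.null(rg)) {
    stopifnot(length(rg) == ncol(profiles))
    sqrt(sum((w[pos] / sum(w[pos])) * rg[pos]^2))
  } else NA_real_
  new("EnsembleFit", modelNumbers = as.integer(modelNumbers[pos]),
      weights = w[pos], percents = 100 * w[pos] / sum(w[pos]),
      nchi2 = nchi2, reconstructed = recon, weightedRg = wrg)
}

#' Ensemble radius of gyration from percent contributions
#'
#' Multiplies each squared Rg by its fractional contribution and takes the
#' square root of the sum: \eqn{R_g = \sqrt{\sum (p_i/100) R_{g,i}^2}}.
#'
#' @param rg per-model Rg values, Angstrom.
#' @param percents percent contributions, summing to 100 (within 1e-6).
#' @return Weighted-RMS Rg in Angstrom.
#' @export
weightedRg <- function(rg, percents) {
  if (length(rg) != length(percents))
    stop("rg and percents must have the same length")
  if (abs(sum(percents) - 100) > 1e-6)
    stop("percents must sum to 100")
  sqrt(sum((percents / 100) * rg^2))
}

#' Reconstruct the ensemble curve with propagated SDs
#'
#' Pointwise weighted sum of the model profiles,
#' \eqn{I = \sum w_i I_i}; when per-column SDs exist the reconstructed SD
#' is \eqn{\sqrt{\sum (w_i \sigma_i)^2}} pointwise.
#'
#' @param profiles matrix of per-model curves (columns).
#' @param weights non-negative weights from [nnlsSelect()]; not all zero.
#' @param grid the shared abscissa (q values).
#' @param sds optional matrix of per-column SDs, same shape as
#'   \code{profiles}.
#' @return A [ScatteringCurve-class].
#' @export
reconstructCurve <- function(profiles, weights, grid, sds = NULL) {
  profiles <- as.matrix(profiles)
  stopifnot(length(weights) == ncol(profiles),
            length(grid) == nrow(profiles))
  if (all(weights == 0)) stop("all weights are zero")
  value <- as.vector(profiles %*% weights)
  sd <- if (!is.null(sds)) {
    sds <- as.matrix(sds)
    stopifnot(all(dim(sds) == dim(profiles)))
    sqrt(as.vector(sds^2 %*% weights^2))
  } else numeric()
  new("ScatteringCurve", q = grid, intensity = value, sd = sd)
}

#' Composite P(r) of a selected ensemble
#'
#' Sums the per-model P(r) columns weighted by fractional contribution and
#' reports the RMSD against the experimentally derived P(r).
#'
#' @param prProfiles matrix of per-model P(r) columns on a shared r grid.
#' @param percents percent contributions (summing to 100).
#' @param experimentalPr a [PofR-class] on the same r grid.
#' @return list with \code{composite} ([PofR-class]) and \code{rmsd}.
#' @export
reconstructPr <- function(prProfiles, percents, experimentalPr) {
  prProfiles <- as.matrix(prProfiles)
  if (nrow(prProfiles) != length(experimentalPr@r))
    stop("P(r) grids differ between models and experimental curve")
  frac <- percents / 100
  stopifnot(length(frac) == ncol(prProfiles))
  p <- as.vector(prProfiles %*% frac)
  dr <- if (length(experimentalPr@r) > 1)
    experimentalPr@r[2] - experimentalPr@r[1] else 1
  composite <- new("PofR", r = experimentalPr@r, p = pmax(p, 0),
                   normalization = sum(pmax(p, 0)) * dr)
  list(composite = composite,
       rmsd = sqrt(mean((experimentalPr@p - p)^2)))
}
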
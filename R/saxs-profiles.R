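#' Convert a curve's abscissa units to inverse Angstrom / Angstrom
#'
#' All internal computation uses q in inverse Angstrom and r in Angstrom;
#' curves declared in inverse nm (nm) are converted on entry.  For P(r) the
#' frequencies are rescaled to the new bin width so the area is conserved.
#'
#' @param curve a [ScatteringCurve-class] or [PofR-class].
#' @param unit the unit the data are currently in:
#'   \code{"inv_angstrom"}/\code{"inv_nm"} for I(q),
#'   \code{"angstrom"}/\code{"nm"} for P(r).
#' @return The curve in inverse Angstrom (or Angstrom).
#' @export
setGeneric("convertUnits", function(curve, unit) standardGeneric("convertUnits"))

#' @rdname convertUnits
setMethod("convertUnits", "ScatteringCurve", function(curve, unit) {
  unit <- match.arg(unit, c("inv_angstrom", "inv_nm"))
  if (unit == "inv_angstrom") return(curve)
  q <- curve@q / 10
  if (length(q) > 1 && any(diff(q) <= 0))
    stop("q grid not strictly increasing after conversion")
  new("ScatteringCurve", q = q, intensity = curve@intensity, sd = curve@sd)
})

#' @rdname convertUnits
setMethod("convertUnits", "PofR", function(curve, unit) {
  unit <- match.arg(unit, c("angstrom", "nm"))
  if (unit == "angstrom") return(curve)
  ## r in nm -> Angstrom: bin width grows 10x, frequencies shrink 10x so
  ## that sum(p) * dr is unchanged
  new("PofR", r = curve@r * 10, p = curve@p / 10,
      sd = if (length(curve@sd)) curve@sd / 10 else numeric(),
      normalization = curve@normalization)
})

#' Pair-distance distribution function of a structure
#'
#' Histograms all unordered atom pair distances into uniform
#' \code{[k*dr, (k+1)*dr)} bins, each pair weighted by the product of the
#' two atoms' electron counts (the SAXS-relevant contrast; uniform
#' weighting available for testing), then rescales so the total area equals
#' the molecular mass in Da.  Computed on the dry structure as given.
#'
#' @param structure a [ProteinStructure-class] with at least 2 atoms.
#' @param binWidth bin width in Angstrom, default 1.
#' @param weighting \code{"electrons"} (default) or \code{"uniform"}.
#' @return A [PofR-class] normalized to the molecular mass.
#' @export
computePr <- function(structure, binWidth = 1.0,
                      weighting = c("electrons", "uniform")) {
  weighting <- match.arg(weighting)
  n <- nAtoms(structure)
  if (n < 2) stop("P(r) needs at least 2 atoms (no pairs)")
  d <- dist(structure@xyz)
  w <- if (weighting == "electrons") {
    z <- structure@atoms$electrons
    ## products z_i * z_j for i < j in dist() ordering
    .pair_products(z)
  } else rep(1, length(d))
  idx <- floor(as.vector(d) / binWidth) + 1L
  nb <- max(idx)
  p <- as.vector(rowsum(w, idx, reorder = TRUE))
  bins_present <- sort(unique(idx))
  full <- numeric(nb)
  full[bins_present] <- p
  mass <- molecularMass(structure)
  area <- sum(full) * binWidth
  full <- full * mass / area
  new("PofR", r = (seq_len(nb) - 1) * binWidth, p = full,
      normalization = mass)
}

## w_i * w_j over unordered pairs i < j, in the column-major order used by
## stats::dist (pairs (2,1), (3,1), ..., (n,1), (3,2), ...)
.pair_products <- function(w) {
  n <- length(w)
  out <- numeric(n * (n - 1) / 2)
  pos <- 1L
  for (i in seq_len(n - 1)) {
    m <- n - i
    out[pos:(pos + m - 1)] <- w[i] * w[(i + 1):n]
    pos <- pos + m
  }
  out
}

#' Debye scattering intensity of a structure
#'
#' Exact orientationally averaged intensity of a rigid atom set:
#' \deqn{I(q) = \sum_i \sum_j f_i(q) f_j(q) \frac{\sin(q r_{ij})}{q r_{ij}}}
#' with \eqn{\sin(x)/x \to 1} as \eqn{x \to 0}.  In \code{"point"} mode the
#' form factors are the electron counts (q-independent point scatterers);
#' \code{"cromer_mann"} uses the 4-Gaussian X-ray form factor table.  This
#' is a vacuum calculation: no excluded-volume or hydration-shell term.
#' External I(q) calculators can stand behind the same curve contract (a
#' structure in, a 2/3-column curve out) and pass through
#' [interpolateToGrid()] and [scaleAndChi2()] unchanged.
#'
#' @param structure a [ProteinStructure-class].
#' @param qGrid strictly increasing q values, inverse Angstrom, q >= 0.
#' @param mode \code{"point"} (default) or \code{"cromer_mann"}.
#' @return A [ScatteringCurve-class].
#' @export
computeIqDebye <- function(structure, qGrid, mode = c("point", "cromer_mann")) {
  mode <- match.arg(mode)
  if (any(qGrid < 0)) stop("negative q is not meaningful")
  if (nAtoms(structure) < 1) stop("structure has no atoms")
  n <- nAtoms(structure)
  z <- structure@atoms$electrons
  if (n == 1) {
    f <- if (mode == "point") rep(z, length(qGrid))
         else .cm_form_factor(structure@atoms$element, qGrid)
    return(new("ScatteringCurve", q = qGrid, intensity = f^2))
  }
  d <- as.vector(dist(structure@xyz))
  if (mode == "point") {
    wpair <- .pair_products(z)
    self <- sum(z^2)
    intensity <- vapply(qGrid, function(q) {
      x <- q * d
      sinc <- sin(x) / x
      sinc[!is.finite(sinc)] <- 1          # sin(x)/x -> 1 as x -> 0
      self + 2 * sum(wpair * sinc)
    }, numeric(1))
  } else {
    els <- structure@atoms$element
    fq <- vapply(unique(els), .cm_form_factor, q = qGrid,
                 numeric(length(qGrid)))
    fq <- matrix(fq, nrow = length(qGrid))
    colnames(fq) <- unique(els)
    fmat <- fq[, els, drop = FALSE]          # n_q x n_atoms
    intensity <- vapply(seq_along(qGrid), function(k) {
      f <- fmat[k, ]
      x <- qGrid[k] * d
      sinc <- sin(x) / x
      sinc[!is.finite(sinc)] <- 1
      sum(f^2) + 2 * sum(.pair_products(f) * sinc)
    }, numeric(1))
  }
  new("ScatteringCurve", q = qGrid, intensity = intensity)
}

#' Linear interpolation of a curve onto the experimental q grid
#'
#' Calculated I(q) profiles are compared to experimental data on the
#' experimental grid; intensities (and SDs, if present) are interpolated
#' piecewise-linearly.  Extrapolation is refused.
#'
#' @param curve a [ScatteringCurve-class].
#' @param targetQ target grid, must lie within the source q range.
#' @return A [ScatteringCurve-class] on \code{targetQ}.
#' @export
interpolateToGrid <- function(curve, targetQ) {
  if (min(targetQ) < min(curve@q) - 1e-12 ||
      max(targetQ) > max(curve@q) + 1e-12)
    stop("target grid [", min(targetQ), ", ", max(targetQ),
         "] extends beyond the source curve [", min(curve@q), ", ",
         max(curve@q), "]; extrapolation not supported")
  intensity <- approx(curve@q, curve@intensity, xout = targetQ)$y
  sd <- if (length(curve@sd))
    approx(curve@q, curve@sd, xout = targetQ)$y else numeric()
  new("ScatteringCurve", q = targetQ, intensity = intensity, sd = sd)
}

#' Scale a calculated curve to an experimental one
#'
#' Finds the multiplier c minimizing the SD-weighted squared deviation of
#' \code{exp - c * calc} and reports the normalized chi-square
#' \eqn{n\chi^2 = \frac{1}{N-1}\sum ((I_e - c I_c)/\sigma)^2} (one fitted
#' parameter) and the unweighted RMSD.  With no experimental SDs, sigma = 1.
#'
#' @param calc,exp [ScatteringCurve-class] objects on identical q grids
#'   (interpolate first); at least 2 points.
#' @return list with \code{scale}, \code{nchi2}, \code{rmsd}.
#' @export
scaleAndChi2 <- function(calc, exp) {
  if (length(calc@q) != length(exp@q) ||
      any(abs(calc@q - exp@q) > 1e-9 * pmax(abs(exp@q), 1)))
    stop("q grids differ; interpolate the calculated curve first")
  n <- length(exp@q)
  if (n < 2) stop("need at least 2 points")
  sig <- if (length(exp@sd)) exp@sd else rep(1, n)
  if (any(sig <= 0)) stop("all SDs must be > 0")
  ic <- calc@intensity; ie <- exp@intensity
  if (all(ic == 0)) stop("calculated curve is identically zero")
  cc <- sum(ie * ic / sig^2) / sum(ic^2 / sig^2)
  resid <- ie - cc * ic
  list(scale = cc,
       nchi2 = sum((resid / sig)^2) / (n - 1),
       rmsd = sqrt(mean(resid^2)))
}

#' Radius of gyration from coordinates
#'
#' \eqn{R_g = \sqrt{\sum w_i |x_i - \bar x|^2 / \sum w_i}} with the
#' w-weighted centroid \eqn{\bar x}; electron weighting by default (the
#' scattering-relevant contrast), mass or uniform weighting optional.
#'
#' @param structure a [ProteinStructure-class].
#' @param weighting \code{"electrons"}, \code{"mass"} or \code{"uniform"}.
#' @return Rg in Angstrom.
#' @export
rgFromCoords <- function(structure,
                         weighting = c("electrons", "mass", "uniform")) {
  weighting <- match.arg(weighting)
  w <- switch(weighting,
              electrons = structure@atoms$electrons,
              mass = structure@atoms$mass,
              uniform = rep(1, nAtoms(structure)))
  .rg_xyz(structure@xyz, w)
}

.rg_xyz <- function(xyz, w) {
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}

#' Radius of gyration from a P(r) curve
#'
#' Second-moment relation \eqn{R_g^2 = \int r^2 P(r) dr / (2 \int P(r) dr)},
#' evaluated discretely at bin centers.
#'
#' @param pr a [PofR-class] with positive total area.
#' @return Rg in Angstrom.
#' @export
rgFromPr <- function(pr) {
  if (!length(pr@r) || sum(pr@p) <= 0)
    stop("P(r) has zero area; cannot compute Rg")
  dr <- if (length(pr@r) > 1) pr@r[2] - pr@r[1] else 1
  rc <- pr@r + dr / 2
  sqrt(sum(rc^2 * pr@p) / (2 * sum(pr@p)))
}
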
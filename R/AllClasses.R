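#' @importClassesFrom IRanges IRanges
#' @importFrom IRanges IRanges start end width reduce findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Single-chain protein structure
#'
#' Ordered atoms of one protein chain with coordinates, element-derived
#' constants (electron count, mass), 1-based residue indexing and a
#' per-atom confidence value taken from the B-factor column (AlphaFold
#' models store the per-residue pLDDT there).
#'
#' @slot atoms data.frame with one row per atom: \code{name}, \code{element},
#'   \code{electrons}, \code{mass}, \code{resno} (1-based residue index),
#'   \code{resid} (3-letter residue name), \code{confidence} (0-100).
#' @slot xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @slot chainId single chain identifier.
#' @slot title,source free-text metadata from the source file.
#'
#' @seealso [readStructure()], [buildToyChain()]
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", xyz = "matrix",
                 chainId = "character", title = "character",
                 source = "character"),
  prototype(chainId = "A", title = "", source = ""))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  msg <- character()
  need <- c("name", "element", "electrons", "mass", "resno", "resid",
            "confidence")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) != nrow(object@xyz) || ncol(object@xyz) != 3)
    msg <- c(msg, "xyz must be an n_atoms x 3 matrix")
  if (length(object@chainId) != 1)
    msg <- c(msg, "exactly one chain")
  if (nrow(a)) {
    if (any(a$electrons < 1)) msg <- c(msg, "electrons must be >= 1")
    if (any(a$mass <= 0)) msg <- c(msg, "mass must be > 0")
    if (any(a$resno < 1)) msg <- c(msg, "residue index must be >= 1")
    if (is.unsorted(a$resno))
      msg <- c(msg, "residue indices must be non-decreasing (contiguous residues)")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

.new_structure <- function(atoms, xyz, chainId = "A", title = "", source = "") {
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  new("ProteinStructure", atoms = atoms, xyz = xyz, chainId = chainId,
      title = title, source = source)
}

#' Pool of conformers generated from one starting structure
#'
#' Frames are keyed by their original 1-based model number (the trial index
#' in the Monte Carlo run that produced them), so a model number reported by
#' the final ensemble selection always indexes the original sampler output.
#'
#' @slot template [ProteinStructure-class] supplying atoms/topology shared by
#'   all frames.
#' @slot coords numeric array \code{n_atoms x 3 x n_frames}.
#' @slot modelNumbers strictly increasing integer model numbers.
#' @slot rg per-frame radius of gyration (Angstrom, electron-weighted).
#' @slot acceptanceLog logical, one flag per Monte Carlo trial.
#'
#' @seealso [runMC()], [reducePool()]
#' @export
setClass("ConformerPool",
  representation(template = "ProteinStructure", coords = "array",
                 modelNumbers = "integer", rg = "numeric",
                 acceptanceLog = "logical"))

setValidity("ConformerPool", function(object) {
  msg <- character()
  d <- dim(object@coords)
  nf <- length(object@modelNumbers)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(object@template@atoms))
    msg <- c(msg, "frame atom count must match the template")
  if (d[3] != nf || length(object@rg) != nf)
    msg <- c(msg, "modelNumbers, rg and coords frames must agree in length")
  if (nf > 1 && any(diff(object@modelNumbers) <= 0))
    msg <- c(msg, "model numbers must be strictly increasing")
  if (nf && any(object@rg <= 0)) msg <- c(msg, "per-frame rg must be > 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Scattering intensity curve I(q)
#'
#' @slot q scattering vector magnitudes, strictly increasing, in inverse
#'   Angstrom (q = 4 pi sin(theta) / lambda).
#' @slot intensity intensities, arbitrary units.
#' @slot sd optional per-point standard deviations (length 0 when absent).
#' @export
setClass("ScatteringCurve",
  representation(q = "numeric", intensity = "numeric", sd = "numeric"),
  prototype(sd = numeric()))

setValidity("ScatteringCurve", function(object) {
  msg <- character()
  if (length(object@q) != length(object@intensity))
    msg <- c(msg, "q and intensity must have the same length")
  if (any(object@q < 0)) msg <- c(msg, "q must be >= 0")
  if (length(object@q) > 1 && any(diff(object@q) <= 0))
    msg <- c(msg, "q must be strictly increasing")
  if (length(object@sd)) {
    if (length(object@sd) != length(object@q))
      msg <- c(msg, "sd must match q in length")
    else if (any(object@sd <= 0)) msg <- c(msg, "sd must be > 0")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Pair-distance distribution function P(r)
#'
#' Distances are binned into uniform left-closed, right-open bins
#' \code{[k*dr, (k+1)*dr)} starting at r = 0; \code{r} holds the left bin
#' edges.  When \code{normalization} is set, the area \code{sum(p)*dr}
#' equals it (the convention here: area = molecular mass in Da).
#'
#' @slot r left bin edges, Angstrom, uniform spacing, starting at 0.
#' @slot p frequency per bin, non-negative.
#' @slot sd optional per-bin standard deviations (length 0 when absent).
#' @slot normalization area the curve is scaled to (Da), or NA when the
#'   curve is not normalized (e.g. experimentally derived input).
#' @export
setClass("PofR",
  representation(r = "numeric", p = "numeric", sd = "numeric",
                 normalization = "numeric"),
  prototype(sd = numeric(), normalization = NA_real_))

setValidity("PofR", function(object) {
  msg <- character()
  r <- object@r
  if (length(r) != length(object@p))
    msg <- c(msg, "r and p must have the same length")
  if (length(r)) {
    if (abs(r[1]) > 1e-9) msg <- c(msg, "r must start at 0")
    if (length(r) > 2) {
      dr <- diff(r)
      if (max(abs(dr - dr[1])) > 1e-6 * dr[1])
        msg <- c(msg, "r must be uniformly spaced")
    }
    if (any(object@p < -1e-12)) msg <- c(msg, "p must be >= 0")
  }
  if (length(object@sd) && length(object@sd) != length(r))
    msg <- c(msg, "sd must match r in length")
  nz <- object@normalization
  if (!is.na(nz) && length(r) > 1) {
    area <- sum(object@p) * (r[2] - r[1])
    if (abs(area - nz) > 1e-6 * abs(nz))
      msg <- c(msg, "normalized area must equal the normalization constant")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Weighted ensemble selected by non-negative least squares
#'
#' @slot modelNumbers original frame numbers with strictly positive weight,
#'   ascending.
#' @slot weights the positive NNLS weights.
#' @slot percents 100 * w / sum(w); totals 100.
#' @slot nchi2 normalized chi-square of the fitted sum against the
#'   experimental curve.
#' @slot reconstructed [ScatteringCurve-class]: the weighted sum of the
#'   selected profiles, with propagated SDs when the inputs carry SDs.
#' @slot weightedRg ensemble radius of gyration,
#'   sqrt(sum(fraction_i * Rg_i^2)); NA when per-model Rg was not supplied.
#' @export
setClass("EnsembleFit",
  representation(modelNumbers = "integer", weights = "numeric",
                 percents = "numeric", nchi2 = "numeric",
                 reconstructed = "ScatteringCurve", weightedRg = "numeric"),
  prototype(weightedRg = NA_real_))

setValidity("EnsembleFit", function(object) {
  msg <- character()
  n <- length(object@modelNumbers)
  if (length(object@weights) != n || length(object@percents) != n)
    msg <- c(msg, "modelNumbers, weights and percents must agree in length")
  if (n) {
    if (any(object@weights <= 0))
      msg <- c(msg, "only strictly positive weights are retained")
    if (is.unsorted(object@modelNumbers, strictly = TRUE))
      msg <- c(msg, "model numbers must be sorted ascending")
    if (abs(sum(object@percents) - 100) > 1e-9)
      msg <- c(msg, "percents must sum to 100")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Monte Carlo sampler configuration
#'
#' @slot trialAttempts number of trial moves.
#' @slot maxAngle largest torsion change per move, degrees.
#' @slot temperature run temperature in Kelvin; inert unless a torsion
#'   energy callback is supplied to [runMC()] (selection pressure comes from
#'   the SAXS fit, not sampler energetics).
#' @slot returnAfterFails consecutive rejections before the working
#'   coordinates reset to the last accepted frame.
#' @slot overlapBasis atom subset for clash checks: heavy, backbone or all.
#' @slot alignRange IRanges residue range used to superpose accepted frames.
#' @slot seed RNG seed.
#' @export
setClass("MCConfig",
  representation(trialAttempts = "integer", maxAngle = "numeric",
                 temperature = "numeric", returnAfterFails = "integer",
                 overlapBasis = "character", alignRange = "IRanges",
                 seed = "integer"))

setValidity("MCConfig", function(object) {
  msg <- character()
  if (object@trialAttempts < 0) msg <- c(msg, "trialAttempts must be >= 0")
  if (object@maxAngle <= 0 || object@maxAngle > 180)
    msg <- c(msg, "maxAngle must be in (0, 180]")
  if (object@returnAfterFails < 1)
    msg <- c(msg, "returnAfterFails must be >= 1")
  if (!object@overlapBasis %in% c("heavy", "backbone", "all"))
    msg <- c(msg, "overlapBasis must be one of heavy, backbone, all")
  if (length(object@alignRange) != 1)
    msg <- c(msg, "alignRange must be a single residue range")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn MCConfig-class Constructor with the standard run defaults
#'   (50000 trials, 30 degree maximum move, 300 K, reset after 20 fails,
#'   heavy-atom overlap basis).
#' @param trialAttempts,maxAngle,temperature,returnAfterFails,overlapBasis,seed
#'   see slots.
#' @param alignRange residue range, either an IRanges or \code{c(start, end)}.
#' @export
mcConfig <- function(alignRange, trialAttempts = 50000L, maxAngle = 30,
                     temperature = 300, returnAfterFails = 20L,
                     overlapBasis = "heavy", seed = 1L) {
  new("MCConfig", trialAttempts = as.integer(trialAttempts),
      maxAngle = as.numeric(maxAngle), temperature = as.numeric(temperature),
      returnAfterFails = as.integer(returnAfterFails),
      overlapBasis = overlapBasis, alignRange = .as_range(alignRange),
      seed = as.integer(seed))
}

.as_range <- function(x) {
  if (is(x, "IRanges")) return(x)
  if (is.numeric(x) && length(x) == 2)
    return(IRanges(start = as.integer(x[1]), end = as.integer(x[2])))
  stop("expected an IRanges or a c(start, end) pair")
}

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat("ProteinStructure: ", nrow(a), " atoms, ",
      length(unique(a$resno)), " residues, chain ", object@chainId, "\n",
      sep = "")
  cat("  molecular mass: ", format(sum(a$mass), digits = 6), " Da\n", sep = "")
  if (nzchar(object@title)) cat("  title: ", object@title, "\n", sep = "")
})

setMethod("show", "ConformerPool", function(object) {
  cat("ConformerPool: ", length(object@modelNumbers), " frames (",
      length(object@acceptanceLog), " trials), ",
      nrow(object@template@atoms), " atoms each\n", sep = "")
  if (length(object@rg))
    cat("  Rg range: ", format(min(object@rg), digits = 4), " - ",
        format(max(object@rg), digits = 4), " Angstrom\n", sep = "")
})

setMethod("show", "ScatteringCurve", function(object) {
  cat("ScatteringCurve: ", length(object@q), " points, q in [",
      format(min(object@q)), ", ", format(max(object@q)), "] 1/Angstrom",
      if (length(object@sd)) ", with SDs" else "", "\n", sep = "")
})

setMethod("show", "PofR", function(object) {
  dr <- if (length(object@r) > 1) object@r[2] - object@r[1] else NA_real_
  cat("PofR: ", length(object@r), " bins of ", format(dr),
      " Angstrom", if (!is.na(object@normalization))
        paste0(", area normalized to ", format(object@normalization,
                                               digits = 6), " Da"),
      "\n", sep = "")
})

setMethod("show", "EnsembleFit", function(object) {
  cat("EnsembleFit: ", length(object@modelNumbers), " models, nchi2 = ",
      format(object@nchi2, digits = 4), "\n", sep = "")
  if (length(object@modelNumbers)) {
    df <- data.frame(model = object@modelNumbers,
                     percent = round(object@percents, 1))
    print(df, row.names = FALSE)
  }
})
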
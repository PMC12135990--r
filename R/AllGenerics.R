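#' Number of atoms
#' @param x a [ProteinStructure-class] or [ConformerPool-class]
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of residues
#' @param x a [ProteinStructure-class]
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Atom coordinates (n x 3 matrix, Angstrom)
#' @param x a [ProteinStructure-class]
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Replace atom coordinates
#' @param x a [ProteinStructure-class]
#' @param value n x 3 numeric matrix
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Atom table
#' @param x a [ProteinStructure-class]
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Molecular mass in Da (sum of atom masses)
#' @param x a [ProteinStructure-class] or [ConformerPool-class]
#' @export
setGeneric("molecularMass", function(x) standardGeneric("molecularMass"))

#' Per-residue confidence (0-100)
#'
#' Reduced from per-atom B-factors by taking each residue's first atom
#' (AlphaFold writes identical values across a residue).
#' @param x a [ProteinStructure-class]
#' @export
setGeneric("confidence", function(x) standardGeneric("confidence"))

#' Number of frames in a pool
#' @param x a [ConformerPool-class]
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Original model numbers of pool frames
#' @param x a [ConformerPool-class] or [EnsembleFit-class]
#' @export
setGeneric("modelNumbers", function(x) standardGeneric("modelNumbers"))

#' Extract one frame of a pool as a structure
#' @param x a [ConformerPool-class]
#' @param i frame position (1-based within the pool)
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Per-frame radius of gyration
#' @param x a [ConformerPool-class]
#' @export
setGeneric("poolRg", function(x) standardGeneric("poolRg"))

#' Acceptance log of the Monte Carlo run (one flag per trial)
#' @param x a [ConformerPool-class]
#' @export
setGeneric("acceptanceLog", function(x) standardGeneric("acceptanceLog"))

#' Curve abscissa and values
#' @param x a [ScatteringCurve-class] or [PofR-class]
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname qValues
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname qValues
#' @export
setGeneric("curveSd", function(x) standardGeneric("curveSd"))

#' @rdname qValues
#' @export
setGeneric("rValues", function(x) standardGeneric("rValues"))

#' @rdname qValues
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' Ensemble weights / percent contributions
#' @param x an [EnsembleFit-class]
#' @export
setGeneric("fitWeights", function(x) standardGeneric("fitWeights"))

#' @rdname fitWeights
#' @export
setGeneric("percents", function(x) standardGeneric("percents"))

#' @rdname fitWeights
#' @export
setGeneric("nChi2", function(x) standardGeneric("nChi2"))

#' @rdname fitWeights
#' @export
setGeneric("reconstructed", function(x) standardGeneric("reconstructed"))

setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))
setMethod("nAtoms", "ConformerPool", function(x) nrow(x@template@atoms))
setMethod("nResidues", "ProteinStructure",
          function(x) length(unique(x@atoms$resno)))
setMethod("coords", "ProteinStructure", function(x) x@xyz)
setMethod("coords<-", "ProteinStructure", function(x, value) {
  stopifnot(is.matrix(value), all(dim(value) == dim(x@xyz)))
  x@xyz <- value
  dimnames(x@xyz) <- list(NULL, c("x", "y", "z"))
  x
})
setMethod("atoms", "ProteinStructure", function(x) x@atoms)
setMethod("molecularMass", "ProteinStructure", function(x) sum(x@atoms$mass))
setMethod("molecularMass", "ConformerPool",
          function(x) molecularMass(x@template))
setMethod("confidence", "ProteinStructure", function(x) {
  first <- !duplicated(x@atoms$resno)
  setNames(x@atoms$confidence[first], x@atoms$resno[first])
})
setMethod("nFrames", "ConformerPool", function(x) length(x@modelNumbers))
setMethod("modelNumbers", "ConformerPool", function(x) x@modelNumbers)
setMethod("modelNumbers", "EnsembleFit", function(x) x@modelNumbers)
setMethod("getFrame", "ConformerPool", function(x, i) {
  stopifnot(length(i) == 1, i >= 1, i <= nFrames(x))
  s <- x@template
  s@xyz <- x@coords[, , i, drop = TRUE]
  dimnames(s@xyz) <- list(NULL, c("x", "y", "z"))
  s
})
setMethod("poolRg", "ConformerPool", function(x) x@rg)
setMethod("acceptanceLog", "ConformerPool", function(x) x@acceptanceLog)
setMethod("qValues", "ScatteringCurve", function(x) x@q)
setMethod("intensities", "ScatteringCurve", function(x) x@intensity)
setMethod("curveSd", "ScatteringCurve", function(x) x@sd)
setMethod("curveSd", "PofR", function(x) x@sd)
setMethod("rValues", "PofR", function(x) x@r)
setMethod("pValues", "PofR", function(x) x@p)
setMethod("fitWeights", "EnsembleFit", function(x) x@weights)
setMethod("percents", "EnsembleFit", function(x) x@percents)
setMethod("nChi2", "EnsembleFit", function(x) x@nchi2)
setMethod("reconstructed", "EnsembleFit", function(x) x@reconstructed)
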
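## Backbone torsion Monte Carlo: perturb phi/psi inside flexible regions,
## reject steric clashes, align accepted frames on a rigid residue range.

## Indices of atoms moved by a torsion, and the two axis atoms.
## phi(i):  axis N(i) -> CA(i); moves the full rigid subtree past CA:
##          all atoms of residue i except N, CA and amide hydrogens, plus
##          every atom of residues > i.
## psi(i):  axis CA(i) -> C(i); moves O (and OXT/HXT) of residue i plus
##          every atom of residues > i.
## Rotating whole subtrees conserves every bond length and 1-3 distance.
.torsion_spec <- function(struct, residue, angle) {
  a <- struct@atoms
  in_res <- which(a$resno == residue)
  nres <- max(a$resno)
  pick <- function(nm) {
    k <- in_res[a$name[in_res] == nm]
    if (!length(k)) stop("residue ", residue, " lacks atom ", nm)
    k[1]
  }
  if (angle == "phi") {
    if (residue == 1) stop("phi is undefined for residue 1")
    axis_from <- pick("N"); axis_to <- pick("CA")
    keep_fixed <- a$name[in_res] %in% c("N", "CA", "H", "HN", "H1", "H2", "H3")
    moved <- c(in_res[!keep_fixed], which(a$resno > residue))
  } else if (angle == "psi") {
    if (residue == nres) stop("psi is undefined for the last residue")
    axis_from <- pick("CA"); axis_to <- pick("C")
    moved_here <- a$name[in_res] %in% c("O", "OXT", "HXT")
    moved <- c(in_res[moved_here], which(a$resno > residue))
  } else stop("angle must be 'phi' or 'psi'")
  list(axis_from = axis_from, axis_to = axis_to, moved = sort(moved))
}

.apply_torsion_xyz <- function(xyz, spec, delta_deg) {
  if (delta_deg == 0) return(xyz)
  origin <- xyz[spec$axis_from, ]
  axis <- xyz[spec$axis_to, ] - origin
  xyz[spec$moved, ] <- .rotate_about_axis(xyz[spec$moved, , drop = FALSE],
                                          origin, axis, .deg2rad(delta_deg))
  xyz
}

#' Rotate one backbone torsion
#'
#' Rigidly rotates the full downstream subtree about the phi (N-CA) or psi
#' (CA-C) bond of a residue by \code{delta} degrees, following the N-to-C
#' directional convention.  All other atoms are untouched; interatomic
#' distances within the moved set are preserved to machine precision.
#'
#' @param structure a [ProteinStructure-class].
#' @param residue 1-based residue index (phi undefined for residue 1, psi
#'   for the last residue).
#' @param angle \code{"phi"} or \code{"psi"}.
#' @param delta rotation in degrees.
#' @return The rotated [ProteinStructure-class].
#' @export
applyTorsion <- function(structure, residue, angle, delta) {
  spec <- .torsion_spec(structure, residue, angle)
  structure@xyz <- .apply_torsion_xyz(structure@xyz, spec, delta)
  structure
}

## Atom subset selected by an overlap basis.
.basis_indices <- function(struct, basis) {
  a <- struct@atoms
  heavy <- toupper(a$element) != "H"
  idx <- switch(basis,
    heavy = which(heavy),
    backbone = which(heavy & a$name %in% c("N", "CA", "C", "O", "OXT")),
    all = {
      if (all(heavy))
        stop("overlap basis 'all' requires hydrogen atoms in the structure")
      seq_len(nrow(a))
    },
    stop("unknown overlap basis: ", basis))
  if (!length(idx)) stop("overlap basis selects no atoms")
  idx
}

#' Steric clash check
#'
#' Flags a clash when any pair of selected atoms in different residues and
#' separated by at least 3 covalent bonds sits closer than the cutoff.  The
#' default cutoff is 0.8 x the sum of the two van der Waals radii
#' (strictly less than; a pair exactly at the cutoff is not a clash).
#'
#' @param structure a [ProteinStructure-class].
#' @param basis \code{"heavy"} (default), \code{"backbone"} or \code{"all"}
#'   (the latter only for structures with hydrogens).
#' @param cutoff either \code{"vdw"} (scaled van der Waals, default) or a
#'   single distance in Angstrom applied to every pair.
#' @param exclusion optional precomputed exclusion matrix (internal reuse).
#' @return \code{TRUE} if any clash exists.
#' @export
checkOverlap <- function(structure, basis = "heavy", cutoff = "vdw",
                         exclusion = NULL) {
  idx <- .basis_indices(structure, basis)
  if (is.null(exclusion)) exclusion <- .exclusion_matrix(structure)
  .clash_xyz(structure@xyz, structure@atoms, idx, exclusion, cutoff)
}

.clash_xyz <- function(xyz, atoms, idx, exclusion, cutoff = "vdw") {
  sub <- xyz[idx, , drop = FALSE]
  d <- as.matrix(dist(sub))
  if (identical(cutoff, "vdw")) {
    r <- .lookup_element(atoms$element[idx])$vdw
    lim <- 0.8 * outer(r, r, "+")
  } else {
    lim <- matrix(cutoff, length(idx), length(idx))
  }
  close_pair <- d < lim
  same_res <- outer(atoms$resno[idx], atoms$resno[idx], "==")
  close_pair[same_res] <- FALSE
  close_pair[exclusion[idx, idx]] <- FALSE
  any(close_pair)
}

#' Rigid-body superposition on a residue range
#'
#' Least-squares superposition (rotation + translation, no reflection) of
#' the mobile structure onto the reference, fitted on the CA atoms of
#' \code{alignRange}.
#'
#' @param mobile,reference [ProteinStructure-class] objects sharing atom
#'   ordering.
#' @param alignRange residue range (IRanges or \code{c(start, end)}).
#' @return list with the aligned \code{structure} and the \code{rmsd}
#'   (Angstrom, over the fitted CA atoms).
#' @export
superpose <- function(mobile, reference, alignRange) {
  ar <- .as_range(alignRange)
  a <- reference@atoms
  fit_idx <- which(a$name == "CA" & a$resno >= start(ar) &
                   a$resno <= end(ar))
  if (length(fit_idx) < 3)
    stop("fewer than 3 CA atoms in alignment range ",
         start(ar), "-", end(ar))
  res <- .kabsch_fit(mobile@xyz, reference@xyz, fit_idx)
  mobile@xyz <- res$xyz
  dimnames(mobile@xyz) <- list(NULL, c("x", "y", "z"))
  list(structure = mobile, rmsd = res$rmsd)
}

#' Monte Carlo conformer generation
#'
#' Runs \code{trialAttempts} torsion trials.  Each trial draws, from the
#' seeded generator, one residue uniformly from the flexible regions, one
#' of phi/psi, and a rotation uniform in \code{[-maxAngle, +maxAngle]}
#' degrees.  The trial structure is accepted iff it is clash-free under the
#' configured overlap basis; accepted structures are superposed on the
#' starting structure over \code{alignRange} and stored as frames whose
#' model number is the 1-based trial index.  Rejected trials keep walking
#' from the rejected coordinates; after \code{returnAfterFails} consecutive
#' rejections the working coordinates reset to the last accepted frame.
#' A draw of a torsion undefined at a chain terminus counts as a rejected
#' trial.  Identical seeds give bit-identical pools.
#'
#' Acceptance is purely steric (hard-sphere).  The configured temperature
#' is inert unless \code{energyFn} is supplied, in which case trials are
#' additionally filtered by a Metropolis test at that temperature;
#' selection pressure in this pipeline comes from the SAXS fit, not from
#' sampler energetics.
#'
#' @param structure starting [ProteinStructure-class].
#' @param regions flexible regions (\code{IRanges}), non-empty.
#' @param config an [MCConfig-class] from [mcConfig()].
#' @param energyFn optional \code{function(structure) -> kcal/mol} torsion
#'   energy callback enabling Metropolis acceptance.
#' @return A [ConformerPool-class].
#' @export
runMC <- function(structure, regions, config, energyFn = NULL) {
  if (!length(regions)) stop("no flexible regions to sample")
  nres <- nResidues(structure)
  validateAlignmentRange(regions, config@alignRange, nres)
  flex_res <- unlist(lapply(seq_along(regions), function(k)
    seq(start(regions)[k], end(regions)[k])))
  set.seed(config@seed)
  ## precompute torsion specs and exclusion topology once
  specs <- list()
  for (res in flex_res) for (ang in c("phi", "psi")) {
    key <- paste0(ang, res)
    specs[[key]] <- tryCatch(.torsion_spec(structure, res, ang),
                             error = function(e) NULL)
  }
  excl <- .exclusion_matrix(structure)
  basis_idx <- .basis_indices(structure, config@overlapBasis)
  atoms <- structure@atoms
  ## flatten the clash test to the dist() pair ordering once: per trial we
  ## then only need the pair distances and one vectorized comparison
  m <- length(basis_idx)
  pair_i <- rep(seq_len(m - 1), times = (m - 1):1)
  pair_j <- unlist(lapply(seq_len(m - 1), function(i) (i + 1):m))
  res_sub <- atoms$resno[basis_idx]
  excl_sub <- excl[basis_idx, basis_idx]
  keep_pair <- res_sub[pair_i] != res_sub[pair_j] &
    !excl_sub[cbind(pair_i, pair_j)]
  rv <- .lookup_element(atoms$element[basis_idx])$vdw
  limv <- (0.8 * (rv[pair_i] + rv[pair_j]))[keep_pair]
  clash_fast <- function(xyz) {
    dv <- dist(xyz[basis_idx, , drop = FALSE])
    any(dv[keep_pair] < limv)
  }
  kB <- 0.0019872041                       # kcal / (mol K)
  n_trials <- config@trialAttempts
  accepted <- logical(n_trials)
  frames <- vector("list", n_trials)
  working <- structure@xyz
  last_accepted <- structure@xyz
  e_last <- if (!is.null(energyFn)) energyFn(structure) else 0
  fails <- 0L
  ref <- structure
  for (t in seq_len(n_trials)) {
    res <- flex_res[sample.int(length(flex_res), 1)]
    ang <- c("phi", "psi")[sample.int(2, 1)]
    delta <- runif(1, -config@maxAngle, config@maxAngle)
    spec <- specs[[paste0(ang, res)]]
    ok <- FALSE
    if (!is.null(spec)) {
      trial <- .apply_torsion_xyz(working, spec, delta)
      ok <- !clash_fast(trial)
      if (ok && !is.null(energyFn)) {
        s_trial <- structure; s_trial@xyz <- trial
        e_trial <- energyFn(s_trial)
        if (e_trial > e_last &&
            runif(1) >= exp(-(e_trial - e_last) / (kB * config@temperature)))
          ok <- FALSE
        e_last <- e_trial
      }
      working <- trial                     # walk continues from the trial
    }
    if (ok) {
      accepted[t] <- TRUE
      last_accepted <- working
      fails <- 0L
      aligned <- .kabsch_fit(working, ref@xyz, .ca_idx(atoms, config@alignRange))
      frames[[t]] <- aligned$xyz
    } else {
      fails <- fails + 1L
      if (fails >= config@returnAfterFails) {
        working <- last_accepted
        fails <- 0L
      }
    }
  }
  keep <- which(accepted)
  n <- nrow(atoms)
  coords <- array(NA_real_, dim = c(n, 3, length(keep)))
  for (k in seq_along(keep)) coords[, , k] <- frames[[keep[k]]]
  z <- atoms$electrons
  rg <- if (length(keep))
    apply(coords, 3, function(m) .rg_xyz(m, z)) else numeric()
  new("ConformerPool", template = structure, coords = coords,
      modelNumbers = as.integer(keep), rg = rg, acceptanceLog = accepted)
}

.ca_idx <- function(atoms, range) {
  which(atoms$name == "CA" & atoms$resno >= start(range) &
        atoms$resno <= end(range))
}
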
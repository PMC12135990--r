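#' Build a synthetic two-domain poly-alanine chain
#'
#' Constructs a single-chain poly-alanine backbone (N, CA, C, O, CB per
#' residue) with ideal geometry (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O
#' 1.231, CA-CB 1.521 Angstrom; trans peptide, extended beta-like
#' phi/psi = -139/135 degrees), emulating a predicted two-domain protein
#' joined by a flexible linker: domain residues carry
#' \code{domainConfidence}, linker residues \code{linkerConfidence} in the
#' confidence (B-factor) field.  Glycine-free, so every non-terminal
#' residue has both phi and psi defined.  The chain is clash-free under
#' the default overlap basis, making it a valid Monte Carlo start.
#'
#' @param nDomain1,nLinker,nDomain2 residue counts, all >= 1.
#' @param domainConfidence,linkerConfidence per-residue confidence values
#'   (0-100) written for domain and linker residues; defaults 90 and 40.
#' @param phi,psi backbone torsions in degrees applied throughout.
#' @return A [ProteinStructure-class].
#' @examples
#' toy <- buildToyChain(20, 10, 20)
#' nResidues(toy)                                    # 50
#' detectFlexibleRegions(confidence(toy), 60)        # 21-30
#' @export
buildToyChain <- function(nDomain1 = 20, nLinker = 10, nDomain2 = 20,
                          domainConfidence = 90, linkerConfidence = 40,
                          phi = -139, psi = 135) {
  stopifnot(nDomain1 >= 1, nLinker >= 1, nDomain2 >= 1)
  nres <- nDomain1 + nLinker + nDomain2
  b <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ca_cb = 1.521)
  ang <- list(n_ca_c = 111.0, ca_c_n = 116.2, c_n_ca = 121.7,
              ca_c_o = 120.5, c_ca_cb = 110.1)
  conf <- c(rep(domainConfidence, nDomain1), rep(linkerConfidence, nLinker),
            rep(domainConfidence, nDomain2))
  ## backbone trace by internal-coordinate chaining
  N <- CA <- CC <- matrix(NA_real_, nres, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b$n_ca, 0, 0)
  th <- .deg2rad(ang$n_ca_c)
  CC[1, ] <- CA[1, ] + b$ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:nres) {
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], CC[i - 1, ],
                          b$c_n, ang$ca_c_n, psi)
    CA[i, ] <- .place_atom(CA[i - 1, ], CC[i - 1, ], N[i, ],
                           b$n_ca, ang$c_n_ca, 180)       # trans omega
    CC[i, ] <- .place_atom(CC[i - 1, ], N[i, ], CA[i, ],
                           b$ca_c, ang$n_ca_c, phi)
  }
  atoms <- NULL; xyz <- NULL
  for (i in seq_len(nres)) {
    ## O anti to the next N across the carbonyl (torsion N-CA-C-O = psi+180)
    O <- .place_atom(N[i, ], CA[i, ], CC[i, ], b$c_o, ang$ca_c_o, psi + 180)
    ## CB by the improper torsion N-C-CA-CB, fixing L-chirality
    CB <- .place_atom(N[i, ], CC[i, ], CA[i, ], b$ca_cb, ang$c_ca_cb, 122.55)
    xyz <- rbind(xyz, N[i, ], CA[i, ], CC[i, ], O, CB)
    atoms <- rbind(atoms, data.frame(
      name = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      resno = i, resid = "ALA", confidence = conf[i],
      stringsAsFactors = FALSE))
  }
  const <- .lookup_element(atoms$element)
  atoms$electrons <- const$electrons
  atoms$mass <- const$mass
  atoms <- atoms[, c("name", "element", "electrons", "mass", "resno",
                     "resid", "confidence")]
  .new_structure(atoms, xyz, chainId = "A",
                 title = "synthetic two-domain poly-alanine chain",
                 source = "buildToyChain")
}

#' Pick well-separated conformers from a pool
#'
#' Mixture-recovery experiments need conformers whose scattering profiles
#' are distinguishable; similarity in Rg alone does not guarantee that.
#' This selects \code{m} frames by greedy farthest-point sampling on
#' unit-normalized I(q) profiles: start from the most distant profile
#' pair, then repeatedly add the frame maximizing the minimum distance to
#' the already-selected set.
#'
#' @param pool a [ConformerPool-class].
#' @param qGrid q values used to compute the candidate profiles.
#' @param m number of conformers to select.
#' @param candidateStride only every candidateStride-th frame is
#'   considered (profile computation cost control), default 5.
#' @return Sorted original model numbers of the selected frames.
#' @export
pickSeparatedModels <- function(pool, qGrid, m = 5, candidateStride = 5) {
  stopifnot(m >= 2, nFrames(pool) >= m)
  cand <- seq(1, nFrames(pool), by = candidateStride)
  if (length(cand) < m) cand <- seq_len(nFrames(pool))
  P <- vapply(cand, function(k)
    computeIqDebye(getFrame(pool, k), qGrid)@intensity,
    numeric(length(qGrid)))
  Pn <- sweep(P, 2, sqrt(colSums(P^2)), "/")
  D <- as.matrix(dist(t(Pn)))
  sel <- as.vector(which(D == max(D), arr.ind = TRUE)[1, ])
  while (length(sel) < m)
    sel <- c(sel, which.max(apply(D[, sel, drop = FALSE], 1, min)))
  sort(pool@modelNumbers[cand[sel]])
}

#' Synthesize an experimental-style I(q)/P(r) pair from known weights
#'
#' Mixes the Debye I(q) and mass-normalized P(r) of chosen pool conformers
#' with given weights, then applies multiplicative Gaussian noise:
#' \eqn{I_{exp}(q) = \sum w_i I_i(q) (1 + \epsilon(q))},
#' \eqn{\epsilon \sim N(0, noise^2)} from the seeded generator.  The SD
#' columns equal \code{noiseFraction * I} (the applied noise scale), so
#' 1/SD-weighted fitting is exercised honestly; with zero noise the curves
#' carry no SD columns.  Ground truth in, recovery out: the generating
#' weights are exactly recoverable by [nnlsSelect()] in the noiseless case.
#'
#' @param pool a [ConformerPool-class].
#' @param models original model numbers of the generating conformers.
#' @param weights true mixture weights, non-negative, summing to 1.
#' @param qGrid q values for the I(q) curve (inverse Angstrom).
#' @param noiseFraction relative SD of the multiplicative noise, >= 0.
#' @param seed RNG seed for the noise draws.
#' @return list with \code{iq} ([ScatteringCurve-class]), \code{pr}
#'   ([PofR-class]), and the per-model \code{iqProfiles}/\code{prProfiles}
#'   matrices used to build them.
#' @export
makeSyntheticExperiment <- function(pool, models, weights, qGrid,
                                    noiseFraction = 0, seed = 1) {
  stopifnot(length(models) == length(weights), all(weights >= 0),
            noiseFraction >= 0)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("true weights must sum to 1")
  pos <- match(models, pool@modelNumbers)
  if (anyNA(pos))
    stop("models not in pool: ",
         paste(models[is.na(pos)], collapse = ", "))
  iq_cols <- vapply(pos, function(p)
    computeIqDebye(getFrame(pool, p), qGrid)@intensity,
    numeric(length(qGrid)))
  prs <- lapply(pos, function(p) computePr(getFrame(pool, p)))
  rmax <- max(vapply(prs, function(x) length(x@r), integer(1)))
  pr_cols <- vapply(prs, function(x) c(x@p, rep(0, rmax - length(x@p))),
                    numeric(rmax))
  r <- (seq_len(rmax) - 1) * 1.0
  iq_true <- as.vector(iq_cols %*% weights)
  pr_true <- as.vector(pr_cols %*% weights)
  set.seed(seed)
  if (noiseFraction > 0) {
    iq_val <- iq_true * (1 + rnorm(length(iq_true), 0, noiseFraction))
    pr_val <- pmax(pr_true * (1 + rnorm(length(pr_true), 0, noiseFraction)), 0)
    iq <- new("ScatteringCurve", q = qGrid, intensity = iq_val,
              sd = noiseFraction * pmax(iq_true, 1e-12))
    pr <- new("PofR", r = r, p = pr_val,
              sd = noiseFraction * pmax(pr_true, 1e-12),
              normalization = NA_real_)
  } else {
    iq <- new("ScatteringCurve", q = qGrid, intensity = iq_true)
    pr <- new("PofR", r = r, p = pr_true, normalization = NA_real_)
  }
  list(iq = iq, pr = pr, iqProfiles = iq_cols, prProfiles = pr_cols,
       r = r)
}
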
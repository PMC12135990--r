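# Shared fixtures, built in code at test time.

# A random rigid "structure": n atoms with protein-ish elements in a box.
random_structure <- function(n, seed = 1, box = 20) {
  set.seed(seed)
  el <- sample(c("C", "N", "O", "S"), n, replace = TRUE,
               prob = c(0.6, 0.2, 0.15, 0.05))
  tab <- data.frame(element = c("C", "N", "O", "S"),
                    electrons = c(6L, 7L, 8L, 16L),
                    mass = c(12.011, 14.007, 15.999, 32.06))
  k <- match(el, tab$element)
  atoms <- data.frame(name = el, element = el,
                      electrons = tab$electrons[k], mass = tab$mass[k],
                      resno = seq_len(n), resid = "UNK",
                      confidence = 0, stringsAsFactors = FALSE)
  xyz <- matrix(runif(3 * n, 0, box), ncol = 3)
  new("ProteinStructure", atoms = atoms, xyz = xyz, chainId = "A",
      title = "", source = "random_structure")
}

# Two-residue hand-written PDB content (alanine dipeptide backbone).
two_residue_pdb <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 91.50           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 91.50           C",
    "ATOM      3  C   ALA A   1       2.005   1.423   0.000  1.00 91.50           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.100  1.00 91.50           O",
    "ATOM      5  N   ALA A   2       3.330   1.536   0.000  1.00 45.25           N",
    "ATOM      6  CA  ALA A   2       4.050   2.800   0.050  1.00 45.25           C",
    "ATOM      7  C   ALA A   2       5.540   2.600   0.150  1.00 45.25           C",
    "ATOM      8  O   ALA A   2       6.050   1.480   0.200  1.00 45.25           O",
    "END")
}

# The same two residues as mmCIF.
two_residue_cif <- function() {
  hdr <- c("data_toy", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  at <- .parse_pdb_fixture(two_residue_pdb())
  rows <- sprintf(
    "ATOM %d %s %s . ALA A 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d ALA A %s 1",
    seq_len(nrow(at)), at$el, at$name, at$resno, at$x, at$y, at$z, at$b,
    at$resno, at$name)
  c(hdr, rows)
}

.parse_pdb_fixture <- function(lines) {
  rec <- lines[startsWith(lines, "ATOM")]
  data.frame(name = trimws(substr(rec, 13, 16)),
             resno = as.integer(substr(rec, 23, 26)),
             x = as.numeric(substr(rec, 31, 38)),
             y = as.numeric(substr(rec, 39, 46)),
             z = as.numeric(substr(rec, 47, 54)),
             b = as.numeric(substr(rec, 61, 66)),
             el = trimws(substr(rec, 77, 78)),
             stringsAsFactors = FALSE)
}

# Independent Kabsch oracle: Horn's quaternion method (closed-form optimal
# rotation via the eigen-decomposition of the 4x4 key matrix), entirely
# separate from the package's SVD route.
quaternion_superpose_rmsd <- function(mobile, reference) {
  pm <- sweep(mobile, 2, colMeans(mobile))
  pr <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(pm, pr)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(pm^2) + sum(pr^2) - 2 * lam) / nrow(pm)
  sqrt(max(msd, 0))
}

# Exhaustive NNLS oracle: best feasible solution over all active subsets.
enumerate_nnls <- function(A, b) {
  m <- ncol(A)
  best <- list(x = numeric(m), dev = sum(b^2))
  for (k in seq_len(2^m - 1)) {
    sub <- which(bitwAnd(k, 2^(seq_len(m) - 1)) > 0)
    cf <- tryCatch(qr.coef(qr(A[, sub, drop = FALSE]), b),
                   error = function(e) NULL)
    if (is.null(cf) || anyNA(cf) || any(cf < 0)) next
    x <- numeric(m); x[sub] <- cf
    dev <- sum((b - A %*% x)^2)
    if (dev < best$dev - 1e-12) best <- list(x = x, dev = dev)
  }
  best
}

# Write a pool's single starting frame as a PDB file (pipeline input).
write_single_model <- function(structure, path) {
  pool <- new("ConformerPool", template = structure,
              coords = array(coords(structure),
                             c(nAtoms(structure), 3, 1)),
              modelNumbers = 1L, rg = rgFromCoords(structure),
              acceptanceLog = TRUE)
  writeMultimodelPDB(pool, path)
  path
}

# Bond and 1-3 (angle) distances of a poly-alanine toy chain, computed
# from explicit topology (independent of the package's bond inference).
toy_internal_distances <- function(xyz, nres) {
  idx <- function(res, at) (res - 1) * 5 + match(at, c("N","CA","C","O","CB"))
  pairs <- NULL
  for (r in seq_len(nres)) {
    pairs <- rbind(pairs,
      cbind(idx(r,"N"), idx(r,"CA")), cbind(idx(r,"CA"), idx(r,"C")),
      cbind(idx(r,"C"), idx(r,"O")), cbind(idx(r,"CA"), idx(r,"CB")),
      # 1-3 within residue
      cbind(idx(r,"N"), idx(r,"C")), cbind(idx(r,"N"), idx(r,"CB")),
      cbind(idx(r,"C"), idx(r,"CB")), cbind(idx(r,"CA"), idx(r,"O")))
    if (r < nres) {
      pairs <- rbind(pairs,
        cbind(idx(r,"C"), idx(r+1,"N")),          # peptide bond
        cbind(idx(r,"CA"), idx(r+1,"N")),         # 1-3 across the bond
        cbind(idx(r,"O"), idx(r+1,"N")),
        cbind(idx(r,"C"), idx(r+1,"CA")))
    }
  }
  sqrt(rowSums((xyz[pairs[,1], , drop=FALSE] - xyz[pairs[,2], , drop=FALSE])^2))
}
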
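## Internal 3D geometry helpers shared by the toy-chain builder and the
## Monte Carlo torsion sampler.  All coordinates in Angstrom, angles in
## degrees at the interfaces, radians internally.

.deg2rad <- function(x) x * pi / 180

## Place atom D given positions of A, B, C and internal coordinates:
## |CD| = bond, angle(B,C,D) = ang (deg), torsion(A,B,C,D) = tor (deg).
## Standard natural-extension-reference-frame construction.
.place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- .deg2rad(ang); tor <- .deg2rad(tor)
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross(n, bc)
  rot <- cbind(bc, m, n)
  c + as.vector(rot %*% d_local)
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Rotate points (n x 3) by `theta` radians about the axis through `origin`
## with unit direction `axis`, using the Rodrigues formula.
.rotate_about_axis <- function(xyz, origin, axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  p <- sweep(xyz, 2, origin)
  ct <- cos(theta); st <- sin(theta)
  kx <- p %*% k                               # component along axis
  cross <- cbind(k[2] * p[, 3] - k[3] * p[, 2],
                 k[3] * p[, 1] - k[1] * p[, 3],
                 k[1] * p[, 2] - k[2] * p[, 1])
  rot <- p * ct + cross * st + outer(as.vector(kx), k) * (1 - ct)
  sweep(rot, 2, origin, "+")
}

## Dihedral angle (degrees, in (-180, 180]) defined by four points.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

## Covalent bond list inferred from the template coordinates by a distance
## criterion (heavy-heavy < 1.9 A, any pair involving H < 1.3 A), restricted
## to atoms in the same or adjacent residues.  Returns a 2-column index
## matrix.  Used once per topology; conformational change never alters it
## because torsion moves conserve bonded geometry.
.bond_list <- function(struct) {
  a <- struct@atoms
  xyz <- struct@xyz
  n <- nrow(a)
  is_h <- toupper(a$element) == "H"
  pairs <- NULL
  ## candidate pairs: same or adjacent residue only (protein chains have no
  ## covalent bonds spanning > 1 residue apart except disulfides, which the
  ## torsion sampler does not support anyway)
  for (shift in 0:1) {
    res_i <- unique(a$resno)
    for (r in res_i) {
      i_idx <- which(a$resno == r)
      j_idx <- which(a$resno == r + shift)
      if (!length(j_idx)) next
      grid <- expand.grid(i = i_idx, j = j_idx)
      grid <- grid[grid$i < grid$j, , drop = FALSE]
      if (!nrow(grid)) next
      d <- sqrt(rowSums((xyz[grid$i, , drop = FALSE] -
                         xyz[grid$j, , drop = FALSE])^2))
      cut <- ifelse(is_h[grid$i] | is_h[grid$j], 1.3, 1.9)
      keep <- d < cut
      if (any(keep))
        pairs <- rbind(pairs, cbind(grid$i[keep], grid$j[keep]))
    }
  }
  if (is.null(pairs)) pairs <- matrix(integer(), ncol = 2)
  pairs
}

## Pairs of atoms separated by fewer than 3 bonds (1-2 and 1-3 neighbours),
## as a logical exclusion matrix including the diagonal.  Same-residue pairs
## are additionally excluded by the overlap check itself.
.exclusion_matrix <- function(struct) {
  n <- nrow(struct@atoms)
  excl <- diag(n) > 0
  bonds <- .bond_list(struct)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    excl[i, j] <- excl[j, i] <- TRUE
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  ## 1-3: two bonds via a shared neighbour
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) > 1) {
      for (a in nb) for (b in nb) if (a != b) excl[a, b] <- excl[b, a] <- TRUE
    }
  }
  excl
}

## Least-squares rigid superposition (Kabsch, SVD route with reflection
## guard).  Returns the transformed mobile coordinates and the RMSD over
## the fitted atom subset.
.kabsch_fit <- function(mobile, reference, fit_idx) {
  pm <- mobile[fit_idx, , drop = FALSE]
  pr <- reference[fit_idx, , drop = FALSE]
  cm <- colMeans(pm); cr <- colMeans(pr)
  h <- crossprod(sweep(pm, 2, cm), sweep(pr, 2, cr))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- sweep(sweep(mobile, 2, cm) %*% t(rot), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((moved[fit_idx, , drop = FALSE] - pr)^2)))
  list(xyz = moved, rmsd = rmsd)
}
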
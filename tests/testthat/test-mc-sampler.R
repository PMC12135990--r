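test_that("torsion moves are identity at 0, invertible, and match a rotation-matrix oracle", {
  toy <- buildToyChain(5, 5, 5)
  expect_equal(coords(applyTorsion(toy, 8, "phi", 0)), coords(toy))
  t1 <- applyTorsion(toy, 8, "psi", 30)
  t2 <- applyTorsion(t1, 8, "psi", -30)
  expect_lt(max(abs(coords(t2) - coords(toy))), 1e-9)

  # independent Rodrigues oracle for an arbitrary move
  delta <- 47.3
  res <- 7
  a <- atoms(toy)
  iN <- which(a$resno == res & a$name == "N")
  iCA <- which(a$resno == res & a$name == "CA")
  moved_idx <- c(which(a$resno == res & !a$name %in% c("N", "CA")),
                 which(a$resno > res))
  p0 <- coords(toy)
  k <- p0[iCA, ] - p0[iN, ]; k <- k / sqrt(sum(k^2))
  th <- delta * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  expected <- p0
  expected[moved_idx, ] <- sweep(sweep(p0[moved_idx, ], 2, p0[iN, ]) %*% t(R),
                                 2, p0[iN, ], "+")
  got <- coords(applyTorsion(toy, res, "phi", delta))
  expect_lt(max(abs(got - expected)), 1e-10)
  # pairwise distances within the moved set are preserved
  expect_lt(max(abs(dist(got[moved_idx, ]) - dist(p0[moved_idx, ]))), 1e-9)
  # untouched atoms are bit-identical
  fixed <- setdiff(seq_len(nAtoms(toy)), moved_idx)
  expect_identical(got[fixed, ], p0[fixed, ])
})

test_that("torsions undefined at the termini are an error", {
  toy <- buildToyChain(3, 5, 3)
  expect_error(applyTorsion(toy, 1, "phi", 10), "undefined")
  expect_error(applyTorsion(toy, nResidues(toy), "psi", 10), "undefined")
})

test_that("overlap check honours exclusions, strict cutoff and basis rules", {
  s <- random_structure(6, seed = 2)
  # plant two far-apart residues then collide them
  xyz <- coords(s)
  xyz[1, ] <- c(0, 0, 0); xyz[6, ] <- c(1, 0, 0)
  coords(s) <- xyz
  expect_true(checkOverlap(s, cutoff = 2))
  # exact cutoff is not a clash (strict <)
  xyz[6, ] <- c(2, 0, 0); coords(s) <- xyz
  d <- as.matrix(dist(coords(s)))
  if (all(d[upper.tri(d)] >= 2)) expect_false(checkOverlap(s, cutoff = 2))
  # bonded neighbours are excluded: a 1.33 A peptide bond never clashes
  toy <- buildToyChain(3, 5, 3)
  expect_false(checkOverlap(toy, cutoff = 1.6))
  # basis "all" requires hydrogens
  expect_error(checkOverlap(toy, basis = "all"), "hydrogen")
})

test_that("superposition is exact on self, recovers known transforms, and matches a quaternion oracle", {
  toy <- buildToyChain(6, 5, 6)
  sp <- superpose(toy, toy, c(1, 6))
  expect_lt(sp$rmsd, 1e-12)

  # known rotation + translation is undone
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- toy
  coords(moved) <- sweep(coords(toy) %*% t(R), 2, c(5, -3, 11), "+")
  sp2 <- superpose(moved, toy, c(1, 17))
  expect_lt(sp2$rmsd, 1e-9)
  expect_lt(max(abs(coords(sp2$structure) - coords(toy))), 1e-8)

  # perturbed coordinates: rmsd equals the closed-form quaternion solution
  set.seed(5)
  pert <- toy
  coords(pert) <- coords(toy) + matrix(rnorm(3 * nAtoms(toy), 0, 0.3),
                                       ncol = 3)
  ar <- c(1, 17)
  a <- atoms(toy)
  ca <- which(a$name == "CA" & a$resno >= ar[1] & a$resno <= ar[2])
  sp3 <- superpose(pert, toy, ar)
  expect_equal(sp3$rmsd,
               quaternion_superpose_rmsd(coords(pert)[ca, ],
                                         coords(toy)[ca, ]),
               tolerance = 1e-10)
  expect_error(superpose(toy, toy, c(2, 3)), "fewer than 3")
})

test_that("the sampler is seed-deterministic, bounded, and conserves rigid geometry", {
  toy <- buildToyChain(8, 6, 8)
  regions <- detectFlexibleRegions(confidence(toy), 60)
  cfg <- mcConfig(alignRange = c(1, 8), trialAttempts = 200, seed = 31)
  pool1 <- runMC(toy, regions, cfg)
  pool2 <- runMC(toy, regions, cfg)
  expect_identical(acceptanceLog(pool1), acceptanceLog(pool2))
  expect_identical(pool1@coords, pool2@coords)
  expect_lte(nFrames(pool1), 200)
  expect_equal(length(acceptanceLog(pool1)), 200)
  expect_identical(modelNumbers(pool1), which(acceptanceLog(pool1)))

  # every accepted frame is clash-free and keeps bonds and 1-3 distances
  ref_d <- toy_internal_distances(coords(toy), nResidues(toy))
  for (i in seq_len(nFrames(pool1))) {
    fr <- getFrame(pool1, i)
    expect_false(checkOverlap(fr))
    expect_lt(max(abs(toy_internal_distances(coords(fr), nResidues(toy)) -
                      ref_d)), 1e-8)
  }
  # sampling actually moves the structure
  expect_gt(sd(poolRg(pool1)), 0)
})

test_that("zero trials give a valid empty pool and missing regions fail", {
  toy <- buildToyChain(5, 5, 5)
  regions <- detectFlexibleRegions(confidence(toy), 60)
  pool <- runMC(toy, regions, mcConfig(alignRange = c(1, 5),
                                       trialAttempts = 0, seed = 1))
  expect_equal(nFrames(pool), 0)
  expect_equal(length(acceptanceLog(pool)), 0)
  expect_error(runMC(toy, IRanges::IRanges(),
                     mcConfig(alignRange = c(1, 5), trialAttempts = 5)),
               "no flexible regions")
  # aligning on a flexible region is refused
  expect_error(runMC(toy, regions,
                     mcConfig(alignRange = c(6, 10), trialAttempts = 5)),
               "overlaps")
})
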
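test_that("a hand-written PDB parses with atoms in file order and B-factor confidence", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(two_residue_pdb(), f)
  s <- readStructure(f)
  expect_s4_class(s, "ProteinStructure")
  expect_equal(nResidues(s), 2)
  expect_equal(atoms(s)$name, rep(c("N", "CA", "C", "O"), 2))
  expect_equal(unname(confidence(s)), c(91.5, 45.25))
  expect_equal(coords(s)[2, ], c(1.458, 0, 0), ignore_attr = TRUE)
  expect_equal(molecularMass(s), sum(atoms(s)$mass))
  # element-derived constants
  expect_equal(atoms(s)$electrons, rep(c(7L, 6L, 6L, 8L), 2))
})

test_that("the same content read as mmCIF matches the PDB route", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  writeLines(two_residue_pdb(), fp)
  writeLines(two_residue_cif(), fc)
  sp <- readStructure(fp)
  sc <- readStructure(fc)
  expect_equal(nAtoms(sc), nAtoms(sp))
  expect_equal(atoms(sc)$name, atoms(sp)$name)
  expect_equal(atoms(sc)$resno, atoms(sp)$resno)
  expect_lt(max(abs(coords(sc) - coords(sp))), 1e-3)
  expect_equal(unname(confidence(sc)), unname(confidence(sp)))
})

test_that("multi-chain files are rejected naming the chains", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- two_residue_pdb()
  lines[5:8] <- sub("ALA A", "ALA B", lines[5:8], fixed = TRUE)
  writeLines(lines, f)
  expect_error(readStructure(f), "A, B")
})

test_that("unknown elements are an error, not a silent default", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- two_residue_pdb()
  lines[1] <- paste0(substr(lines[1], 1, 76), "XX")
  writeLines(lines, f)
  expect_error(readStructure(f), "unknown element")
})

test_that("multi-model PDB write/read round trip preserves everything to format precision", {
  toy <- buildToyChain(6, 5, 6)
  cfg <- mcConfig(alignRange = c(1, 6), trialAttempts = 60, seed = 4)
  pool <- runMC(toy, detectFlexibleRegions(confidence(toy), 60), cfg)
  expect_gt(nFrames(pool), 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeMultimodelPDB(pool, f)
  # one MODEL block per frame, serial = model number
  lines <- readLines(f)
  serials <- as.integer(substr(grep("^MODEL", lines, value = TRUE), 11, 14))
  expect_identical(serials, modelNumbers(pool))
  back <- readMultimodelPDB(f)
  expect_identical(modelNumbers(back), modelNumbers(pool))
  expect_lt(max(abs(back@coords - pool@coords)), 1e-3)
  expect_equal(atoms(back@template)$resno, atoms(toy)$resno)
})

test_that("writing an empty or inconsistent pool fails", {
  expect_error(writeMultimodelPDB(NULL, tempfile()), "non-empty")
  toy <- buildToyChain(3, 5, 3)
  expect_error(new("ConformerPool", template = toy,
                   coords = array(0, c(nAtoms(toy) - 1, 3, 1)),
                   modelNumbers = 1L, rg = 1, acceptanceLog = TRUE),
               "atom count")
})

test_that("curve CSV writer round-trips values and rejects mismatched grids", {
  q <- c(0.01, 0.05, 0.1, 0.2, 0.3)
  c1 <- new("ScatteringCurve", q = q, intensity = exp(-q^2 * 300) * 1e5)
  c2 <- new("ScatteringCurve", q = q, intensity = sqrt(q) + 1 / 3)
  f <- withr::local_tempfile(fileext = ".csv")
  writeCurvesCSV(list(c1, c2), c("a", "b"), f)
  df <- read.csv(f)
  expect_identical(names(df), c("q", "a", "b"))
  expect_equal(nrow(df), 5)
  expect_lt(max(abs(df$a - intensities(c1)) / intensities(c1)), 1e-9)
  expect_lt(max(abs(df$b - intensities(c2)) / intensities(c2)), 1e-9)
  c3 <- new("ScatteringCurve", q = q + 0.001, intensity = q)
  expect_error(writeCurvesCSV(list(c1, c3), c("a", "c"), f), "grid")
})

test_that("molecular mass is invariant across all frames of a pool", {
  toy <- buildToyChain(6, 5, 6)
  cfg <- mcConfig(alignRange = c(1, 6), trialAttempts = 40, seed = 9)
  pool <- runMC(toy, detectFlexibleRegions(confidence(toy), 60), cfg)
  masses <- vapply(seq_len(nFrames(pool)),
                   function(i) molecularMass(getFrame(pool, i)), numeric(1))
  expect_true(all(abs(masses - molecularMass(toy)) <
                  1e-9 * molecularMass(toy)))
})
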
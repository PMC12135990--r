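test_that("unit conversion maps nm to Angstrom and conserves P(r) area", {
  cv <- new("ScatteringCurve", q = c(0.5, 1.0, 2.0), intensity = c(3, 2, 1))
  conv <- convertUnits(cv, "inv_nm")
  expect_equal(qValues(conv), c(0.05, 0.10, 0.20))
  expect_equal(intensities(conv), intensities(cv))
  expect_identical(convertUnits(cv, "inv_angstrom"), cv)

  pr <- new("PofR", r = c(0, 0.25, 0.5, 0.75), p = c(0, 4, 2, 1))
  prA <- convertUnits(pr, "nm")
  expect_equal(rValues(prA), c(0, 2.5, 5, 7.5))
  expect_equal(sum(pValues(prA)) * 2.5, sum(pValues(pr)) * 0.25)
})

test_that("P(r) of two carbons has one bin and area twice the carbon mass", {
  at <- data.frame(name = c("C", "C"), element = c("C", "C"),
                   electrons = 6L, mass = 12.011, resno = 1:2,
                   resid = "UNK", confidence = 0)
  s <- new("ProteinStructure", atoms = at,
           xyz = rbind(c(0, 0, 0), c(5.4, 0, 0)), chainId = "A")
  pr <- computePr(s)
  expect_equal(sum(pValues(pr) > 0), 1)
  expect_equal(which(pValues(pr) > 0), 6)        # bin [5, 6)
  expect_equal(sum(pValues(pr)) * 1.0, 2 * 12.011)
  expect_error(computePr(new("ProteinStructure", atoms = at[1, ],
                             xyz = rbind(c(0, 0, 0)), chainId = "A")),
               "2 atoms")
})

test_that("P(r) and I(q) are rigid-motion invariant", {
  s <- random_structure(30, seed = 7)
  th <- 1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  s2 <- s
  coords(s2) <- sweep(coords(s) %*% R, 2, c(7, -2, 3), "+")
  expect_identical(pValues(computePr(s)), pValues(computePr(s2)))
  q <- seq(0.01, 0.4, length.out = 25)
  i1 <- intensities(computeIqDebye(s, q))
  i2 <- intensities(computeIqDebye(s2, q))
  expect_lt(max(abs(i1 - i2) / i1), 1e-12)
})

test_that("Debye closed forms hold for one and two scatterers", {
  at1 <- data.frame(name = "C", element = "C", electrons = 6L,
                    mass = 12.011, resno = 1L, resid = "UNK",
                    confidence = 0)
  s1 <- new("ProteinStructure", atoms = at1, xyz = rbind(c(1, 2, 3)),
            chainId = "A")
  q <- c(0, 0.1, 0.3)
  expect_equal(intensities(computeIqDebye(s1, q)), rep(36, 3))

  # two hydrogens (f = 1 in point mode) at distance d
  at2 <- data.frame(name = c("H", "H"), element = "H", electrons = 1L,
                    mass = 1.008, resno = 1:2, resid = "UNK",
                    confidence = 0)
  d <- 4.2
  s2 <- new("ProteinStructure", atoms = at2,
            xyz = rbind(c(0, 0, 0), c(d, 0, 0)), chainId = "A")
  qq <- c(0.05, 0.2, 0.45)
  expect_equal(intensities(computeIqDebye(s2, qq)),
               2 * (1 + sin(qq * d) / (qq * d)), tolerance = 1e-12)
  expect_equal(intensities(computeIqDebye(s2, 0)), 4)
  expect_error(computeIqDebye(s2, c(-0.1, 0.1)), "negative")
})

test_that("Debye matches a brute-force double loop, point and Cromer-Mann", {
  for (seed in 1:3) {
    s <- random_structure(20, seed = seed)
    q <- seq(0.02, 0.5, length.out = 8)
    for (mode in c("point", "cromer_mann")) {
      got <- intensities(computeIqDebye(s, q, mode = mode))
      xyz <- coords(s)
      n <- nAtoms(s)
      oracle <- vapply(q, function(qk) {
        f <- if (mode == "point") atoms(s)$electrons
        else vapply(atoms(s)$element, function(e) {
          cm <- saxsens:::.cromer_mann[[e]]
          sum(cm$a * exp(-cm$b * (qk / (4 * pi))^2)) + cm$c
        }, numeric(1))
        tot <- 0
        for (i in 1:n) for (j in 1:n) {
          r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
          x <- qk * r
          tot <- tot + f[i] * f[j] * if (x == 0) 1 else sin(x) / x
        }
        tot
      }, numeric(1))
      expect_lt(max(abs(got - oracle) / oracle), 1e-10)
    }
  }
})

test_that("interpolation is exact on the source grid, linear in between, and refuses extrapolation", {
  q <- c(0.1, 0.2, 0.3, 0.4)
  cv <- new("ScatteringCurve", q = q, intensity = 2 * q + 1,
            sd = 0.1 * q)
  same <- interpolateToGrid(cv, q)
  expect_equal(intensities(same), intensities(cv))
  mid <- interpolateToGrid(cv, c(0.15, 0.25))
  expect_equal(intensities(mid), c(mean(c(1.2, 1.4)), mean(c(1.4, 1.6))))
  expect_equal(curveSd(mid), c(0.015, 0.025))
  expect_error(interpolateToGrid(cv, c(0.05, 0.2)), "extrapolation")
})

test_that("scaling reproduces hand-computed scale, nchi2 and rmsd", {
  calc <- new("ScatteringCurve", q = 1:3, intensity = c(1, 2, 3))
  ex <- new("ScatteringCurve", q = 1:3, intensity = c(2, 4, 6))
  r0 <- scaleAndChi2(calc, ex)
  expect_equal(r0$scale, 2)
  expect_equal(r0$nchi2, 0)
  expect_equal(r0$rmsd, 0)

  # 3-point hand computation: c = 31/14, residuals e - c*calc
  ex2 <- new("ScatteringCurve", q = 1:3, intensity = c(2, 4, 7))
  r1 <- scaleAndChi2(calc, ex2)
  cc <- 31 / 14
  resid <- c(2, 4, 7) - cc * c(1, 2, 3)
  expect_equal(r1$scale, cc)
  expect_equal(r1$nchi2, sum(resid^2) / 2)
  expect_equal(r1$rmsd, sqrt(mean(resid^2)))

  # SD-weighted route and scale equivariance
  ex3 <- new("ScatteringCurve", q = 1:3, intensity = c(2, 4, 7),
             sd = c(0.5, 1, 2))
  r2 <- scaleAndChi2(calc, ex3)
  w <- 1 / c(0.5, 1, 2)^2
  cc2 <- sum(c(2, 4, 7) * c(1, 2, 3) * w) / sum(c(1, 2, 3)^2 * w)
  expect_equal(r2$scale, cc2)
  calc_scaled <- new("ScatteringCurve", q = 1:3, intensity = 5 * c(1, 2, 3))
  r3 <- scaleAndChi2(calc_scaled, ex3)
  expect_equal(r3$scale, cc2 / 5)
  expect_equal(r3$nchi2, r2$nchi2)
  expect_equal(r3$rmsd, r2$rmsd)
  expect_error(scaleAndChi2(new("ScatteringCurve", q = 1:3,
                                intensity = rep(0, 3)), ex3),
               "zero")
})

test_that("coordinate Rg matches its definition and simple closed forms", {
  at <- data.frame(name = c("H", "H"), element = "H", electrons = 1L,
                   mass = 1.008, resno = 1:2, resid = "UNK", confidence = 0)
  s2 <- new("ProteinStructure", atoms = at,
            xyz = rbind(c(0, 0, 0), c(2, 0, 0)), chainId = "A")
  expect_equal(rgFromCoords(s2), 1.0)
  s1 <- new("ProteinStructure", atoms = at[1, ],
            xyz = rbind(c(3, 1, 4)), chainId = "A")
  expect_equal(rgFromCoords(s1), 0)

  s <- random_structure(50, seed = 12)
  w <- atoms(s)$electrons
  xyz <- coords(s)
  ctr <- colSums(xyz * w) / sum(w)
  oracle <- sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
  expect_equal(rgFromCoords(s), oracle, tolerance = 1e-12)
})

test_that("P(r)-moment Rg: two-point closed form, uniform sphere, zero-area error", {
  d <- 7
  pr <- new("PofR", r = 0:9, p = c(rep(0, 7), 1, 0, 0))
  # single occupied bin [7, 8): bin center 7.5 -> Rg = 7.5/sqrt(2)
  expect_equal(rgFromPr(pr), 7.5 / sqrt(2))

  # uniform sphere of radius R: p(r) ~ r^2 (1 - 3r/(4R) + r^3/(16R^3)),
  # Rg = R sqrt(3/5)
  R <- 40
  dr <- 0.1
  r <- seq(0, 2 * R - dr, by = dr)
  rc <- r + dr / 2
  p <- rc^2 * (1 - 3 * rc / (4 * R) + rc^3 / (16 * R^3))
  p[rc > 2 * R] <- 0
  prs <- new("PofR", r = r, p = pmax(p, 0))
  expect_equal(rgFromPr(prs), R * sqrt(3 / 5), tolerance = 0.01)
  expect_error(rgFromPr(new("PofR", r = 0:3, p = rep(0, 4))), "zero area")
})

test_that("consistency triangle: coordinate, P(r) and Guinier Rg agree on rigid structures", {
  for (seed in c(3, 17)) {
    s <- random_structure(40, seed = seed, box = 30)
    rg_c <- rgFromCoords(s)
    rg_p <- rgFromPr(computePr(s))
    expect_lt(abs(rg_c - rg_p), 0.5)
    q <- seq(1e-3, 0.4 / rg_c, length.out = 12)   # q*Rg < 0.5
    iq <- computeIqDebye(s, q)
    slope <- coef(lm(log(intensities(iq)) ~ I(q^2)))[2]
    rg_g <- sqrt(-3 * slope)
    expect_lt(abs(rg_g - rg_c) / rg_c, 0.02)
    # area equals molecular mass
    pr <- computePr(s)
    expect_lt(abs(sum(pValues(pr)) - molecularMass(s)) / molecularMass(s),
              1e-6)
  }
})
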
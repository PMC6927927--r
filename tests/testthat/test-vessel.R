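test_that("strain energy is zero at the reference state and matches the polynomial", {
  tb <- vesselTube(R_ref = 10)
  expect_equal(strainEnergy(tb, 3, 1), 0)
  # direct polynomial evaluation at I1 = 3.01
  x <- 0.01
  expect_equal(strainEnergy(tb, 3.01), sum(tb$c * x^(1:6)), tolerance = 1e-12)
  expect_equal(strainEnergy(tb, 3.01), 5.614e-5, tolerance = 1e-3)
  # printed coefficient echo
  expect_equal(tb$c[1], 0.0048)
  expect_equal(tb$c[6], 46.3921)
  expect_error(strainEnergy(tb, 2.9))
  expect_error(strainEnergy(tb, 3.1, J_el = -1))
})

test_that("tube inflation is monotone and strain-stiffening over 80-120 mmHg", {
  tb <- vesselTube(R_ref = 10)
  expect_equal(pressureRadius(tb, 0), tb$R_ref)
  r <- vapply(c(80, 100, 120), function(P) pressureRadius(tb, P), numeric(1))
  expect_true(all(diff(r) > 0))
  # dP/dR increases with pressure (high-order terms stiffen the wall)
  expect_gt((120 - 100) / (r[3] - r[2]), (100 - 80) / (r[2] - r[1]))
  # hoop response monotone over the working stretch range
  lam <- seq(1.001, 1.3, length.out = 30)
  s <- 2 * (lam^2 - 1 / lam^2) *
    vapply(lam^2 + 1 / lam^2 + 1, function(I1) ringmech:::.dWdI1(tb, I1),
           numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("mean pressure and vessel sizing follow the stated rules", {
  expect_equal(meanPressure(80, 120), 93.3, tolerance = 1e-3)
  cfg <- ringConfig(0.180, 27.02, 10)
  tb <- sizeVessel(cfg, 10)
  target <- (27.02 / 2) / 1.1
  expect_equal(pressureRadius(tb, meanPressure()), target, tolerance = 1e-4)
  expect_equal(tb$length, 2 * 27.02)
  expect_equal(tb$thickness, 2)
  # oversize -> 0 limit: vessel radius approaches the ring radius
  tb2 <- sizeVessel(cfg, 0.1)
  expect_equal(pressureRadius(tb2, meanPressure()), 13.51 / 1.001,
               tolerance = 1e-4)
  expect_error(sizeVessel(cfg, -5))
})

test_that("volumetric parameters imply near incompressibility", {
  tb <- vesselTube()
  mu0 <- 2 * tb$c[1]          # small-strain shear modulus
  K0 <- 2 / tb$D1             # small-strain bulk modulus
  nu <- (3 * K0 - 2 * mu0) / (2 * (3 * K0 + mu0))
  expect_gt(nu, 0.4999)
})

test_that("ring load coupling inflates the vessel beyond the unloaded radius", {
  cfg <- ringConfig(0.180, 27.02, 10)
  tb <- sizeVessel(cfg, 10)
  r0 <- pressureRadius(tb, 93.3)
  r2 <- vesselRadiusUnderLoad(tb, 93.3, 2)
  expect_gt(r2, r0)
  expect_lt(r2 - r0, 1)  # a few newtons move the wall a fraction of a mm
  expect_equal(vesselRadiusUnderLoad(tb, 93.3, 0), r0)
})
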
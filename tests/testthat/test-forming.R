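test_that("analytic manufacturing strain is R_wire/R_ring", {
  expect_equal(analyticFormingStrain(ringConfig(0.200, 48.09, 9)),
               0.200 / 48.09)
  expect_equal(analyticFormingStrain(ringConfig(0.220, 39.25, 14)),
               0.220 / 39.25)
  suppressWarnings(
    expect_equal(analyticFormingStrain(ringConfig(1e-9, 27.02, 1)), 1e-9 / 27.02))
  expect_error(ringConfig(0.2, 0, 9))
  expect_warning(ringConfig(2, 30, 1))  # slenderness warning
})

test_that("FE forming strain matches the bending closed form for all fixture rings", {
  for (nm in names(fixtureRings())) {
    fr <- formedRingFx(nm, n_elem = 32)
    expect_lt(abs(fr$eps_fe / fr$eps_analytic - 1), 0.001)  # < 0.1 %
    # analytic magnitudes sit in the 0.4-0.7e-2 range
    expect_gte(fr$eps_analytic, 0.004)
    expect_lte(fr$eps_analytic, 0.007)
  }
})

test_that("a formed welded ring is self-equilibrated after release", {
  fr <- formedRingFx("ring1", n_elem = 32)
  expect_lt(equilibriumResidual(fr$model), 1e-6)
  # every fiber carries a bending history: outer fibers near +/- r/R
  expect_gt(max(fr$model$lastFib), 0.9 * fr$eps_analytic)
  expect_lt(min(fr$model$lastFib), -0.9 * fr$eps_analytic)
})

test_that("the no-prestrain variant is a virgin circle with zero stored energy", {
  cfg <- ringConfig(0.200, 48.09, 9, include_prestrain = FALSE)
  fr <- formRing(cfg, n_elem = 32)
  expect_equal(max(abs(fr$model$lastFib)), 0)
  expect_equal(max(fr$model$xi), 0)
  expect_equal(fr$eps_fe, 0)
  # stored elastic energy exactly zero: zero stress everywhere
  asm <- ringmech:::.assemble(fr$model, needK = FALSE)
  expect_equal(max(abs(asm$sig)), 0)
})

test_that("quarter nodes sit at the axis crossings", {
  fr <- formedRingFx("ring2", n_elem = 32)
  qn <- quarterNodes(fr$model)
  x <- fr$model$x
  expect_lt(abs(x[2, qn["B"]]), 1e-8)   # B on +x axis
  expect_lt(abs(x[1, qn["A"]]), 1e-6)   # A on +y axis
  expect_gt(x[2, qn["A"]], 0)
})
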
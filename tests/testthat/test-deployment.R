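test_that("deployment configuration validates its physical constraints", {
  expect_error(deploymentConfig(P_d = 120, P_s = 80))
  expect_error(deploymentConfig(catheter_diameter = 1, inner_tube_diameter = 2))
  expect_error(deploymentConfig(mu_vessel = -0.1))
  cfg <- deploymentConfig()
  expect_equal(cfg$P_d, 80)
  expect_equal(cfg$P_s, 120)
  expect_equal(cfg$mu_vessel, 0.05)
  expect_equal(cfg$mu_sheath, 0)
})

test_that("compaction strain history grows monotonically to the fold extreme", {
  cp <- cachedFixture("compact_ring2_48", {
    fr <- formedRingFx("ring2", n_elem = 48)
    compact(fr, deploymentConfig(), nincr = 25, opts = testOpts())
  })
  h <- cp$history
  # peak strain non-decreasing along the shrink (within numerical jitter)
  expect_true(all(diff(h$eps_max) > -1e-4))
  # compaction drives the wire deep into the plateau
  expect_gt(max(h$xi_max), 0.5)
  # compacted profile fits the catheter bore
  nb <- length(cp$model$el$n1)
  rho <- sqrt(colSums(cp$model$x[1:2, 1:nb, drop = FALSE]^2))
  expect_lte(max(rho) + cp$model$r_bundle, 6.9 / 2 + 0.01)
  # too-small catheter rejected
  expect_error(compact(fr, deploymentConfig(catheter_diameter = 2.2)),
               "bore")
})

test_that("deployed rings land on the wall with strains at peaks or valleys", {
  res <- deployedFx("ring2")
  # contact established, chronic outward force positive
  expect_gt(res$COF, 0)
  expect_gt(res$COF_diast, 0)
  # strain extremum within 10 degrees of a quarter point
  angs <- c(res$angle_diast, res$angle_syst) %% 90
  expect_true(all(pmin(angs, 90 - angs) <= 10))
  # diastole (smaller vessel) bends the ring at least as much as systole
  expect_gte(res$eps_diast, res$eps_syst - 5e-4)
  # cycle-mean strain lies between the phase extremes
  expect_lte(res$M_eps, max(res$eps_diast, res$eps_syst) + 1e-12)
  # compaction was the severest load the wire saw
  cp <- cachedFixture("compact_ring2_48", {
    fr <- formedRingFx("ring2", n_elem = 48)
    compact(fr, deploymentConfig(), nincr = 25, opts = testOpts())
  })
  expect_gt(max(cp$history$eps_max), max(res$eps_diast, res$eps_syst))
})

test_that("contact force distribution is near four-fold symmetric", {
  # symmetric conditions: the seeded guide jitter switched off
  res <- cachedFixture("deploy_ring2_sym",
    runDeployment(fixtureRings()$ring2,
                  config = deploymentConfig(perturb = 0),
                  n_elem = 64, nincr_compact = 40))
  cf <- contactForces(res$model, "vessel")
  m <- res$model
  phi <- atan2(m$x[2, cf$node], m$x[1, cf$node]) %% (2 * pi)
  quad <- floor(((phi + pi / 4) %% (2 * pi)) / (pi / 2))
  qs <- tapply(cf$N, quad, sum)
  expect_equal(length(qs), 4L)
  # the deployed saddle has two-fold symmetry (peaks and valleys load the
  # wall differently); opposite quadrants must match
  expect_lt(abs(qs[1] - qs[3]) / sum(qs), 0.01)  # valley B vs valley D
  expect_lt(abs(qs[2] - qs[4]) / sum(qs), 0.01)  # peak A vs peak C
})

test_that("pulsation settles and the load history changes the outcome", {
  res3 <- deployedFx("ring2", cycles = 3)
  h <- res3$history
  eD <- h$eps[h$phase == 1]
  eS <- h$eps[h$phase == 2]
  expect_lt(abs(eD[3] - eD[2]) / eD[2], 0.005)
  expect_lt(abs(eS[3] - eS[2]) / eS[2], 0.005)
  # deploying without the compaction step gives a measurably different state
  resNoC <- cachedFixture("deploy_ring2_nocompact",
    runDeployment(fixtureRings()$ring2,
                  config = deploymentConfig(),
                  n_elem = 64, nincr_compact = 40, skip_compaction = TRUE))
  res <- deployedFx("ring2")
  expect_gt(abs(resNoC$COF - res$COF) / res$COF +
              abs(resNoC$eps_diast - res$eps_diast) / res$eps_diast, 1e-3)
})

test_that("chronic outward force equals the vessel-side radial sum", {
  res <- deployedFx("ring2")
  cof <- chronicOutwardForce(res$model, "vessel")
  cf <- contactForces(res$model, "vessel")
  expect_equal(cof, sum(cf$N), tolerance = 1e-12)
  # action-reaction: nodal force magnitudes match the normal force
  act <- cf$N > 0
  expect_equal(sqrt(cf$Fx[act]^2 + cf$Fy[act]^2)[1:3], cf$N[act][1:3],
               tolerance = 0.06)  # tangential friction adds a small vector
})
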
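test_that("cantilever tip deflection matches the Euler-Bernoulli closed form", {
  p <- nitinolParams()
  m <- straightWireModel(20, 40, p, 0.09)
  m <- fixDof(m, 1, 1:6)
  EI <- p$E_A * pi * 0.09^4 / 4
  P <- 0.001  # small enough for linearity
  F1 <- m$Fext; F1[3, m$nn] <- P
  sol <- solveProgram(m, list(list(nincr = 2, Fext = F1)), testOpts())
  expect_true(sol$converged)
  expect_equal(sol$model$x[3, m$nn], P * 20^3 / (3 * EI), tolerance = 0.01)
  expect_lt(equilibriumResidual(sol$model), 1e-6)
})

test_that("pure end moment bends the wire into a circle with strain r/R", {
  # keep the material elastic so the elastica closed form applies
  p <- nitinolParams(sigma_LS = 1e6, sigma_LE = 1.1e6, sigma_US = 5e5,
                     sigma_UE = 4e5, sigma_CS = 1.5e6)
  L <- 60
  m <- straightWireModel(L, 48, p, 0.09)
  m <- fixDof(m, 1, 1:6)
  EI <- p$E_A * pi * 0.09^4 / 4
  F1 <- m$Fext; F1[6, m$nn] <- EI * 2 * pi / L
  sol <- suppressWarnings(
    solveProgram(m, list(list(nincr = 40, Fext = F1)), testOpts()))
  expect_true(sol$converged)
  # free end meets the clamped end: full circle
  expect_lt(sqrt(sum((sol$model$x[, m$nn] - sol$model$x[, 1])^2)), 1e-4 * L)
  emax <- max(surfaceStrains(sol$model)$eps_absmax)
  expect_equal(emax, 0.09 / (L / (2 * pi)), tolerance = 0.005)
})

test_that("pinched elastic ring matches the thin-ring diametral stiffness", {
  p <- nitinolParams()
  R <- 13.51
  m <- circleRingModel(R, 64, p, 0.09)
  m <- fixDof(m, 1, c(2, 3, 4, 6))
  m <- fixDof(m, 17, c(1, 3))
  m <- fixDof(m, 33, 3)
  EI <- p$E_A * pi * 0.09^4 / 4
  P <- 0.002
  F1 <- m$Fext; F1[1, 1] <- -P; F1[1, 33] <- P
  sol <- solveProgram(m, list(list(nincr = 2, Fext = F1)), testOpts())
  dD <- abs(sol$model$x[1, 1] - m$X0[1, 1]) +
    abs(sol$model$x[1, 33] - m$X0[1, 33])
  # Roark: diameter change under diametral pinch = P R^3 (pi/4 - 2/pi) / EI
  expect_equal(dD, P * R^3 * (pi / 4 - 2 / pi) / EI, tolerance = 0.03)
})

test_that("weld ties are exact and reject non-coincident nodes", {
  fr <- formedRingFx("ring1", n_elem = 32)
  m <- fr$model
  # welded pair remains coincident after loading
  qn <- quarterNodes(m)
  m2 <- fixDof(m, qn["A"], 1:6)
  F1 <- m2$Fext; F1[1, qn["D"]] <- 0.005
  sol <- solveProgram(m2, list(list(nincr = 2, Fext = F1)), testOpts())
  # the open-chain end node (33) is welded to node 1: joint never opens
  expect_lt(sqrt(sum((sol$model$x[, 33] - sol$model$x[, 1])^2)), 1e-9)
  # welding nodes 1 mm apart is rejected
  mm <- straightWireModel(10, 4, nitinolParams(), 0.09)
  expect_error(weldClose(mm, 1, 5), "apart")
})

test_that("turn multiplier is equivalent to coincident duplicated wires", {
  p <- nitinolParams()
  # model A: one wire with nmult = 3
  mA <- straightWireModel(20, 16, p, 0.09, nmult = 3)
  mA <- fixDof(mA, 1, 1:6)
  # model B: three coincident wires sharing all nodes (elements duplicated)
  mB <- straightWireModel(20, 16, p, 0.09, nmult = 1)
  ne <- length(mB$el$n1)
  mB$el$n1 <- rep(mB$el$n1, 3); mB$el$n2 <- rep(mB$el$n2, 3)
  mB$el$l0 <- rep(mB$el$l0, 3)
  mB$el$qCa <- mB$el$qCa[, rep(seq_len(ne), 3)]
  mB$el$qCb <- mB$el$qCb[, rep(seq_len(ne), 3)]
  mB$xi <- matrix(0, nrow(mB$xi), 3 * ne)
  mB$eptr <- matrix(0, nrow(mB$eptr), 3 * ne)
  mB <- fixDof(mB, 1, 1:6)
  F1 <- mA$Fext; F1[3, mA$nn] <- 0.003
  sA <- solveProgram(mA, list(list(nincr = 2, Fext = F1)), testOpts())
  sB <- solveProgram(mB, list(list(nincr = 2, Fext = F1)), testOpts())
  expect_equal(sA$model$x, sB$model$x, tolerance = 1e-9)
})

test_that("cylindrical contact produces physically consistent nodal forces", {
  fr <- formedRingFx("ring1", n_elem = 32)
  m <- fr$model
  R <- 27.02 / 2
  # ring strictly inside a larger cylinder: no contact force
  m <- addContact(m, "outer1", "outer", R + 5)
  cf <- contactForces(m, "outer1")
  expect_equal(sum(abs(cf$N)), 0)
  # pressed into a smaller frictionless cylinder: self-equilibrated inward
  qn <- quarterNodes(m)
  m2 <- ringmech:::.deployBCs(m, qn)
  m2$contacts$outer1$R <- R + m$r_bundle - 0.05
  sol <- solveProgram(m2, list(list(nincr = 6)), testOpts())
  cf2 <- contactForces(sol$model, "outer1")
  expect_gt(sum(cf2$N), 0)                      # radial scalar sum positive
  expect_lt(abs(sum(cf2$Fx)), 1e-4 * sum(cf2$N))  # net vector ~ 0
  expect_lt(abs(sum(cf2$Fy)), 1e-4 * sum(cf2$N))
  expect_equal(sum(abs(cf2$Fz)), 0)             # frictionless: no tangential
})
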
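test_that("oversize ratio maps to vessel radius and saddle amplitude", {
  r2 <- ringConfig(0.160, 33.16, 8)
  p10 <- saddlePositionsFromOversize(r2, 10)
  expect_equal(p10$R_vessel, 16.58 / 1.1, tolerance = 1e-6)
  r1 <- ringConfig(0.180, 27.02, 10)
  p30 <- saddlePositionsFromOversize(r1, 30)
  expect_equal(p30$R_vessel, 13.51 / 1.3, tolerance = 1e-6)
  # amplitude consistent with arc-length conservation on the cylinder
  a <- p30$R_vessel; h <- p30$amplitude
  phi <- seq(0, 2 * pi, length.out = 3601)
  len <- sum(sqrt(a^2 + 4 * h^2 * sin(2 * phi[-1])^2) * diff(phi))
  expect_equal(len, 2 * pi * 13.51, tolerance = 1e-4)
  # vanishing oversize: no saddle
  expect_lt(saddlePositionsFromOversize(r1, 1e-4)$displacement, 0.2)
  expect_error(saddlePositionsFromOversize(r1, 0))
  expect_error(saddlePositionsFromOversize(r1, -10))
})

test_that("string connectors obey the inverse-length stiffness rule", {
  sr <- saddleFx("ring4")
  m <- sr$model
  for (cn in m$connectors)
    expect_equal(cn$k, 7.41 * 100 / cn$L0, tolerance = 1e-10)
  # force equals stiffness times elongation at the final state
  asm <- ringmech:::.assemble(m, needK = FALSE)
  for (ci in seq_along(m$connectors)) {
    cn <- m$connectors[[ci]]
    L <- sqrt(sum((m$x[, cn$nb] - m$x[, cn$na])^2))
    expect_equal(asm$connForce[ci], max(0, cn$k * (L - cn$L0)),
                 tolerance = 1e-10)
  }
})

test_that("the pull drives the ring into a saddle and a settling loop", {
  sr <- saddleFx("ring4", cycles = 2)
  expect_true(sr$converged)
  cv <- sr$curve
  # force starts near zero (self-equilibrated ring) and grows on pull
  expect_lt(cv$force_N[1], 0.1 * max(cv$force_N))
  expect_gt(max(cv$force_N), 0.2)
  # peaks rise, valleys drop: saddle shape
  qn <- quarterNodes(sr$model)
  expect_gt(sr$model$x[3, qn["A"]], 1)
  expect_lt(sr$model$x[3, qn["B"]], -1)
  # wire enters the transformation plateau at the pull extreme
  expect_gt(max(sr$model$xi), 0)
})

test_that("removing the manufacturing pre-strain stiffens the response everywhere", {
  for (nm in c("ring1", "ring4")) {
    with_ps <- saddleFx(nm, prestrain = TRUE)
    without <- saddleFx(nm, prestrain = FALSE)
    roi <- function(s) s$curve[s$curve$roi, ]
    lo <- max(min(roi(with_ps)$displacement_mm), min(roi(without)$displacement_mm))
    hi <- min(max(roi(with_ps)$displacement_mm), max(roi(without)$displacement_mm))
    gr <- seq(lo + 0.05 * (hi - lo), hi - 0.05 * (hi - lo), length.out = 25)
    fw <- approx(roi(with_ps)$displacement_mm, roi(with_ps)$force_N, gr,
                 ties = mean)$y
    fo <- approx(roi(without)$displacement_mm, roi(without)$force_N, gr,
                 ties = mean)$y
    expect_true(all(fo > fw))
  }
})

test_that("stiffness deviation is computed on the overlapping cycling region", {
  d <- data.frame(displacement_mm = seq(1, 10, by = 0.5),
                  force_N = seq(0.1, 1, length.out = 19), roi = TRUE)
  expect_equal(stiffnessDeviation(d, d), c(0, 0))
  ref <- d; ref$force_N <- 1.05 * d$force_N
  dv <- stiffnessDeviation(d, ref)
  expect_equal(dv[1], 100 * (1 - 1 / 1.05), tolerance = 1e-6)
  expect_equal(dv[2], 100 * (1 - 1 / 1.05), tolerance = 1e-6)
  far <- d; far$displacement_mm <- far$displacement_mm + 100
  expect_error(stiffnessDeviation(d, far), "disjoint")
})
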
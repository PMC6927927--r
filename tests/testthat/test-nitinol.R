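test_that("austenite branch is linear elastic up to the transformation onset", {
  p <- nitinolParams()
  expect_equal(updateState(p, materialState(), 0)$sigma, 0)
  expect_equal(updateState(p, materialState(), 0)$xi, 0)
  st <- updateState(p, materialState(), 0.005)
  expect_equal(st$sigma, 295, tolerance = 1e-10)   # E_A * eps = 59000 * 0.005
  expect_equal(st$xi, 0)
  expect_equal(100 * austeniteStrainLimit(p), 1.08, tolerance = 2e-3)
})

test_that("forward transformation onsets match the calibrated surfaces", {
  p <- nitinolParams()
  # monotonic tension: plateau entry at sigma_LS / E_A
  tr <- driveCycle(p, seq(0, 0.02, length.out = 2001))
  i <- which(tr$xi > 1e-10)[1]
  expect_equal(tr$eps[i], p$sigma_LS / p$E_A, tolerance = 1e-4)
  expect_lt(abs(tr$sigma[i - 1] - p$sigma_LS), 1)
  # monotonic compression: onset magnitude 965 MPa
  trc <- driveCycle(p, seq(0, -0.03, length.out = 3001))
  j <- which(trc$xi > 1e-10)[1]
  expect_equal(abs(trc$sigma[j - 1]), p$sigma_CS, tolerance = 1e-3)
  # asymmetry
  expect_gt(p$sigma_CS, p$sigma_LS)
})

test_that("a full tension cycle traces the printed hysteresis plateaus", {
  p <- nitinolParams()
  amp <- 0.085  # past full transformation (740/26500 + 0.05 = 0.0779)
  path <- c(seq(0, amp, length.out = 400), seq(amp, 0, length.out = 400))
  tr <- driveCycle(p, path)
  up <- tr[2:400, ]
  lo <- tr[402:800, ]
  upl <- up$sigma[up$xi > 1e-9 & up$xi < 1 - 1e-9]
  lol <- lo$sigma[lo$xi > 1e-9 & lo$xi < 1 - 1e-9]
  expect_equal(min(upl), 636, tolerance = 1e-2)
  expect_equal(max(upl), 740, tolerance = 1e-2)
  expect_equal(max(lol), 430, tolerance = 1e-2)
  expect_equal(min(lol), 302, tolerance = 1e-2)
  # closed loop: returns to virgin
  expect_equal(tail(tr$sigma, 1), 0, tolerance = 1e-8)
  expect_equal(tail(tr$xi, 1), 0, tolerance = 1e-12)
  # sub-plateau cycle has no hysteresis
  tr2 <- driveCycle(p, c(0, 0.005, 0))
  expect_equal(tail(tr2$sigma, 1), 0, tolerance = 1e-10)
  expect_equal(tail(tr2$xi, 1), 0)
})

test_that("repeated cycles are identical (rate-independent, no accumulation)", {
  p <- nitinolParams()
  one <- c(seq(0, 0.085, length.out = 150), seq(0.085, 0, length.out = 150))
  tr <- driveCycle(p, c(one, one))
  expect_equal(tr$sigma[1:300], tr$sigma[301:600], tolerance = 1e-12)
  # path refinement does not change the final state
  coarse <- driveCycle(p, seq(0, 0.04, length.out = 5))
  fine <- driveCycle(p, seq(0, 0.04, length.out = 500))
  expect_equal(tail(coarse$sigma, 1), tail(fine$sigma, 1), tolerance = 1e-10)
  expect_equal(tail(coarse$xi, 1), tail(fine$xi, 1), tolerance = 1e-12)
})

test_that("dissipation over closed strain cycles is non-negative", {
  p <- nitinolParams()
  for (amp in c(0.005, 0.02, 0.05, 0.09, -0.03, -0.06)) {
    path <- c(seq(0, amp, length.out = 200), seq(amp, 0, length.out = 200))
    tr <- driveCycle(p, path)
    area <- sum(diff(path) * (tr$sigma[-1] + tr$sigma[-length(path)]) / 2)
    expect_gte(area, -1e-10)
  }
})

test_that("tangent modulus is consistent with finite differences of the update", {
  p <- nitinolParams()
  expect_equal(tangentModulus(p, materialState()), p$E_A)
  stM <- updateState(p, materialState(), 0.09)
  expect_equal(stM$xi, 1)
  expect_equal(tangentModulus(p, stM), p$E_M)
  # mid-plateau: finite positive slope below E_M, and FD agreement
  probes <- list(updateState(p, materialState(), 0.03),          # forward plateau
                 updateState(p, materialState(), 0.005),         # elastic
                 Reduce(function(s, e) updateState(p, s, e),
                        c(0.085, 0.04), materialState()))        # reverse plateau
  for (st in probes) {
    for (dir in c("loading", "unloading")) {
      h <- 1e-7 * (if (dir == "loading") 1 else -1) * (if (st$sigma < 0) -1 else 1)
      fd <- (updateState(p, st, st$eps_total + h)$sigma - st$sigma) / h
      expect_equal(tangentModulus(p, st, dir), fd, tolerance = 1e-6)
    }
  }
  mid <- updateState(p, materialState(), 0.03)
  slope <- tangentModulus(p, mid, "loading")
  expect_gt(slope, 0)
  expect_lt(slope, p$E_M)
})

test_that("state is history dependent and invariants hold along random paths", {
  p <- nitinolParams()
  # same total strain, different histories, different stress
  a <- updateState(p, materialState(), 0.03)
  b <- Reduce(function(s, e) updateState(p, s, e), c(0.085, 0.03), materialState())
  expect_equal(a$eps_total, b$eps_total)
  expect_gt(a$sigma - b$sigma, 50)
  # invariants: 0 <= xi <= 1, |eps_tr| <= xi * eps_L along arbitrary paths
  set.seed(42)
  for (rep in 1:5) {
    path <- cumsum(stats::rnorm(60, sd = 0.012))
    tr <- driveCycle(p, path)
    expect_true(all(tr$xi >= -1e-12 & tr$xi <= 1 + 1e-12))
    expect_true(all(abs(tr$eps_tr) <= tr$xi * p$eps_L + 1e-10))
  }
})

test_that("parameter validation rejects ill-posed sets and bad strains", {
  expect_error(nitinolParams(E_A = 20000, E_M = 26500))
  expect_error(nitinolParams(sigma_LS = 800, sigma_LE = 740))
  expect_error(nitinolParams(sigma_CS = 500))
  p <- nitinolParams()
  expect_error(updateState(p, materialState(), NaN))
  expect_error(driveCycle(p, c(0, 0.01, Inf)))
})
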
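test_that("embedded packing ratios match the closed forms and table", {
  expect_equal(bwRatio(1), 1)
  expect_equal(bwRatio(2), 2)
  expect_equal(bwRatio(3), 2.154)  # printed value; 1 + 2/sqrt(3) = 2.1547
  expect_lt(abs(bwRatio(3) - (1 + 2 / sqrt(3))), 1e-3)
  expect_equal(bwRatio(4), round(1 + sqrt(2), 3))
  expect_equal(bwRatio(7), 3)
  # monotone non-decreasing, and area lower bound BW >= sqrt(n)
  bw <- vapply(1:14, bwRatio, numeric(1))
  expect_true(all(diff(bw) >= 0))
  expect_true(all(bw >= sqrt(1:14) - 5e-4))
  expect_error(bwRatio(0))
  expect_warning(bwRatio(20))
})

test_that("bundle diameters reproduce the four fixture configurations", {
  # wire diameter (mm), turns -> printed bundle diameter (mm), 2 d.p.
  fix <- list(c(0.180, 10, 0.69), c(0.160, 8, 0.53),
              c(0.220, 14, 0.95), c(0.200, 9, 0.72))
  for (f in fix)
    expect_equal(round(bundleDiameter(f[1] / 2, f[2]), 2), f[3])
  expect_equal(bundleDiameter(1, 1), 2)
  expect_error(bundleDiameter(-0.1, 3))
})

test_that("numerical packing optimizer independently recovers small-n optima", {
  set.seed(11)
  for (n in c(2, 3, 5, 6)) {
    v <- verifyPacking(n, tol = 1e-3)
    expect_gte(as.numeric(v), bwRatio(n) - 1e-3)
    expect_lte(as.numeric(v), bwRatio(n) + 1e-3)
  }
  expect_error(verifyPacking(12))
})
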
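# Giant-spin scaling arithmetic, coupling schemes, and the scalability audit.

test_that("moment-to-spin and anisotropy-field relations", {
  expect_equal(spin_from_moment(10, 2), 5)
  expect_equal(spin_from_moment(0, 2), 0)
  expect_equal(spin_from_moment(1e4, 2), 5000)
  expect_error(spin_from_moment(1, 0), "positive")
  # D = g beta B_a / 2S, easy-axis sign
  D <- anisotropy_field_to_D(1400, 5000, 2.00)
  expect_lt(D, 0)
  expect_equal(abs(D), 1.307e-5, tolerance = 1e-3)
  expect_equal(anisotropy_field_to_D(0, 10), 0)
  # doubling S halves |D|
  expect_equal(anisotropy_field_to_D(1400, 10000), D / 2)
  expect_error(anisotropy_field_to_D(1400, 0), "positive")
})

test_that("scaling relations are exact arithmetic", {
  expect_identical(scale_down(5000, 500), 10)
  expect_identical(scale_down(5000, 50), 100)
  expect_identical(scale_down(7, 1), 7)
  expect_equal(scale_D(-1.2e-5, 500), -6e-3)
  expect_identical(scale_D(0.4, 1), 0.4)
  expect_equal(scale_T(5, 500), 0.01)
  expect_error(scale_down(10, 0), "positive integer")
  expect_error(scale_D(1, 2.5), "positive integer")
  expect_warning(scale_down(5000, 3), "half-integral")
})

test_that("scaling round-trip bookkeeping holds for any integer n", {
  for (n in c(1, 8, 500)) {
    S <- 5000; D <- -1.2e-5
    sch <- scaling_scheme(S = S, n = n, D = D, T_K = 5)
    expect_equal(sch$D_eff / sch$S_eq, n^2 * D / S)
    expect_equal(scale_T(scale_T(5, n), 1), 5 / n)
    expect_equal(sch$S_eq * n, S)
    expect_equal(sch$B20_eff, sch$D_eff / 3)
  }
})

test_that("coupling-scheme spin arithmetic", {
  mn12 <- net_spin(list(list(count = 8, spin = 2, orientation = "parallel"),
                        list(count = 4, spin = 3/2,
                             orientation = "antiparallel")))
  expect_identical(mn12, 10)
  fe8 <- net_spin(list(list(count = 4, spin = 5/2,
                            orientation = "parallel"),
                       list(count = 1, spin = 0,
                            orientation = "parallel")))
  expect_identical(fe8, 10)
  ni4 <- net_spin(list(list(count = 4, spin = 1,
                            orientation = "parallel")))
  expect_identical(ni4, 4)
  expect_warning(s <- net_spin(list(list(count = 1, spin = 1/2,
                                         orientation = "antiparallel"))),
                 "floored")
  expect_identical(s, 0)
})

test_that("largest diagonal elements match hand-derived values", {
  expect_equal(max_diag_element(10, -2e-3, 2), 0.38)      # 190 * 2e-3
  expect_equal(max_diag_element(10, -2e-7, 4), 58140 * 2e-7)
  expect_equal(max_diag_element(10, 0, 6), 0)
  expect_error(max_diag_element(1, 1e-3, 4), "not allowed")
})

test_that("closed-form diagonals agree with brute-force operator matrices", {
  for (S in c(10, 35, 100)) {
    for (k in c(2, 4, 6)) {
      B <- -3.7e-6
      brute <- max(abs(B * diag(stevens_operator(S, k, 0))))
      expect_equal(max_diag_element(S, B, k), brute, tolerance = 1e-12)
    }
  }
})

test_that("audit reproduces the decreasing / comparable / increasing verdicts", {
  aud <- divergence_audit(D = -1.2e-5, S = 5000, S_eq = c(10, 100, 1000),
                          per_step_ratio = 1e-4)
  v <- attr(aud, "verdicts")
  expect_identical(unname(v["10"]), "decreasing")
  expect_identical(unname(v["100"]), "comparable")
  expect_identical(unname(v["1000"]), "increasing")
  # derived B20 inputs match the scaling chain
  expect_equal(aud$B[aud$S_eq == 10 & aud$k == 2], -2e-3)
  expect_equal(aud$B[aud$S_eq == 100 & aud$k == 2], -2e-4)
  expect_equal(aud$B[aud$S_eq == 1000 & aud$k == 2], -2e-5)
  # comparable means within one order of magnitude
  m100 <- aud$max_element[aud$S_eq == 100]
  expect_lte(max(m100) / min(m100), 10)
  m1000 <- aud$max_element[aud$S_eq == 1000]
  expect_true(all(diff(m1000) > 0))
})

test_that("scaling_scheme derives spin and D from mu and B_a when asked", {
  sch <- scaling_scheme(mu = 1e4, n = 500, B_a = 1400, T_K = 5, g = 2)
  expect_equal(sch$S, 5000)
  expect_equal(sch$S_eq, 10)
  expect_equal(sch$D, anisotropy_field_to_D(1400, 5000, 2))
  expect_equal(sch$T_eff, 0.01)
})
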
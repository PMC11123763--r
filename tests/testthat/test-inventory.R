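# Feature detector, threshold search, and presets.  The full S = 10
# inventory is exercised in test-acceptance.R; here the detector rules are
# validated on analytically constructed traces and the search on a cheap
# low-spin system.

test_that("a spectrum compared against itself reports no extra features", {
  sp <- synthetic_spectrum(3394, 1, 300)
  f <- detect_features(sp, sp)
  expect_false(f$main_split)
  expect_equal(f$main_width_ratio, 1.0)
  expect_equal(f$broadening_ratio, 1.0)
  expect_false(f$half_field)
  expect_false(f$near_zero)
  expect_length(f$shoulders, 0)
})

test_that("featureless input yields an empty report", {
  base <- synthetic_spectrum(3394, 1, 300)
  flat <- base
  flat$absorption[] <- 0
  flat$derivative[] <- 0
  f <- detect_features(flat, flat)
  expect_false(f$main_split)
  expect_true(is.na(f$main_width_ratio))
})

test_that("the detector flags a split main line and measures the splitting", {
  base <- synthetic_spectrum(3394, 1, 300)
  split <- synthetic_spectrum(c(3394 - 300, 3394 + 300), c(1, 1), 300)
  f <- detect_features(split, base)
  expect_true(f$main_split)
  expect_equal(f$split_G, 600, tolerance = 0.15)
  expect_gt(f$broadening_ratio, 1.2)
})

test_that("the detector flags half-field and near-zero-field features", {
  base <- synthetic_spectrum(3394, 1, 300)
  withf <- synthetic_spectrum(c(3394, 1700, 150), c(1, 0.05, 0.05), 300)
  f <- detect_features(withf, base)
  expect_true(f$half_field)
  expect_true(f$near_zero)
  # a feature well below the declared 1% floor is not reported
  weak <- synthetic_spectrum(c(3394, 1700), c(1, 0.0003), 300)
  expect_false(detect_features(weak, base)$half_field)
})

test_that("the detector reports flanking shoulders with an unaffected main line", {
  base <- synthetic_spectrum(3394, 1, 300)
  sh <- synthetic_spectrum(c(3394, 2450, 4500), c(1, 0.12, 0.12), 300)
  f <- detect_features(sh, base)
  expect_gte(length(f$shoulders), 2)
  expect_true(any(f$shoulders < 3394) && any(f$shoulders > 3394))
  expect_equal(f$main_width_ratio, 1.0, tolerance = 0.1)
  expect_false(f$main_split)
})

test_that("threshold search: edge cases and monotone deviation", {
  sys <- spin_system(2, g = 2)
  ex <- epr_experiment(range_G = c(1500, 5500), n_points = 512,
                       fwhm_G = 150, n_orient = 200, n_scan = 96)
  expect_identical(resolve_threshold(sys, ex, 4, 0, fraction = 0), 0)
  thr <- resolve_threshold(sys, ex, 4, 0, fraction = 0.05)
  expect_true(is.finite(thr) && thr > 0)
  base <- powder_spectrum(sys, ex)
  dev_at <- function(B) {
    s <- powder_spectrum(spin_system(2, g = 2,
                                     terms = list(zfi_term(4, 0, B))), ex)
    max(abs(s$derivative - base$derivative))
  }
  d1 <- dev_at(thr); d2 <- dev_at(2 * thr); d3 <- dev_at(3 * thr)
  expect_gt(d2, d1)
  expect_gt(d3, d2)
  # the threshold sits at the declared fraction of the base amplitude
  pkpk <- max(base$derivative) - min(base$derivative)
  expect_equal(d1 / pkpk, 0.05, tolerance = 0.25)
})

test_that("presets carry the published parameter values", {
  fx <- epr_fixtures()
  blue <- fx$fig2_blue$system
  expect_equal(blue$S, 5/2)
  expect_equal(blue$conventional$D, -0.9)
  expect_equal(blue$conventional$E, -0.3)
  expect_equal(blue$g, rep(2, 3))
  expect_equal(fx$fig2_blue$experiment$temperature_K, 15)
  expect_equal(fx$fig2_blue$experiment$fwhm_G, 100)
  red <- fx$fig2_red$system
  expect_equal(red$conventional$E, -0.14)
  b44 <- Filter(function(t) t$k == 4 && t$q == 4, red$terms)
  expect_equal(b44[[1]]$B, 0.24)
  inv <- fx$fig5_inventory
  expect_equal(inv$system$S, 10)
  expect_null(inv$experiment$temperature_K)
  expect_equal(inv$experiment$fwhm_G, 300)
  expect_equal(inv$D_base_MHz, 100)
  pff <- fx$pff_scaling
  expect_equal(pff$S, 5000)
  expect_equal(pff$D, -1.2e-5)
  expect_equal(pff$n, 500)
  aud <- fx$fig3_audit
  expect_equal(aud$per_step_ratio, 1e-4)
})

test_that("inventory output is deterministic across repeat runs", {
  sys <- spin_system(2, g = 2)
  ex <- epr_experiment(range_G = c(1500, 5500), n_points = 256,
                       fwhm_G = 150, n_orient = 150, n_scan = 96)
  run <- function() {
    s <- powder_spectrum(spin_system(2, g = 2,
                                     terms = list(zfi_term(4, 4, 2e-3))),
                         ex)
    s$derivative
  }
  expect_identical(run(), run())
})

test_that("the q = 4 sextic term has the strongest low-field features of order six", {
  inv <- get_inventory()$inv
  x <- inv$base$field_G
  B0 <- x[which.max(inv$base$absorption)]
  low_share <- function(nm) {
    s <- inv$spectra[[nm]]
    low <- x < 0.65 * B0
    c(share = sum(s$absorption[low]) / sum(s$absorption),
      peak = max(s$absorption[low]) / max(s$absorption))
  }
  s62 <- low_share("6_2:3"); s64 <- low_share("6_4:3"); s66 <- low_share("6_6:3")
  expect_gt(s64["share"], s62["share"])
  expect_gt(s64["share"], s66["share"])
  expect_gt(s64["peak"], s62["peak"])
  expect_gt(s64["peak"], s66["peak"])
})
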
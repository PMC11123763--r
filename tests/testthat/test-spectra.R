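# Resonance search, powder averaging, lineshapes, effective g values,
# rhombograms, distributions and I/O.  Small grids throughout; the figure
# presets are exercised in test-acceptance.R.

small_exp <- function(..., n_orient = 300) {
  epr_experiment(n_points = 512, n_orient = n_orient, n_scan = 128, ...)
}

test_that("zero-ZFI resonances collapse onto h nu / (g beta)", {
  sys <- spin_system(5/2, g = 2)
  ex <- small_exp(range_G = c(2000, 5000), fwhm_G = 50)
  rf <- resonance_fields(sys, ex, theta = 0.8, phi = 0.3)
  B0 <- zeeman_field(2, 9.5)
  expect_equal(nrow(rf), 5)                      # the 5 delta-M = 1 lines
  expect_equal(rf$field_G, rep(B0, 5), tolerance = 1e-6)
  # weights all positive
  expect_true(all(rf$weight > 0))
})

test_that("S = 10 axial resonances follow B(m) = B0 - D'(2m+1)/(g beta)", {
  B20 <- 1e-3
  sys <- spin_system(10, g = 2, terms = list(zfi_term(2, 0, B20)))
  ex <- epr_experiment(range_G = c(0, 7000), n_scan = 512, fwhm_G = 100)
  rf <- resonance_fields(sys, ex, theta = 0, phi = 0)
  rf1 <- rf[rf$upper - rf$lower == 1 & rf$moment > 1, ]   # allowed lines
  bG <- gs_constants()$beta_cm_per_G
  m <- seq(-10, 9)
  pred <- zeeman_field(2, 9.5) - 3 * B20 * (2 * m + 1) / (2 * bG)
  pred <- sort(pred[pred >= 0 & pred <= 7000])
  expect_equal(sort(rf1$field_G), pred, tolerance = 1e-5)
  # symmetric about the g = 2 field
  expect_equal(mean(range(pred)), zeeman_field(2, 9.5), tolerance = 1e-6)
})

test_that("empty field windows yield no resonances", {
  sys <- spin_system(1/2, g = 2)
  ex <- small_exp(range_G = c(100, 800), fwhm_G = 50)
  rf <- resonance_fields(sys, ex, 0.3, 0.1)
  expect_equal(nrow(rf), 0)
})

test_that("compiled search agrees with the independent R reference", {
  sys <- spin_system(3/2, g = 2, D = 0.08, E = 0.02)
  ex <- epr_experiment(range_G = c(0, 7000), n_scan = 256, fwhm_G = 50)
  for (ang in list(c(0.3, 0.9), c(1.2, 0.2))) {
    rf <- resonance_fields(sys, ex, ang[1], ang[2])
    rf <- rf[order(rf$field_G), ]
    ref <- r_reference_resonances(sys, 9.5, c(0, 7000), ang[1], ang[2])
    expect_equal(nrow(rf), nrow(ref))
    expect_equal(rf$field_G, ref$field_G, tolerance = 1e-4)
    expect_equal(rf$lower, ref$lower)
    expect_equal(rf$upper, ref$upper)
  }
})

test_that("transition_weight reproduces the compiled weights", {
  sys <- spin_system(3/2, g = 2, D = 0.08, E = 0.02)
  ex <- epr_experiment(range_G = c(0, 7000), n_scan = 256, fwhm_G = 50,
                       temperature_K = 10)
  rf <- resonance_fields(sys, ex, 0.7, 0.4)
  expect_gt(nrow(rf), 1)
  for (i in seq_len(nrow(rf))) {
    w <- transition_weight(sys, ex, rf$field_G[i],
                           c(rf$lower[i], rf$upper[i]), 0.7, 0.4)
    expect_equal(as.numeric(w), rf$weight[i], tolerance = 0.05)
    expect_gte(as.numeric(w), 0)
  }
})

test_that("equal-population mode sets the population factor to exactly 1", {
  sys <- spin_system(1, g = 2, D = 0.05)
  ex <- small_exp(range_G = c(0, 7000), fwhm_G = 50)
  rf <- resonance_fields(sys, ex, 0.5, 0.2)
  expect_true(all(rf$population == 1))
  w <- transition_weight(sys, ex, rf$field_G[1],
                         c(rf$lower[1], rf$upper[1]), 0.5, 0.2)
  expect_identical(attr(w, "population"), 1)
})

test_that("high-temperature Boltzmann weights approach Delta E / kT", {
  sys <- spin_system(1/2, g = 2)
  B0 <- zeeman_field(2, 9.5)
  gap <- ghz_to_cm1(9.5)
  for (T_K in c(300, 1000)) {
    ex <- small_exp(range_G = c(2000, 5000), fwhm_G = 50,
                    temperature_K = T_K)
    rf <- resonance_fields(sys, ex, 0.4, 0.1)
    kT <- gs_constants()$kB_cm_per_K * T_K
    # population difference of a two-level system ~ tanh(gap/2kT)
    expect_equal(rf$population[1], gap / (2 * kT), tolerance = 0.01)
  }
})

test_that("a zero-ZFI powder collapses to one symmetric line", {
  sys <- spin_system(5/2, g = 2)
  ex <- small_exp(range_G = c(2400, 4400), fwhm_G = 100)
  sp <- powder_spectrum(sys, ex)
  B0 <- zeeman_field(2, 9.5)
  i0 <- which.max(sp$absorption)
  dx <- diff(sp$field_G[1:2])
  expect_lt(abs(sp$field_G[i0] - B0), 2 * dx)
  # derivative crosses zero at the center
  expect_lt(abs(sp$derivative[i0]) , 0.05 * max(abs(sp$derivative)))
  # symmetry of the absorption about the center
  lhs <- sp$absorption[i0 - (1:100)]
  rhs <- sp$absorption[i0 + (1:100)]
  expect_equal(lhs, rhs, tolerance = 0.02)
  # absorption is non-negative
  expect_gte(min(sp$absorption), -1e-10 * max(sp$absorption))
})

test_that("derivative trace is the field-derivative of the absorption", {
  sys <- spin_system(5/2, g = 2, D = -0.9, E = -0.3)
  ex <- small_exp(range_G = c(0, 3000), fwhm_G = 100, temperature_K = 15)
  sp <- powder_spectrum(sys, ex)
  dx <- diff(sp$field_G[1:2])
  num <- diff(sp$absorption) / dx
  mid <- (sp$derivative[-1] + sp$derivative[-length(sp$derivative)]) / 2
  expect_equal(num, mid, tolerance = 0.02)
})

test_that("absorption integral is invariant under linewidth changes", {
  sys <- spin_system(1, g = 2, D = 0.01)
  ex1 <- small_exp(range_G = c(1000, 6000), fwhm_G = 60)
  ex2 <- small_exp(range_G = c(1000, 6000), fwhm_G = 150)
  s1 <- powder_spectrum(sys, ex1)
  s2 <- powder_spectrum(sys, ex2)
  expect_equal(sum(s1$absorption), sum(s2$absorption), tolerance = 0.01)
})

test_that("x<->y relabeling with the matching E sign flip leaves the powder unchanged", {
  ex <- small_exp(range_G = c(0, 3000), fwhm_G = 100, temperature_K = 15)
  a <- powder_spectrum(spin_system(5/2, g = 2, D = -0.9, E = -0.3), ex)
  b <- powder_spectrum(spin_system(5/2, g = 2, D = -0.9, E = 0.3), ex)
  expect_equal(a$derivative, b$derivative, tolerance = 0.02)
})

test_that("effective g follows g = h nu / (beta B)", {
  expect_equal(effective_g(3393, 9.5), 2.0005, tolerance = 1e-4)
  expect_equal(effective_g(1000, 9.5), 2 * effective_g(2000, 9.5))
  expect_error(effective_g(0, 9.5), "positive")
})

test_that("rhombogram reproduces the S = 5/2 landmark g values", {
  rh0 <- rhombogram(5/2, doublet = 1, eta = 0)
  expect_equal(rh0$gz, 2, tolerance = 0.02)
  expect_equal(rh0$gx, 6, tolerance = 0.02)
  expect_equal(rh0$gy, 6, tolerance = 0.02)
  rhm <- rhombogram(5/2, doublet = 2, eta = 1/3)
  expect_equal(unlist(rhm[c("gz", "gx", "gy")]),
               c(gz = 4.29, gx = 4.29, gy = 4.29), tolerance = 0.01)
  expect_error(rhombogram(2, 1), "Kramers")
})

test_that("rhombogram g values vary continuously with eta", {
  # the lowest doublet has finite g along every axis across the whole range
  rh <- rhombogram(5/2, doublet = 1, eta = seq(0, 1/3, length.out = 12))
  for (col in c("gz", "gx", "gy")) {
    v <- rh[[col]]
    expect_true(all(is.finite(v)))
    expect_lt(max(abs(diff(v))), 1.0)   # no grid-incommensurate jumps
  }
  # the middle doublet converges onto the isotropic 4.3 point; transverse
  # g values are NA (no resonance) at low rhombicity, without any jumps in
  # the axial one
  rhm <- rhombogram(5/2, doublet = 2, eta = seq(0, 1/3, length.out = 12))
  expect_true(all(is.finite(rhm$gz)))
  expect_lt(max(abs(diff(rhm$gz))), 1.0)
})

test_that("rhombicity distribution: limits, truncation and conservation", {
  sys <- spin_system(3/2, g = 2, D = 0.5, E = 0.5 / 6)
  ex0 <- small_exp(range_G = c(500, 6000), fwhm_G = 150,
                   n_orient = 200)
  # sigma = 0 reduces exactly to the plain powder
  ex0$sigma_eta <- 0
  s0 <- distributed_spectrum(sys, ex0)
  sp <- powder_spectrum(sys, ex0)
  expect_identical(s0$derivative, sp$derivative)
  # sigma > 0 broadens but conserves the absorption integral
  exs <- ex0; exs$sigma_eta <- 0.08
  sd <- distributed_spectrum(sys, exs)
  expect_lt(max(sd$absorption), max(sp$absorption))
  expect_equal(sum(sd$absorption), sum(sp$absorption), tolerance = 0.03)
  expect_true(all(sd$metadata$eta_nodes >= 0 &
                  sd$metadata$eta_nodes <= 1/3))
})

test_that("spectral similarity is a Pearson score with its edge cases", {
  sys <- spin_system(1, g = 2, D = 0.02)
  ex <- small_exp(range_G = c(1000, 6000), fwhm_G = 100)
  sp <- powder_spectrum(sys, ex)
  expect_equal(spectral_similarity(sp, sp), 1.0)
  neg <- sp; neg$derivative <- -neg$derivative
  expect_equal(spectral_similarity(sp, neg), -1.0)
  flat <- sp; flat$derivative <- rep(0, length(flat$derivative))
  expect_error(spectral_similarity(sp, flat), "zero-variance")
})

test_that("orientation grids are deterministic, normalized, octant-limited", {
  g1 <- orientation_grid(1000)
  g2 <- orientation_grid(1000)
  expect_identical(g1, g2)
  expect_equal(sum(g1[, "weight"]), 1)
  expect_true(all(g1[, "theta"] >= 0 & g1[, "theta"] <= pi / 2))
  expect_true(all(g1[, "phi"] >= 0 & g1[, "phi"] <= pi / 2))
  expect_gt(nrow(orientation_grid(2000)), nrow(g1))
  # quarter-octant reduction
  gq <- orientation_grid(1000, phi_max = pi / 4)
  expect_true(all(gq[, "phi"] <= pi / 4))
  expect_lt(nrow(gq), nrow(g1))
})

test_that("spectrum files round-trip bit-exactly", {
  sys <- spin_system(1, g = 2, D = 0.02)
  ex <- small_exp(range_G = c(1000, 6000), fwhm_G = 100)
  sp <- powder_spectrum(sys, ex)
  path <- tempfile(fileext = ".dat")
  write_spectrum(sp, path)
  rd <- read_spectrum(path)
  expect_identical(rd$field_G, sp$field_G)
  expect_identical(rd$absorption, sp$absorption)
  expect_identical(rd$derivative, sp$derivative)
  # header carries the configuration echo
  expect_true(any(grepl("freq_GHz", names(rd$metadata))))
  first <- readLines(path, n = 1)
  expect_match(first, "^#")
  unlink(path)
})
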
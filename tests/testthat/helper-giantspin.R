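# Shared helpers: an independent pure-R resonance finder used to cross-check
# the compiled search, and lazily cached heavy simulations shared between
# test files (computed once per session).

# independent reference: dense eigenvalue scan + uniroot per bracket,
# entirely through the R-level Hamiltonian path
r_reference_resonances <- function(system, freq_GHz, range_G, theta, phi,
                                   n_scan = 400) {
  freq <- ghz_to_cm1(freq_GHz)
  Bs <- seq(range_G[1], range_G[2], length.out = n_scan)
  ev <- vapply(Bs, function(B)
    eigensystem(build_hamiltonian(system, B, theta, phi))$values,
    numeric(2 * system$S + 1))
  dim <- nrow(ev)
  out <- list()
  for (a in 1:(dim - 1)) for (b in (a + 1):dim) {
    f <- ev[b, ] - ev[a, ] - freq
    brk <- which(f[-length(f)] * f[-1] <= 0 &
                 !(f[-length(f)] == 0 & f[-1] == 0))
    for (k in brk) {
      root <- uniroot(function(B) {
        e <- eigensystem(build_hamiltonian(system, B, theta, phi))$values
        e[b] - e[a] - freq
      }, c(Bs[k], Bs[k + 1]), tol = 1e-8)$root
      out[[length(out) + 1]] <- data.frame(field_G = root,
                                           lower = a, upper = b)
    }
  }
  if (length(out) == 0) return(data.frame(field_G = numeric(0),
                                          lower = integer(0),
                                          upper = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$field_G), ]
}

# session cache for expensive shared simulations
.gs_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.gs_cache[[key]])) .gs_cache[[key]] <- force(expr)
  .gs_cache[[key]]
}

get_fig2_spectra <- function() {
  cached("fig2", {
    fx <- epr_fixtures()
    list(blue = powder_spectrum(fx$fig2_blue$system, fx$fig2_blue$experiment),
         red = powder_spectrum(fx$fig2_red$system, fx$fig2_red$experiment))
  })
}

get_inventory <- function() {
  cached("inventory", {
    fx <- epr_fixtures()
    inv <- inventory_run(fx$fig5_inventory$system,
                         fx$fig5_inventory$experiment,
                         D_base_MHz = fx$fig5_inventory$D_base_MHz)
    list(inv = inv, features = inventory_features(inv))
  })
}

# small synthetic epr_spectrum built from analytic gaussian components,
# for exercising the feature detector independently of the simulator
synthetic_spectrum <- function(centers, amps, fwhm, range_G = c(0, 7000),
                               n = 1024) {
  x <- seq(range_G[1], range_G[2], length.out = n)
  s <- fwhm / (2 * sqrt(2 * log(2)))
  absn <- rep(0, n)
  der <- rep(0, n)
  for (i in seq_along(centers)) {
    absn <- absn + amps[i] * exp(-(x - centers[i])^2 / (2 * s^2))
    der <- der - amps[i] * (x - centers[i]) / s^2 *
      exp(-(x - centers[i])^2 / (2 * s^2))
  }
  structure(list(field_G = x, absorption = absn, derivative = der,
                 metadata = list(synthetic = TRUE)),
            class = "epr_spectrum")
}
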
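# Powder spectrum engine: experiment configuration, orientation grids,
# resonance search (compiled core), lineshape convolution, effective g
# values, rhombograms and rhombicity-distributed spectra.

#' Declare an EPR experiment
#'
#' Spectrometer and simulation settings for a field-swept CW experiment.
#' With `temperature_K = NULL` all sublevels are taken equally populated
#' (the population factor is exactly 1); otherwise transition weights carry
#' the Boltzmann population difference of the two connected levels.
#'
#' `n_orient` is the approximate number of orientations of the deterministic
#' equal-solid-angle ("igloo") grid on one octant (sufficient for
#' orthorhombic symmetry).  `n_scan` is the number of points of the
#' eigenvalue pre-scan per orientation from which resonance brackets are
#' taken; brackets are polished to a relative field tolerance of 1e-6.
#'
#' @param freq_GHz microwave frequency in GHz.
#' @param range_G field axis start and stop, gauss.
#' @param n_points number of field-axis points.
#' @param temperature_K sample temperature in kelvin, or `NULL` for equal
#'   populations.
#' @param lineshape `"gaussian"` or `"lorentzian"`.
#' @param fwhm_G full width at half maximum of the convolution line, gauss.
#' @param n_orient approximate orientation count of the powder grid.
#' @param n_scan eigenvalue pre-scan points per orientation.
#' @param sigma_eta standard deviation of a rhombicity distribution
#'   (dimensionless), used by [distributed_spectrum()].
#' @param n_eta_nodes Gauss-Hermite node count for the rhombicity
#'   quadrature.
#' @param jac_floor_frac floor on |d(deltaE)/dB| at a resonance, as a
#'   fraction of the isotropic Zeeman slope g*beta; transitions flatter than
#'   this are flagged and their frequency-to-field Jacobian clamped.
#' @param mom_cutoff_frac transitions whose squared transition moment at
#'   both bracket endpoints is below this fraction of S(S+1) are treated as
#'   forbidden and dropped before root polishing.
#' @return object of class `epr_experiment`.
#' @examples
#' epr_experiment(freq_GHz = 9.5, range_G = c(0, 4000), fwhm_G = 100,
#'                temperature_K = 15)
#' @export
epr_experiment <- function(freq_GHz = 9.5, range_G = c(0, 7000),
                           n_points = 1024, temperature_K = NULL,
                           lineshape = c("gaussian", "lorentzian"),
                           fwhm_G = 100, n_orient = 2000, n_scan = 256,
                           sigma_eta = NULL, n_eta_nodes = 11,
                           jac_floor_frac = 1e-2, mom_cutoff_frac = 1e-6) {
  lineshape <- match.arg(lineshape)
  stopifnot(is.numeric(freq_GHz), length(freq_GHz) == 1L, freq_GHz > 0,
            length(range_G) == 2L, range_G[2] > range_G[1], range_G[1] >= 0,
            n_points >= 8, fwhm_G > 0, n_orient >= 1, n_scan >= 16,
            jac_floor_frac > 0, mom_cutoff_frac >= 0)
  if (!is.null(temperature_K))
    stopifnot(is.numeric(temperature_K), temperature_K > 0)
  if (!is.null(sigma_eta))
    stopifnot(is.numeric(sigma_eta), sigma_eta >= 0)
  structure(list(freq_GHz = freq_GHz, range_G = as.numeric(range_G),
                 n_points = as.integer(n_points),
                 temperature_K = temperature_K, lineshape = lineshape,
                 fwhm_G = fwhm_G, n_orient = as.integer(n_orient),
                 n_scan = as.integer(n_scan), sigma_eta = sigma_eta,
                 n_eta_nodes = as.integer(n_eta_nodes),
                 jac_floor_frac = jac_floor_frac,
                 mom_cutoff_frac = mom_cutoff_frac),
            class = "epr_experiment")
}

#' @export
print.epr_experiment <- function(x, ...) {
  cat(sprintf(
    "EPR experiment: %.4g GHz, %g-%g G (%d pts), %s FWHM %g G\n",
    x$freq_GHz, x$range_G[1], x$range_G[2], x$n_points, x$lineshape,
    x$fwhm_G))
  cat(sprintf("  populations: %s; powder grid: ~%d orientations\n",
              if (is.null(x$temperature_K)) "equal"
              else paste0("Boltzmann at ", x$temperature_K, " K"),
              x$n_orient))
  invisible(x)
}

#' Deterministic equal-solid-angle orientation grid on one octant
#'
#' Igloo-type grid: rings of constant polar angle theta at midpoints of
#' equal theta intervals, with the azimuthal point count of each ring
#' proportional to sin(theta), so every point subtends approximately the
#' same solid angle.  Weights are exact ring solid angles divided by the
#' ring's point count, normalized to sum to 1.  For axially symmetric
#' problems (`axial = TRUE`) a single-azimuth theta grid is returned.
#'
#' @param n_orient requested approximate number of orientations.
#' @param axial logical; restrict to phi = 0 (theta-only grid).
#' @param phi_max azimuthal extent of the fundamental domain (pi/2 for
#'   orthorhombic symmetry; smaller when the in-plane anisotropy has a
#'   higher rotational symmetry, e.g. pi/4 for a pure q = 4 term).
#' @return matrix with columns `theta`, `phi`, `weight`.
#' @export
orientation_grid <- function(n_orient, axial = FALSE, phi_max = pi / 2) {
  stopifnot(n_orient >= 1, phi_max > 0, phi_max <= pi / 2)
  if (axial) {
    L <- max(100L, 2L * ceiling(sqrt(n_orient * pi / 2)))
    th <- (seq_len(L) - 0.5) * (pi / 2) / L
    w <- sin(th)
    return(cbind(theta = th, phi = rep(0, L), weight = w / sum(w)))
  }
  L <- max(4L, ceiling(sqrt(n_orient * pi / 2)))
  th <- (seq_len(L) - 0.5) * (pi / 2) / L
  frac <- phi_max / (pi / 2)
  res <- vector("list", L)
  for (i in seq_len(L)) {
    nphi <- max(1L, round((L - 1) * sin(th[i]) * frac))
    ph <- (seq_len(nphi) - 0.5) * phi_max / nphi
    res[[i]] <- cbind(theta = th[i], phi = ph,
                      weight = sin(th[i]) / nphi)
  }
  g <- do.call(rbind, res)
  g[, "weight"] <- g[, "weight"] / sum(g[, "weight"])
  g
}

# TRUE when the powder pattern cannot depend on the azimuth: isotropic
# gx = gy and only q = 0 zero-field components.
.is_axial <- function(system) {
  qs <- vapply(system$terms, function(t) t$q, 0L)
  all(qs == 0L) && isTRUE(all.equal(system$g[1], system$g[2]))
}

# fundamental azimuthal domain of the powder average: the in-plane pattern
# repeats with the rotational period of the transverse terms and is even in
# phi, so a pure q = 4 (q = 6) anisotropy needs only phi in [0, pi/4]
# ([0, pi/6]); any q = 2 content needs the full octant
.phi_max <- function(system) {
  if (!isTRUE(all.equal(system$g[1], system$g[2]))) return(pi / 2)
  qs <- unique(vapply(system$terms, function(t) t$q, 0L))
  qs <- setdiff(qs, 0L)
  if (length(qs) == 0) return(pi / 2)
  if (all(qs == 4L)) return(pi / 4)
  if (all(qs == 6L)) return(pi / 6)
  pi / 2
}

# lineshape kernels on a symmetric offset grid; absorption normalized to
# unit integral, derivative the analytic d/dB of the same shape
.lineshape_kernel <- function(dx, fwhm, shape) {
  half_w <- if (shape == "gaussian") 5 * fwhm else 40 * fwhm
  K <- max(4L, ceiling(half_w / dx))
  x <- (-K:K) * dx
  if (shape == "gaussian") {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    a <- exp(-x^2 / (2 * s^2)) / (s * sqrt(2 * pi))
    d <- -x / s^2 * a
  } else {
    gam <- fwhm / 2
    a <- (gam / pi) / (x^2 + gam^2)
    d <- -(2 * gam / pi) * x / (x^2 + gam^2)^2
  }
  norm <- sum(a) * dx
  list(absorption = a / norm, derivative = d / norm, K = K)
}

.conv_open <- function(x, k) {
  nk <- length(k)
  full <- stats::convolve(x, rev(k), type = "open")
  K <- (nk - 1L) / 2L
  full[(K + 1L):(K + length(x))]
}

# documented floor below which the powder grid is considered under-resolved
.grid_floor <- function(S) 50 * (2 * S + 1)

#' Simulate a powder EPR spectrum
#'
#' Accumulates the resonance-field stick spectrum over the deterministic
#' octant orientation grid and convolves it with the configured lineshape.
#' Each stick carries the perpendicular-mode transition moment
#' \eqn{(|\langle i|S_{x'}|j\rangle|^2 + |\langle i|S_{y'}|j\rangle|^2)/2}
#' in the frame with z' along the static field, the Boltzmann population
#' difference of the two connected levels (or 1 in equal-population mode),
#' and the frequency-to-field Jacobian \eqn{1/|d\Delta E/dB|}.  The result
#' is fully deterministic.
#'
#' @param system a [spin_system()].
#' @param experiment an [epr_experiment()].
#' @return object of class `epr_spectrum`: list with `field_G`,
#'   `absorption`, `derivative` (equal-length numeric vectors) and
#'   `metadata` (full input echo plus diagnostics).
#' @examples
#' \donttest{
#' sys <- spin_system(5/2, g = 2, D = -0.9, E = -0.3)
#' exp <- epr_experiment(range_G = c(0, 3000), fwhm_G = 100,
#'                       temperature_K = 15, n_orient = 500)
#' sp <- powder_spectrum(sys, exp)
#' plot(sp)
#' }
#' @export
powder_spectrum <- function(system, experiment) {
  stopifnot(inherits(system, "spin_system"),
            inherits(experiment, "epr_experiment"))
  op <- spin_matrices(system$S)
  H0 <- zfi_hamiltonian(system) + 0i
  axial <- .is_axial(system)
  grid <- orientation_grid(experiment$n_orient, axial = axial,
                           phi_max = .phi_max(system))

  ax <- seq(experiment$range_G[1], experiment$range_G[2],
            length.out = experiment$n_points)
  dx <- ax[2] - ax[1]
  ker <- .lineshape_kernel(dx, experiment$fwhm_G, experiment$lineshape)
  pad <- ker$K
  n_ext <- experiment$n_points + 2L * pad
  ext_start <- ax[1] - pad * dx

  freq_cm <- ghz_to_cm1(experiment$freq_GHz)
  kT <- if (is.null(experiment$temperature_K)) -1
        else .gs_const$kB_cm_per_K * experiment$temperature_K
  g_iso <- mean(system$g)
  jac_floor <- experiment$jac_floor_frac * g_iso * .gs_const$beta_cm_per_G
  search_min <- max(0, ext_start)
  search_max <- ax[experiment$n_points] + pad * dx

  sticks <- powder_sticks_cpp(
    H0, op$Sx + 0i, op$Sy, op$Sz + 0i, system$g,
    .gs_const$beta_cm_per_G, grid, freq_cm,
    search_min, search_max, experiment$n_scan,
    ext_start, dx, n_ext, kT, jac_floor,
    experiment$mom_cutoff_frac %||% 1e-6, 4L)

  absorption <- .conv_open(as.numeric(sticks), ker$absorption)
  derivative <- .conv_open(as.numeric(sticks), ker$derivative)
  keep <- (pad + 1L):(pad + experiment$n_points)

  warn <- character(0)
  if (nrow(grid) < .grid_floor(system$S))
    warn <- c(warn, sprintf(
      "powder grid (%d orientations) below the documented floor (%d) for S = %s",
      nrow(grid), .grid_floor(system$S), format(system$S)))

  structure(list(
    field_G = ax,
    absorption = absorption[keep] * dx,
    derivative = derivative[keep] * dx,
    metadata = list(
      system = system, experiment = experiment,
      n_orientations = nrow(grid), axial_grid = axial,
      n_sticks = attr(sticks, "n_sticks"),
      n_clamped = attr(sticks, "n_clamped"),
      warnings = warn)),
    class = "epr_spectrum")
}

#' @export
print.epr_spectrum <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "EPR powder spectrum: %d points, %g-%g G, %s transitions from %d orientations\n",
    length(x$field_G), min(x$field_G), max(x$field_G),
    format(md$n_sticks %||% NA), md$n_orientations %||% NA))
  for (w in md$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param x an `epr_spectrum`.
#' @param what `"derivative"` (CW-EPR convention) or `"absorption"`.
#' @param ... passed to [plot()].
#' @rdname powder_spectrum
#' @export
plot.epr_spectrum <- function(x, what = c("derivative", "absorption"), ...) {
  what <- match.arg(what)
  plot(x$field_G, x[[what]], type = "l", xlab = "Field (gauss)",
       ylab = paste0(what, " (arb. units)"), ...)
  abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Resonance fields for one molecular orientation
#'
#' All fields in the experiment's window where a level gap matches the
#' microwave quantum, for the static field along (theta, phi): segment-wise
#' bracketing on a dense eigenvalue scan, then bisection-type polishing to a
#' relative tolerance of 1e-6.  Looping transitions (multiple roots of the
#' same level pair) are all reported.
#'
#' @param system a [spin_system()].
#' @param experiment an [epr_experiment()].
#' @param theta,phi field orientation, radians.
#' @return data frame with columns `field_G`, `lower`, `upper` (sorted level
#'   indices, ascending energies), `moment`, `population`, `jacobian`,
#'   `weight` and `clamped`.
#' @export
resonance_fields <- function(system, experiment, theta = 0, phi = 0) {
  stopifnot(inherits(system, "spin_system"),
            inherits(experiment, "epr_experiment"))
  if (!is.finite(theta) || !is.finite(phi))
    stop("orientation angles must be finite", call. = FALSE)
  op <- spin_matrices(system$S)
  H0 <- zfi_hamiltonian(system) + 0i
  freq_cm <- ghz_to_cm1(experiment$freq_GHz)
  kT <- if (is.null(experiment$temperature_K)) -1
        else .gs_const$kB_cm_per_K * experiment$temperature_K
  jac_floor <- experiment$jac_floor_frac * mean(system$g) *
    .gs_const$beta_cm_per_G
  orientation_resonances_cpp(
    H0, op$Sx + 0i, op$Sy, op$Sz + 0i, system$g, .gs_const$beta_cm_per_G,
    theta, phi, freq_cm, experiment$range_G[1], experiment$range_G[2],
    experiment$n_scan, kT, jac_floor,
    experiment$mom_cutoff_frac %||% 1e-6)
}

#' Weight of one transition at its resonance field
#'
#' Recomputes, in plain R, the weight of the transition between the sorted
#' levels `pair = c(i, j)` at field `field_G` along (theta, phi): the
#' perpendicular-mode transition moment, times the Boltzmann population
#' difference (or 1 in equal-population mode), times the clamped
#' frequency-to-field Jacobian.
#'
#' @param system a [spin_system()].
#' @param experiment an [epr_experiment()] (population mode and Jacobian
#'   floor are taken from it).
#' @param field_G resonance field, gauss.
#' @param pair integer pair (i, j), ascending level indices, i < j.
#' @param theta,phi field orientation, radians.
#' @param dB_G finite-difference step for the gap slope, gauss.
#' @return the non-negative weight, with components `moment`, `population`,
#'   `jacobian` and `clamped` as attributes.
#' @export
transition_weight <- function(system, experiment, field_G, pair,
                              theta = 0, phi = 0, dB_G = 0.5) {
  stopifnot(length(pair) == 2L, pair[1] < pair[2])
  es <- eigensystem(build_hamiltonian(system, field_G, theta, phi))
  i <- pair[1]; j <- pair[2]
  op <- spin_matrices(system$S)
  u <- c(cos(theta) * cos(phi), cos(theta) * sin(phi), -sin(theta))
  v <- c(-sin(phi), cos(phi), 0)
  S1 <- u[1] * op$Sx + u[2] * op$Sy + u[3] * op$Sz
  S2 <- v[1] * op$Sx + v[2] * op$Sy + v[3] * op$Sz
  m1 <- sum(Conj(es$vectors[, i]) * (S1 %*% es$vectors[, j]))
  m2 <- sum(Conj(es$vectors[, i]) * (S2 %*% es$vectors[, j]))
  moment <- 0.5 * (Mod(m1)^2 + Mod(m2)^2)
  pop <- 1
  if (!is.null(experiment$temperature_K)) {
    kT <- .gs_const$kB_cm_per_K * experiment$temperature_K
    w <- exp(-(es$values - min(es$values)) / kT)
    w <- w / sum(w)
    pop <- w[i] - w[j]
  }
  gap <- function(B) {
    ev <- eigensystem(build_hamiltonian(system, B, theta, phi))$values
    ev[j] - ev[i]
  }
  slope <- abs(gap(field_G + dB_G) - gap(max(0, field_G - dB_G))) /
    (field_G + dB_G - max(0, field_G - dB_G))
  floor_ <- experiment$jac_floor_frac * mean(system$g) *
    .gs_const$beta_cm_per_G
  clamped <- slope < floor_
  if (clamped) slope <- floor_
  structure(moment * pop / slope, moment = moment, population = pop,
            jacobian = 1 / slope, clamped = clamped)
}

#' Effective g value of a resonance
#'
#' \eqn{g_{eff} = h\nu / (\beta B)}: the apparent g value of a transition
#' observed at field `field_G` for microwave frequency `freq_GHz`.
#'
#' @param field_G resonance field(s), gauss, > 0.
#' @param freq_GHz microwave frequency, GHz.
#' @return effective g value(s).
#' @examples
#' effective_g(3393, 9.5)   # about 2.00
#' @export
effective_g <- function(field_G, freq_GHz = 9.5) {
  if (any(!is.finite(field_G)) || any(field_G <= 0))
    stop("resonance field must be positive", call. = FALSE)
  ghz_to_cm1(freq_GHz) / (.gs_const$beta_cm_per_G * field_G)
}

#' Field of the free-spin resonance
#'
#' \eqn{B_0 = h\nu/(g\beta)}, the resonance field of a zero-ZFI system.
#'
#' @param g g value.
#' @param freq_GHz microwave frequency, GHz.
#' @return field in gauss.
#' @export
zeeman_field <- function(g = 2.00, freq_GHz = 9.5) {
  ghz_to_cm1(freq_GHz) / (g * .gs_const$beta_cm_per_G)
}

# intra-doublet resonance field along one axis by monotone bracketing
.doublet_resonance <- function(system, pair, theta, phi, freq_cm,
                               B_hi = 3e4) {
  gap <- function(B) {
    ev <- eigensystem(build_hamiltonian(system, B, theta, phi))$values
    ev[pair[2]] - ev[pair[1]] - freq_cm
  }
  lo <- 1e-3
  if (gap(lo) > 0 || gap(B_hi) < 0) return(NA_real_)
  uniroot(gap, c(lo, B_hi), tol = 1e-6 * B_hi)$root
}

#' Rhombogram: effective g values versus rhombicity
#'
#' For a half-integer (Kramers) spin in the strong zero-field limit
#' |D| >> h nu, computes the three principal-axis effective g values of one
#' Kramers doublet as a function of rhombicity eta = E/D in [0, 1/3].  Each
#' g value comes from a numerical search for the intra-doublet resonance
#' field with the field along z, x and y, evaluated at a documented large
#' |D| (default 10 cm^-1, X-band).  Doublets are indexed by ascending
#' zero-field energy for the sign of `D_cm` given (use negative D to flip
#' the doublet order).
#'
#' @param S half-integer spin.
#' @param doublet doublet index, 1 = lowest in energy.
#' @param eta rhombicity grid in [0, 1/3].
#' @param D_cm axial parameter used for the strong-ZFI limit, cm^-1.
#' @param freq_GHz microwave frequency, GHz.
#' @param g intrinsic (real) g value.
#' @return data frame of class `rhombogram` with columns `eta`, `gz`, `gx`,
#'   `gy` (NA where no resonance below the field search limit).
#' @examples
#' \donttest{
#' rh <- rhombogram(5/2, doublet = 2, eta = c(0, 1/6, 1/3))
#' }
#' @export
rhombogram <- function(S, doublet = 1, eta = seq(0, 1/3, length.out = 34),
                       D_cm = 10, freq_GHz = 9.5, g = 2.00) {
  S <- .check_spin(S)
  if (abs(2 * S) %% 2 != 1)
    stop("rhombograms are defined for Kramers (half-integer) spins",
         call. = FALSE)
  ndoub <- (2 * S + 1) / 2
  stopifnot(doublet >= 1, doublet <= ndoub)
  if (any(eta < -1e-12) || any(eta > 1/3 + 1e-12))
    stop("eta must lie in [0, 1/3]", call. = FALSE)
  freq_cm <- ghz_to_cm1(freq_GHz)
  pair <- c(2 * doublet - 1, 2 * doublet)
  axes <- list(z = c(0, 0), x = c(pi / 2, 0), y = c(pi / 2, pi / 2))
  out <- lapply(eta, function(e) {
    sys <- spin_system(S, g = g, D = D_cm, E = e * D_cm)
    vapply(axes, function(a) {
      B <- .doublet_resonance(sys, pair, a[1], a[2], freq_cm)
      if (is.na(B)) NA_real_ else effective_g(B, freq_GHz)
    }, 0)
  })
  res <- data.frame(eta = eta, gz = vapply(out, `[[`, 0, "z"),
                    gx = vapply(out, `[[`, 0, "x"),
                    gy = vapply(out, `[[`, 0, "y"))
  class(res) <- c("rhombogram", "data.frame")
  attr(res, "S") <- S; attr(res, "doublet") <- doublet
  res
}

#' @export
plot.rhombogram <- function(x, ...) {
  matplot(x$eta, cbind(x$gz, x$gx, x$gy), type = "l", lty = 1,
          xlab = expression(eta == E / D), ylab = "effective g", ...)
  legend("topleft", legend = c("z", "x", "y"), lty = 1, col = 1:3, bty = "n")
  invisible(x)
}

#' Powder spectrum averaged over a rhombicity distribution
#'
#' Superposes powder spectra over a normal distribution of the rhombicity
#' eta with mean the system's own E/D and standard deviation
#' `experiment$sigma_eta`, by Gauss-Hermite quadrature truncated to the
#' canonical interval [0, 1/3] (nodes outside are dropped and the remaining
#' weights renormalized).  Deterministic.  With `sigma_eta` zero or unset
#' this reduces exactly to [powder_spectrum()].
#'
#' @param system a [spin_system()] built with conventional `D` and `E`.
#' @param experiment an [epr_experiment()] with `sigma_eta` set.
#' @return an `epr_spectrum`; metadata records the quadrature nodes.
#' @export
distributed_spectrum <- function(system, experiment) {
  stopifnot(inherits(system, "spin_system"),
            inherits(experiment, "epr_experiment"))
  sig <- experiment$sigma_eta
  if (is.null(sig) || sig == 0) return(powder_spectrum(system, experiment))
  if (is.null(system$conventional) || system$conventional$D == 0)
    stop("distributed_spectrum needs a system built with conventional D, E",
         call. = FALSE)
  eta0 <- system$conventional$eta
  gh <- pracma::gaussHermite(experiment$n_eta_nodes)
  eta_i <- eta0 + sqrt(2) * sig * gh$x
  w_i <- gh$w / sqrt(pi)
  keep <- eta_i >= 0 & eta_i <= 1/3
  if (!any(keep))
    stop("no quadrature node falls inside eta in [0, 1/3]", call. = FALSE)
  eta_i <- eta_i[keep]
  w_i <- w_i[keep] / sum(w_i[keep])
  extra <- Filter(function(t) t$k > 2, system$terms)
  acc_a <- acc_d <- 0
  base <- NULL
  for (i in seq_along(eta_i)) {
    sys_i <- spin_system(system$S, g = system$g,
                         D = system$conventional$D,
                         E = eta_i[i] * system$conventional$D,
                         terms = extra)
    sp <- powder_spectrum(sys_i, experiment)
    acc_a <- acc_a + w_i[i] * sp$absorption
    acc_d <- acc_d + w_i[i] * sp$derivative
    if (is.null(base)) base <- sp
  }
  base$absorption <- acc_a
  base$derivative <- acc_d
  base$metadata$system <- system
  base$metadata$eta_nodes <- eta_i
  base$metadata$eta_weights <- w_i
  base
}

#' Similarity of two first-derivative spectra
#'
#' Pearson correlation of the first-derivative traces; spectrum `b` is
#' resampled onto the field axis of `a` by linear interpolation if the axes
#' differ.  1 means identical line shape (up to scale), -1 an inverted one.
#'
#' @param a,b `epr_spectrum` objects.
#' @return correlation in [-1, 1].
#' @export
spectral_similarity <- function(a, b) {
  stopifnot(inherits(a, "epr_spectrum"), inherits(b, "epr_spectrum"))
  da <- a$derivative
  db <- if (isTRUE(all.equal(a$field_G, b$field_G))) b$derivative
        else approx(b$field_G, b$derivative, xout = a$field_G,
                    rule = 2)$y
  if (stats::sd(da) == 0 || stats::sd(db) == 0)
    stop("cannot correlate a zero-variance trace", call. = FALSE)
  cor(da, db)
}
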
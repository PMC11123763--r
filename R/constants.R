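# Physical constants, centralized.  Energies are carried in cm^-1 throughout
# the package; magnetic fields in gauss (1 T = 1e4 G).

.gs_const <- list(
  beta_cm_per_T = 0.4668645,      # Bohr magneton / hc, cm^-1 T^-1
  beta_cm_per_G = 0.4668645e-4,   # same, per gauss
  kB_cm_per_K   = 0.69503480,     # Boltzmann constant / hc, cm^-1 K^-1
  MHz_per_cm    = 29979.2458      # c in MHz cm (1 cm^-1 = 29979.2458 MHz)
)

#' Unit conversions between wavenumbers and frequency
#'
#' Energy unit converters based on 1 cm^-1 = 29979.2458 MHz (exact, via the
#' defined speed of light).  Zero-field coefficients are stored in cm^-1 in
#' this package; experimental microwave frequencies are usually quoted in
#' GHz and zero-field splittings of nanoparticle cores often in MHz.
#'
#' @param x numeric vector of values to convert.
#' @return numeric vector in the target unit.
#' @examples
#' mhz_to_cm1(100)      # 100 MHz = 0.00334 cm^-1
#' cm1_to_ghz(0.3)      # X-band microwave quantum is about 0.3 cm^-1
#' @export
cm1_to_mhz <- function(x) x * .gs_const$MHz_per_cm

#' @rdname cm1_to_mhz
#' @export
mhz_to_cm1 <- function(x) x / .gs_const$MHz_per_cm

#' @rdname cm1_to_mhz
#' @export
cm1_to_ghz <- function(x) x * .gs_const$MHz_per_cm / 1000

#' @rdname cm1_to_mhz
#' @export
ghz_to_cm1 <- function(x) x * 1000 / .gs_const$MHz_per_cm

#' Physical constants used by the simulator
#'
#' Returns the constant table: the Bohr magneton in cm^-1 T^-1 and
#' cm^-1 G^-1, the Boltzmann constant in cm^-1 K^-1, and the MHz-per-cm^-1
#' conversion factor.
#'
#' @return named list of constants.
#' @export
gs_constants <- function() .gs_const
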
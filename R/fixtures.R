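# Ready-to-run parameter presets for the model calculations the package
# reproduces: the g = 4.3 degeneracy pair, the scalability audit, the
# S = 10 switch-on inventory, and the ferritin-core scaling numbers.

#' Named parameter presets
#'
#' Returns every preset as a ready-to-run configuration:
#' \describe{
#'   \item{`fig2_blue`}{maximally rhombic high-spin Fe(III): S = 5/2,
#'     D = -0.9, E = -0.3 cm^-1 (E/D = 1/3), g = 2.00, 15 K, Gaussian
#'     FWHM 100 G.}
#'   \item{`fig2_red`}{the spectrally near-degenerate alternative: S = 5/2,
#'     D = -0.9, E = -0.14, B44 = 0.24 cm^-1, same experiment.}
#'   \item{`fig3_audit`}{inputs of the higher-order-term scalability audit:
#'     D = -1.2e-5 cm^-1 at S = 5000, ratio 1e-4 per step in k,
#'     S_eq = 10, 100, 1000.}
#'   \item{`fig5_inventory`}{the switch-on inventory base: S = 10,
#'     g = 2.00, equal populations, Gaussian FWHM 300 G, D = 100 MHz.}
#'   \item{`pff_scaling`}{ferritin-core giant-spin scaling: S = 5000,
#'     D = -1.2e-5 cm^-1, n = 500, anisotropy field 1400 G.}
#' }
#'
#' The microwave frequency is not part of the published parameter sets;
#' the presets use 9.50 GHz (X-band).  Field ranges and grid sizes are
#' package choices documented in the methods vignette.
#'
#' @return named list of presets; spectrum presets hold `system` and
#'   `experiment`, the others hold plain parameter lists.
#' @examples
#' fx <- epr_fixtures()
#' fx$fig2_blue$system
#' @export
epr_fixtures <- function() {
  exp_fig2 <- epr_experiment(freq_GHz = 9.5, range_G = c(0, 3000),
                             n_points = 1024, temperature_K = 15,
                             lineshape = "gaussian", fwhm_G = 100,
                             n_orient = 5000, n_scan = 256)
  exp_fig5 <- epr_experiment(freq_GHz = 9.5, range_G = c(0, 7000),
                             n_points = 1024, temperature_K = NULL,
                             lineshape = "gaussian", fwhm_G = 300,
                             n_orient = 2000, n_scan = 256)
  list(
    fig2_blue = list(
      system = spin_system(5/2, g = 2.00, D = -0.9, E = -0.3),
      experiment = exp_fig2),
    fig2_red = list(
      system = spin_system(5/2, g = 2.00, D = -0.9, E = -0.14,
                           terms = list(zfi_term(4, 4, 0.24))),
      experiment = exp_fig2),
    fig3_audit = list(D = -1.2e-5, S = 5000, S_eq = c(10, 100, 1000),
                      per_step_ratio = 1e-4),
    fig5_inventory = list(
      system = spin_system(10, g = 2.00),
      experiment = exp_fig5,
      D_base_MHz = 100),
    pff_scaling = list(S = 5000, D = -1.2e-5, n = 500, B_a = 1400,
                       g = 2.00)
  )
}
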
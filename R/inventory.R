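# Coefficient switch-on inventory: starting from a zero-ZFI giant spin,
# each orthorhombic Stevens coefficient is switched on individually at a
# "just resolved" level, then doubled and tripled, and the resulting powder
# line shapes are catalogued by a rule-based feature detector.

.inventory_coeffs <- list(
  c(2, 0), c(2, 2), c(4, 0), c(4, 2), c(4, 4),
  c(6, 0), c(6, 2), c(6, 4), c(6, 6))

# declared feature-detection tolerances, in one place
.feature_cfg <- list(
  half_field_window = 0.15,   # half-width of the half-field window, as a
                              # fraction of B0 (window: |B - B0/2| <= 0.15 B0)
  near_zero_frac    = 0.10,   # near-zero window: below this fraction of B0
  main_window_frac  = 0.20,   # main-line window: B0 * (1 +/- this)
  shoulder_max_frac = 1.60,   # shoulder search ends at this fraction of B0
  amp_floor_frac    = 0.01,   # derivative feature floor, fraction of base pk-pk
  split_floor_frac  = 0.10,   # swing required around a main-line zero
                              # crossing for it to count toward a split,
                              # as a fraction of the trace's own pk-pk
  abs_floor_frac    = 0.01,   # absorption bump floor, fraction of trace max
  resolve_frac      = 0.05    # "just resolved": max |delta deriv| vs base pk-pk
)

# terms for one switched-on coefficient; the (2,2) coefficient requires a
# finite axial partner and is tied to it at maximal rhombicity B22 = B20
.switch_terms <- function(k, q, B) {
  if (k == 2 && q == 2) list(zfi_term(2, 0, B), zfi_term(2, 2, B))
  else list(zfi_term(k, q, B))
}

.deviation <- function(sp, base) max(abs(sp$derivative - base$derivative))

.pkpk <- function(sp) max(sp$derivative) - min(sp$derivative)

#' Minimal coefficient producing a resolved spectral change
#'
#' Grows and then bisects the coefficient of one Stevens term (k, q) until
#' the maximum absolute difference of the first-derivative trace from the
#' zero-ZFI base spectrum first exceeds `fraction` of the base peak-to-peak
#' amplitude.  The bracket is refined to 2% relative width; deterministic.
#' For (k, q) = (2, 2) the axial partner is tied as B20 = B22 (maximal
#' rhombicity).
#'
#' @param system the base [spin_system()] (its ZFI terms are ignored; spin
#'   and g are used).
#' @param experiment the [epr_experiment()] used for the search spectra.
#' @param k,q the Stevens coefficient to switch on.
#' @param fraction resolution criterion as a fraction of the base
#'   peak-to-peak derivative amplitude (0 returns the lower search bound).
#' @param base precomputed base spectrum on `experiment` (optional).
#' @param B_max upper coefficient search bound, cm^-1.
#' @return the threshold coefficient in cm^-1, or `NA` (with a warning) if
#'   no resolved change occurs below `B_max`.
#' @export
resolve_threshold <- function(system, experiment, k, q,
                              fraction = .feature_cfg$resolve_frac,
                              base = NULL, B_max = 1) {
  stopifnot(fraction >= 0)
  if (fraction == 0) return(0)
  sys0 <- spin_system(system$S, g = system$g)
  if (is.null(base)) base <- powder_spectrum(sys0, experiment)
  target <- fraction * .pkpk(base)
  dev_at <- function(B) {
    sys <- spin_system(system$S, g = system$g, terms = .switch_terms(k, q, B))
    .deviation(powder_spectrum(sys, experiment), base)
  }
  # physically scaled initial guess: coefficient at which the largest
  # operator matrix element is comparable to the linewidth in energy
  Omax <- max(abs(stevens_operator(system$S, k, q)))
  B_hi <- (experiment$fwhm_G * mean(system$g) * .gs_const$beta_cm_per_G) /
    Omax
  f_hi <- dev_at(B_hi)
  n_grow <- 0
  while (f_hi < target && B_hi < B_max && n_grow < 30) {
    B_hi <- B_hi * 2
    f_hi <- dev_at(B_hi)
    n_grow <- n_grow + 1
  }
  if (f_hi < target) {
    warning("coefficient (", k, ",", q, ") unresolved below B_max = ",
            B_max, " cm^-1", call. = FALSE)
    return(NA_real_)
  }
  B_lo <- 0
  while ((B_hi - B_lo) > 0.02 * B_hi) {
    B_mid <- (B_lo + B_hi) / 2
    if (dev_at(B_mid) >= target) B_hi <- B_mid else B_lo <- B_mid
  }
  B_hi
}

#' Run the coefficient switch-on inventory
#'
#' Produces the deterministic set of 28 spectra: one base spectrum (zero
#' ZFI) plus, for each of the nine orthorhombic Stevens coefficients
#' (2,0), (2,2), (4,0), (4,2), (4,4), (6,0), (6,2), (6,4), (6,6), the
#' spectra at one, two and three times its base value.  The (2,0) base
#' value defaults to D = 100 MHz via B20 = D/3; the (2,2) coefficient is
#' tied to an equal B20 (maximal rhombicity); every other base value is
#' determined by [resolve_threshold()] (the "just resolved" criterion),
#' unless supplied in `base_values`.
#'
#' @param system base [spin_system()] (typically S = 10, g = 2, no ZFI).
#' @param experiment [epr_experiment()] for the final spectra.
#' @param D_base_MHz axial parameter defining the (2,0) and (2,2) base
#'   coefficients, MHz.
#' @param multipliers multiplier schedule (default 1:3).
#' @param base_values optional named vector of base coefficients in cm^-1,
#'   names like `"4_2"`, overriding the threshold search.
#' @param search_experiment reduced-resolution [epr_experiment()] used only
#'   inside the threshold search (defaults to `experiment` with a quarter
#'   of the orientations and half the scan points).
#' @param fraction resolution criterion passed to [resolve_threshold()];
#'   `NULL` (the default) calibrates it on the inventory's own (2,0)
#'   anchor: the fraction is set to the relative spectral deviation that
#'   the `D_base_MHz` axial term itself produces, so that "just resolved"
#'   means the same thing for every coefficient as for the published
#'   second-order base value.
#' @return object of class `inventory_run`: list with the `base` spectrum,
#'   a named list `spectra` (`"k_q:mult"`), the named vector `bases` of
#'   base coefficients, and the configuration.
#' @export
inventory_run <- function(system, experiment, D_base_MHz = 100,
                          multipliers = 1:3, base_values = NULL,
                          search_experiment = NULL,
                          fraction = NULL) {
  stopifnot(inherits(system, "spin_system"),
            inherits(experiment, "epr_experiment"))
  sys0 <- spin_system(system$S, g = system$g)
  base <- powder_spectrum(sys0, experiment)
  if (is.null(search_experiment)) {
    search_experiment <- experiment
    search_experiment$n_orient <- max(200L,
                                      as.integer(experiment$n_orient / 4))
    search_experiment$n_scan <- max(96L, as.integer(experiment$n_scan / 2))
  }
  search_base <- powder_spectrum(sys0, search_experiment)

  B20_base <- mhz_to_cm1(D_base_MHz) / 3
  if (is.null(fraction)) {
    anchor <- spin_system(system$S, g = system$g,
                          terms = .switch_terms(2, 0, B20_base))
    fraction <- .deviation(powder_spectrum(anchor, search_experiment),
                           search_base) / .pkpk(search_base)
  }
  bases <- numeric(0)
  spectra <- list()
  for (kq in .inventory_coeffs) {
    k <- kq[1]; q <- kq[2]
    key <- paste0(k, "_", q)
    Bb <- if (!is.null(base_values) && key %in% names(base_values))
      base_values[[key]]
    else if (k == 2) B20_base
    else resolve_threshold(system, search_experiment, k, q,
                           fraction = fraction, base = search_base)
    bases[key] <- Bb
    for (mult in multipliers) {
      sys <- spin_system(system$S, g = system$g,
                         terms = .switch_terms(k, q, mult * Bb))
      spectra[[paste0(key, ":", mult)]] <- powder_spectrum(sys, experiment)
    }
  }
  structure(list(base = base, spectra = spectra, bases = bases,
                 multipliers = multipliers, D_base_MHz = D_base_MHz,
                 fraction = fraction, system = system,
                 experiment = experiment),
            class = "inventory_run")
}

#' @export
print.inventory_run <- function(x, ...) {
  cat(sprintf("Switch-on inventory: S = %s, %d spectra + base\n",
              format(x$system$S), length(x$spectra)))
  cat("base coefficients (cm^-1):\n")
  print(signif(x$bases, 3))
  invisible(x)
}

# local extrema of y strictly inside the index window, as a data frame
.local_extrema <- function(x, y, lo, hi) {
  idx <- which(x >= lo & x <= hi)
  if (length(idx) < 3) return(data.frame(field = numeric(0),
                                         value = numeric(0)))
  idx <- idx[idx > 1 & idx < length(x)]
  d1 <- y[idx] - y[idx - 1]
  d2 <- y[idx + 1] - y[idx]
  ext <- idx[(d1 > 0 & d2 <= 0) | (d1 < 0 & d2 >= 0)]
  data.frame(field = x[ext], value = y[ext])
}

# zero crossings of y between samples inside [lo, hi], with the sign swing
# around each crossing required to exceed `floor`
.zero_crossings <- function(x, y, lo, hi, floor) {
  idx <- which(x >= lo & x <= hi)
  if (length(idx) < 2) return(numeric(0))
  idx <- idx[-length(idx)]
  cross <- idx[y[idx] * y[idx + 1] < 0]
  keep <- vapply(cross, function(i) {
    left <- max(abs(y[x >= lo & x <= x[i]]))
    right <- max(abs(y[x >= x[i + 1] & x <= hi]))
    min(left, right) >= floor
  }, TRUE)
  x[cross[keep]]
}

#' Rule-based spectral feature detection
#'
#' Compares a spectrum against the zero-ZFI base spectrum on the same field
#' axis and reports: main-line splitting (two or more qualifying zero
#' crossings of the derivative within the g = 2 window, with the splitting
#' in gauss), the main-line peak-to-peak width ratio, an overall broadening
#' ratio (RMS width of the absorption distribution relative to base),
#' shoulder positions flanking the main line (derivative extrema), and the
#' presence of half-field and near-zero-field features (absorption local
#' maxima, judged against the trace's own absorption maximum since sharp
#' central lines would otherwise mask broad low-field intensity).  All
#' windows and amplitude floors are declared in one internal table:
#' half-field window |B - B0/2| <= 0.15 B0, near-zero window below 10% of
#' B0, main window +/-20% of B0, derivative floor 1% of the base
#' peak-to-peak amplitude (10% around a zero crossing for it to count
#' toward a main-line split), absorption floor 1% of the trace maximum.
#'
#' @param spectrum an `epr_spectrum`.
#' @param base the zero-ZFI base `epr_spectrum` on the same field axis.
#' @return object of class `feature_report`: list with elements
#'   `main_split` (logical), `split_G`, `main_width_ratio`,
#'   `broadening_ratio`, `half_field` (logical), `near_zero` (logical),
#'   `shoulders` (fields, gauss), `center_G`.
#' @export
detect_features <- function(spectrum, base) {
  stopifnot(inherits(spectrum, "epr_spectrum"),
            inherits(base, "epr_spectrum"))
  if (!isTRUE(all.equal(spectrum$field_G, base$field_G)))
    stop("spectrum and base must share one field axis", call. = FALSE)
  x <- base$field_G
  cfg <- .feature_cfg
  A <- .pkpk(base)
  if (A == 0 || max(abs(spectrum$derivative)) == 0) {
    return(structure(list(main_split = FALSE, split_G = NA_real_,
                          main_width_ratio = NA_real_,
                          broadening_ratio = NA_real_, half_field = FALSE,
                          near_zero = FALSE, shoulders = numeric(0),
                          center_G = NA_real_),
                     class = "feature_report"))
  }
  B0 <- x[which.max(base$absorption)]
  floor_ <- cfg$amp_floor_frac * A
  main_lo <- B0 * (1 - cfg$main_window_frac)
  main_hi <- B0 * (1 + cfg$main_window_frac)

  # main-line split and splitting; a crossing counts only when the
  # derivative swings substantially on both sides relative to the trace's
  # own amplitude, so weak shoulder spill-over does not mimic a split
  zc <- .zero_crossings(x, spectrum$derivative, main_lo, main_hi,
                        cfg$split_floor_frac * .pkpk(spectrum))
  main_split <- length(zc) >= 2
  split_G <- if (main_split) max(zc) - min(zc) else NA_real_

  # peak-to-peak width of the main feature
  ppw <- function(sp) {
    w <- x >= main_lo & x <= main_hi
    x[w][which.min(sp$derivative[w])] - x[w][which.max(sp$derivative[w])]
  }
  main_width_ratio <- abs(ppw(spectrum)) / abs(ppw(base))

  # overall broadening: rms width of the absorption distribution
  rmsw <- function(sp) {
    a <- pmax(sp$absorption, 0)
    mu <- sum(x * a) / sum(a)
    sqrt(sum((x - mu)^2 * a) / sum(a))
  }
  broadening_ratio <- rmsw(spectrum) / rmsw(base)

  # low-field bumps are judged on the absorption trace: a local maximum
  # whose height is at least abs_floor_frac of the trace's own absorption
  # maximum (per-trace normalization, as spectra are conventionally drawn)
  abs_floor <- cfg$abs_floor_frac * max(spectrum$absorption)
  has_bump <- function(lo, hi) {
    ex <- .local_extrema(x, spectrum$absorption, lo, hi)
    ex <- ex[ex$value >= abs_floor, , drop = FALSE]
    # a maximum at the low edge of the axis also counts (feature centred
    # at or below the start of the sweep)
    edge <- lo <= x[1] && spectrum$absorption[1] >= abs_floor &&
      spectrum$absorption[1] > spectrum$absorption[2]
    nrow(ex) > 0 || edge
  }
  hf_lo <- 0.5 * B0 - cfg$half_field_window * B0
  hf_hi <- 0.5 * B0 + cfg$half_field_window * B0
  half_field <- has_bump(hf_lo, hf_hi)
  near_zero <- has_bump(min(x), cfg$near_zero_frac * B0)

  # shoulders: new extrema flanking the main line (between the half-field
  # window and the main window, and above it)
  sh <- rbind(.local_extrema(x, spectrum$derivative, hf_hi, main_lo),
              .local_extrema(x, spectrum$derivative, main_hi,
                             cfg$shoulder_max_frac * B0))
  sh <- sh[abs(sh$value) >= floor_, , drop = FALSE]
  structure(list(main_split = main_split, split_G = split_G,
                 main_width_ratio = main_width_ratio,
                 broadening_ratio = broadening_ratio,
                 half_field = half_field, near_zero = near_zero,
                 shoulders = sh$field, center_G = B0),
            class = "feature_report")
}

#' @export
print.feature_report <- function(x, ...) {
  cat("Spectral features vs zero-ZFI base:\n")
  cat(sprintf("  main line: %s%s, pk-pk width ratio %.3g\n",
              if (isTRUE(x$main_split)) "split" else "not split",
              if (isTRUE(x$main_split))
                sprintf(" (%.0f G)", x$split_G) else "",
              x$main_width_ratio))
  cat(sprintf("  overall broadening ratio %.3g\n", x$broadening_ratio))
  cat(sprintf("  half-field feature: %s; near-zero-field feature: %s\n",
              x$half_field, x$near_zero))
  if (length(x$shoulders))
    cat("  shoulders at", paste(sprintf("%.0f", x$shoulders),
                                collapse = ", "), "G\n")
  invisible(x)
}

#' Feature table for a whole inventory
#'
#' Applies [detect_features()] to every spectrum of an [inventory_run()]
#' and tabulates the flags.
#'
#' @param inv an `inventory_run`.
#' @return data frame with one row per spectrum: `k`, `q`, `mult`,
#'   `deviation` (max |derivative difference| / base pk-pk), and the
#'   feature columns.
#' @export
inventory_features <- function(inv) {
  stopifnot(inherits(inv, "inventory_run"))
  rows <- lapply(names(inv$spectra), function(nm) {
    kq <- strsplit(sub(":.*", "", nm), "_")[[1]]
    f <- detect_features(inv$spectra[[nm]], inv$base)
    data.frame(k = as.integer(kq[1]), q = as.integer(kq[2]),
               mult = as.integer(sub(".*:", "", nm)),
               deviation = .deviation(inv$spectra[[nm]], inv$base) /
                 .pkpk(inv$base),
               main_split = f$main_split, split_G = f$split_G,
               main_width_ratio = f$main_width_ratio,
               broadening_ratio = f$broadening_ratio,
               half_field = f$half_field, near_zero = f$near_zero,
               n_shoulders = length(f$shoulders))
  })
  do.call(rbind, rows)
}
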
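# Giant-spin scaling bookkeeping for superparamagnetic cores: the exact
# scaling relations S_eq = S/n, D_eff = n D, T_eff = T/n, the link between
# the classical anisotropy field and D, coupling-scheme spin arithmetic,
# and the largest-diagonal-element audit of higher-order term scalability.

#' System spin from the effective magnetic moment
#'
#' \eqn{S = \mu / (g\beta)}: with the moment given in Bohr magnetons the
#' magneton cancels and S is simply mu/g.
#'
#' @param mu effective magnetic moment, Bohr magnetons (>= 0).
#' @param g isotropic g value (> 0).
#' @return spin quantum number (not necessarily half-integral).
#' @examples
#' spin_from_moment(10, 2)      # 5
#' spin_from_moment(2e4, 2)     # the fully loaded ferritin-core regime
#' @export
spin_from_moment <- function(mu, g = 2.00) {
  if (any(g <= 0)) stop("g must be positive", call. = FALSE)
  if (any(mu < 0)) stop("moment must be non-negative", call. = FALSE)
  mu / g
}

#' Giant-spin scaling relations
#'
#' `scale_down()` maps the true system spin onto the computationally
#' tractable equivalent spin \eqn{S_{eq} = S/n}; `scale_D()` compensates
#' the axial zero-field parameter as \eqn{D_{eff} = nD} and `scale_T()`
#' the temperature as \eqn{T_{eff} = T/n}.  All three are exact arithmetic
#' for positive integer `n`.
#'
#' @param S true system spin.
#' @param D axial zero-field parameter, cm^-1.
#' @param T_K temperature, K.
#' @param n positive integer scaling divisor.
#' @return the scaled quantity.
#' @examples
#' scale_down(5000, 500)        # 10
#' scale_D(-1.2e-5, 500)        # -6e-3
#' scale_T(5, 500)              # 0.01
#' @export
scale_down <- function(S, n) {
  .check_scale_n(n)
  S_eq <- S / n
  if (abs(2 * S_eq - round(2 * S_eq)) > 1e-9)
    warning("scaled spin S_eq = ", format(S_eq),
            " is not half-integral; it cannot index a physical multiplet",
            call. = FALSE)
  S_eq
}

#' @rdname scale_down
#' @export
scale_D <- function(D, n) {
  .check_scale_n(n)
  n * D
}

#' @rdname scale_down
#' @export
scale_T <- function(T_K, n) {
  .check_scale_n(n)
  T_K / n
}

.check_scale_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0 ||
      abs(n - round(n)) > 1e-9)
    stop("scaling divisor n must be a positive integer", call. = FALSE)
  invisible(round(n))
}

#' Axial zero-field parameter from the classical anisotropy field
#'
#' \eqn{D = \gamma B_a / (2S)} with the gyromagnetic factor taken as
#' \eqn{g\beta} in energy units, expressed in cm^-1; the sign is set
#' negative following the easy-axis convention of single-domain
#' superparamagnets.
#'
#' @param B_a anisotropy field, gauss (>= 0).
#' @param S system spin (> 0).
#' @param g isotropic g value.
#' @return D in cm^-1 (<= 0).
#' @examples
#' anisotropy_field_to_D(1400, 5000, 2.00)   # about -1.3e-5 cm^-1
#' @export
anisotropy_field_to_D <- function(B_a, S, g = 2.00) {
  if (any(B_a < 0)) stop("anisotropy field must be non-negative",
                         call. = FALSE)
  if (any(S <= 0)) stop("spin must be positive", call. = FALSE)
  -g * .gs_const$beta_cm_per_G * B_a / (2 * S)
}

#' Net spin of a coupling scheme
#'
#' Spin arithmetic of exchange-coupled clusters: groups of equivalent ions
#' couple their spins either parallel or antiparallel to the net moment,
#' \eqn{S = \sum_{par} n_i S_i - \sum_{anti} n_i S_i} (incomplete
#' antiparallel compensation).  A negative sum is floored at 0 with a
#' warning.
#'
#' @param groups list of groups, each a list/vector with elements `count`
#'   (number of ions), `spin` (ion spin) and `orientation` (`"parallel"`
#'   or `"antiparallel"`).
#' @return the net system spin.
#' @examples
#' # Mn12: eight S = 2 parallel, four S = 3/2 antiparallel -> S = 10
#' net_spin(list(list(count = 8, spin = 2, orientation = "parallel"),
#'               list(count = 4, spin = 3/2, orientation = "antiparallel")))
#' @export
net_spin <- function(groups) {
  s <- 0
  for (g in groups) {
    cnt <- g$count %||% g[[1]]
    sp <- .check_spin(g$spin %||% g[[2]])
    ori <- match.arg(g$orientation %||% g[[3]],
                     c("parallel", "antiparallel"))
    s <- s + (if (ori == "parallel") 1 else -1) * cnt * sp
  }
  if (s < 0) {
    warning("net spin negative (", s, "); floored at 0", call. = FALSE)
    s <- 0
  }
  s
}

#' Giant-spin scaling scheme
#'
#' Assembles the full bookkeeping for one scaled giant-spin calculation:
#' true spin `S` (optionally derived from a moment), divisor `n`, axial
#' parameter `D` (optionally derived from an anisotropy field), and the
#' derived `S_eq`, `D_eff`, `T_eff` and `B_2^0` values.
#'
#' @param S true system spin (omit if `mu` given).
#' @param n positive integer divisor.
#' @param D true axial parameter, cm^-1 (omit if `B_a` given).
#' @param T_K true temperature, K (optional).
#' @param mu effective moment in Bohr magnetons (alternative to `S`).
#' @param B_a anisotropy field in gauss (alternative to `D`).
#' @param g isotropic g value.
#' @return object of class `scaling_scheme`.
#' @examples
#' scaling_scheme(S = 5000, n = 500, D = -1.2e-5, T_K = 5)
#' @export
scaling_scheme <- function(S = NULL, n = 1, D = NULL, T_K = NULL,
                           mu = NULL, B_a = NULL, g = 2.00) {
  if (is.null(S)) {
    if (is.null(mu)) stop("give S or mu", call. = FALSE)
    S <- spin_from_moment(mu, g)
  }
  if (is.null(D)) {
    if (is.null(B_a)) stop("give D or B_a", call. = FALSE)
    D <- anisotropy_field_to_D(B_a, S, g)
  }
  out <- list(S = S, n = .check_scale_n(n), D = D, T_K = T_K, g = g,
              mu = mu, B_a = B_a,
              S_eq = scale_down(S, n), D_eff = scale_D(D, n),
              T_eff = if (is.null(T_K)) NULL else scale_T(T_K, n))
  out$B20_eff <- out$D_eff / 3
  structure(out, class = "scaling_scheme")
}

#' @export
print.scaling_scheme <- function(x, ...) {
  cat(sprintf("Giant-spin scaling: S = %g, n = %d -> S_eq = %g\n",
              x$S, x$n, x$S_eq))
  cat(sprintf("  D = %g cm^-1 -> D_eff = %g cm^-1 (B_2^0 = %g)\n",
              x$D, x$D_eff, x$B20_eff))
  if (!is.null(x$T_eff))
    cat(sprintf("  T = %g K -> T_eff = %g K\n", x$T_K, x$T_eff))
  invisible(x)
}

# closed-form diagonal <m|O_k^0|m> of the axial Stevens operators
.stevens_diag <- function(S, k, m) {
  X <- S * (S + 1)
  switch(as.character(k),
         "2" = 3 * m^2 - X,
         "4" = 35 * m^4 - (30 * X - 25) * m^2 + 3 * X^2 - 6 * X,
         "6" = 231 * m^6 - (315 * X - 735) * m^4 +
               (105 * X^2 - 525 * X + 294) * m^2 -
               5 * X^3 + 40 * X^2 - 60 * X,
         stop("k must be 2, 4 or 6", call. = FALSE))
}

#' Largest diagonal element of an axial zero-field term
#'
#' \eqn{\max_m |B \langle m|O_k^0|m\rangle|} over the 2S+1 sublevels,
#' evaluated from the closed-form diagonal polynomial (no matrix is built,
#' so arbitrary spins up to thousands are cheap).
#'
#' @param S_eq spin of the multiplet.
#' @param B Stevens coefficient \eqn{B_k^0}, cm^-1.
#' @param k axial operator order, 2, 4 or 6.
#' @return magnitude in cm^-1.
#' @examples
#' max_diag_element(10, -2e-3, 2)    # 0.38
#' @export
max_diag_element <- function(S_eq, B, k) {
  S_eq <- .check_spin(S_eq)
  if (!k %in% c(2, 4, 6))
    stop("k must be 2, 4 or 6", call. = FALSE)
  if (k > 2 * S_eq)
    stop("order k = ", k, " not allowed for spin S = ", S_eq, call. = FALSE)
  m <- seq(-S_eq, S_eq, by = 1)
  max(abs(B * .stevens_diag(S_eq, k, m)))
}

#' Divergence audit of higher-order axial terms under giant-spin scaling
#'
#' Starting from the axial parameter `D` reported at true spin `S`, derives
#' the scaled \eqn{B_2^0 = nD/3} at each requested equivalent spin, takes
#' \eqn{B_4^0} and \eqn{B_6^0} smaller by `per_step_ratio` per step in k,
#' and tabulates the magnitude of the largest diagonal element of each
#' \eqn{B_k^0 O_k^0}.  The qualitative verdict per `S_eq` is `"decreasing"`
#' or `"increasing"` when the three magnitudes are strictly ordered in k,
#' `"comparable"` when max/min <= 10, and `"mixed"` otherwise.
#'
#' @param D axial parameter at the true spin, cm^-1.
#' @param S true system spin.
#' @param S_eq equivalent spins to audit.
#' @param per_step_ratio coefficient ratio per step k -> k+2, in (0, 1].
#' @return object of class `zfi_audit`: a data frame with columns `S_eq`,
#'   `k`, `B`, `max_element`, with the verdicts in attribute `verdicts`.
#' @examples
#' divergence_audit()
#' @export
divergence_audit <- function(D = -1.2e-5, S = 5000,
                             S_eq = c(10, 100, 1000),
                             per_step_ratio = 1e-4) {
  stopifnot(per_step_ratio > 0, per_step_ratio <= 1)
  rows <- list()
  verdicts <- character(length(S_eq))
  names(verdicts) <- as.character(S_eq)
  for (s in S_eq) {
    n <- S / s
    if (abs(n - round(n)) > 1e-9)
      stop("S/S_eq must be a positive integer (got n = ", n, ")",
           call. = FALSE)
    B20 <- scale_D(D, round(n)) / 3
    Bs <- c(B20, B20 * per_step_ratio, B20 * per_step_ratio^2)
    vals <- vapply(1:3, function(i)
      max_diag_element(s, Bs[i], c(2, 4, 6)[i]), 0)
    rows[[length(rows) + 1]] <- data.frame(
      S_eq = s, k = c(2, 4, 6), B = Bs, max_element = vals)
    verdicts[as.character(s)] <-
      if (all(diff(vals) < 0)) "decreasing"
      else if (all(diff(vals) > 0)) "increasing"
      else if (max(vals) / min(vals) <= 10) "comparable"
      else "mixed"
  }
  out <- do.call(rbind, rows)
  # a non-monotone triple can still be "comparable"
  for (s in S_eq) {
    v <- out$max_element[out$S_eq == s]
    if (verdicts[as.character(s)] %in% c("decreasing", "increasing") &&
        max(v) / min(v) <= 10)
      verdicts[as.character(s)] <- "comparable"
  }
  structure(out, verdicts = verdicts, class = c("zfi_audit", "data.frame"))
}

#' @export
print.zfi_audit <- function(x, ...) {
  cat("Axial-term scalability audit (largest diagonal element, cm^-1)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  v <- attr(x, "verdicts")
  for (nm in names(v))
    cat(sprintf("  S_eq = %s: %s across k = 2, 4, 6\n", nm, v[nm]))
  invisible(x)
}
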
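# Spin-system container, conventional (D, E) mapping, Hamiltonian assembly
# and diagonalization.

#' Convert conventional (D, E) parameters to Stevens terms
#'
#' The conventional second-order zero-field Hamiltonian
#' \eqn{D[S_z^2 - S(S+1)/3] + E(S_x^2 - S_y^2)} maps onto the Stevens form
#' via \eqn{B_2^0 = D/3} and \eqn{B_2^2 = E}.
#'
#' @param D axial parameter, cm^-1.
#' @param E rhombic parameter, cm^-1.
#' @return list of two [zfi_term()] objects, (2,0) and (2,2).
#' @examples
#' conventional_to_stevens(-0.9, -0.3)   # B20 = -0.3, B22 = -0.3
#' @export
conventional_to_stevens <- function(D, E = 0) {
  list(zfi_term(2, 0, D / 3), zfi_term(2, 2, E))
}

#' Declare a spin system
#'
#' Bundles a spin quantum number, g value(s), and zero-field terms.  The
#' second-order interaction can be given either conventionally through `D`
#' and `E` (cm^-1) or as explicit Stevens terms; higher-order terms are
#' always given as [zfi_term()] objects.  Signed D and E are preserved as
#' given; for isotropic g only |E/D| affects a powder spectrum.
#'
#' @param S spin quantum number (integer or half-integer).
#' @param g isotropic g value, or a length-3 vector (gx, gy, gz).
#' @param D,E conventional axial and rhombic parameters, cm^-1 (optional).
#' @param terms list of additional [zfi_term()] objects.
#' @return object of class `spin_system`.
#' @examples
#' spin_system(5/2, g = 2.00, D = -0.9, E = -0.3)
#' spin_system(10, g = 2.00, terms = list(zfi_term(4, 4, 1e-6)))
#' @export
spin_system <- function(S, g = 2.00, D = NULL, E = 0, terms = list()) {
  S <- .check_spin(S)
  if (!is.numeric(g) || !length(g) %in% c(1L, 3L) || any(!is.finite(g)) ||
      any(g <= 0))
    stop("g must be one positive number or three principal values",
         call. = FALSE)
  g3 <- if (length(g) == 1L) rep(g, 3) else as.numeric(g)
  if (inherits(terms, "zfi_term")) terms <- list(terms)
  conventional <- NULL
  if (!is.null(D)) {
    stopifnot(is.numeric(D), length(D) == 1L, is.numeric(E),
              length(E) == 1L)
    terms <- c(conventional_to_stevens(D, E), terms)
    conventional <- list(D = D, E = E,
                         eta = if (D != 0) E / D else NA_real_)
  }
  terms <- terms[vapply(terms, function(t) t$B != 0, TRUE)]
  validate_terms(S, terms)
  structure(list(S = S, g = g3, terms = terms, conventional = conventional),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("Spin system: S = %s, g = (%g, %g, %g)\n",
              format(x$S), x$g[1], x$g[2], x$g[3]))
  if (!is.null(x$conventional))
    cat(sprintf("  conventional: D = %g, E = %g cm^-1 (E/D = %s)\n",
                x$conventional$D, x$conventional$E,
                format(x$conventional$eta, digits = 4)))
  if (length(x$terms) == 0) cat("  no zero-field terms\n")
  for (tm in x$terms)
    cat(sprintf("  B_%d^%d = %g cm^-1\n", tm$k, tm$q, tm$B))
  invisible(x)
}

# Zero-field part of the Hamiltonian (real symmetric, cm^-1).
zfi_hamiltonian <- function(system) {
  dim <- as.integer(2 * system$S + 1)
  H <- matrix(0, dim, dim)
  for (tm in system$terms)
    H <- H + tm$B * stevens_operator(system$S, tm$k, tm$q)
  H
}

#' Assemble the full spin Hamiltonian at one field and orientation
#'
#' \eqn{H = \sum_{k,q} B_k^q O_k^q + \beta B \sum_a g_a l_a S_a}, with the
#' static field of magnitude `field_G` (gauss) along the unit vector
#' \eqn{(\sin\theta\cos\phi, \sin\theta\sin\phi, \cos\theta)} in the
#' molecular frame.  Energies in cm^-1.
#'
#' @param system a [spin_system()].
#' @param field_G field magnitude in gauss (>= 0).
#' @param theta polar angle from the molecular z axis, radians.
#' @param phi azimuth from the molecular x axis, radians.
#' @return complex Hermitian matrix of dimension 2S+1, cm^-1.
#' @export
build_hamiltonian <- function(system, field_G, theta = 0, phi = 0) {
  stopifnot(inherits(system, "spin_system"))
  if (!is.numeric(field_G) || length(field_G) != 1L || !is.finite(field_G) ||
      field_G < 0)
    stop("field magnitude must be a single non-negative number (gauss)",
         call. = FALSE)
  if (!is.finite(theta) || !is.finite(phi))
    stop("orientation angles must be finite", call. = FALSE)
  op <- spin_matrices(system$S)
  n <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  bG <- .gs_const$beta_cm_per_G
  Hz <- bG * field_G * (system$g[1] * n[1] * op$Sx +
                        system$g[2] * n[2] * (op$Sy + 0i) +
                        system$g[3] * n[3] * op$Sz)
  zfi_hamiltonian(system) + Hz + 0i
}

#' Eigenvalues and eigenvectors of a Hermitian Hamiltonian
#'
#' Real eigenvalues sorted ascending with orthonormal eigenvectors; rejects
#' non-Hermitian input.  Column j of `vectors` belongs to `values[j]`.
#'
#' @param H Hermitian (possibly complex) matrix.
#' @return list with `values` (ascending, cm^-1) and `vectors`.
#' @export
eigensystem <- function(H) {
  if (!is.matrix(H) || nrow(H) != ncol(H))
    stop("H must be a square matrix", call. = FALSE)
  scale <- max(abs(H), 1e-300)
  if (max(abs(H - Conj(t(H)))) > 1e-10 * scale)
    stop("H is not Hermitian", call. = FALSE)
  e <- eigen(H, symmetric = TRUE)   # values in decreasing order
  idx <- rev(seq_along(e$values))
  list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
}
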
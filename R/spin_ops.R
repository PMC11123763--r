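# Angular-momentum and extended Stevens operator matrices.
#
# Basis convention (shared by every module): magnetic sublevels in
# descending order m = +S, S-1, ..., -S.  All zero-field operators here are
# real symmetric in this basis because only even q components (orthorhombic
# or higher symmetry) are supported.

.check_spin <- function(S) {
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S < 0)
    stop("spin S must be a single non-negative number", call. = FALSE)
  if (abs(2 * S - round(2 * S)) > 1e-9)
    stop("spin S must be integer or half-integer (2S integral), got S = ",
         S, call. = FALSE)
  round(2 * S) / 2
}

#' Angular-momentum matrices for arbitrary spin
#'
#' Constructs the spin operator matrices Sz, S+ and S- of dimension 2S+1 in
#' the descending basis m = +S ... -S, from the ladder algebra
#' \eqn{\langle m+1|S_+|m\rangle = \sqrt{S(S+1) - m(m+1)}}.
#'
#' @param S spin quantum number; non-negative integer or half-integer.
#' @return list with elements `Sz`, `Sp`, `Sm` (real matrices), plus `Sx`
#'   (real) and `Sy` (complex) for convenience, and the sublevel vector `m`.
#' @examples
#' spin_matrices(1/2)$Sz       # diag(+1/2, -1/2)
#' spin_matrices(1)$Sp[2, 3]   # <0|S+|-1> = sqrt(2)
#' @export
spin_matrices <- function(S) {
  S <- .check_spin(S)
  dim <- as.integer(2 * S + 1)
  m <- S - seq_len(dim) + 1           # descending
  Sz <- diag(m, nrow = dim)
  Sp <- matrix(0, dim, dim)
  if (dim > 1) {
    for (j in 2:dim) {
      mm <- m[j]                       # S+ |m> -> |m+1>, one row up
      Sp[j - 1, j] <- sqrt(S * (S + 1) - mm * (mm + 1))
    }
  }
  Sm <- t(Sp)
  list(Sz = Sz, Sp = Sp, Sm = Sm,
       Sx = (Sp + Sm) / 2,
       Sy = (Sp - Sm) / (2i),
       m = m, S = S)
}

.stevens_supported <- rbind(
  c(2, 0), c(2, 2),
  c(4, 0), c(4, 2), c(4, 4),
  c(6, 0), c(6, 2), c(6, 4), c(6, 6)
)

#' Extended Stevens operator matrices
#'
#' Matrix of the extended Stevens operator \eqn{O_k^q} for even order
#' k = 2, 4, 6 and even component 0 <= q <= k, built by polynomial expansion
#' in Sz and the ladder operators with the conventional anticommutator
#' symmetrization for the mixed (k, q > 0) operators.  Operators of order
#' k are only admissible within a multiplet when k <= 2S; higher orders are
#' identically zero there and are rejected.
#'
#' @param S spin quantum number.
#' @param k operator order, one of 2, 4, 6.
#' @param q operator component, even, `0 <= q <= k`.
#' @return real symmetric, traceless matrix of dimension 2S+1.
#' @examples
#' stevens_operator(1, 2, 0)        # diag(1, -2, 1)
#' stevens_operator(5/2, 2, 0)[1,1] # 10
#' @export
stevens_operator <- function(S, k, q) {
  S <- .check_spin(S)
  if (!any(.stevens_supported[, 1] == k & .stevens_supported[, 2] == q))
    stop("unsupported Stevens operator (k = ", k, ", q = ", q,
         "); supported: even k in {2,4,6}, even q <= k", call. = FALSE)
  if (k > 2 * S)
    stop("operator order k = ", k, " not allowed for spin S = ", S,
         " (requires k <= 2S)", call. = FALSE)
  op <- spin_matrices(S)
  Sz <- op$Sz; Sp <- op$Sp; Sm <- op$Sm
  X <- S * (S + 1)
  I <- diag(nrow(Sz))
  Sz2 <- Sz %*% Sz
  key <- paste(k, q)
  if (key == "2 0") return(3 * Sz2 - X * I)
  A2 <- Sp %*% Sp + Sm %*% Sm
  if (key == "2 2") return(A2 / 2)
  Sz4 <- Sz2 %*% Sz2
  if (key == "4 0")
    return(35 * Sz4 - (30 * X - 25) * Sz2 + (3 * X^2 - 6 * X) * I)
  if (key == "4 2") {
    P <- 7 * Sz2 - (X + 5) * I
    return((P %*% A2 + A2 %*% P) / 4)
  }
  A4 <- Sp %*% Sp %*% Sp %*% Sp + Sm %*% Sm %*% Sm %*% Sm
  if (key == "4 4") return(A4 / 2)
  Sz6 <- Sz4 %*% Sz2
  if (key == "6 0")
    return(231 * Sz6 - (315 * X - 735) * Sz4 +
           (105 * X^2 - 525 * X + 294) * Sz2 +
           (-5 * X^3 + 40 * X^2 - 60 * X) * I)
  if (key == "6 2") {
    P <- 33 * Sz4 - (18 * X + 123) * Sz2 + (X^2 + 10 * X + 102) * I
    return((P %*% A2 + A2 %*% P) / 4)
  }
  if (key == "6 4") {
    P <- 11 * Sz2 - (X + 38) * I
    return((P %*% A4 + A4 %*% P) / 4)
  }
  # 6 6
  (Sp %*% Sp %*% Sp %*% Sp %*% Sp %*% Sp +
   Sm %*% Sm %*% Sm %*% Sm %*% Sm %*% Sm) / 2
}

#' Cubic-symmetry quartic and sextic operator combinations
#'
#' In cubic symmetry the fourth-order terms collapse into the single
#' combination \eqn{B_4 (O_4^0 + 5 O_4^4)} and the sixth-order terms into
#' \eqn{B_6 (O_6^0 - 21 O_6^6)}.
#'
#' @param S spin quantum number.
#' @param order 4 or 6.
#' @param B coefficient in cm^-1.
#' @return real symmetric, traceless matrix of dimension 2S+1.
#' @export
cubic_combination <- function(S, order, B) {
  if (!order %in% c(4, 6))
    stop("cubic combination defined for order 4 or 6", call. = FALSE)
  if (order == 4)
    B * (stevens_operator(S, 4, 0) + 5 * stevens_operator(S, 4, 4))
  else
    B * (stevens_operator(S, 6, 0) - 21 * stevens_operator(S, 6, 6))
}

#' A single zero-field interaction term
#'
#' One Stevens term \eqn{B_k^q O_k^q}: order `k`, component `q`, and
#' coefficient `B` in cm^-1.
#'
#' @param k even operator order (2, 4 or 6).
#' @param q even component, `0 <= q <= k`.
#' @param B coefficient in cm^-1.
#' @return object of class `zfi_term`.
#' @examples
#' zfi_term(4, 4, 0.24)
#' @export
zfi_term <- function(k, q, B) {
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B))
    stop("coefficient B must be a single finite number", call. = FALSE)
  if (!any(.stevens_supported[, 1] == k & .stevens_supported[, 2] == q))
    stop("unsupported zero-field term (k = ", k, ", q = ", q, ")",
         call. = FALSE)
  structure(list(k = as.integer(k), q = as.integer(q), B = B),
            class = "zfi_term")
}

#' @export
print.zfi_term <- function(x, ...) {
  cat(sprintf("B_%d^%d = %g cm^-1\n", x$k, x$q, x$B))
  invisible(x)
}

#' Validate a set of zero-field terms against a spin
#'
#' Rejects terms whose order exceeds the multiplet (k > 2S) and any
#' unsupported (k, q) combination; warns, without rejecting, when the
#' rhombic second-order coefficient exceeds the axial one (|B_2^2| > |B_2^0|,
#' i.e. the conventional rhombicity bound |E| <= |D|/3 is violated).
#'
#' @param S spin quantum number.
#' @param terms list of [zfi_term()] objects.
#' @return the validated list, invisibly.
#' @export
validate_terms <- function(S, terms) {
  S <- .check_spin(S)
  if (length(terms) == 0) return(invisible(terms))
  if (inherits(terms, "zfi_term")) terms <- list(terms)
  for (tm in terms) {
    if (!inherits(tm, "zfi_term"))
      stop("terms must be built with zfi_term()", call. = FALSE)
    if (tm$k > 2 * S)
      stop("zero-field term (k = ", tm$k, ", q = ", tm$q,
           ") not allowed for spin S = ", S, " (requires k <= 2S)",
           call. = FALSE)
  }
  B20 <- sum(vapply(terms, function(t) if (t$k == 2 && t$q == 0) t$B else 0,
                    0))
  B22 <- sum(vapply(terms, function(t) if (t$k == 2 && t$q == 2) t$B else 0,
                    0))
  if (abs(B22) > abs(B20) + 1e-15 && abs(B22) > 0)
    warning("|B_2^2| > |B_2^0| violates the conventional rhombicity bound ",
            "|E| <= |D|/3; proceeding with the values as given",
            call. = FALSE)
  invisible(terms)
}
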
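# Special functions for the spherical solution: modified spherical Bessel
# functions of complex argument, complex cylindrical I0/I1, and Legendre
# polynomial tables.  Implemented by power series: the arguments arising here
# (sqrt(M)*r with principal square root, so Re(z) >= |z|/sqrt(2)) stay small
# enough that the all-positive-coefficient series is accurate; a guard refuses
# |z| beyond the validated range.

.Z_MAX <- 80

#' Modified spherical Bessel function of the first kind, complex argument
#'
#' Evaluates `i_n(z) = sqrt(pi/(2 z)) I_{n+1/2}(z)`, the regular radial
#' solution of the modified Helmholtz equation, by its power series
#' `i_n(z) = z^n sum_k (z^2/2)^k / (k! (2n+2k+1)!!)`. Accurate for complex
#' `z` with `|z| <= 80` and `Re z >= 0` (principal-root arguments).
#'
#' @param n non-negative integer order.
#' @param z complex (or numeric) vector.
#' @return complex vector `i_n(z)`.
#' @export
sph_bessel_i <- function(n, z) {
  stopifnot(length(n) == 1, n >= 0, n == round(n))
  z <- as.complex(z)
  if (any(Mod(z) > .Z_MAX)) {
    stop("sph_bessel_i: |z| exceeds the validated series range (", .Z_MAX, ")")
  }
  w <- z^2 / 2
  # term_0 = 1/(2n+1)!!
  term <- rep(1 / prod(seq(1, 2 * n + 1, by = 2)), length(z))
  s <- term
  for (k in seq_len(400)) {
    term <- term * w / (k * (2 * n + 2 * k + 1))
    s <- s + term
    if (all(Mod(term) <= 1e-17 * (Mod(s) + 1e-300))) break
  }
  z^n * s
}

#' @rdname sph_bessel_i
#' @details `sph_bessel_i_deriv` evaluates `d i_n / d z` through the stable
#'   identity `i_n'(z) = i_{n+1}(z) + (n/z) i_n(z)` (series limit used at
#'   `z = 0`).
#' @export
sph_bessel_i_deriv <- function(n, z) {
  z <- as.complex(z)
  out <- sph_bessel_i(n + 1, z)
  if (n > 0) {
    nz <- Mod(z) > 0
    # n * z^{n-1} * series : finite limit at z = 0 only when n = 1
    out[nz] <- out[nz] + n * sph_bessel_i(n, z[nz]) / z[nz]
    if (any(!nz)) out[!nz] <- if (n == 1) 1 / 3 else 0
  }
  out
}

#' Half-integer-order modified Bessel function `I_{n+1/2}(z)`
#'
#' Convenience wrapper, `I_{n+1/2}(z) = sqrt(2 z / pi) i_n(z)` with the
#' principal square root.
#' @inheritParams sph_bessel_i
#' @export
bessel_i_half <- function(n, z) {
  z <- as.complex(z)
  sqrt(2 * z / pi) * sph_bessel_i(n, z)
}

# Cylindrical modified Bessel I0, I1 at complex argument (power series).
bessel_i0c <- function(z) {
  z <- as.complex(z)
  if (any(Mod(z) > .Z_MAX)) stop("bessel_i0c: |z| too large for the series")
  w <- z^2 / 4
  term <- rep(1 + 0i, length(z))
  s <- term
  for (k in seq_len(400)) {
    term <- term * w / k^2
    s <- s + term
    if (all(Mod(term) <= 1e-17 * (Mod(s) + 1e-300))) break
  }
  s
}

bessel_i2c <- function(z) {
  z <- as.complex(z)
  if (any(Mod(z) > .Z_MAX)) stop("bessel_i2c: |z| too large for the series")
  w <- z^2 / 4
  term <- rep(0.5 + 0i, length(z)) # k = 0: 1/(0! 2!)
  s <- term
  for (k in seq_len(400)) {
    term <- term * w / (k * (k + 2))
    s <- s + term
    if (all(Mod(term) <= 1e-17 * (Mod(s) + 1e-300))) break
  }
  (z / 2)^2 * s
}

bessel_i1c <- function(z) {
  z <- as.complex(z)
  if (any(Mod(z) > .Z_MAX)) stop("bessel_i1c: |z| too large for the series")
  w <- z^2 / 4
  term <- rep(1 + 0i, length(z))
  s <- term
  for (k in seq_len(400)) {
    term <- term * w / (k * (k + 1))
    s <- s + term
    if (all(Mod(term) <= 1e-17 * (Mod(s) + 1e-300))) break
  }
  (z / 2) * s
}

#' Legendre polynomial table
#'
#' Evaluates `P_0 ... P_nmax` at the points `x` by the three-term recurrence.
#'
#' @param nmax maximum order.
#' @param x numeric vector in `[-1, 1]`.
#' @return matrix `length(x) x (nmax+1)`; column `n+1` holds `P_n(x)`.
#' @export
legendre_table <- function(nmax, x) {
  P <- matrix(0, length(x), nmax + 1)
  P[, 1] <- 1
  if (nmax >= 1) P[, 2] <- x
  if (nmax >= 2) {
    for (n in 1:(nmax - 1)) {
      P[, n + 2] <- ((2 * n + 1) * x * P[, n + 1] - n * P[, n]) / (n + 1)
    }
  }
  P
}

# d P_n(cos theta) / d theta evaluated at zeta = cos theta:
# -sin(theta) P_n'(zeta) = -n (P_{n-1} - zeta P_n) / sin(theta); the analytic
# limit 0 is taken at the poles zeta = +/-1.
legendre_dtheta_table <- function(nmax, zeta) {
  P <- legendre_table(nmax, zeta)
  D <- matrix(0, length(zeta), nmax + 1)
  s <- sqrt(pmax(0, 1 - zeta^2))
  inner <- abs(s) > 1e-14
  if (nmax >= 1) {
    for (n in 1:nmax) {
      D[inner, n + 1] <- -n * (P[inner, n] - zeta[inner] * P[inner, n + 1]) /
        s[inner]
    }
  }
  D
}
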
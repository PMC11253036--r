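# Conductivity spectra and time kernels: the frequency-domain face of the
# Darcy-with-memory law is a complex effective conductivity K(omega); its
# inverse Fourier transform (convention e^{-2*pi*i*t*omega}, omega in Hz) is
# the real, decaying memory kernel that multiplies the pressure-gradient
# history.

#' Construct a conductivity spectrum
#'
#' A conductivity spectrum holds the complex effective hydraulic conductivity
#' of the matrix phase on a frequency grid (Hz, transform convention
#' `e^{-2 pi i t omega}`), in dimensional units mm^3 s mg^-1. The grid may be
#' restricted to `omega >= 0`; negative frequencies are implied by Hermitian
#' symmetry `K(-omega) = Conj(K(omega))`, which guarantees a real time kernel.
#'
#' @param omega numeric frequency grid in Hz, strictly increasing.
#' @param values complex conductivities on `omega`.
#' @param check validate Hermitian symmetry / positivity (default `TRUE`).
#' @return object of class `conductivity_spectrum`.
#' @export
conductivity_spectrum_obj <- function(omega, values, check = TRUE) {
  stopifnot(length(omega) == length(values), !is.unsorted(omega))
  values <- as.complex(values)
  obj <- structure(list(omega = omega, values = values),
    class = "conductivity_spectrum"
  )
  if (check) validate_spectrum(obj)
  obj
}

#' Validate a conductivity spectrum
#'
#' Checks Hermitian symmetry where both `omega` and `-omega` are on the grid,
#' positivity of the real part, and (with `monotone = TRUE`) that `|K|` is
#' non-increasing in `|omega|`.
#'
#' @param s a `conductivity_spectrum`.
#' @param monotone also check monotone decay of the magnitude.
#' @return `s` invisibly; errors on violation.
#' @export
validate_spectrum <- function(s, monotone = FALSE) {
  o <- s$omega
  v <- s$values
  for (i in seq_along(o)) {
    j <- which(abs(o + o[i]) <= 1e-12 * max(1, abs(o[i])))
    if (length(j) == 1 && Mod(v[j] - Conj(v[i])) > 1e-8 * (Mod(v[i]) + 1e-300)) {
      stop("spectrum is not Hermitian at omega = ", o[i])
    }
  }
  if (any(Re(v) <= 0)) stop("spectrum real part must be positive")
  if (monotone) {
    m <- Mod(v)[order(abs(o))]
    if (any(diff(m) > 1e-8 * m[1])) {
      stop("spectrum magnitude must be non-increasing in |omega|")
    }
  }
  invisible(s)
}

#' Evaluate a spectrum at arbitrary frequencies
#'
#' Exact grid matches are returned as stored; other frequencies are linearly
#' interpolated (real and imaginary parts separately). Negative frequencies
#' use Hermitian symmetry when the grid holds only `omega >= 0`.
#'
#' @param s a `conductivity_spectrum`.
#' @param omega frequencies (Hz) to evaluate at.
#' @return complex vector.
#' @export
spectrum_at <- function(s, omega) {
  out <- complex(length(omega))
  neg <- omega < min(s$omega)
  oq <- omega
  oq[neg] <- -oq[neg]
  if (any(oq > max(s$omega) + 1e-12) || any(oq < min(s$omega) - 1e-12)) {
    stop("requested frequency outside the spectrum grid")
  }
  if (length(s$omega) == 1) {
    out[] <- s$values[1]
  } else {
    out <- complex(
      real = approx(s$omega, Re(s$values), xout = oq, rule = 2)$y,
      imaginary = approx(s$omega, Im(s$values), xout = oq, rule = 2)$y
    )
  }
  out[neg] <- Conj(out[neg])
  out
}

#' @export
print.conductivity_spectrum <- function(x, ...) {
  cat(sprintf(
    "Conductivity spectrum: %d frequencies in [%g, %g] Hz\n",
    length(x$omega), min(x$omega), max(x$omega)
  ))
  cat(sprintf(
    "  K(omega_min) = %g%+gi mm^3 s mg^-1\n",
    Re(x$values[1]), Im(x$values[1])
  ))
  invisible(x)
}

#' Convert a conductivity spectrum to a time-domain memory kernel
#'
#' Discrete inverse Fourier transform (convention `e^{-2 pi i t omega}`) of a
#' Hermitian spectrum sampled on a uniform grid. Grids restricted to
#' `omega >= 0` are completed by Hermitian mirroring before the transform. The
#' imaginary residual of the transform must be below `1e-10` of the kernel
#' norm; it is checked and discarded.
#'
#' @param s a `conductivity_spectrum` on a uniform grid.
#' @return object of class `time_kernel` with fields `t` (s) and `values`
#'   (mm^3 s mg^-1 per unit time); the kernel lives on one period
#'   `T = 1/d_omega` of the implied time discretization.
#' @export
spectrum_to_time_kernel <- function(s) {
  o <- s$omega
  do <- diff(o)
  if (length(do) < 1 || any(abs(do - do[1]) > 1e-9 * do[1])) {
    stop("spectrum grid must be uniform for kernel extraction")
  }
  do <- do[1]
  validate_spectrum(s)
  if (min(o) >= 0) {
    if (abs(o[1]) > 1e-12 * do) stop("omega >= 0 grid must start at 0")
    n0 <- length(o)
    nfull <- 2L * (n0 - 1L)
    v <- complex(nfull)
    v[1:n0] <- s$values
    v[n0] <- complex(real = Re(s$values[n0])) # Nyquist bin must be real
    v[(n0 + 1):nfull] <- Conj(s$values[(n0 - 1):2])
  } else {
    # symmetric grid -W..W-do in increasing order -> wrapped order
    nfull <- length(o)
    if (nfull %% 2 != 0) stop("symmetric grid must have even length")
    i0 <- which.min(abs(o))
    if (abs(o[i0]) > 1e-12 * do) stop("symmetric grid must contain omega = 0")
    v <- c(s$values[i0:nfull], s$values[1:(i0 - 1)])
  }
  k <- do * fft(v, inverse = TRUE)
  nk <- sqrt(mean(Mod(k)^2))
  if (sqrt(mean(Im(k)^2)) > 1e-10 * nk) {
    stop("non-Hermitian spectrum: imaginary kernel residual too large")
  }
  dt <- 1 / (nfull * do)
  structure(
    list(t = (seq_len(nfull) - 1) * dt, values = Re(k)),
    class = "time_kernel"
  )
}

#' Forward transform of a time kernel (discrete, exact inverse pair)
#'
#' Maps a kernel on a uniform time grid back to its uniform frequency grid;
#' `spectrum_to_time_kernel` composed with this map is the identity.
#'
#' @param k a `time_kernel` on a uniform time grid starting at 0.
#' @return a `conductivity_spectrum` on the grid `omega >= 0`.
#' @export
time_kernel_to_spectrum <- function(k) {
  dt <- diff(k$t)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1])) stop("time grid must be uniform")
  dt <- dt[1]
  n <- length(k$t)
  v <- dt * fft(as.complex(k$values))
  do <- 1 / (n * dt)
  n0 <- n %/% 2 + 1L
  conductivity_spectrum_obj((0:(n0 - 1)) * do, v[1:n0], check = FALSE)
}

#' @export
print.time_kernel <- function(x, ...) {
  cat(sprintf(
    "Time kernel: %d samples, dt = %g s, integral = %g mm^3 s mg^-1\n",
    length(x$t), x$t[2] - x$t[1], kernel_integral(x)
  ))
  invisible(x)
}

#' Time integral of a memory kernel
#'
#' Rectangle-rule integral; for a kernel obtained from a spectrum this equals
#' the steady (`omega = 0`) conductivity exactly, since the long-time limit of
#' the integrated cell solution solves the steady cell problem.
#'
#' @param k a `time_kernel`.
#' @return scalar, mm^3 s mg^-1.
#' @export
kernel_integral <- function(k) {
  dt <- k$t[2] - k$t[1]
  dt * sum(k$values)
}
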
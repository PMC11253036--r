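# Synthetic inputs with the structure the solver assumes: a single-pole
# surrogate conductivity spectrum, manufactured Legendre-cosine boundary
# data with known coefficients, and a finite-difference radial oracle for
# the coupled mode-n pressure system.

#' Single-pole surrogate conductivity spectrum
#'
#' `K(omega) = K0 / (1 + 2 pi i omega tau)`: Hermitian by construction, with
#' `K(0) = K0`, monotonically decaying magnitude, and the closed-form time
#' kernel `(K0/tau) exp(-t/tau)`. Emulates the qualitative decay of the
#' homogenized matrix conductivity without running the 3D cell solver.
#'
#' @param K0 steady conductivity (mm^3 s mg^-1), `> 0`.
#' @param tau relaxation time (s), `> 0`.
#' @param omega_grid frequencies (Hz).
#' @return a `conductivity_spectrum`.
#' @export
make_surrogate_spectrum <- function(K0, tau = 0.05, omega_grid) {
  if (K0 <= 0 || tau <= 0) stop("K0 and tau must be positive")
  conductivity_spectrum_obj(
    sort(omega_grid),
    K0 / (1 + 2i * pi * sort(omega_grid) * tau)
  )
}

#' Manufactured boundary data with known mode coefficients
#'
#' Builds a finite Legendre x cosine-tone series
#' `pm(zeta, t) = sum_n P_n(zeta) [ C_{n,1} + sum_{k>1} 2 Re(C_{n,k}
#' e^{2 pi i f_k t}) ]` with coefficients drawn reproducibly from `seed`
#' (or supplied), enabling exact round-trip tests of the Legendre/tone
#' projection.
#'
#' @param n_modes highest Legendre order.
#' @param tones frequencies (Hz, multiples of `1/period`; first must be 0).
#' @param amplitudes optional complex matrix `(n_modes+1) x length(tones)`;
#'   the DC column must be real.
#' @param seed RNG seed for random amplitudes.
#' @param period fundamental period (s).
#' @return list with `bd` (a `boundary_data`) and `coefficients` (the exact
#'   `b_m` matrix the projection must recover).
#' @export
make_manufactured_boundary <- function(n_modes, tones, amplitudes = NULL,
                                       seed = 1, period = 2) {
  ntone <- length(tones)
  if (abs(tones[1]) > 1e-12) stop("first tone must be 0 (DC)")
  if (is.null(amplitudes)) {
    set.seed(seed)
    amplitudes <- matrix(
      complex(real = stats::rnorm((n_modes + 1) * ntone),
              imaginary = stats::rnorm((n_modes + 1) * ntone)),
      n_modes + 1, ntone
    )
    amplitudes[, 1] <- complex(real = Re(amplitudes[, 1]))
  }
  pm <- function(zeta, t) {
    P <- legendre_table(n_modes, zeta)
    out <- numeric(length(zeta))
    for (q in seq_len(ntone)) {
      ph <- if (abs(tones[q]) < 1e-12) 1 else 2 * exp(2i * pi * tones[q] * t)
      out <- out + as.vector(P %*% Re(amplitudes[, q] * ph))
    }
    out
  }
  list(
    bd = boundary_data(pm, pv = 0, pbar = 0, period = period),
    coefficients = amplitudes
  )
}

#' Brute-force radial oracle for the coupled mode-n pressure system
#'
#' Independent second-order finite-difference solve of the coupled radial
#' system for one Legendre mode `n`:
#' `Lap_n p_v = -M_v (p_m - p_v - pbar)`,
#' `Lap_n p_m = +M_m (p_m - p_v - pbar)`,
#' with `Lap_n = d2/dr2 + (2/r) d/dr - n(n+1)/r^2`, regularity at the origin
#' and Dirichlet data `bm`, `bv` at `r = R`. The substitution `u = r p`
#' removes the first-derivative term; complex exchange coefficients are
#' handled by a real augmented solve. Used as the oracle for the closed-form
#' series solution.
#'
#' @param n Legendre order.
#' @param Mm,Mv exchange coefficients (possibly complex, mm^-2).
#' @param R sphere radius.
#' @param bm,bv Dirichlet boundary values of the mode.
#' @param pbar interphase offset (applied to the `n = 0` mode only).
#' @param n_grid number of radial intervals (`>= 500`).
#' @return list with `r` (interior + boundary nodes) and complex `pm`, `pv`.
#' @export
make_reference_radial_oracle <- function(n, Mm, Mv, R, bm, bv, pbar = 0,
                                         n_grid = 2000) {
  if (n_grid < 500) stop("oracle grid must have at least 500 points")
  hh <- R / n_grid
  ri <- hh * seq_len(n_grid - 1) # interior nodes; r_0 = 0, r_N = R
  ni <- n_grid - 1
  pb <- if (n == 0) pbar else 0
  # unknowns x = (u_m, u_v), u = r p ; u'' - n(n+1)/r^2 u -/+ M (...) = 0
  lap_i <- -2 / hh^2 - n * (n + 1) / ri^2
  off <- 1 / hh^2
  idx <- function(block, i) (block - 1) * ni + i
  ii <- integer(0); jj <- integer(0); xx <- complex(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  rhs <- complex(2 * ni)
  for (i in seq_len(ni)) {
    # u_m equation: u_m'' - n(n+1)u_m/r^2 - Mm(u_m - u_v - r pb) = 0
    add(idx(1, i), idx(1, i), lap_i[i] - Mm)
    add(idx(1, i), idx(2, i), Mm)
    rhs[idx(1, i)] <- -Mm * ri[i] * pb
    # u_v equation: u_v'' - n(n+1)u_v/r^2 + Mv(u_m - u_v - r pb) = 0
    add(idx(2, i), idx(2, i), lap_i[i] - Mv)
    add(idx(2, i), idx(1, i), Mv)
    rhs[idx(2, i)] <- Mv * ri[i] * pb
    if (i > 1) {
      add(idx(1, i), idx(1, i - 1), off)
      add(idx(2, i), idx(2, i - 1), off)
    }
    if (i < ni) {
      add(idx(1, i), idx(1, i + 1), off)
      add(idx(2, i), idx(2, i + 1), off)
    }
  }
  # left end: u(0) = 0 (regularity); right end: u(R) = R*b
  rhs[idx(1, ni)] <- rhs[idx(1, ni)] - off * R * bm
  rhs[idx(2, ni)] <- rhs[idx(2, ni)] - off * R * bv
  ntot <- 2 * ni
  Ar <- Matrix::sparseMatrix(i = ii, j = jj, x = Re(xx), dims = c(ntot, ntot))
  Ai <- Matrix::sparseMatrix(i = ii, j = jj, x = Im(xx), dims = c(ntot, ntot))
  imnorm <- if (length(Ai@x)) max(abs(Ai@x)) else 0
  if (imnorm == 0 && all(Im(rhs) == 0)) {
    sol <- as.vector(Matrix::solve(Ar, Re(rhs)))
    sol <- as.complex(sol)
  } else {
    Abig <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
    bb <- c(Re(rhs), Im(rhs))
    sb <- as.vector(Matrix::solve(Abig, bb))
    sol <- sb[seq_len(ntot)] + 1i * sb[ntot + seq_len(ntot)]
  }
  um <- sol[seq_len(ni)]; uv <- sol[ni + seq_len(ni)]
  list(
    r = c(ri, R),
    pm = c(um / ri, bm),
    pv = c(uv / ri, bv)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a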
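# Spectral macroscale solver on the sphere.  The coupled averaged equations
# reduce, per Legendre mode n and frequency omega, to a Helmholtz-type system
# for the transmural difference u = p_m - p_v - pbar:
#   Lap u = M(omega) u,  M = M_v + M_m(omega),
# whose regular radial solution is the modified spherical Bessel function
# i_n(sqrt(M) r).  Pressures are assembled from harmonic parts r^n plus the
# Bessel part; boundary recovery at r = R is exact by construction.  Time
# synthesis is a finite tone sum (pulsatile boundaries are band-limited) or a
# full FFT-bin set for general periodic data.

#' Interphase exchange parameters
#'
#' Computes `M_v = Lp*S_tot/(V_v_tot*Kv_eff)` and the frequency-dependent
#' `M_m(omega) = Lp*S_tot/(V_m_tot*Km(omega))`, the exchange coefficients
#' (mm^-2) coupling the vessel and matrix pressure fields, and their sum `M`.
#'
#' @param params a `physiological_parameters` object.
#' @param Kv_eff effective vessel conductivity (mm^3 s mg^-1), `> 0`.
#' @param Km_spectrum a `conductivity_spectrum` for the matrix phase.
#' @return object of class `exchange_params` with fields `Mv` (scalar) and
#'   functions `Mm(omega)`, `M(omega)`.
#' @examples
#' pp <- physiological_parameters()
#' sp <- make_surrogate_spectrum(3.6e-9, 0.05, seq(0, 2, by = 0.25))
#' xp <- compute_exchange_params(pp, 4.12e-7, sp)
#' xp$Mv # ~0.553 mm^-2
#' @export
compute_exchange_params <- function(params, Kv_eff, Km_spectrum) {
  if (Kv_eff <= 0) stop("Kv_eff must be positive")
  if (any(Mod(Km_spectrum$values) == 0)) {
    stop("zero spectrum value at omega = ",
         Km_spectrum$omega[which(Mod(Km_spectrum$values) == 0)[1]])
  }
  Lp <- params$Lp
  cM <- Lp * params$S_tot
  Mv <- cM / (params$V_v_tot * Kv_eff)
  Mm <- function(omega) cM / (params$V_m_tot * spectrum_at(Km_spectrum, omega))
  structure(
    list(
      Mv = Mv, Mm = Mm, M = function(omega) Mv + Mm(omega),
      Lp = Lp, params = params, Kv_eff = Kv_eff, spectrum = Km_spectrum
    ),
    class = "exchange_params"
  )
}

#' Boundary data on the sphere surface
#'
#' Holds the subcapsular-sinus pressure sampler `pm(zeta, t)` (mPa), the
#' vessel boundary pressure `pv` (constant or a sampler), the Starling
#' interphase offset `pbar` (mPa, time-constant) and the fundamental period.
#'
#' @param pm function of `(zeta, t)` returning mPa; must be `period`-periodic.
#' @param pv scalar mPa or function of `(zeta, t)`.
#' @param pbar interphase pressure offset `sigma*(pi_m - pi_v)` in mPa.
#' @param period fundamental period in s.
#' @return object of class `boundary_data`.
#' @export
boundary_data <- function(pm, pv = 0, pbar = 0, period = 2) {
  if (!is.function(pm)) stop("pm must be a function(zeta, t)")
  pvf <- if (is.function(pv)) pv else function(zeta, t) rep(pv, length(zeta))
  structure(
    list(pm = pm, pv = pvf, pbar = pbar, period = period),
    class = "boundary_data"
  )
}

#' Project boundary data onto Legendre modes and discrete tones
#'
#' Gauss-Legendre quadrature in `zeta` (order `n_quad >= n_max + 1`) gives
#' the Legendre coefficients `b_gamma^(n) = ((2n+1)/2) Int p_gamma P_n dzeta`;
#' a length-`n_t` DFT over one period extracts the complex tone coefficients
#' (one-sided convention: `f(t) = C(0) + sum_{w>0} 2 Re[C(w) e^{2 pi i w t}]`).
#' With `tones = NULL` all FFT bins up to the Nyquist bin are kept (general
#' periodic data); a finite tone set selects the corresponding bins, exact
#' for band-limited boundaries.
#'
#' @param bd a `boundary_data`.
#' @param n_max Legendre truncation order.
#' @param tones frequencies in Hz (multiples of `1/period`), or `NULL`.
#' @param n_quad Gauss-Legendre order (default `max(n_max + 2, 24)`).
#' @param n_t time samples per period (power of two preferred).
#' @return object of class `mode_coefficients` with complex matrices `bm`,
#'   `bv`, `b` of size `(n_max+1) x length(tones)`, the `tones`, `pbar_tone`.
#' @export
project_boundary_to_modes <- function(bd, n_max, tones = NULL,
                                      n_quad = NULL, n_t = 32) {
  if (n_max < 0) stop("n_max must be >= 0")
  if (is.null(n_quad)) n_quad <- max(n_max + 2, 24)
  if (n_quad < n_max + 1) {
    stop("configuration error: quadrature order must be at least n_max + 1")
  }
  gl <- pracma::gaussLegendre(n_quad, -1, 1)
  P <- legendre_table(n_max, gl$x)
  Tt <- bd$period
  tk <- (0:(n_t - 1)) * Tt / n_t
  if (is.null(tones)) {
    tones <- (0:(n_t %/% 2)) / Tt
  } else {
    jj <- tones * Tt
    if (any(abs(jj - round(jj)) > 1e-9)) {
      stop("tones must be multiples of 1/period")
    }
    if (any(round(jj) > n_t %/% 2)) stop("tone beyond the Nyquist bin")
  }
  ntone <- length(tones)
  extract <- function(sampler) {
    smp <- sapply(tk, function(t) sampler(gl$x, t)) # n_quad x n_t
    if (any(!is.finite(smp))) stop("boundary sampler returned non-finite data")
    Ct <- t(apply(smp, 1, function(row) fft(row) / n_t)) # n_quad x n_t bins
    out <- matrix(0i, n_max + 1, ntone)
    for (q in seq_len(ntone)) {
      j <- round(tones[q] * Tt)
      cz <- Ct[, j + 1]
      out[, q] <- vapply(0:n_max, function(n) {
        ((2 * n + 1) / 2) * sum(gl$w * cz * P[, n + 1])
      }, complex(1))
    }
    out
  }
  bm <- extract(bd$pm)
  bv <- extract(bd$pv)
  pbar_tone <- complex(ntone)
  pbar_tone[abs(tones) < 1e-12] <- bd$pbar
  structure(
    list(
      n_max = n_max, tones = tones, bm = bm, bv = bv, b = bm - bv,
      pbar_tone = pbar_tone, period = bd$period
    ),
    class = "mode_coefficients"
  )
}

#' Assemble radial mode amplitudes
#'
#' For each tone and Legendre order, forms the exchange coefficients
#' `M_v, M_m(omega), M(omega)`, the principal root `sqrt(M)`, and the driving
#' amplitudes `g_n` of the transmural Helmholtz solution (`g_0` includes the
#' Starling offset). `Lp = 0` engages the exact harmonic (decoupled) limit.
#' Accessors [coef_A_tilde()], [coef_c1()], [coef_d1()] expose the classical
#' coefficient families.
#'
#' @param modes a `mode_coefficients`.
#' @param xp an `exchange_params`.
#' @param R sphere radius (mm).
#' @return object of class `mode_amplitudes`.
#' @export
assemble_mode_amplitudes <- function(modes, xp, R) {
  ntone <- length(modes$tones)
  per_tone <- vector("list", ntone)
  for (q in seq_len(ntone)) {
    w <- modes$tones[q]
    harmonic <- xp$Lp == 0
    Mv <- xp$Mv
    Mmw <- if (harmonic) 0i else xp$Mm(w)
    Mw <- Mv + Mmw
    g <- modes$b[, q]
    g[1] <- g[1] - modes$pbar_tone[q]
    sqrtM <- if (harmonic) 0i else sqrt(Mw) # principal root, Re >= 0
    if (!harmonic && Mod(Mw) == 0) {
      stop("M(omega) = 0 with Lp > 0 at omega = ", w)
    }
    per_tone[[q]] <- list(
      omega = w, Mv = Mv, Mm = Mmw, M = Mw, sqrtM = sqrtM,
      bm = modes$bm[, q], bv = modes$bv[, q], g = g,
      pbar = modes$pbar_tone[q], harmonic = harmonic
    )
  }
  structure(
    list(n_max = modes$n_max, tones = modes$tones, R = R,
         per_tone = per_tone, period = modes$period, xp = xp),
    class = "mode_amplitudes"
  )
}

# normalized regular radial solution rho_n(r) = i_n(z r)/i_n(z R) and its
# radial derivative, vectorized over r
radial_bessel_ratio <- function(n, z, r, R, deriv = FALSE) {
  iR <- sph_bessel_i(n, z * R)
  if (deriv) {
    z * sph_bessel_i_deriv(n, z * r) / iR
  } else {
    sph_bessel_i(n, z * r) / iR
  }
}

#' Classical coefficient accessors
#'
#' `coef_A_tilde` returns the Bessel-part amplitude
#' `A~_n = g_n sqrt(R) / I_{n+1/2}(sqrt(M) R)` (the normalization that makes
#' the boundary recovery exact), `coef_c1` and `coef_d1` the harmonic-part
#' coefficients `c1^(n) = [b_m^(n) - (M_m/M) g_n]/R^n` and
#' `d1^(n) = [b_v^(n) + (M_v/M) g_n]/R^n`.
#'
#' @param amp a `mode_amplitudes`.
#' @param tone index into `amp$tones`.
#' @return complex vector over `n = 0..n_max`.
#' @export
coef_A_tilde <- function(amp, tone = 1) {
  pt <- amp$per_tone[[tone]]
  if (pt$harmonic) return(rep(0i, amp$n_max + 1))
  vapply(0:amp$n_max, function(n) {
    pt$g[n + 1] * sqrt(amp$R) / bessel_i_half(n, pt$sqrtM * amp$R)
  }, complex(1))
}

#' @rdname coef_A_tilde
#' @export
coef_c1 <- function(amp, tone = 1) {
  pt <- amp$per_tone[[tone]]
  wm <- if (pt$harmonic) 0i else pt$Mm / pt$M
  (pt$bm - wm * pt$g) / amp$R^(0:amp$n_max)
}

#' @rdname coef_A_tilde
#' @export
coef_d1 <- function(amp, tone = 1) {
  pt <- amp$per_tone[[tone]]
  wv <- if (pt$harmonic) 0i else pt$Mv / pt$M
  (pt$bv + wv * pt$g) / amp$R^(0:amp$n_max)
}

#' Evaluate the complex pressure fields of one tone
#'
#' Sums the Legendre series of the matrix and vessel pressure solutions at a
#' single frequency on an `(r, zeta)` grid. The Bessel radial factor is the
#' regular solution normalized at `r = R`, finite at the origin.
#'
#' @param amp a `mode_amplitudes`.
#' @param r radial points, `0 <= r <= R` (mm).
#' @param zeta polar points in `[-1, 1]`.
#' @param tone index into `amp$tones`.
#' @return list of complex matrices `pm_hat`, `pv_hat` (`length(r)` x
#'   `length(zeta)`).
#' @export
evaluate_pressure_hat <- function(amp, r, zeta, tone = 1) {
  R <- amp$R
  if (any(r < 0) || any(r > R * (1 + 1e-12))) {
    stop("domain error: radial points must satisfy 0 <= r <= R")
  }
  pt <- amp$per_tone[[tone]]
  P <- legendre_table(amp$n_max, zeta)
  pm <- matrix(0i, length(r), length(zeta))
  pv <- matrix(0i, length(r), length(zeta))
  for (n in 0:amp$n_max) {
    harm <- (r / R)^n
    if (pt$harmonic) {
      cm <- pt$bm[n + 1] * harm
      cv <- pt$bv[n + 1] * harm
    } else {
      bess <- radial_bessel_ratio(n, pt$sqrtM, r, R)
      wm <- pt$Mm / pt$M
      wv <- pt$Mv / pt$M
      gn <- pt$g[n + 1]
      cm <- (pt$bm[n + 1] - wm * gn) * harm + wm * gn * bess
      cv <- (pt$bv[n + 1] + wv * gn) * harm - wv * gn * bess
    }
    pm <- pm + outer(cm, P[, n + 1])
    pv <- pv + outer(cv, P[, n + 1])
  }
  list(pm_hat = pm, pv_hat = pv)
}

# complex velocity components of one tone: v = -K grad p, spherical
# components (radial, polar).  Gradients are assembled mode-by-mode from the
# analytic radial derivatives and dP_n/dtheta.
evaluate_velocity_hat <- function(amp, r, zeta, tone, K_m_tone, K_v) {
  R <- amp$R
  pt <- amp$per_tone[[tone]]
  P <- legendre_table(amp$n_max, zeta)
  D <- legendre_dtheta_table(amp$n_max, zeta)
  rs <- pmax(r, 1e-9 * R) # origin regularization for the 1/r polar factor
  vmr <- matrix(0i, length(r), length(zeta))
  vmt <- vmr; vvr <- vmr; vvt <- vmr
  for (n in 0:amp$n_max) {
    harm <- (rs / R)^n
    dharm <- if (n == 0) rep(0, length(rs)) else n * rs^(n - 1) / R^n
    if (pt$harmonic) {
      dm <- pt$bm[n + 1] * dharm; dv <- pt$bv[n + 1] * dharm
      cm <- pt$bm[n + 1] * harm; cv <- pt$bv[n + 1] * harm
    } else {
      wm <- pt$Mm / pt$M; wv <- pt$Mv / pt$M
      gn <- pt$g[n + 1]
      bess <- radial_bessel_ratio(n, pt$sqrtM, rs, R)
      dbess <- radial_bessel_ratio(n, pt$sqrtM, rs, R, deriv = TRUE)
      dm <- (pt$bm[n + 1] - wm * gn) * dharm + wm * gn * dbess
      dv <- (pt$bv[n + 1] + wv * gn) * dharm - wv * gn * dbess
      cm <- (pt$bm[n + 1] - wm * gn) * harm + wm * gn * bess
      cv <- (pt$bv[n + 1] + wv * gn) * harm - wv * gn * bess
    }
    vmr <- vmr - K_m_tone * outer(dm, P[, n + 1])
    vvr <- vvr - K_v * outer(dv, P[, n + 1])
    vmt <- vmt - K_m_tone * outer(cm / rs, D[, n + 1])
    vvt <- vvt - K_v * outer(cv / rs, D[, n + 1])
  }
  list(vm_r = vmr, vm_theta = vmt, vv_r = vvr, vv_theta = vvt)
}

# synthesize real periodic fields from one-sided tone coefficients:
# f(t) = C0 + sum_{w>0} 2 Re(Cw e^{2 pi i w t});  `hats` is a list of
# complex matrices aligned with `tones`
tone_synthesis <- function(hats, tones, t) {
  d <- dim(hats[[1]])
  out <- array(0, c(d, length(t)))
  for (q in seq_along(tones)) {
    w <- tones[q]
    for (m in seq_along(t)) {
      ph <- exp(2i * pi * w * t[m])
      contrib <- if (abs(w) < 1e-12) {
        Re(hats[[q]])
      } else {
        2 * Re(hats[[q]] * ph)
      }
      out[, , m] <- out[, , m] + contrib
    }
  }
  out
}

#' Inverse-transform tone-resolved pressure fields to the time domain
#'
#' Exact synthesis of the finite (Hermitian, one-sided) tone sum; for data
#' projected with the full FFT bin set this is the standard inverse FFT
#' evaluated at arbitrary times. Fields are real by construction; an explicit
#' imaginary-residual validation (`< 1e-8` relative) is performed on the DC
#' tone.
#'
#' @param hats list of complex matrices, one per tone (e.g. `pm_hat`).
#' @param tones the one-sided tone frequencies (Hz).
#' @param t times (s).
#' @return real array `dim(hat) x length(t)`.
#' @export
inverse_transform_pressure <- function(hats, tones, t) {
  dc <- which(abs(tones) < 1e-12)
  if (length(dc) == 1) {
    h0 <- hats[[dc]]
    if (max(Mod(Im(h0))) > 1e-8 * max(Mod(h0), 1e-300)) {
      stop("non-Hermitian field data: DC tone has imaginary part")
    }
  }
  tone_synthesis(hats, tones, t)
}

#' Solve the coupled macroscale model on the sphere
#'
#' End-to-end driver: projects the boundary data onto Legendre modes and
#' tones, assembles the radial mode solutions, evaluates pressures,
#' velocities and the interphase exchange on the requested `(r, zeta, t)`
#' grid, and synthesizes real time-domain fields.
#'
#' @param params a `physiological_parameters`.
#' @param Kv_eff effective vessel conductivity (mm^3 s mg^-1).
#' @param Km_spectrum matrix `conductivity_spectrum` (dimensional).
#' @param bd a `boundary_data`.
#' @param r,zeta,t evaluation grid (defaults: 60 radii, 41 Gauss-Legendre
#'   polar nodes, 9 times over one period).
#' @param n_max Legendre truncation (default 16; affine boundaries need 1).
#' @param tones tone set in Hz, or `NULL` for the full FFT-bin backend.
#' @param n_t time samples per period for the projection DFT.
#' @return object of class `field_grid`: arrays `p_m`, `p_v` (mPa), `v_m_r`,
#'   `v_m_theta`, `v_v_r`, `v_v_theta` (mm/s), `q_exchange` (s^-1, volumetric
#'   matrix-to-vessel exchange), `transmural` (mPa), and the mass-balance
#'   `residual`.
#' @export
solve_node <- function(params, Kv_eff, Km_spectrum, bd,
                       r = NULL, zeta = NULL, t = NULL,
                       n_max = 16, tones = NULL, n_t = 32) {
  R <- params$R
  if (is.null(r)) r <- seq(R / 60, R, length.out = 60)
  if (is.null(zeta)) zeta <- pracma::gaussLegendre(41, -1, 1)$x
  if (is.null(t)) t <- seq(0, bd$period, length.out = 9)
  xp <- compute_exchange_params(params, Kv_eff, Km_spectrum)
  modes <- project_boundary_to_modes(bd, n_max, tones = tones, n_t = n_t)
  # drop energy-free tones (keeps the FFT-bin backend inside the spectrum
  # band for band-limited boundaries; the DC tone is always retained)
  energy <- colSums(Mod(modes$bm)) + colSums(Mod(modes$bv)) +
    Mod(modes$pbar_tone)
  keep <- energy > 1e-12 * max(energy) | abs(modes$tones) < 1e-12
  modes$tones <- modes$tones[keep]
  modes$bm <- modes$bm[, keep, drop = FALSE]
  modes$bv <- modes$bv[, keep, drop = FALSE]
  modes$b <- modes$b[, keep, drop = FALSE]
  modes$pbar_tone <- modes$pbar_tone[keep]
  amp <- assemble_mode_amplitudes(modes, xp, R)
  ntone <- length(amp$tones)
  pm_hats <- vector("list", ntone)
  pv_hats <- vector("list", ntone)
  vmr_hats <- vector("list", ntone); vmt_hats <- vector("list", ntone)
  vvr_hats <- vector("list", ntone); vvt_hats <- vector("list", ntone)
  for (q in seq_len(ntone)) {
    ph <- evaluate_pressure_hat(amp, r, zeta, q)
    pm_hats[[q]] <- ph$pm_hat
    pv_hats[[q]] <- ph$pv_hat
    Kmw <- spectrum_at(Km_spectrum, amp$tones[q])
    vh <- evaluate_velocity_hat(amp, r, zeta, q, Kmw, Kv_eff)
    vmr_hats[[q]] <- vh$vm_r; vmt_hats[[q]] <- vh$vm_theta
    vvr_hats[[q]] <- vh$vv_r; vvt_hats[[q]] <- vh$vv_theta
  }
  p_m <- inverse_transform_pressure(pm_hats, amp$tones, t)
  p_v <- inverse_transform_pressure(pv_hats, amp$tones, t)
  v_m_r <- tone_synthesis(vmr_hats, amp$tones, t)
  v_m_theta <- tone_synthesis(vmt_hats, amp$tones, t)
  v_v_r <- tone_synthesis(vvr_hats, amp$tones, t)
  v_v_theta <- tone_synthesis(vvt_hats, amp$tones, t)
  u <- p_m - p_v - bd$pbar # transmural driving difference
  cS <- params$Lp * params$S_tot
  q_m <- (cS / params$V_m_tot) * u # volume lost by the matrix
  q_v <- (cS / params$V_v_tot) * u # volume gained by the vessels
  residual <- max(abs(params$V_m_tot * (-q_m) + params$V_v_tot * q_v)) /
    max(cS * max(abs(u)), 1e-300)
  structure(
    list(
      r = r, zeta = zeta, t = t, p_m = p_m, p_v = p_v,
      v_m_r = v_m_r, v_m_theta = v_m_theta,
      v_v_r = v_v_r, v_v_theta = v_v_theta,
      transmural = u, q_exchange = q_v, q_matrix = q_m,
      residual = residual, amp = amp, bd = bd, params = params
    ),
    class = "field_grid"
  )
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf(
    "Field grid: %d r x %d zeta x %d t\n  p_m in [%.4g, %.4g] mPa, p_v in [%.4g, %.4g] mPa\n",
    length(x$r), length(x$zeta), length(x$t),
    min(x$p_m), max(x$p_m), min(x$p_v), max(x$p_v)
  ))
  cat(sprintf("  mass-balance residual %.3g\n", x$residual))
  invisible(x)
}

#' Interphase exchange flux and mass-balance residual
#'
#' Evaluates the volumetric Starling exchange
#' `q = Lp S_tot / V_gamma (p_m - p_v - pbar)` for both phases and the
#' weighted-divergence identity
#' `V_m div<v_m> + V_v div<v_v> = 0`, whose residual vanishes analytically
#' because the exchange terms cancel between the phases.
#'
#' @param fields a `field_grid` from [solve_node()].
#' @return list with `q_matrix`, `q_vessel` (s^-1) and `residual` (relative).
#' @export
exchange_flux <- function(fields) {
  list(
    q_matrix = fields$q_matrix, q_vessel = fields$q_exchange,
    residual = fields$residual
  )
}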
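test_that("exchange parameters match hand evaluation and degenerate limits", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  xp <- compute_exchange_params(pp, 4.12e-7, sp)
  # hand evaluation: Lp*S/(V_v*Kv) with the Table values
  expect_equal(xp$Mv, 5.475e-10 * 13.4 / (0.0322 * 4.12e-7), tolerance = 1e-12)
  expect_equal(xp$Mv, 0.553, tolerance = 1e-3)
  expect_equal(xp$M(0.5), xp$Mv + xp$Mm(0.5), tolerance = 1e-15)
  # Lp = 0: no exchange
  xp0 <- compute_exchange_params(physiological_parameters(Lp = 0), 4.12e-7, sp)
  expect_equal(xp0$Mv, 0)
  expect_equal(Mod(xp0$Mm(0.3)), 0)
  # Hermitian symmetry of M in omega
  expect_equal(xp$Mm(-0.5), Conj(xp$Mm(0.5)))
})

test_that("Legendre projection: orthogonality and affine boundaries", {
  pp <- default_params()
  # pm = P_2(zeta), steady: only b_m^(2) = 1 survives
  bd <- boundary_data(pm = function(z, t) 0.5 * (3 * z^2 - 1), period = 2)
  m <- project_boundary_to_modes(bd, n_max = 5, tones = 0)
  expect_equal(Re(m$bm[3, 1]), 1, tolerance = 1e-12)
  expect_lt(max(Mod(m$bm[-3, 1])), 1e-12)
  # constant boundary c: only n = 0, value c
  bdc <- boundary_data(pm = function(z, t) rep(7.5, length(z)), period = 2)
  mc <- project_boundary_to_modes(bdc, n_max = 4, tones = 0)
  expect_equal(Re(mc$bm[1, 1]), 7.5, tolerance = 1e-12)
  expect_lt(max(Mod(mc$bm[-1, 1])), 1e-12)
  # the pulsatile boundary is affine in zeta: exactly two Legendre modes
  bdl <- baseline_boundary(pp)
  ml <- project_boundary_to_modes(bdl, n_max = 6, tones = c(0, 0.5))
  expect_lt(max(Mod(ml$bm[3:7, ])), 1e-9 * max(Mod(ml$bm)))
  expect_error(project_boundary_to_modes(bdl, n_max = 10, n_quad = 5),
               "quadrature")
})

test_that("mode amplitudes: equilibrium, Bessel normalization, Lp = 0 limit", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  xp <- compute_exchange_params(pp, 4.12e-7, sp)
  # equilibrium: pm = pv = const, pbar = 0 -> A~_n = 0, fields constant
  bd <- boundary_data(pm = function(z, t) rep(5e5, length(z)), pv = 5e5,
                      pbar = 0, period = 2)
  m <- project_boundary_to_modes(bd, 4, tones = 0)
  amp <- assemble_mode_amplitudes(m, xp, pp$R)
  expect_lt(max(Mod(coef_A_tilde(amp, 1))), 1e-9)
  ph <- evaluate_pressure_hat(amp, c(0.1, 0.3, pp$R), c(-0.5, 0.5), 1)
  expect_equal(Re(ph$pm_hat), matrix(5e5, 3, 2), tolerance = 1e-9)
  expect_equal(Re(ph$pv_hat), matrix(5e5, 3, 2), tolerance = 1e-9)

  # direct special-function value: b0 = 1, pbar = 0, R = 1, sqrt(M) R = 1
  # -> A~_0 = 1/I_{1/2}(1), with I_{1/2}(1) = sqrt(2/pi) sinh(1)
  xp1 <- xp; xp1$Mv <- 1; xp1$Mm <- function(w) 0i; xp1$M <- function(w) 1
  m1 <- structure(list(n_max = 0, tones = 0, bm = matrix(1 + 0i), bv = matrix(0i),
                       b = matrix(1 + 0i), pbar_tone = 0i, period = 2),
                  class = "mode_coefficients")
  a1 <- assemble_mode_amplitudes(m1, xp1, R = 1)
  expect_equal(Re(coef_A_tilde(a1, 1)[1]), 1 / (sqrt(2 / pi) * sinh(1)),
               tolerance = 1e-12)

  # Lp = 0 decoupled harmonic limit: c1 = bm/R^n, d1 = bv/R^n, and the
  # n = 1 mode gives pm = (r/R) zeta exactly
  pp0 <- physiological_parameters(Lp = 0)
  xp0 <- compute_exchange_params(pp0, 4.12e-7, sp)
  bdh <- boundary_data(pm = function(z, t) 1e5 * z, pv = 0, period = 2)
  mh <- project_boundary_to_modes(bdh, 3, tones = 0)
  ah <- assemble_mode_amplitudes(mh, xp0, pp$R)
  expect_equal(Re(coef_c1(ah, 1)[2]), 1e5 / pp$R, tolerance = 1e-9)
  r <- seq(0, pp$R, length.out = 11)
  phh <- evaluate_pressure_hat(ah, r, c(-1, 0.3, 1), 1)
  expect_equal(Re(phh$pm_hat), outer(r / pp$R, c(-1, 0.3, 1)) * 1e5,
               tolerance = 1e-9)
})

test_that("series solution matches the brute-force radial ODE oracle", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  xp <- compute_exchange_params(pp, 4.12e-7, sp)
  for (case in list(
    list(n = 0, Mm = Re(xp$Mm(0)) + 0i, pbar = -8.976e5),
    list(n = 1, Mm = Re(xp$Mm(0)) + 0i, pbar = 0),
    list(n = 2, Mm = xp$Mm(0.5), pbar = 0)
  )) {
    orc <- make_reference_radial_oracle(case$n, case$Mm, xp$Mv, pp$R,
                                        bm = 1e5, bv = 2e5,
                                        pbar = case$pbar, n_grid = 2000)
    modes <- structure(list(
      n_max = case$n, tones = 0.5,
      bm = matrix(c(rep(0i, case$n), 1e5 + 0i), case$n + 1, 1),
      bv = matrix(c(rep(0i, case$n), 2e5 + 0i), case$n + 1, 1),
      b = matrix(c(rep(0i, case$n), -1e5 + 0i), case$n + 1, 1),
      pbar_tone = as.complex(case$pbar), period = 2
    ), class = "mode_coefficients")
    xpc <- xp; xpc$Mm <- function(w) case$Mm
    xpc$M <- function(w) xp$Mv + case$Mm
    amp <- assemble_mode_amplitudes(modes, xpc, pp$R)
    ph <- evaluate_pressure_hat(amp, orc$r, 1, 1) # zeta = 1: P_n(1) = 1
    expect_lt(max(Mod(ph$pm_hat[, 1] - orc$pm)) / max(Mod(orc$pm)), 1e-6)
    expect_lt(max(Mod(ph$pv_hat[, 1] - orc$pv)) / max(Mod(orc$pv)), 1e-6)
  }
})

test_that("boundary recovery and realness of synthesized fields", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  bd <- baseline_boundary(pp)
  f <- solve_node(pp, 4.12e-7, sp, bd, n_max = 1, tones = c(0, 0.5))
  nr <- length(f$r)
  for (m in seq_along(f$t)) {
    expect_lt(
      max(abs(f$p_m[nr, , m] - bd$pm(f$zeta, f$t[m]))) / max(abs(f$p_m)),
      1e-8
    )
    expect_lt(max(abs(f$p_v[nr, , m] - pp$pbar_v)) / pp$pbar_v, 1e-8)
  }
  expect_true(all(is.finite(f$p_m)), all(is.finite(f$v_m_r)))
  expect_true(is.numeric(f$p_m) && is.numeric(f$v_v_theta))
})

test_that("tone backend and FFT backend agree on a band-limited boundary", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  bd <- baseline_boundary(pp)
  s1 <- solve_node(pp, 4.12e-7, sp, bd, n_max = 3, tones = c(0, 0.5))
  s2 <- solve_node(pp, 4.12e-7, sp, bd, n_max = 3, tones = NULL, n_t = 64)
  expect_lt(max(abs(s1$p_m - s2$p_m)) / max(abs(s1$p_m)), 1e-8)
  expect_lt(max(abs(s1$v_m_r - s2$v_m_r)) / max(abs(s1$v_m_r)), 1e-8)
})

test_that("velocities: gradient of the n = 1 harmonic mode is uniform axial", {
  pp <- physiological_parameters(Lp = 0)
  K0 <- 3.6e-9
  sp <- surrogate_spectrum(K0 = K0)
  b <- 1e5
  bd <- boundary_data(pm = function(z, t) b * z, pv = 0, period = 2)
  f <- solve_node(pp, 4.12e-7, sp, bd, n_max = 3, tones = 0)
  # v = -K grad(b r zeta / R): radial = -(K b/R) zeta, polar = (K b/R) sin
  expect_equal(f$v_m_r[, , 1], outer(rep(-K0 * b / pp$R, length(f$r)), f$zeta),
               tolerance = 1e-10)
  expect_equal(f$v_m_theta[, , 1],
               outer(rep(K0 * b / pp$R, length(f$r)), sqrt(1 - f$zeta^2)),
               tolerance = 1e-10)
  # uniform-pressure vessel phase: zero vessel velocity everywhere
  expect_lt(max(abs(f$v_v_r)), 1e-20)
})

test_that("mass balance: weighted divergence identity and equilibrium flux", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  f <- solve_node(pp, 4.12e-7, sp, baseline_boundary(pp), n_max = 2,
                  tones = c(0, 0.5))
  expect_lt(f$residual, 1e-8)
  q <- exchange_flux(f)
  expect_lt(q$residual, 1e-8)
  # equilibrium: q vanishes
  bd0 <- boundary_data(pm = function(z, t) rep(5e5, length(z)), pv = 5e5,
                       pbar = 0, period = 2)
  f0 <- solve_node(pp, 4.12e-7, sp, bd0, n_max = 2, tones = 0)
  expect_lt(max(abs(f0$q_exchange)) * pp$V_v_tot / (pp$Lp * pp$S_tot), 1e-3)
  # baseline direction: transmural difference positive (matrix -> vessel)
  # wherever p_m - p_v + sigma*delta_pi > 0 -- at baseline, everywhere
  expect_true(all(f$transmural > 0))
  expect_true(all(f$q_exchange > 0))
})

test_that("convergence in n_max for smooth non-polynomial boundary data", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  bd <- boundary_data(pm = function(z, t) 4e5 + 5e4 * exp(z), pv = 5e5,
                      pbar = -1e5, period = 2)
  errs <- sapply(c(2, 6, 12), function(nm) {
    f <- solve_node(pp, 4.12e-7, sp, bd, n_max = nm, tones = 0,
                    r = pp$R, zeta = seq(-0.95, 0.95, by = 0.05), t = 0)
    max(abs(f$p_m[1, , 1] - bd$pm(seq(-0.95, 0.95, by = 0.05), 0)))
  })
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], 1e-6 * 5e5)
})
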
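test_that("Starling offset and pulsatile boundary match their closed forms", {
  expect_equal(starling_pbar(0.88, 0, 1.02e6), -8.976e5)
  expect_equal(starling_pbar(0, 1e5, 9e5), 0)
  expect_equal(starling_pbar(0.5, 3e5, 3e5), 0)
  expect_error(starling_pbar(1.2, 0, 1), "sigma")

  # t = 0: uniform midpoint; t = 1 s: spans [pmin, pmax] between the poles
  expect_equal(boundary_linear_pulsatile(0.37, 0), 4.6e5)
  expect_equal(boundary_linear_pulsatile(1, 1), 5.2e5)
  expect_equal(boundary_linear_pulsatile(-1, 1), 4.0e5)
  # literal form: unit-amplitude zeta coefficient
  expect_equal(boundary_linear_pulsatile(1, 1, mode = "as_printed"),
               4.6e5 + 1)
  expect_error(boundary_linear_pulsatile(0, 0, mode = "nope"))
  # 2 s periodicity
  tt <- seq(0, 2, by = 0.25)
  expect_equal(boundary_linear_pulsatile(0.5, tt),
               boundary_linear_pulsatile(0.5, tt + 2))
})

test_that("baseline run: boundary trace, finiteness, minimum migration", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  run <- run_baseline(pp, 4.12e-7, sp)
  f <- run$fields
  bd <- baseline_boundary(pp)
  nr <- length(f$r)
  expect_lt(
    max(abs(f$p_m[nr, , 3] - bd$pm(f$zeta, f$t[3]))) / max(abs(f$p_m)), 1e-8
  )
  expect_true(all(is.finite(f$v_m_r)) && all(is.finite(f$v_v_theta)))
  # the p_m minimum migrates from the centre toward the lower pole while
  # the pulse grows, and rises while the pulse relaxes (t in [1, 2] s)
  s <- run$summary
  expect_lt(s$r_at_min[s$t == 0], 0.05 * pp$R)
  expect_gt(s$r_at_min[s$t == 1], s$r_at_min[s$t == 0])
  expect_lt(s$zeta_at_min[s$t == 1], -0.9)
  relax <- s[s$t >= 1, ]
  expect_true(all(diff(relax$p_m_min) > 0))
})

test_that("sweeps reproduce the directional responses", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  # increasing Lp lowers the interstitial centre pressure and raises the
  # vessel centre pressure
  swL <- parameter_sweep("Lp", c(1e-10, 5.475e-10, 2e-9, 1e-8), pp,
                         4.12e-7, sp)
  expect_true(all(diff(swL$p_m_center) < 0))
  expect_true(all(diff(swL$p_v_center) > 0))
  # increasing pbar_v raises the maximum vessel pressure and the p_m minimum
  swP <- parameter_sweep("pbar_v", c(6.66e5, 9e5, 1.2e6), pp, 4.12e-7, sp)
  expect_true(all(diff(swP$p_v_max) > 0))
  expect_true(all(diff(swP$p_m_min) > 0))
  # empty sweep: empty table
  expect_equal(nrow(parameter_sweep("Lp", numeric(0), pp, 4.12e-7, sp)), 0)
  expect_error(parameter_sweep("Lp", c(1e-10, NaN), pp, 4.12e-7, sp),
               "finite")
})

test_that("flow-inversion threshold: location, translation property, errors", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  inv <- flow_inversion_threshold(pp, 4.12e-7, sp, tol = 50)
  # boundary-dominated estimate: max boundary p_m + sigma*delta_pi
  expect_equal(inv$threshold_mPa, 5.2e5 + 0.88 * 1.02e6, tolerance = 1e-2)
  expect_gt(inv$max_u_below, 0)
  expect_lte(inv$max_u_above, 0)
  # raising sigma*delta_pi by delta shifts the threshold up by exactly delta
  dpi <- 1e5
  pp2 <- physiological_parameters(pi_v_minus_pi_m = 1.02e6 + dpi)
  inv2 <- flow_inversion_threshold(pp2, 4.12e-7, sp, tol = 50,
                                   bracket = c(1.0e6, 2.2e6))
  expect_equal(inv2$threshold_mPa - inv$threshold_mPa, 0.88 * dpi,
               tolerance = 300)
  # per-time reporting flags each sampled time as inverted at the threshold
  invt <- flow_inversion_threshold(pp, 4.12e-7, sp, tol = 1e3,
                                   per_time = TRUE)
  expect_type(invt$inverted_per_time, "logical")
  # degenerate input: no exchange
  expect_error(
    flow_inversion_threshold(physiological_parameters(Lp = 0), 4.12e-7, sp),
    "degenerate|Lp"
  )
  # bracket without a sign change
  expect_error(
    flow_inversion_threshold(pp, 4.12e-7, sp, bracket = c(2.5e6, 3e6)),
    "bracket"
  )
})

test_that("conductivity sensitivity: zero at zero, linear, metric options", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  s <- sensitivity_conductivity(pp, 4.12e-7, sp, c(0, 0.01, 0.02))
  expect_equal(s$variation_percent[1], 0)
  expect_gt(s$variation_percent[2], 0)
  # local linearity: variation(2%)/variation(1%) in [1.8, 2.2]
  ratio <- s$variation_percent[3] / s$variation_percent[2]
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
  sm <- sensitivity_conductivity(pp, 4.12e-7, sp, 0.01, metric = "mean")
  expect_lt(sm$variation_percent, s$variation_percent[2])
  expect_error(sensitivity_conductivity(pp, 4.12e-7, sp, -1.5), "> -1")
})

test_that("sweeps are pure: identical inputs give identical outputs", {
  pp <- default_params()
  sp <- surrogate_spectrum()
  a <- parameter_sweep("delta_pi", c(8e5, 1.02e6), pp, 4.12e-7, sp)
  b <- parameter_sweep("delta_pi", c(8e5, 1.02e6), pp, 4.12e-7, sp)
  expect_identical(a, b)
})
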
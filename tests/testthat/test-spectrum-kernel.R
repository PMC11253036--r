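test_that("single-pole surrogate: closed-form kernel and DC consistency", {
  K0 <- 2e-9; tau <- 0.05
  om <- seq(0, 640 - 0.3125, by = 0.3125)
  sp <- make_surrogate_spectrum(K0, tau, om)
  expect_equal(sp$values[1], as.complex(K0))
  k <- spectrum_to_time_kernel(sp)
  it <- which(k$t >= 0.02 & k$t <= 0.3)
  exact <- (K0 / tau) * exp(-k$t[it] / tau)
  # frequency-truncation error of the band-limited reconstruction
  expect_lt(max(abs(k$values[it] - exact)) / max(exact), 0.01)
  # rectangle-rule integral equals the DC value exactly (discrete identity)
  expect_equal(kernel_integral(k), K0, tolerance = 1e-12)
})

test_that("surrogate spectra satisfy the declared invariants", {
  sp <- make_surrogate_spectrum(1e-9, 0.1, seq(-2, 2, by = 0.25))
  expect_silent(validate_spectrum(sp, monotone = TRUE))
  # Hermitian symmetry exact by construction
  n <- length(sp$omega)
  expect_equal(sp$values, Conj(rev(sp$values)))
  expect_error(make_surrogate_spectrum(-1, 0.1, 0:3), "positive")
})

test_that("frequency-constant spectrum gives a first-bin (discrete delta) kernel", {
  om <- seq(0, 16 - 0.5, by = 0.5)
  sp <- conductivity_spectrum_obj(om, rep(3e-9 + 0i, length(om)))
  k <- spectrum_to_time_kernel(sp)
  expect_gt(abs(k$values[1]), 0.9 * sum(abs(k$values)))
  expect_equal(kernel_integral(k), 3e-9, tolerance = 1e-12)
})

test_that("non-Hermitian or non-uniform spectra are rejected", {
  expect_error(
    spectrum_to_time_kernel(
      conductivity_spectrum_obj(c(-1, 0, 1), c(2 + 1i, 1 + 0i, 2 + 1i),
                                check = FALSE)
    ),
    "Hermitian|imaginary"
  )
  expect_error(
    spectrum_to_time_kernel(
      conductivity_spectrum_obj(c(0, 1, 3), c(1, 0.5, 0.2) + 0i)
    ),
    "uniform"
  )
})

test_that("frequency/time duality: transform round-trip is the identity", {
  sp <- make_surrogate_spectrum(5e-9, 0.08, seq(0, 64 - 0.25, by = 0.25))
  k <- spectrum_to_time_kernel(sp)
  k2 <- spectrum_to_time_kernel(time_kernel_to_spectrum(k))
  expect_lt(max(abs(k2$values - k$values)) / max(abs(k$values)), 1e-8)
})

test_that("Hermitian spectra always yield real kernels (property sweep)", {
  set.seed(42)
  om <- seq(0, 32 - 0.5, by = 0.5)
  for (rep in 1:5) {
    K0 <- 10^stats::runif(1, -10, -8)
    tau <- 10^stats::runif(1, -2, -0.5)
    k <- spectrum_to_time_kernel(make_surrogate_spectrum(K0, tau, om))
    expect_true(is.numeric(k$values)) # imaginary residual checked internally
    expect_lt(abs(kernel_integral(k) - K0), 1e-10 * K0)
  }
})
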
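# Axial Brinkman flow in a circular cylinder: the closed-form solution used
# to validate the cell solvers, its finite-volume radial reduction, and the
# fast eigendecomposition sweep used for the frequency/time kernel
# consistency study.

# I1(z)/I0(z) by Lentz's continued fraction (valid for all complex z off the
# negative real axis; our arguments have Re z >= 0)
bessel_ratio_i1_i0 <- function(z) {
  z <- as.complex(z)
  out <- complex(length(z))
  for (m in seq_along(z)) {
    zz <- z[m]
    if (Mod(zz) < 1e-8) {
      out[m] <- zz / 2
      next
    }
    # I_{nu+1}/I_nu(z) = z / (2(nu+1) + z^2/(2(nu+2) + z^2/(...)))
    tiny <- 1e-30
    f <- tiny; C <- f; D <- 0
    k <- 1
    repeat {
      b <- 2 * k / zz # CF in the form f = 1/(b1 + 1/(b2 + ...)) after scaling
      a <- 1
      D <- b + a * D
      if (Mod(D) == 0) D <- tiny
      C <- b + a / C
      if (Mod(C) == 0) C <- tiny
      D <- 1 / D
      delta <- C * D
      f <- f * delta
      if (Mod(delta - 1) < 1e-15 || k > 10000) break
      k <- k + 1
    }
    out[m] <- f
  }
  out
}

#' Closed-form axial Brinkman flow in a cylinder
#'
#' For axial flow driven by a unit pressure gradient in a cylinder of
#' (nondimensional) radius `r_hat_c` with drag `1/K_star` and viscosity ratio
#' `mu_star`, the velocity profile is
#' `W(r) = K* (1 - I0(r/sqrt(mu* K*)) / I0(r_hat_c/sqrt(mu* K*)))`
#' and its cross-section average has the closed form used to validate the
#' numerical cell solvers (complex `K_star` encodes the oscillatory drag).
#'
#' @param K_star complex conductivity (nonzero).
#' @param mu_star viscosity ratio.
#' @param r_hat_c cylinder radius.
#' @param r optional radial points (`0 <= r <= r_hat_c`) for the profile.
#' @return list with `average` (complex scalar) and, when `r` is given,
#'   `profile` (complex vector).
#' @export
analytic_cylinder_profile <- function(K_star, mu_star = 1, r_hat_c,
                                      r = NULL) {
  if (K_star == 0) stop("K_star must be nonzero")
  a <- 1 / sqrt(as.complex(mu_star * K_star)) # principal root, Re >= 0
  # 1 - (2/x) I1/I0 = I2/I0 (recurrence): cancellation-free for small |x|
  x <- a * r_hat_c
  avg <- K_star * bessel_i2c(x) / bessel_i0c(x)
  out <- list(average = avg)
  if (!is.null(r)) {
    if (any(r > r_hat_c + 1e-14) || any(r < 0)) {
      stop("profile points must satisfy 0 <= r <= r_hat_c")
    }
    out$profile <- K_star * (1 - bessel_i0c(a * r) / bessel_i0c(a * r_hat_c))
  }
  out
}

# staggered radial finite-volume operator L = (1/r) d/dr (r d/dr) on
# (0, r_hat_c), natural regularity at 0, Dirichlet 0 at r_hat_c (ghost
# reflection, second order). Banded form: lower/diag/upper coefficient
# vectors plus the cross-section averaging weights.
cylinder_radial_system <- function(n_r, r_hat_c) {
  hr <- r_hat_c / n_r
  r <- (seq_len(n_r) - 0.5) * hr
  rp <- r + hr / 2 # r_{i+1/2}; rp[n_r] = r_hat_c
  rm <- r - hr / 2 # r_{i-1/2}; rm[1] = 0
  lower <- rm / (r * hr^2) # coefficient of W_{i-1} (index 1 unused)
  upper <- rp / (r * hr^2) # coefficient of W_{i+1} (index n_r unused)
  diagv <- -(rm + rp) / (r * hr^2)
  diagv[n_r] <- diagv[n_r] - rp[n_r] / (r[n_r] * hr^2) # ghost W = -W_N
  lower[1] <- 0
  upper[n_r] <- 0
  w <- 2 * r * hr / r_hat_c^2 # cross-section average weights (sum to 1)
  list(r = r, lower = lower, diagv = diagv, upper = upper, w = w, hr = hr)
}

# dense matrix form of the banded radial operator (small n_r only)
cylinder_radial_dense <- function(sys) {
  n_r <- length(sys$r)
  L <- matrix(0, n_r, n_r)
  L[cbind(seq_len(n_r), seq_len(n_r))] <- sys$diagv
  L[cbind(2:n_r, 1:(n_r - 1))] <- sys$lower[2:n_r]
  L[cbind(1:(n_r - 1), 2:n_r)] <- sys$upper[1:(n_r - 1)]
  L
}

#' Numerical axial Brinkman flow in a cylinder (radial reduction)
#'
#' Solves `(1/K_star) W - mu_star (1/r)(r W')' = 1` with regularity at the
#' axis and no-slip at `r = r_hat_c` by staggered finite volumes, and returns
#' the cross-section average for comparison with
#' [analytic_cylinder_profile()].
#'
#' @inheritParams analytic_cylinder_profile
#' @param n_r number of radial cells.
#' @return list with `r`, `W` (complex profile) and `average`.
#' @export
solve_cylinder_brinkman_radial <- function(K_star, mu_star = 1, r_hat_c,
                                           n_r = 2000) {
  sys <- cylinder_radial_system(n_r, r_hat_c)
  # complex tridiagonal Thomas solve of (s I - mu* L) W = 1
  s <- 1 / as.complex(K_star)
  lower <- -mu_star * sys$lower
  upper <- -mu_star * sys$upper
  diagc <- s - mu_star * sys$diagv
  d <- rep(1 + 0i, n_r)
  # forward sweep
  cp <- complex(n_r); dp <- complex(n_r)
  cp[1] <- upper[1] / diagc[1]
  dp[1] <- d[1] / diagc[1]
  for (i in 2:n_r) {
    m <- diagc[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / m
    dp[i] <- (d[i] - lower[i] * dp[i - 1]) / m
  }
  W <- complex(n_r)
  W[n_r] <- dp[n_r]
  for (i in (n_r - 1):1) W[i] <- dp[i] - cp[i] * W[i + 1]
  list(r = sys$r, W = W, average = sum(sys$w * W))
}

#' Conductivity spectrum of the cylinder analogue (fast frequency sweep)
#'
#' One-dimensional analogue of the matrix cell problem: axial Brinkman flow
#' in a cylinder with local conductivity `K_m`, swept over many frequencies
#' through an eigendecomposition of the radial operator (the operator is
#' frequency-independent; only the drag shift varies).
#'
#' @param K_m local conductivity.
#' @param mu_star viscosity ratio.
#' @param r_hat_c cylinder radius.
#' @param inertia coefficient of `2*pi*i*omega` in the drag.
#' @param omega_grid frequencies (Hz), `>= 0` uniform from 0.
#' @param n_r radial cells.
#' @return a `conductivity_spectrum` (nondimensional values).
#' @export
cylinder_conductivity_spectrum <- function(K_m, mu_star = 1, r_hat_c,
                                           inertia, omega_grid, n_r = 200) {
  sys <- cylinder_radial_system(n_r, r_hat_c)
  B <- diag(1 / K_m, n_r) - mu_star * cylinder_radial_dense(sys)
  eg <- eigen(B)
  Vi1 <- solve(eg$vectors, rep(1, n_r))
  c_k <- as.vector(crossprod(sys$w, eg$vectors)) * Vi1
  vals <- vapply(omega_grid, function(w) {
    sum(c_k / (2i * pi * w * inertia + eg$values))
  }, complex(1))
  conductivity_spectrum_obj(omega_grid, vals, check = FALSE)
}

#' Time-stepped memory kernel of the cylinder analogue
#'
#' Direct time integration of the integrated kernel problem
#' `inertia * dQbar/dt = 1 - (1/K_m) Qbar + mu_star (1/r)(r Qbar')'`,
#' `Qbar(0) = 0`, by Crank-Nicolson with an implicit-Euler (Rannacher) start
#' to damp the initial discontinuity. The kernel `d<Qbar>/dt` is evaluated
#' from the spatial operator (not by differencing), so it is smooth in time.
#'
#' @inheritParams cylinder_conductivity_spectrum
#' @param t_grid uniform time grid from 0.
#' @param n_startup number of implicit-Euler half-step pairs at the start.
#' @return a `time_kernel` on `t_grid`.
#' @export
cylinder_kernel_time <- function(K_m, mu_star = 1, r_hat_c, inertia, t_grid,
                                 n_r = 200, n_startup = 32) {
  sys <- cylinder_radial_system(n_r, r_hat_c)
  B <- diag(1 / K_m, n_r) - mu_star * cylinder_radial_dense(sys)
  dt <- t_grid[2] - t_grid[1]
  nt <- length(t_grid)
  eta <- inertia
  Id <- diag(1, n_r)
  # CN step: (eta/dt I + B/2) Q_{m+1} = (eta/dt I - B/2) Q_m + 1
  Acn <- eta / dt * Id + B / 2
  Scn <- solve(Acn, eta / dt * Id - B / 2)
  bcn <- solve(Acn, rep(1, n_r))
  # IE quarter-steps for startup
  die <- dt / 4
  Aie <- eta / die * Id + B
  Sie <- solve(Aie, eta / die * Id)
  bie <- solve(Aie, rep(1, n_r))
  Q <- rep(0, n_r)
  kern <- numeric(nt)
  kern[1] <- sum(sys$w) / eta # Qbar = 0 at t = 0
  for (m in 2:nt) {
    if (m <= n_startup + 1) {
      for (q in 1:4) Q <- Sie %*% Q + bie
    } else {
      Q <- Scn %*% Q + bcn
    }
    kern[m] <- sum(sys$w * (1 - B %*% Q)) / eta
  }
  structure(list(t = t_grid, values = kern), class = "time_kernel")
}
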
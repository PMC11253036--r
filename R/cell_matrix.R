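# Matrix-phase (Brinkman) cell problem.  The auxiliary tensor Q solves, per
# forcing direction j and frequency omega,
#   (2*pi*i*omega*inertia + 1/K_m) Q_j - mu_star Lap Q_j + grad h_j = e_j,
#   div Q_j = 0                        in the matrix phase,
#   Q_j . n = 0                        on the vessel interface (no penetration),
#   Q_j . tau = -(K_m/alpha) (d/dn) Q_j . tau   (Beavers-Joseph slip),
# periodic on the cell boundary, <h_j> = 0.  Voxel staggered grid: velocities
# on faces between matrix voxels, pressure at voxel centers.  No-penetration
# is enforced strongly on wall faces; the slip condition is discretized with a
# one-sided normal gradient (first order).  Complex systems are solved in the
# real augmented form, the zero-mean pressure by one Lagrange multiplier.

#' Configuration for matrix-phase cell problems
#'
#' @param K_m local nondimensional matrix conductivity (isotropic scalar).
#' @param mu_star viscosity ratio `mu_e/mu`.
#' @param alpha Beavers-Joseph slip constant (> 0).
#' @param inertia coefficient multiplying `2*pi*i*omega` in the drag; for
#'   dimensional frequencies in Hz this is `rho0*d^2/mu` (the U-independent
#'   combination `eta * L/U`), the default when built from parameters via
#'   [cell_config_from_params()].
#' @param drag optional complex override of the full drag coefficient
#'   `2*pi*i*omega*inertia + 1/K_m` (used by validation against closed forms).
#' @return object of class `cell_problem_config`.
#' @export
cell_problem_config <- function(K_m, mu_star = 1, alpha = 1, inertia = 0,
                                drag = NULL) {
  if (is.null(drag)) {
    if (K_m <= 0) stop("K_m must be positive (symmetric positive definite)")
  }
  if (alpha <= 0) stop("alpha must be positive")
  structure(
    list(K_m = K_m, mu_star = mu_star, alpha = alpha, inertia = inertia,
         drag = drag),
    class = "cell_problem_config"
  )
}

#' @rdname cell_problem_config
#' @param params a `physiological_parameters` object; `K_m` defaults to the
#'   interstitial permeability scaled by `d^2`, `mu_star` to `mu_e/mu`.
#' @export
cell_config_from_params <- function(params, alpha = 1) {
  cell_problem_config(
    K_m = params$K_m_interstitial / params$d^2,
    mu_star = params$mu_e / params$mu,
    alpha = alpha,
    inertia = params$rho0 * params$d^2 / params$mu
  )
}

# Assemble the real building blocks of the staggered saddle system on the
# matrix phase of `geom`: viscous operator A0 (with slip/no-slip walls),
# velocity identity pattern, gradient G, divergence D, bordered zero-mean row.
# Returns an environment reused across frequencies/time steps.
assemble_matrix_cell <- function(geom, config) {
  Mm <- !geom$phase
  n <- geom$resolution
  h <- geom$h
  nm <- sum(Mm)
  if (nm == 0) stop("matrix phase is empty")
  if (!phase_connected(Mm)) {
    stop("matrix phase is not periodically connected")
  }
  lam <- config$K_m / config$alpha # slip length
  beta <- (lam / h) / (1 + lam / h)
  mu_s <- config$mu_star

  vox_id <- array(0L, dim(Mm))
  vox_id[Mm] <- seq_len(nm)

  dofmask <- vector("list", 3)
  faceid <- vector("list", 3)
  ndof_k <- integer(3)
  off <- 0L
  for (k in 1:3) {
    dm <- Mm & shift_array(Mm, k, 1L)
    fid <- array(0L, dim(Mm))
    fid[dm] <- off + seq_len(sum(dm))
    dofmask[[k]] <- dm
    faceid[[k]] <- fid
    ndof_k[k] <- sum(dm)
    off <- off + sum(dm)
  }
  nu <- off # total velocity dofs

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  # viscous operator A0 = -mu* Lap with wall closures (no drag term)
  for (k in 1:3) {
    dm <- dofmask[[k]]
    f <- faceid[[k]][dm] # rows
    diagc <- rep(6 * mu_s / h^2, ndof_k[k])
    for (d in 1:3) {
      for (sgn in c(1L, -1L)) {
        nb <- shift_array(faceid[[k]], d, sgn)[dm]
        isdof <- nb > 0L
        add(f[isdof], nb[isdof], rep(-mu_s / h^2, sum(isdof)))
        if (d != k) {
          # tangential wall neighbour: ghost value beta*u (BJ slip)
          nw <- sum(!isdof)
          if (nw > 0) {
            diag_adj <- rep(0, ndof_k[k]); diag_adj[!isdof] <- -mu_s * beta / h^2
            diagc <- diagc + diag_adj
          }
        }
        # longitudinal wall neighbour: value 0 (no-penetration), no term
      }
    }
    add(f, f, diagc)
  }
  A0 <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nu, nu))

  # divergence D (nm x nu) and gradient G = -t(D)
  di <- integer(0); dj <- integer(0); dx <- numeric(0)
  for (k in 1:3) {
    dm <- dofmask[[k]]
    P <- vox_id[dm]
    E <- shift_array(vox_id, k, 1L)[dm]
    f <- faceid[[k]][dm]
    di <- c(di, P, E); dj <- c(dj, f, f); dx <- c(dx, rep(1 / h, sum(dm)),
                                                 rep(-1 / h, sum(dm)))
  }
  D <- Matrix::sparseMatrix(i = di, j = dj, x = dx, dims = c(nm, nu))

  # forcing: unit body force e_j on the momentum rows of direction j
  Frc <- matrix(0, nu, 3)
  for (j in 1:3) {
    dm <- dofmask[[j]]
    Frc[faceid[[j]][dm], j] <- 1
  }

  list(
    A0 = A0, D = D, Frc = Frc, nu = nu, nm = nm, n = n, h = h,
    faceid = faceid, dofmask = dofmask, vox_id = vox_id, Mm = Mm,
    config = config, cache = new.env(parent = emptyenv())
  )
}

# Real saddle matrix [A0 + a*I, -D^T; Dtil, P].  The pressure nullspace
# (constants) is grounded by replacing the first continuity row -- redundant
# for compatible right-hand sides, since the periodic divergence rows sum to
# zero -- with the pinning equation p_1 = 0; the zero-mean convention is
# restored after the solve by subtracting the mean.  This keeps the factor
# sparse (a global zero-mean Lagrange row would produce massive fill-in).
saddle_matrix <- function(asm, a) {
  nu <- asm$nu; nm <- asm$nm
  Dtil <- asm$D
  Dtil[1, ] <- 0
  P <- Matrix::sparseMatrix(i = 1L, j = 1L, x = 1 / asm$h, dims = c(nm, nm))
  rbind(
    cbind(asm$A0 + Matrix::Diagonal(nu, a), -Matrix::t(asm$D)),
    cbind(Dtil, P)
  )
}

# intrinsic average of the face velocities -> <Q>_{kj}
average_Q <- function(asm, U) {
  out <- matrix(if (is.complex(U)) 0i else 0, 3, 3)
  for (k in 1:3) {
    dm <- asm$dofmask[[k]]
    f <- asm$faceid[[k]][dm]
    for (j in 1:3) out[k, j] <- sum(U[f, j]) / asm$nm
  }
  out
}

# Augmented-Lagrangian Uzawa solve of the real saddle system
#   (A0 + s I) u - D^T p = F,  D u = 0,
# using the CHOLMOD Cholesky factor of the SPD grad-div-augmented operator
# H = A0 + s I + gamma D^T D.  With gamma ~ ||A|| the contraction factor is
# bounded by ~1/(1 + gamma lambda_min(Schur)), a mesh-independent ~0.03, so a
# handful of back-solves reach 1e-12.  The constant pressure mode is inert
# (D^T 1 = 0) and irrelevant to the velocity.
uzawa_solve <- function(asm, s, F, tol = 1e-12, maxit = 60) {
  mu_s <- asm$config$mu_star
  gamma <- s + 12 * mu_s / asm$h^2
  key <- paste0("chol_", signif(s, 14))
  cached <- get0(key, envir = asm$cache)
  if (is.null(cached)) {
    DtD <- Matrix::crossprod(asm$D)
    H <- Matrix::forceSymmetric(asm$A0 + Matrix::Diagonal(asm$nu, s) +
                                  gamma * DtD)
    cached <- Matrix::Cholesky(H, LDL = FALSE)
    assign(key, cached, envir = asm$cache)
  }
  ch <- cached
  q <- matrix(0, asm$nm, ncol(F))
  U <- matrix(0, asm$nu, ncol(F))
  f0 <- sqrt(mean(F^2))
  rprev <- Inf
  for (it in seq_len(maxit)) {
    rhs <- F - as.matrix(Matrix::t(asm$D) %*% q)
    U <- as.matrix(Matrix::solve(ch, rhs))
    r <- as.matrix(asm$D %*% U)
    q <- q + gamma * r
    rn <- sqrt(mean(r^2)) * asm$h
    # converged, or stalled at the roundoff floor of the contraction
    if (rn <= tol * max(f0 / s, 1e-300) || rn > 0.5 * rprev) break
    rprev <- rn
  }
  if (it == maxit) warning("uzawa_solve: divergence residual not converged")
  list(U = U, p = -q)
}

#' Solve the frequency-domain matrix cell problem
#'
#' Returns the cell-averaged complex auxiliary tensor `<Q(omega)>` (intrinsic
#' average over the matrix phase, nondimensional: multiply by `d^2/mu` for the
#' dimensional conductivity). At `omega = 0` the solve is the steady Brinkman
#' cell problem (purely real).
#'
#' Methods: `"direct"` factors the full (real or real-augmented complex)
#' saddle matrix -- robust for any drag but only economical on small cells;
#' `"uzawa"` (real drag) uses the augmented-Lagrangian iteration with a
#' CHOLMOD Cholesky factor and scales to finer cells; `"perturbative"`
#' expands in the small oscillatory drag `2 pi omega inertia` around the
#' steady solve (three Uzawa solves; relative truncation error
#' `~(Im(s)/Re(s))^3`, about 1e-24 at physiological frequencies). `"auto"`
#' picks perturbative when `|Im(s)| < 1e-3 Re(s)`, otherwise uzawa for real
#' drag and direct for genuinely complex drag.
#'
#' @param geom a `periodic_cell` (vessel voxels are excluded from the flow).
#' @param config a `cell_problem_config`.
#' @param omega frequency in Hz (may be 0 or negative).
#' @param asm optional pre-assembled operator set (for sweeps).
#' @param method one of `"auto"`, `"direct"`, `"uzawa"`, `"perturbative"`.
#' @return list with `average` (3x3 complex), `U` (face velocities), `asm`.
#' @export
solve_matrix_cell_problem_frequency <- function(geom, config, omega,
                                                asm = NULL,
                                                method = c("auto", "direct",
                                                           "uzawa",
                                                           "perturbative")) {
  method <- match.arg(method)
  if (is.null(asm)) asm <- assemble_matrix_cell(geom, config)
  s <- if (!is.null(config$drag)) {
    as.complex(config$drag)
  } else {
    2i * pi * omega * config$inertia + 1 / config$K_m
  }
  if (method == "auto") {
    method <- if (Im(s) == 0) {
      "uzawa"
    } else if (abs(Im(s)) < 1e-3 * Re(s)) {
      "perturbative"
    } else {
      "direct"
    }
  }
  nu <- asm$nu; nm <- asm$nm
  ntot <- nu + nm
  rhs <- rbind(asm$Frc, matrix(0, nm, 3))
  if (method == "uzawa") {
    if (Im(s) != 0) stop("uzawa method requires real drag; use perturbative")
    U <- uzawa_solve(asm, Re(s), asm$Frc)$U
  } else if (method == "perturbative") {
    # U(s_r + i sig) = U0 + (i sig) U1 + (i sig)^2 U2 + O(sig^3),
    # U_{k+1} = -M^{-1}|_vel U_k with M the real saddle operator at s_r
    sig <- Im(s)
    U0 <- uzawa_solve(asm, Re(s), asm$Frc)$U
    U1 <- -uzawa_solve(asm, Re(s), U0)$U
    U2 <- -uzawa_solve(asm, Re(s), U1)$U
    U <- U0 + (1i * sig) * U1 + (1i * sig)^2 * U2
  } else if (Im(s) == 0) {
    K <- saddle_matrix(asm, Re(s))
    sol <- as.matrix(Matrix::solve(K, rhs))
    U <- sol[seq_len(nu), , drop = FALSE]
  } else {
    # real augmented form [[K, -Im(s) Iu], [Im(s) Iu, K]]
    K <- saddle_matrix(asm, Re(s))
    Iu <- Matrix::Diagonal(ntot, c(rep(Im(s), nu), rep(0, nm)))
    Kbig <- rbind(cbind(K, -Iu), cbind(Iu, K))
    sol <- as.matrix(Matrix::solve(Kbig, rbind(rhs, matrix(0, ntot, 3))))
    U <- sol[seq_len(nu), , drop = FALSE] +
      1i * sol[ntot + seq_len(nu), , drop = FALSE]
  }
  avg <- average_Q(asm, U)
  list(average = avg, U = U, asm = asm, omega = omega)
}

#' Effective matrix conductivity spectrum from the 3D cell problem
#'
#' Runs the frequency-domain Brinkman cell solve for each `omega >= 0` in
#' `omega_grid` (negative frequencies follow by Hermitian symmetry and are
#' filled by conjugation) and dimensionalizes by `K_ref = d^2/mu`. The scalar
#' spectrum is the mean of the tensor diagonal (isotropy by cubic symmetry).
#'
#' @param geom a `periodic_cell`.
#' @param config a `cell_problem_config`.
#' @param omega_grid frequencies in Hz; must be `>= 0` or symmetric about 0.
#' @param K_ref dimensionalization factor `d^2/mu` (default 1: nondimensional).
#' @return a `conductivity_spectrum`.
#' @export
conductivity_spectrum <- function(geom, config, omega_grid, K_ref = 1) {
  o <- sort(unique(omega_grid))
  if (any(o < 0)) {
    neg <- o[o < 0]
    if (!all(sapply(neg, function(w) any(abs(o + w) < 1e-12)))) {
      stop("omega grid must be >= 0 or symmetric about 0")
    }
  }
  opos <- o[o >= 0]
  asm <- assemble_matrix_cell(geom, config)
  vals_pos <- vapply(opos, function(w) {
    sol <- tryCatch(
      solve_matrix_cell_problem_frequency(geom, config, w, asm = asm),
      error = function(e) stop("cell solve failed at omega = ", w, " Hz: ",
                               conditionMessage(e))
    )
    mean(diag(sol$average))
  }, complex(1))
  vals <- complex(length(o))
  for (i in seq_along(o)) {
    if (o[i] >= 0) {
      vals[i] <- vals_pos[which.min(abs(opos - o[i]))]
    } else {
      vals[i] <- Conj(vals_pos[which.min(abs(opos + o[i]))])
    }
  }
  conductivity_spectrum_obj(o, K_ref * vals)
}

#' Time-domain matrix cell problem (integrated kernel form)
#'
#' Implicit time stepping of the integrated cell problem for `Qbar(t)`
#' (initial condition `Qbar(0) = 0`; the memory kernel is `d<Qbar>/dt`). The
#' long-time limit of `<Qbar>` is the steady cell solution. Implicit Euler
#' (default) is unconditionally stable; `scheme = "cn"` gives second order.
#'
#' @param geom a `periodic_cell`.
#' @param config a `cell_problem_config` with positive `inertia` (here the
#'   coefficient `eta` of the time derivative).
#' @param t_grid uniform time grid starting at 0.
#' @param scheme `"euler"` or `"cn"`.
#' @return list with `t`, `Qbar_avg` (length(t) x 3 x 3 array of intrinsic
#'   averages) and `kernel` (a `time_kernel` of the mean diagonal, by central
#'   differences).
#' @export
solve_matrix_cell_problem_time <- function(geom, config, t_grid,
                                           scheme = c("euler", "cn")) {
  scheme <- match.arg(scheme)
  if (abs(t_grid[1]) > 1e-15 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be uniform and start at 0")
  }
  dt <- diff(t_grid)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1])) stop("t_grid must be uniform")
  dt <- dt[1]
  eta <- config$inertia
  if (eta <= 0) stop("time stepping needs positive inertia")
  asm <- assemble_matrix_cell(geom, config)
  nu <- asm$nu; nm <- asm$nm
  theta <- if (scheme == "cn") 0.5 else 1
  # (eta/dt + theta*(1/K - mu* Lap)) U_{m+1} + grad h = eta/dt U_m
  #   - (1-theta)*(...) U_m + F ; div U_{m+1} = 0
  K <- saddle_matrix(asm, theta / config$K_m + eta / dt)
  # note: A0 enters scaled by theta for CN -> build explicitly
  if (theta != 1) {
    K <- saddle_matrix(asm, 0)
    # replace velocity block: eta/dt I + theta (A0 + I/K_m)
    nuI <- Matrix::Diagonal(nu + nm, c(rep(1, nu), rep(0, nm)))
    K <- K - nuI %*% K %*% nuI # zero the velocity-velocity block
    Avel <- theta * (asm$A0 + Matrix::Diagonal(nu, 1 / config$K_m)) +
      Matrix::Diagonal(nu, eta / dt)
    K[seq_len(nu), seq_len(nu)] <- Avel
  }
  lu <- Matrix::lu(K)
  Aexp <- if (theta != 1) {
    (1 - theta) * (asm$A0 + Matrix::Diagonal(nu, 1 / config$K_m))
  } else {
    NULL
  }
  nt <- length(t_grid)
  U <- matrix(0, nu, 3)
  Qbar <- array(0, c(nt, 3, 3))
  for (m in 2:nt) {
    rhs_u <- (eta / dt) * U + asm$Frc
    if (!is.null(Aexp)) rhs_u <- rhs_u - as.matrix(Aexp %*% U)
    rhs <- rbind(rhs_u, matrix(0, nm, 3))
    sol <- as.matrix(Matrix::solve(lu, rhs))
    U <- sol[seq_len(nu), , drop = FALSE]
    Qbar[m, , ] <- average_Q(asm, U)
  }
  # kernel = d<Qbar>/dt of the mean diagonal, central differences
  qd <- (Qbar[, 1, 1] + Qbar[, 2, 2] + Qbar[, 3, 3]) / 3
  kern <- c((qd[2] - qd[1]) / dt,
            (qd[3:nt] - qd[1:(nt - 2)]) / (2 * dt),
            (qd[nt] - qd[nt - 1]) / dt)
  list(
    t = t_grid, Qbar_avg = Qbar,
    kernel = structure(list(t = t_grid, values = kern), class = "time_kernel"),
    asm = asm
  )
}
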
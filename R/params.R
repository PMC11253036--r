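#' lymphomog: multiscale dual-porosity flow in the lymph node
#'
#' Periodic-cell homogenization solvers for effective hydraulic conductivities
#' (a Darcy cell problem for the vessel network, a frequency-domain Brinkman
#' cell problem for the interstitium), a spectral macroscale solver for the
#' coupled Darcy / Darcy-with-memory equations on a sphere, and application
#' routines for pulsatile lymph-node perfusion with Starling transvascular
#' exchange.
#'
#' All internal computation uses a self-consistent mm-mg-s-mPa unit system
#' (1 mPa = 1 mg mm^-1 s^-2); conversions happen only at I/O.
#'
#' @docType package
#' @name lymphomog-package
#' @aliases lymphomog
#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft setNames approx
#' @importFrom utils modifyList write.csv
NULL

# mPa per mmHg
.MPA_PER_MMHG <- 133322.387

#' Convert pressures between mmHg and mPa
#'
#' The package works internally in mPa; physiological literature quotes vessel
#' and sinus pressures in mmHg. One mmHg is 133322.387 mPa.
#'
#' @param p numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' mmhg_to_mpa(3.9)   # ~5.2e5 mPa
#' mpa_to_mmhg(mmhg_to_mpa(10.5))
#' @export
mmhg_to_mpa <- function(p) p * .MPA_PER_MMHG

#' @rdname mmhg_to_mpa
#' @export
mpa_to_mmhg <- function(p) p / .MPA_PER_MMHG

#' Physiological parameter set for the spherical lymph node
#'
#' Builds the dimensional parameter set describing the lymphoid compartment
#' (LC): geometry of the node and of the periodic microvascular cell, fluid
#' properties, membrane (Starling) parameters and boundary pressure levels.
#' Defaults are read from the packaged config `table1.yaml`; any field can be
#' overridden. Derived fields: `mu_e = mu/phi` (effective Brinkman viscosity),
#' `V_m_tot = (4/3)*pi*R^3 - V_v_tot` (the LC is treated as the full sphere),
#' and `U = eta*mu*L/(rho0*d^2)` (the characteristic velocity implied by the
#' inertia number `eta`, which is the quantity actually exposed).
#'
#' @param ... named overrides of any field in the config (e.g. `Lp = 0`).
#' @param config_file path to an alternative YAML parameter file.
#' @return object of class `physiological_parameters`: a named list with units
#'   documented in the package vignette.
#' @examples
#' pp <- physiological_parameters()
#' pp$R
#' physiological_parameters(sigma = 0.9)$sigma
#' @export
physiological_parameters <- function(..., config_file = NULL) {
  if (is.null(config_file)) {
    config_file <- system.file("extdata", "table1.yaml", package = "lymphomog")
  }
  base <- read_parameter_config(config_file)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), c(names(base), "mu_e", "V_m_tot", "U"))
    if (length(bad)) {
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    }
    base <- modifyList(base, over)
  }
  p <- base
  if (is.null(p$mu_e)) p$mu_e <- p$mu / p$phi
  if (is.null(p$V_m_tot)) p$V_m_tot <- (4 / 3) * pi * p$R^3 - p$V_v_tot
  if (is.null(p$U)) p$U <- p$eta * p$mu * p$L / (p$rho0 * p$d^2)
  class(p) <- "physiological_parameters"
  validate_parameters(p)
  p
}

#' Read a flat key/value parameter config (YAML)
#'
#' @param path file path.
#' @return named list of numeric values.
#' @export
read_parameter_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(x) {
    # YAML 1.1 parses exponent forms without a sign (e.g. 1.02e6) as strings
    x <- suppressWarnings(as.numeric(x))
    if (length(x) != 1 || is.na(x)) stop("non-numeric entry in parameter config")
    x
  })
}

#' @export
print.physiological_parameters <- function(x, ...) {
  units <- c(
    R = "mm", mu = "mg mm^-1 s^-1", phi = "-", mu_e = "mg mm^-1 s^-1",
    rho0 = "mg mm^-3", sigma = "-", pi_v_minus_pi_m = "mPa",
    Lp = "mm s^-1 mPa^-1", pbar_v = "mPa", S_tot = "mm^2",
    V_v_tot = "mm^3", V_m_tot = "mm^3", r_c = "mm", d = "mm", L = "mm",
    K_m_interstitial = "mm^2", eta = "-", U = "mm s^-1"
  )
  cat("Physiological parameters (mm-mg-s-mPa unit system)\n")
  for (nm in names(units)) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %-18s %-12.6g [%s]\n", nm, x[[nm]], units[[nm]]))
    }
  }
  invisible(x)
}

#' Validate a physiological parameter set
#'
#' Checks positivity, `0 < phi < 1`, `0 <= sigma <= 1`, and that the phase
#' volumes fill the sphere: `V_m_tot + V_v_tot` must equal `(4/3)*pi*R^3`
#' within 1%.
#'
#' @param p a `physiological_parameters` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_parameters <- function(p) {
  pos <- c(
    "R", "mu", "phi", "mu_e", "rho0", "S_tot", "V_v_tot", "V_m_tot",
    "r_c", "d", "L", "K_m_interstitial"
  )
  for (nm in pos) {
    if (is.null(p[[nm]]) || !is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be strictly positive")
    }
  }
  for (nm in c("Lp", "eta", "U")) {
    if (is.null(p[[nm]]) || !is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop("parameter '", nm, "' must be non-negative")
    }
  }
  if (p$phi >= 1) stop("porosity phi must lie in (0, 1)")
  if (p$sigma < 0 || p$sigma > 1) stop("sigma must lie in [0, 1]")
  vol <- (4 / 3) * pi * p$R^3
  if (abs(p$V_m_tot + p$V_v_tot - vol) > 0.01 * vol) {
    stop("V_m_tot + V_v_tot must equal the sphere volume within 1%")
  }
  invisible(p)
}

#' Nondimensional groups of the dual-porosity problem
#'
#' Computes the scale ratio `epsilon = d/L`, the inertia number
#' `eta = rho0*U*d^2/(mu*L)`, the viscosity ratio `mu_star = mu_e/mu`, the
#' reference conductivity `K_ref = d^2/mu` and the scaled membrane conductivity
#' `Lp_bar = Lp*mu*L^2/d^3`. When `U` is not supplied, `eta` is taken directly
#' from the parameter set (its default 0.1 characterizes lymph pulsation).
#'
#' @param params a `physiological_parameters` object.
#' @param U optional characteristic velocity in mm/s; overrides `params$eta`.
#' @return object of class `nondimensional_groups`.
#' @examples
#' build_nondimensional(physiological_parameters())$epsilon  # 0.02
#' @export
build_nondimensional <- function(params, U = NULL) {
  p <- params
  for (nm in c("d", "L", "mu")) {
    if (p[[nm]] <= 0) stop("invalid parameter: ", nm, " must be positive")
  }
  if (!is.null(U)) {
    if (U < 0) stop("invalid parameter: U must be non-negative")
    eta <- p$rho0 * U * p$d^2 / (p$mu * p$L)
  } else {
    eta <- p$eta
  }
  g <- list(
    epsilon = p$d / p$L,
    eta = eta,
    mu_star = p$mu_e / p$mu,
    K_ref = p$d^2 / p$mu,
    Lp_bar = p$Lp * p$mu * p$L^2 / p$d^3
  )
  class(g) <- "nondimensional_groups"
  g
}

#' @export
print.nondimensional_groups <- function(x, ...) {
  cat("Nondimensional groups\n")
  cat(sprintf("  epsilon (d/L)      %g\n", x$epsilon))
  cat(sprintf("  eta (inertia)      %g\n", x$eta))
  cat(sprintf("  mu_star (mu_e/mu)  %g\n", x$mu_star))
  cat(sprintf("  K_ref (d^2/mu)     %g  [mm^3 s mg^-1]\n", x$K_ref))
  cat(sprintf("  Lp_bar             %g\n", x$Lp_bar))
  invisible(x)
}

#' Kozeny-Carman estimate of the vessel hydraulic conductivity
#'
#' Estimates the local (Darcy) hydraulic conductivity of the blood-vessel
#' network from its total volume and surface as
#' `(1/c0) * (V/S)^2 / mu`, i.e. the squared hydraulic radius over the Kozeny
#' constant, divided by viscosity. The classical value `c0 = 5` is the default.
#'
#' @param V vessel volume (mm^3), `>= 0`.
#' @param S vessel surface (mm^2), `> 0`.
#' @param c0 Kozeny constant, `> 0`.
#' @param mu dynamic viscosity (mg mm^-1 s^-1), `> 0`.
#' @return hydraulic conductivity in mm^3 s mg^-1.
#' @examples
#' kozeny_carman(0.0322, 13.4)  # vessel network of the default node
#' @export
kozeny_carman <- function(V, S, c0 = 5, mu = 1) {
  if (S <= 0) stop("invalid parameter: S must be positive")
  if (c0 <= 0) stop("invalid parameter: c0 must be positive")
  if (mu <= 0) stop("invalid parameter: mu must be positive")
  if (V < 0) stop("invalid parameter: V must be non-negative")
  (1 / c0) * (V / S)^2 / mu
}
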
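# Lymph-node application layer: pulsatile subcapsular-sinus boundary
# condition, Starling interphase offset, baseline perfusion run, parameter
# sweeps, the flow-inversion threshold of the mean vessel pressure, and the
# conductivity sensitivity analysis.

#' Starling interphase pressure offset
#'
#' `pbar = sigma (pi_m - pi_v)`: the effective osmotic contribution to the
#' transmural pressure difference across the vessel walls (Starling
#' equation), with `sigma` the Staverman reflection coefficient.
#'
#' @param sigma Staverman coefficient in `[0, 1]`.
#' @param pi_m,pi_v osmotic pressures (mPa); only the difference matters.
#' @return offset in mPa.
#' @examples
#' starling_pbar(0.88, 0, 1.02e6) # baseline: -8.976e5 mPa
#' @export
starling_pbar <- function(sigma, pi_m, pi_v) {
  if (sigma < 0 || sigma > 1) stop("sigma must lie in [0, 1]")
  sigma * (pi_m - pi_v)
}

#' Pulsatile linear subcapsular-sinus boundary pressure
#'
#' A pressure linear in `zeta = cos(theta)` whose amplitude pulses with
#' period 2 s: at `t = 0` the boundary is uniform at the midpoint
#' `(pmin + pmax)/2`; at `t = 1` s (`span_calibrated`, the default) it spans
#' exactly `[pmin, pmax]` between the poles. `as_printed` uses a
#' `zeta`-coefficient of `(1 - cos(pi t))/2` mPa (unit amplitude).
#'
#' @param zeta polar coordinate(s) in `[-1, 1]`.
#' @param t time(s) in s.
#' @param pmin,pmax minimum/maximum boundary pressure (mPa).
#' @param mode `"span_calibrated"` or `"as_printed"`.
#' @return pressure(s) in mPa.
#' @examples
#' boundary_linear_pulsatile(1, 1)  # 5.2e5 mPa
#' boundary_linear_pulsatile(-1, 1) # 4.0e5 mPa
#' @export
boundary_linear_pulsatile <- function(zeta, t, pmin = 4e5, pmax = 5.2e5,
                                      mode = c("span_calibrated",
                                               "as_printed")) {
  mode <- match.arg(mode)
  amp <- switch(mode,
    span_calibrated = (pmax - pmin) / 2,
    as_printed = 1
  )
  pmin + 0.5 * (1 - cos(pi * t)) * amp * zeta + 0.5 * (pmax - pmin)
}

#' Assemble the pulsatile boundary data of the baseline study
#'
#' @param params a `physiological_parameters` (supplies `sigma`, the osmotic
#'   difference and `pbar_v`).
#' @param pmin,pmax boundary pressure extremes (mPa).
#' @param mode passed to [boundary_linear_pulsatile()].
#' @return a `boundary_data` with period 2 s.
#' @export
baseline_boundary <- function(params, pmin = 4e5, pmax = 5.2e5,
                              mode = "span_calibrated") {
  pbar <- starling_pbar(params$sigma, 0, params$pi_v_minus_pi_m)
  boundary_data(
    pm = function(zeta, t) boundary_linear_pulsatile(zeta, t, pmin, pmax,
                                                     mode),
    pv = params$pbar_v,
    pbar = pbar,
    period = 2
  )
}

#' Baseline pulsatile perfusion run
#'
#' End-to-end solve at the baseline parameter set (Table-defaults with
#' `sigma = 0.88`, osmotic difference `1.02e6` mPa, `Lp = 5.475e-10`
#' mm s^-1 mPa^-1, `pbar_v = 6.66e5` mPa and the pulsatile linear boundary).
#' Returns the field grid plus summary scalars: the location and value of
#' the minimum interstitial pressure at each output time.
#'
#' @param params a `physiological_parameters`.
#' @param Kv_eff effective vessel conductivity (mm^3 s mg^-1).
#' @param Km_spectrum matrix `conductivity_spectrum`.
#' @param r,zeta,t evaluation grid (defaults as in [solve_node()]).
#' @param n_max Legendre truncation.
#' @param tones tone set (default `c(0, 0.5)` Hz: the pulsatile boundary is
#'   band-limited to the DC and half-Hz tones).
#' @return list with `fields` (a `field_grid`) and `summary` (data frame of
#'   per-time minima of `p_m`).
#' @export
run_baseline <- function(params, Kv_eff, Km_spectrum,
                         r = NULL, zeta = NULL, t = NULL, n_max = 16,
                         tones = c(0, 0.5)) {
  bd <- baseline_boundary(params)
  fields <- solve_node(params, Kv_eff, Km_spectrum, bd,
                       r = r, zeta = zeta, t = t,
                       n_max = n_max, tones = tones)
  summ <- do.call(rbind, lapply(seq_along(fields$t), function(m) {
    sl <- fields$p_m[, , m]
    ij <- arrayInd(which.min(sl), dim(sl))
    data.frame(
      t = fields$t[m],
      p_m_min = sl[ij],
      r_at_min = fields$r[ij[1]],
      zeta_at_min = fields$zeta[ij[2]]
    )
  }))
  list(fields = fields, summary = summ)
}

#' Parameter sweep of the baseline study
#'
#' Re-solves the baseline for each value of one parameter (`Lp`, `pbar_v`,
#' `delta_pi`, or a uniform matrix-conductivity scaling `Km_scale`) and
#' reports per-run summaries: interstitial and vessel center pressures at
#' `t = 1` s, the minimum of `p_m` and the maximum of `p_v`.
#'
#' @param parameter one of `"Lp"`, `"pbar_v"`, `"delta_pi"`, `"Km_scale"`.
#' @param values numeric vector of parameter values (finite).
#' @inheritParams run_baseline
#' @return data frame, one row per value.
#' @export
parameter_sweep <- function(parameter = c("Lp", "pbar_v", "delta_pi",
                                          "Km_scale"),
                            values, params, Kv_eff, Km_spectrum,
                            r = NULL, zeta = NULL, n_max = 16) {
  parameter <- match.arg(parameter)
  if (!length(values)) {
    return(data.frame(value = numeric(0), p_m_center = numeric(0),
                      p_v_center = numeric(0), p_m_min = numeric(0),
                      p_v_max = numeric(0)))
  }
  if (any(!is.finite(values))) stop("sweep values must be finite")
  rows <- lapply(values, function(v) {
    p <- params
    sp <- Km_spectrum
    if (parameter == "Lp") p$Lp <- v
    if (parameter == "pbar_v") p$pbar_v <- v
    if (parameter == "delta_pi") p$pi_v_minus_pi_m <- v
    if (parameter == "Km_scale") {
      sp <- conductivity_spectrum_obj(sp$omega, sp$values * v, check = FALSE)
    }
    run <- tryCatch(
      run_baseline(p, Kv_eff, sp, r = r, zeta = zeta, t = 1, n_max = n_max),
      error = function(e) stop("sweep failed at ", parameter, " = ", v, ": ",
                               conditionMessage(e))
    )
    f <- run$fields
    ic <- which.min(f$r) # innermost radius ~ node center
    data.frame(
      value = v,
      p_m_center = mean(f$p_m[ic, , 1]),
      p_v_center = mean(f$p_v[ic, , 1]),
      p_m_min = min(f$p_m[, , 1]),
      p_v_max = max(f$p_v[, , 1])
    )
  })
  do.call(rbind, rows)
}

#' Flow-inversion threshold of the mean vessel pressure
#'
#' Bisects on the vessel boundary pressure `pbar_v` for the smallest value at
#' which the transmural driving difference `p_m - p_v - pbar` is non-positive
#' at every grid point for every sampled time in one period -- i.e. fluid
#' everywhere enters the interstitium from the vessels ("inversion for every
#' t"). With `per_time = TRUE` the time-resolved criterion is also reported.
#'
#' @inheritParams run_baseline
#' @param bracket `c(lo, hi)` in mPa; the predicate must change across it.
#' @param tol bisection tolerance in mPa.
#' @param per_time also report, at the threshold, which sampled times are
#'   individually inverted at the bracketing values.
#' @return object of class `inversion_result`: `threshold_mPa`,
#'   `threshold_mmHg` (3 significant figures), bracketing diagnostics.
#' @export
flow_inversion_threshold <- function(params, Kv_eff, Km_spectrum,
                                     bracket = c(1.0e6, 2.0e6), tol = 100,
                                     r = NULL, zeta = NULL, t = NULL,
                                     n_max = 16, per_time = FALSE) {
  if (params$Lp <= 0) {
    stop("degenerate input: no interphase exchange with Lp = 0, ",
         "the inversion predicate is undefined")
  }
  max_u <- function(pv) {
    p <- params
    p$pbar_v <- pv
    run <- run_baseline(p, Kv_eff, Km_spectrum, r = r, zeta = zeta, t = t,
                        n_max = n_max)
    max(run$fields$transmural)
  }
  lo <- bracket[1]; hi <- bracket[2]
  ulo <- max_u(lo); uhi <- max_u(hi)
  if (!(ulo > 0 && uhi <= 0)) {
    stop("bracketing error: transmural difference does not change sign ",
         "on the bracket (max u = ", signif(ulo, 4), " at lo, ",
         signif(uhi, 4), " at hi)")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (max_u(mid) > 0) lo <- mid else hi <- mid
  }
  thr <- (lo + hi) / 2
  out <- list(
    threshold_mPa = thr,
    threshold_mmHg = signif(mpa_to_mmhg(thr), 3),
    bracket = bracket, tol = tol,
    max_u_below = max_u(thr - 2 * tol),
    max_u_above = max_u(thr + 2 * tol)
  )
  if (per_time) {
    p <- params; p$pbar_v <- thr
    run <- run_baseline(p, Kv_eff, Km_spectrum, r = r, zeta = zeta, t = t,
                        n_max = n_max)
    u <- run$fields$transmural
    out$inverted_per_time <- apply(u, 3, function(sl) max(sl) <= 0)
    names(out$inverted_per_time) <- signif(run$fields$t, 4)
  }
  class(out) <- "inversion_result"
  out
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf(
    "Flow-inversion threshold: %.4g mPa (= %.3g mmHg)\n",
    x$threshold_mPa, x$threshold_mmHg
  ))
  invisible(x)
}

#' Sensitivity of the interstitial pressure to the matrix conductivity
#'
#' Scales the matrix conductivity spectrum uniformly by `(1 + p)` for each
#' perturbation `p`, re-solves the baseline, and reports the relative
#' variation of the interstitial pressure in percent. The default metric is
#' the maximum over the `(r, zeta, t)` grid of `|dp_m| / |p_m|` at the
#' evaluation times `{0, 0.5, 1, 1.5, 2}` s; `metric = "mean"` averages over
#' the grid instead.
#'
#' @inheritParams run_baseline
#' @param perturbations numeric vector of relative scalings (each `> -1`).
#' @param metric `"max"` or `"mean"`.
#' @param times evaluation times (s).
#' @return data frame with columns `perturbation` and `variation_percent`.
#' @export
sensitivity_conductivity <- function(params, Kv_eff, Km_spectrum,
                                     perturbations,
                                     metric = c("max", "mean"),
                                     times = c(0, 0.5, 1, 1.5, 2),
                                     r = NULL, zeta = NULL, n_max = 16) {
  metric <- match.arg(metric)
  if (any(!is.finite(perturbations)) || any(perturbations <= -1)) {
    stop("perturbations must be finite and > -1")
  }
  base <- run_baseline(params, Kv_eff, Km_spectrum, r = r, zeta = zeta,
                       t = times, n_max = n_max)$fields
  rows <- lapply(perturbations, function(p) {
    sp <- conductivity_spectrum_obj(Km_spectrum$omega,
                                    Km_spectrum$values * (1 + p),
                                    check = FALSE)
    f <- run_baseline(params, Kv_eff, sp, r = r, zeta = zeta, t = times,
                      n_max = n_max)$fields
    rel <- abs(f$p_m - base$p_m) / pmax(abs(base$p_m), 1e-300)
    data.frame(
      perturbation = p,
      variation_percent = 100 * switch(metric, max = max(rel),
                                       mean = mean(rel))
    )
  })
  do.call(rbind, rows)
}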
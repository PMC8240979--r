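## Independent verification oracles and convergence studies.
##
## The oracles are closed-form solutions evaluated directly from special
## functions; they never call the mesh solvers, so agreement between the
## two code paths is a genuine cross-check.

#' Tolerances used by the verification suite
#'
#' Single source of truth for the numerical acceptance thresholds:
#' relative error of the mesh pressure solve against the spherical oracle
#' (`pressure_oracle`), of the steady transport solve against the
#' reaction-diffusion oracle (`rd_oracle`), budget closure
#' (`budget`), the minimal observed order of accuracy (`order_min`) and
#' the maximum-principle slack (`maxprin`, relative).
#'
#' @return Named list of tolerances.
#' @export
verification_tolerances <- function() {
  list(pressure_oracle = 0.005, rd_oracle = 0.01, budget = 0.01,
       order_min = 1.9, maxprin = 1e-6)
}

#' Spherical pressure oracle
#'
#' Closed-form radial Starling/Darcy pressure (see
#' [analytic_sphere_ifp()]) packaged as a radial function for use in
#' tests and convergence studies.
#'
#' @param R nodule radius, m.
#' @param r_n necrotic core radius, m.
#' @param tissue a [tissue_params].
#' @return A function of `r` returning pressure in Pa.
#' @export
sphere_pressure_oracle <- function(R, r_n, tissue) {
  force(R); force(r_n); force(tissue)
  function(r) analytic_sphere_ifp(R, r_n, tissue, r)
}

#' Spherical reaction-diffusion oracle
#'
#' Steady concentration in a sphere with fixed surface concentration `C0`,
#' no convection and a lumped first-order loss `k_e`:
#' `C(r) = C0 (R/r) sinh(phi r)/sinh(phi R)`, `phi = sqrt(k_e / D)`, with
#' the limit at the centre (r = 0) handled analytically.
#'
#' @param R sphere radius, m.
#' @param D diffusivity, m^2/s.
#' @param k_e lumped first-order loss rate, 1/s (>= 0).
#' @param C0 surface concentration, mol/m^3.
#' @return A function of `r` returning concentration in mol/m^3.
#' @export
sphere_reaction_diffusion_oracle <- function(R, D, k_e, C0) {
  stopifnot(k_e >= 0, D > 0, R > 0)
  phi <- sqrt(k_e / D)
  function(r) {
    if (phi == 0) return(rep(C0, length(r)))
    ifelse(r == 0,
           C0 * phi * R / sinh(phi * R),
           C0 * (R / r) * sinh(phi * r) / sinh(phi * R))
  }
}

#' Transient pure-diffusion series solution in a sphere
#'
#' Classical separation-of-variables series for diffusion into a sphere
#' with fixed surface concentration and zero initial condition:
#' `C/C0 = 1 + (2R/(pi r)) sum_n ((-1)^n / n) sin(n pi r / R)
#' exp(-D n^2 pi^2 t / R^2)`.
#'
#' @param r radii, m.
#' @param t time, s.
#' @param R sphere radius, m.
#' @param D diffusivity, m^2/s.
#' @param C0 surface concentration, mol/m^3.
#' @param nterms series terms.
#' @return Concentrations, mol/m^3.
#' @export
diffusion_sphere_series <- function(r, t, R, D, C0, nterms = 400) {
  n <- seq_len(nterms)
  sapply(r, function(ri) {
    if (ri == 0) {
      s <- sum((-1)^n * exp(-D * n^2 * pi^2 * t / R^2))
      C0 * (1 + 2 * s)
    } else {
      s <- sum(((-1)^n / n) * sin(n * pi * ri / R) *
                 exp(-D * n^2 * pi^2 * t / R^2))
      C0 * (1 + (2 * R / (pi * ri)) * s)
    }
  })
}

#' Mesh-refinement convergence study
#'
#' Re-runs a scenario at `levels` successively halved fine cell sizes and
#' reports the metric at each level, the observed order of accuracy
#' `log2((m1 - m2) / (m2 - m3))` and the Richardson extrapolation from the
#' two finest levels.  Non-monotone differences yield a warning (order
#' `NA`), not an error.
#'
#' @param s an [scenario()].
#' @param metric one of `"IFP_max"`, `"APD_LA"`, `"APD_SA"`, `"LP50_LA"`.
#' @param levels number of refinement levels (>= 3).
#' @param control base [solver_control()]; its `target_h` (or the
#'   geometry default) is the coarsest level.
#' @return A list of class `convergence_report`: `h`, `values`,
#'   `observed_order`, `extrapolated`.
#' @export
run_convergence <- function(s, metric = "IFP_max", levels = 3,
                            control = solver_control()) {
  stopifnot(levels >= 3)
  h0 <- control$target_h
  if (is.null(h0))
    h0 <- if (s$geometry$shape == "sphere") s$geometry$r_s / 1000
          else s$geometry$r_s / 400
  hs <- h0 / 2^(seq_len(levels) - 1)
  vals <- vapply(hs, function(h) {
    ctrl <- control; ctrl$target_h <- h
    fit <- run_case(s, ctrl)
    switch(metric,
      IFP_max = fit$pressure$IFP_max,
      APD_LA = fit$metrics$APD_mm[fit$metrics$axis == "LA"],
      APD_SA = fit$metrics$APD_mm[fit$metrics$axis == "SA"],
      LP50_LA = fit$metrics$LP50[fit$metrics$axis == "LA"],
      stop("unknown metric '", metric, "'"))
  }, numeric(1))
  d <- diff(vals)
  ord <- if (length(d) >= 2 && all(d[-length(d)] * d[-1] > 0))
    log2(abs(d[length(d) - 1] / d[length(d)])) else NA_real_
  if (is.na(ord)) warning("run_convergence: non-monotone refinement differences")
  extrap <- if (!is.na(ord) && abs(2^ord - 1) > 1e-8)
    vals[levels] + d[length(d)] / (2^ord - 1) else vals[levels]
  structure(list(metric = metric, h = hs, values = vals,
                 observed_order = ord, extrapolated = extrap),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("convergence_report [%s]\n", x$metric))
  print(data.frame(h = x$h, value = x$values))
  cat(sprintf("observed order %.2f; extrapolated %.6g\n",
              x$observed_order, x$extrapolated))
  invisible(x)
}
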
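## The study matrix: single-case pipeline and one-command studies.

#' Solver settings
#'
#' @param target_h characteristic fine cell size, m (`NULL`: per-geometry
#'   default, `r_s/1000` radial, `r_s/400` axisymmetric).
#' @param n_theta angular intervals of axisymmetric meshes.
#' @param dt transient time step, s.
#' @param n_profile samples per axis profile.
#' @param store_every snapshot interval in steps.
#' @param mode mesh mode passed to [build_mesh()].
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(target_h = NULL, n_theta = 48, dt = 30,
                           n_profile = 400, store_every = 10L,
                           mode = "auto") {
  structure(list(target_h = target_h, n_theta = n_theta, dt = dt,
                 n_profile = n_profile, store_every = store_every,
                 mode = mode),
            class = "solver_control")
}

#' Define a simulation scenario
#'
#' A scenario is a fully serializable description of one model run: the
#' geometry, the drug, and the parameter-study knobs (vascular
#' normalization fraction, necrotic-core toggle, intrinsic permeability
#' override, instillate concentration override, evaluation time).
#'
#' @param geometry a geometry label (`"LS"`, ..., `"ST"`) or a
#'   [geometry_spec].
#' @param drug a drug name (`"cisplatin"`, `"paclitaxel"`) or a
#'   [drug_params].
#' @param normalization vascular normalization fraction in \[0, 1\].
#' @param necrotic_core if `FALSE`, the necrotic region is treated as
#'   viable tissue (sinks and filtration active everywhere); the mesh is
#'   unchanged.
#' @param k_intrinsic optional intrinsic permeability override, m^2.
#' @param C0 optional instillate concentration override, mol/m^3.
#' @param t_end evaluation time for transient metrics, s.
#' @param bath_flat_face cropped geometries: also bathe the flat face.
#' @return An object of class `ip_scenario`.
#' @export
scenario <- function(geometry, drug = "cisplatin", normalization = 0,
                     necrotic_core = TRUE, k_intrinsic = NULL, C0 = NULL,
                     t_end = 3600, bath_flat_face = FALSE) {
  geom <- if (inherits(geometry, "geometry_spec")) geometry
          else geometry_preset(geometry)
  drg <- if (inherits(drug, "drug_params")) drug else drug_preset(drug)
  if (!is.null(C0)) drg$C0 <- C0
  tis <- baseline_tissue()
  if (normalization > 0) tis <- normalize_vasculature(tis, normalization)
  if (!is.null(k_intrinsic)) tis <- with_permeability(tis, k_intrinsic)
  structure(list(geometry = geom, drug = drg, tissue = tis,
                 normalization = normalization,
                 necrotic_core = isTRUE(necrotic_core),
                 k_intrinsic = k_intrinsic, C0 = C0, t_end = t_end,
                 bath_flat_face = isTRUE(bath_flat_face),
                 label = sprintf("%s/%s%s%s%s%s",
                   geom$label, drg$name,
                   if (normalization > 0) sprintf("/norm%.0f%%", 100 * normalization) else "",
                   if (!isTRUE(necrotic_core)) "/no-core" else "",
                   if (!is.null(k_intrinsic)) sprintf("/k=%.2g", k_intrinsic) else "",
                   if (!is.null(C0)) sprintf("/C0=%.2g", C0) else "")),
            class = "ip_scenario")
}

#' @export
print.ip_scenario <- function(x, ...) {
  cat("ip_scenario:", x$label, sprintf("(t_end = %g s)\n", x$t_end))
  invisible(x)
}

#' Run one simulation case
#'
#' The full segregated pipeline: mesh the geometry, solve the steady
#' interstitial pressure, derive the Darcy velocity, advance the drug
#' transport to `t_end` (and solve its steady form), then measure
#' IFP_max, IFV_max and the per-axis LP50 / APD / PD% / Pe metrics.
#' Deterministic given the solver settings.
#'
#' @param s an [scenario()].
#' @param control a [solver_control()].
#' @return An object of class `ip_nodule` carrying the solved fields, the
#'   metrics table and the solver diagnostics; see [summary.ip_nodule()].
#' @examples
#' \donttest{
#' fit <- run_case(scenario("SS"))
#' summary(fit)
#' }
#' @export
run_case <- function(s, control = solver_control()) {
  stopifnot(inherits(s, "ip_scenario"))
  if (!inherits(control, "solver_control")) control <- do.call(solver_control, control)
  t0 <- proc.time()[["elapsed"]]
  mesh <- build_mesh(s$geometry, target_h = control$target_h,
                     n_theta = control$n_theta, mode = control$mode)
  region <- if (s$necrotic_core) mesh$cell_region
            else rep("viable", length(mesh$cell_region))
  press <- solve_ifp(mesh, s$tissue, region = region,
                     bath_flat_face = s$bath_flat_face)
  vel <- velocity_from_pressure(press)
  t1 <- proc.time()[["elapsed"]]
  conc <- solve_transport(mesh, vel, press, s$drug, s$tissue,
                          t_end = s$t_end, dt = control$dt, region = region,
                          bath_flat_face = s$bath_flat_face,
                          store_every = control$store_every)
  steady <- steady_transport(mesh, vel, press, s$drug, s$tissue,
                             region = region,
                             bath_flat_face = s$bath_flat_face)
  t2 <- proc.time()[["elapsed"]]

  metric_rows <- function(cf, eval_time) {
    do.call(rbind, lapply(names(mesh$axes), function(axn) {
      ax <- mesh$axes[[axn]]
      pp <- extract_profile(press, axis = axn, n_samples = control$n_profile)
      cp <- extract_profile(cf, axis = axn, n_samples = control$n_profile)
      a <- apd(cp, s$drug)
      data.frame(geometry = s$geometry$label, drug = s$drug$name,
                 scenario = s$label, axis = axn,
                 half_length_mm = 1e3 * ax$half_length,
                 IFP_max_Pa = press$IFP_max, IFV_max_m_s = vel$IFV_max,
                 LP50 = lp50(pp), APD_mm = 1e3 * a,
                 PD_percent = pd_percent(a, ax),
                 Pe = global_peclet(ax, vel, s$drug),
                 eval_time_s = eval_time,
                 stringsAsFactors = FALSE)
    }))
  }
  metrics <- metric_rows(conc, conc$t_end)
  metrics_steady <- metric_rows(steady, Inf)

  structure(list(scenario = s, control = control, mesh = mesh,
                 region = region, pressure = press, velocity = vel,
                 transport = conc, steady = steady,
                 metrics = metrics, metrics_steady = metrics_steady,
                 timings = c(setup_flow = t1 - t0, transport = t2 - t1)),
            class = "ip_nodule")
}

## scenario lists of the named studies ---------------------------------------

.geometry_labels <- c("LS", "LE", "LT", "SS", "SE", "ST")

.study_scenarios <- function(name) {
  g <- .geometry_labels
  switch(name,
    baseline = lapply(g, scenario),
    drug = c(lapply(g, scenario),
             lapply(g, scenario, drug = "paclitaxel"),
             list(scenario("LS", drug = "paclitaxel", C0 = 0.14)),
             list(scenario("LS"))),
    normalization = c(lapply(g, scenario),
                      lapply(g, scenario, normalization = 0.5),
                      lapply(g, scenario, normalization = 1)),
    necrotic = c(lapply(g, scenario),
                 lapply(g, scenario, necrotic_core = FALSE)),
    permeability = {
      ks <- permeability_sweep_values()
      c(lapply(g, scenario),
        unlist(lapply(ks[c("normal_tissue", "upper")], function(k)
          lapply(g, scenario, k_intrinsic = k)), recursive = FALSE))
    },
    stop("unknown study '", name, "'; valid: baseline, drug, ",
         "normalization, necrotic, permeability"))
}

#' Run a named parameter study
#'
#' Reproduces one block of the study matrix: `baseline` (six geometries
#' with cisplatin), `drug` (cisplatin vs paclitaxel at equal C0, plus the
#' clinical-dose paclitaxel sphere at C0 = 0.14 mol/m^3), `normalization`
#' (0 / 50% / 100% vascular normalization), `necrotic` (core present vs
#' treated as viable tissue), `permeability` (intrinsic permeability
#' sweep).  Non-baseline rows carry deltas against the matched baseline
#' case (same geometry and axis), both as absolute differences and as
#' ratios.
#'
#' @param name study name.
#' @param control a [solver_control()].
#' @param baseline optionally, a previously computed baseline `ip_study`
#'   whose cases are reused instead of re-solving them.
#' @return An object of class `ip_study`: the per-case `ip_nodule` fits,
#'   the pooled `metrics` table and the `deltas` comparison table.
#' @export
run_study <- function(name = c("baseline", "drug", "normalization",
                               "necrotic", "permeability"),
                      control = solver_control(), baseline = NULL) {
  name <- match.arg(name)
  scen <- .study_scenarios(name)
  base_lab <- vapply(lapply(.geometry_labels, scenario), `[[`, "",  "label")
  cached <- list()
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "ip_study"))
    cached <- baseline$cases
  }
  cases <- lapply(scen, function(s) {
    hit <- cached[[s$label]]
    if (!is.null(hit)) hit else run_case(s, control)
  })
  names(cases) <- vapply(scen, `[[`, "", "label")
  cases <- cases[!duplicated(names(cases))]
  metrics <- do.call(rbind, lapply(cases, `[[`, "metrics"))
  rownames(metrics) <- NULL

  base_rows <- metrics[metrics$scenario %in% base_lab, ]
  key <- function(df) paste(df$geometry, df$axis)
  deltas <- metrics[!(metrics$scenario %in% base_lab), , drop = FALSE]
  if (nrow(deltas)) {
    m <- match(key(deltas), key(base_rows))
    deltas$dAPD_mm <- deltas$APD_mm - base_rows$APD_mm[m]
    deltas$dPD_percent <- deltas$PD_percent - base_rows$PD_percent[m]
    deltas$dIFP_max_Pa <- deltas$IFP_max_Pa - base_rows$IFP_max_Pa[m]
    deltas$PD_ratio <- deltas$PD_percent / base_rows$PD_percent[m]
  }
  structure(list(name = name, cases = cases, metrics = metrics,
                 deltas = deltas, control = control),
            class = "ip_study")
}

#' @export
print.ip_study <- function(x, digits = 4, ...) {
  cat(sprintf("ip_study '%s': %d cases, %d metric rows\n", x$name,
              length(x$cases), nrow(x$metrics)))
  print(x$metrics[, c("scenario", "axis", "IFP_max_Pa", "LP50", "APD_mm",
                      "PD_percent", "Pe")], digits = digits)
  invisible(x)
}

#' Aggregate a study into the size-group summary
#'
#' Averages PD% (per geometry-axis pair, equal weight) and IFP_max (per
#' geometry) over the small (SS/SE/ST) and large (LS/LE/LT) groups of the
#' baseline rows, and locates the APD extremes with their case labels.
#'
#' @param object an `ip_study`.
#' @param ... unused.
#' @return A list of class `ip_study_summary`.
#' @export
summary.ip_study <- function(object, ...) {
  m <- object$metrics
  grp <- ifelse(substr(m$geometry, 1, 1) == "S", "small", "large")
  base <- m$scenario %in% vapply(lapply(.geometry_labels, scenario), `[[`, "", "label")
  bm <- m[base, ]; bg <- grp[base]
  ifp_by_geom <- tapply(bm$IFP_max_Pa, bm$geometry, mean)
  geo_grp <- ifelse(substr(names(ifp_by_geom), 1, 1) == "S", "small", "large")
  i_min <- which.min(bm$APD_mm); i_max <- which.max(bm$APD_mm)
  out <- list(
    study = object$name,
    PD_percent_average = tapply(bm$PD_percent, bg, mean),
    IFP_max_average_Pa = tapply(ifp_by_geom, geo_grp, mean),
    APD_min = bm[i_min, c("geometry", "axis", "APD_mm")],
    APD_max = bm[i_max, c("geometry", "axis", "APD_mm")],
    deltas = object$deltas)
  class(out) <- "ip_study_summary"
  out
}

#' @export
print.ip_study_summary <- function(x, ...) {
  cat(sprintf("Study '%s' summary (baseline rows)\n", x$study))
  cat(sprintf("  PD%% average:  small %.2f%%  large %.2f%%\n",
              x$PD_percent_average[["small"]], x$PD_percent_average[["large"]]))
  cat(sprintf("  IFP_max avg:  small %.1f Pa  large %.1f Pa\n",
              x$IFP_max_average_Pa[["small"]], x$IFP_max_average_Pa[["large"]]))
  cat(sprintf("  APD min %.3g mm (%s-%s), max %.3g mm (%s-%s)\n",
              x$APD_min$APD_mm, x$APD_min$axis, x$APD_min$geometry,
              x$APD_max$APD_mm, x$APD_max$axis, x$APD_max$geometry))
  if (!is.null(x$deltas) && nrow(x$deltas))
    cat(sprintf("  max |dPD%%| vs baseline: %.3g\n", max(abs(x$deltas$dPD_percent))))
  invisible(x)
}
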
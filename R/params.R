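## Physical parameter sets, presets, unit handling and the vascular
## normalization interpolation.  All internal computation is in SI units
## (m, s, Pa, mol/m^3); unit conversion happens only at the parsing boundary.

#' Tissue (interstitium + vasculature) parameter set
#'
#' Bundles every symbol of the interstitial flow problem: Darcy conductivity
#' of the tissue, vessel-wall hydraulic conductivity, vascular
#' surface-to-volume ratio and the Starling pressures.  `K` must equal
#' `k_intrinsic / mu` (Darcy conductivity is intrinsic permeability over
#' fluid viscosity); the constructor enforces this to within 1%.
#'
#' @param K hydraulic conductivity of the tissue for interstitial fluid,
#'   m^2/(Pa s).
#' @param L_p hydraulic conductivity of the vessel wall, m/(Pa s).
#' @param S_over_V vascular surface-to-volume ratio, 1/m.
#' @param P_v vascular (microvascular) pressure, Pa.
#' @param pi_v vascular osmotic pressure, Pa.
#' @param pi_i interstitial osmotic pressure, Pa.
#' @param c_osm dimensionless osmotic reflection coefficient, in \[0, 1\].
#' @param mu interstitial fluid dynamic viscosity, Pa s.
#' @param k_intrinsic intrinsic (Darcy) permeability of the tissue, m^2.
#' @param rho interstitial fluid density, kg/m^3.  Stored for provenance;
#'   the flow model is incompressible and never uses it.
#' @return An object of class `tissue_params` (a named list).
#' @seealso [baseline_tissue()], [normalize_vasculature()],
#'   [effective_pressure()]
#' @export
tissue_params <- function(K, L_p, S_over_V, P_v, pi_v, pi_i, c_osm,
                          mu = 1.00e-3, k_intrinsic = K * mu, rho = 1000) {
  x <- list(K = K, k_intrinsic = k_intrinsic, mu = mu, L_p = L_p,
            S_over_V = S_over_V, P_v = P_v, pi_v = pi_v, pi_i = pi_i,
            c_osm = c_osm, rho = rho)
  for (f in c("K", "k_intrinsic", "mu", "L_p", "S_over_V", "P_v", "pi_v",
              "pi_i", "rho")) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("tissue_params: '", f, "' must be a single positive number")
  }
  if (!is.numeric(c_osm) || c_osm < 0 || c_osm > 1)
    stop("tissue_params: 'c_osm' must lie in [0, 1]")
  if (abs(x$K * x$mu - x$k_intrinsic) > 0.01 * x$k_intrinsic)
    stop("tissue_params: K * mu must equal k_intrinsic to within 1% ",
         "(got K*mu = ", format(x$K * x$mu), ", k = ", format(x$k_intrinsic), ")")
  structure(x, class = "tissue_params")
}

#' Drug parameter set
#'
#' @param name drug name (text).
#' @param D interstitial diffusion coefficient, m^2/s.
#' @param beta first-order cellular elimination constant, 1/s.
#' @param sigma dimensionless solute reflection coefficient of the vessel
#'   wall, in \[0, 1\].
#' @param P_c vessel-wall permeability for the drug, m/s.
#' @param IC50 half-maximal inhibitory concentration, mol/m^3.
#' @param C0 instillate (boundary) concentration, mol/m^3.
#' @param MW molecular weight, g/mol (metadata only).
#' @return An object of class `drug_params`.
#' @export
drug_params <- function(name, D, beta, sigma, P_c, IC50, C0, MW = NA_real_) {
  x <- list(name = as.character(name)[1L], D = D, beta = beta, sigma = sigma,
            P_c = P_c, IC50 = IC50, C0 = C0, MW = MW)
  if (!is.numeric(D) || D <= 0) stop("drug_params: 'D' must be positive")
  for (f in c("beta", "P_c")) {
    v <- x[[f]]
    if (!is.numeric(v) || v < 0)
      stop("drug_params: '", f, "' must be non-negative")
  }
  for (f in c("IC50", "C0")) {
    if (!is.numeric(x[[f]]) || x[[f]] <= 0)
      stop("drug_params: '", f, "' must be positive")
  }
  if (!is.numeric(sigma) || sigma < 0 || sigma > 1)
    stop("drug_params: 'sigma' must lie in [0, 1]")
  structure(x, class = "drug_params")
}

#' Parametric nodule geometry specification
#'
#' Three analytic shapes are supported.  `sphere`: radius `r_l == r_s` with a
#' concentric spherical necrotic core of radius `r_ln`.  `ellipsoid`: prolate
#' spheroid with long half-axis `r_l` (axis of rotational symmetry) and short
#' half-axis `r_s`, core a similar ellipsoid (`r_ln`, `r_sn`).  `cropped`:
#' an oblate "peritoneal" nodule obtained by cutting the ellipsoid along the
#' shorter axis, i.e. a dome with in-plane (long-axis) half-length `r_l`,
#' height `r_s` above the flat face, and a similar dome-shaped core
#' (`r_ln`, `r_sn`) sharing the flat face.
#'
#' @param shape one of `"sphere"`, `"ellipsoid"`, `"cropped"`.
#' @param r_l long-axis half-length, m.
#' @param r_s short-axis half-length (for `cropped`: the perpendicular
#'   extent, i.e. dome height), m.
#' @param r_ln,r_sn necrotic-core half-lengths along the same directions, m.
#' @param has_necrotic_core logical; when `FALSE` the core half-lengths are
#'   ignored and the whole nodule is viable tissue.
#' @param label optional case label (e.g. `"LS"`).
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(shape = c("sphere", "ellipsoid", "cropped"),
                          r_l, r_s = r_l, r_ln = 0, r_sn = r_ln,
                          has_necrotic_core = r_ln > 0, label = "") {
  shape <- match.arg(shape)
  if (!is.numeric(r_l) || r_l <= 0 || !is.numeric(r_s) || r_s <= 0)
    stop("geometry_spec: half-lengths must be positive")
  if (shape == "sphere" && abs(r_l - r_s) > 1e-12 * r_l)
    stop("geometry_spec: a sphere requires r_l == r_s")
  if (has_necrotic_core) {
    if (r_ln <= 0 || r_sn <= 0)
      stop("geometry_spec: necrotic half-lengths must be positive when a core is present")
    if (r_ln >= r_l || r_sn >= r_s)
      stop("geometry_spec: the necrotic core must lie strictly inside the nodule")
  } else {
    r_ln <- 0; r_sn <- 0
  }
  structure(list(shape = shape, r_l = r_l, r_s = r_s, r_ln = r_ln,
                 r_sn = r_sn, has_necrotic_core = has_necrotic_core,
                 label = as.character(label)),
            class = "geometry_spec")
}

## ---- presets -------------------------------------------------------------

#' Baseline tumor tissue parameters
#'
#' The literature-derived baseline set for vascularized tumor tissue:
#' K = 3.10e-14 m^2/(Pa s) (k = 3.10e-17 m^2, mu = 1e-3 Pa s),
#' L_p = 2.10e-11 m/(Pa s), S/V = 2.00e4 1/m, P_v = 2080 Pa,
#' pi_v = 2670 Pa, pi_i = 2000 Pa, c = 0.82.
#'
#' @return A [tissue_params] object.
#' @export
baseline_tissue <- function() {
  tissue_params(K = 3.10e-14, L_p = 2.10e-11, S_over_V = 2.00e4,
                P_v = 2.08e3, pi_v = 2.67e3, pi_i = 2.00e3, c_osm = 0.82,
                mu = 1.00e-3, k_intrinsic = 3.10e-17, rho = 1000)
}

#' Drug presets
#'
#' Cisplatin is the baseline drug (D = 2.5e-10 m^2/s, IC50 = 6.2e-3
#' mol/m^3).  Paclitaxel differs in diffusivity (0.77e-10 m^2/s) and IC50
#' (1.4e-6 mol/m^3); every other drug parameter keeps its baseline value.
#' Both default to the instillate concentration C0 = 0.8 mol/m^3 used for
#' the baseline study; override `C0` for clinical-dose comparisons.
#'
#' @param name `"cisplatin"` or `"paclitaxel"`.
#' @param C0 boundary concentration, mol/m^3.
#' @return A [drug_params] object.
#' @export
drug_preset <- function(name = c("cisplatin", "paclitaxel"), C0 = 0.8) {
  name <- match.arg(name)
  base <- list(beta = 7.32e-4, sigma = 8.17e-5, P_c = 1.43e-6, MW = 300)
  if (name == "cisplatin")
    drug_params("cisplatin", D = 2.5e-10, beta = base$beta, sigma = base$sigma,
                P_c = base$P_c, IC50 = 6.2e-3, C0 = C0, MW = base$MW)
  else
    drug_params("paclitaxel", D = 0.77e-10, beta = base$beta, sigma = base$sigma,
                P_c = base$P_c, IC50 = 1.4e-6, C0 = C0, MW = base$MW)
}

.geometry_table <- function() {
  ## large shapes; the small family is the same scaled down by a factor 5
  list(
    LS = list(shape = "sphere",    r_l = 0.010, r_s = 0.010, r_ln = 0.0050,  r_sn = 0.0050),
    LE = list(shape = "ellipsoid", r_l = 0.020, r_s = 0.010, r_ln = 0.0100,  r_sn = 0.0050),
    LT = list(shape = "cropped",   r_l = 0.020, r_s = 0.010, r_ln = 0.0087,  r_sn = 0.00453)
  )
}

#' Geometry presets
#'
#' Six nodule geometries: large sphere (LS, radius 10 mm, core 5 mm), large
#' ellipsoid (LE, half-axes 20/10 mm, core 10/5 mm), large cropped
#' "peritoneal" nodule (LT, in-plane half-length 20 mm, height 10 mm, core
#' 8.7/4.53 mm), and the same three scaled down by a factor 5 (SS, SE, ST).
#'
#' @param label one of `"LS"`, `"LE"`, `"LT"`, `"SS"`, `"SE"`, `"ST"`.
#' @return A [geometry_spec] object.
#' @export
geometry_preset <- function(label) {
  valid <- c("LS", "LE", "LT", "SS", "SE", "ST")
  if (!is.character(label) || length(label) != 1L || !(label %in% valid))
    stop("unknown geometry label '", paste(label, collapse = ","),
         "'; valid labels: ", paste(valid, collapse = ", "))
  size <- substr(label, 1, 1)
  fam <- .geometry_table()[[paste0("L", substr(label, 2, 2))]]
  f <- if (size == "S") 1 / 5 else 1
  geometry_spec(fam$shape, r_l = fam$r_l * f, r_s = fam$r_s * f,
                r_ln = fam$r_ln * f, r_sn = fam$r_sn * f,
                has_necrotic_core = TRUE, label = label)
}

#' Baseline case preset
#'
#' Returns the full baseline parameterization for one of the six geometry
#' labels and a drug: baseline tissue values, the drug preset, and the
#' geometry half-lengths.
#'
#' @param geometry geometry label (see [geometry_preset()]).
#' @param drug drug name (see [drug_preset()]).
#' @return A list with elements `tissue`, `drug`, `geometry`.
#' @examples
#' p <- preset_case("LS")
#' p$geometry$r_l     # 0.01 m
#' @export
preset_case <- function(geometry = "LS", drug = "cisplatin") {
  list(tissue = baseline_tissue(), drug = drug_preset(drug),
       geometry = geometry_preset(geometry))
}

## ---- units ---------------------------------------------------------------

.si_factors <- c(
  "m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6,
  "m/s" = 1, "cm/s" = 1e-2, "mm/s" = 1e-3,
  "m2" = 1, "cm2" = 1e-4, "mm2" = 1e-6,
  "m2/s" = 1, "cm2/s" = 1e-4, "mm2/s" = 1e-6,
  "pa" = 1, "kpa" = 1e3, "mmhg" = 133.322,
  "pa.s" = 1, "m2/pa.s" = 1, "m/pa.s" = 1,
  "1/s" = 1, "s-1" = 1, "1/m" = 1, "m-1" = 1,
  "mol/m3" = 1, "mmol/l" = 1, "kg/m3" = 1, "g/mol" = 1, "s" = 1
)

#' Convert a printed value with unit to SI
#'
#' The parameter tables mix cm/s with SI units; this is the single place
#' where units are interpreted.  Unrecognized or missing units are an error,
#' never a silent assumption.
#'
#' @param value numeric vector as printed.
#' @param unit unit string, e.g. `"cm/s"`.
#' @return The value(s) in the corresponding SI unit.
#' @examples
#' to_si(1.43e-4, "cm/s")   # 1.43e-6 m/s
#' @export
to_si <- function(value, unit) {
  if (missing(unit) || length(unit) != 1L || is.na(unit) || !nzchar(unit))
    stop("to_si: a unit string is required")
  key <- gsub("·", ".", tolower(unit))
  key <- gsub("\\s+", "", key)
  key <- gsub("\\^", "", key)
  key <- gsub("\\((.*)\\)", "\\1", key)   # "m/(Pa s)" -> "m/pa.s" after below
  key <- gsub("pas", "pa.s", key, fixed = TRUE)
  if (!key %in% names(.si_factors))
    stop("to_si: unrecognized unit '", unit, "'")
  value * unname(.si_factors[[key]])
}

## ---- derived quantities --------------------------------------------------

#' Effective (Starling steady-state) pressure
#'
#' The interstitial pressure at which the transvascular filtration source
#' vanishes: `P_ss = P_v - c * (pi_v - pi_i)`.  It is the least upper bound
#' of the interstitial fluid pressure for a zero-pressure surface boundary.
#'
#' @param tissue a [tissue_params] object.
#' @return Pressure in Pa.
#' @examples
#' effective_pressure(baseline_tissue())   # 1530.6 Pa
#' @export
effective_pressure <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_params"))
  tissue$P_v - tissue$c_osm * (tissue$pi_v - tissue$pi_i)
}

## endpoints of the vascular normalization interpolation (normal tissue)
.normal_vasculature <- list(L_p = 2.70e-12, S_over_V = 7.00e3, c_osm = 0.91)

#' Vascular normalization therapy interpolation
#'
#' Anti-angiogenic (normalization) therapy shifts the vascular wall
#' properties toward normal-tissue values, lowering the interstitial fluid
#' pressure.  All vascular-related properties (`L_p`, `S_over_V`, `c_osm`)
#' are interpolated linearly between the tumor baseline (`fraction = 0`) and
#' normal tissue (`fraction = 1`: L_p = 2.70e-12 m/(Pa s), S/V = 7.00e3 1/m,
#' c = 0.91); every other field is untouched.
#'
#' @param base tumor-baseline [tissue_params].
#' @param fraction degree of normalization in \[0, 1\].
#' @return A [tissue_params] object.
#' @export
normalize_vasculature <- function(base, fraction) {
  stopifnot(inherits(base, "tissue_params"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1)
    stop("normalize_vasculature: 'fraction' must lie in [0, 1]")
  lerp <- function(a, b) (1 - fraction) * a + fraction * b
  out <- unclass(base)
  out$L_p      <- lerp(base$L_p,      .normal_vasculature$L_p)
  out$S_over_V <- lerp(base$S_over_V, .normal_vasculature$S_over_V)
  out$c_osm    <- lerp(base$c_osm,    .normal_vasculature$c_osm)
  structure(out, class = "tissue_params")
}

#' Override the intrinsic tissue permeability
#'
#' Sets `k_intrinsic` and recomputes `K = k / mu` (the two are tied by the
#' definition of the Darcy conductivity).
#'
#' @param tissue a [tissue_params] object.
#' @param k intrinsic permeability, m^2.
#' @return A [tissue_params] object.
#' @export
with_permeability <- function(tissue, k) {
  stopifnot(inherits(tissue, "tissue_params"), is.numeric(k), k > 0)
  tissue$k_intrinsic <- k
  tissue$K <- k / tissue$mu
  tissue
}

#' Permeability sweep values
#'
#' The three intrinsic permeabilities of the permeability study:
#' normal tissue 6.4e-18 m^2, the commonly used tumor value 3.1e-17 m^2
#' (baseline), and 6.4e-17 m^2.
#'
#' @return Named numeric vector, m^2.
#' @export
permeability_sweep_values <- function() {
  c(normal_tissue = 6.4e-18, baseline = 3.1e-17, upper = 6.4e-17)
}

## ---- printing ------------------------------------------------------------

#' @export
print.tissue_params <- function(x, ...) {
  cat("Tissue parameters (SI units)\n")
  cat(sprintf("  K = %.3g m^2/(Pa s)  [k = %.3g m^2, mu = %.3g Pa s]\n",
              x$K, x$k_intrinsic, x$mu))
  cat(sprintf("  L_p = %.3g m/(Pa s), S/V = %.3g 1/m, c = %.3g\n",
              x$L_p, x$S_over_V, x$c_osm))
  cat(sprintf("  P_v = %.4g Pa, pi_v = %.4g Pa, pi_i = %.4g Pa  (P_ss = %.6g Pa)\n",
              x$P_v, x$pi_v, x$pi_i, effective_pressure(x)))
  invisible(x)
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("Drug '%s': D = %.3g m^2/s, beta = %.3g 1/s, sigma = %.3g,\n",
              x$name, x$D, x$beta, x$sigma))
  cat(sprintf("  P_c = %.3g m/s, IC50 = %.3g mol/m^3, C0 = %.3g mol/m^3\n",
              x$P_c, x$IC50, x$C0))
  invisible(x)
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat(sprintf("Geometry %s (%s): r_l = %g mm, r_s = %g mm", x$label, x$shape,
              1e3 * x$r_l, 1e3 * x$r_s))
  if (x$has_necrotic_core)
    cat(sprintf("; necrotic core %g/%g mm", 1e3 * x$r_ln, 1e3 * x$r_sn))
  cat("\n")
  invisible(x)
}

## ---- configuration files -------------------------------------------------

#' Read a case configuration file
#'
#' Structured YAML configuration naming a geometry label (or explicit
#' half-lengths), a drug name (or explicit drug parameters), tissue
#' overrides, the normalization fraction, the necrotic-core toggle and
#' solver settings.  See `system.file("extdata", "config-schema.md",
#' package = "ipchemo")` for every key, unit and default, and
#' `system.file("extdata", "example-case.yaml", package = "ipchemo")` for a
#' complete example.
#'
#' @param path path to a YAML file.
#' @return A list with elements `scenario` (an [scenario()] object) and
#'   `control` (a [solver_control()] object).
#' @export
read_case_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geo <- cfg$geometry
  if (is.null(geo)) stop("config: a 'geometry' block or label is required")
  s <- scenario(
    geometry = if (is.character(geo)) geo else geometry_spec(
      shape = geo$shape, r_l = geo$r_l, r_s = geo$r_s,
      r_ln = if (is.null(geo$r_ln)) 0 else geo$r_ln,
      r_sn = if (is.null(geo$r_sn)) 0 else geo$r_sn,
      has_necrotic_core = isTRUE(geo$has_necrotic_core) ||
        (!is.null(geo$r_ln) && geo$r_ln > 0),
      label = if (is.null(geo$label)) "custom" else geo$label),
    drug = if (is.null(cfg$drug)) "cisplatin" else if (is.character(cfg$drug))
      cfg$drug else do.call(drug_params, cfg$drug),
    normalization = if (is.null(cfg$normalization)) 0 else cfg$normalization,
    necrotic_core = if (is.null(cfg$necrotic_core)) TRUE else isTRUE(cfg$necrotic_core),
    k_intrinsic = cfg$k_intrinsic,
    C0 = cfg$C0,
    t_end = if (is.null(cfg$t_end)) 3600 else cfg$t_end,
    bath_flat_face = isTRUE(cfg$bath_flat_face))
  if (!is.null(cfg$tissue)) {
    tis <- unclass(s$tissue)
    for (nm in names(cfg$tissue)) {
      if (!nm %in% names(tis)) stop("config: unknown tissue field '", nm, "'")
      tis[[nm]] <- cfg$tissue[[nm]]
    }
    s$tissue <- do.call(tissue_params, tis[setdiff(names(tis), character())])
  }
  ctrl <- do.call(solver_control,
                  if (is.null(cfg$solver)) list() else cfg$solver)
  list(scenario = s, control = ctrl)
}
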
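## Analyzed variables: axis profiles and the scalar metrics derived from
## them.
##
## IFP_max / IFV_max  -- maximal interstitial fluid pressure / velocity.
## LP50               -- normalized distance from the centre at which the
##                       pressure first falls to 50% of its maximum; the
##                       steeper the profile, the higher LP50.
## APD                -- absolute penetration depth: depth from the outer
##                       surface to the innermost point where C >= IC50.
## PD%                -- APD as a percentage of the axis half-length.
## Pe                 -- global Peclet number L * IFV_max / D.

#' Extract a field profile along a nodule axis
#'
#' Samples a solved field at evenly spaced positions from the centre to the
#' surface along one of the geometry axes, interpolating linearly from the
#' discrete solution (the mesh places nodes exactly on the axes).
#'
#' @param field a `pressure_field`, `concentration_field`, or a numeric
#'   vector of nodal values on the same mesh.
#' @param mesh the mesh (only needed when `field` is a bare numeric
#'   vector).
#' @param axis `"LA"` or `"SA"`.
#' @param n_samples number of samples (>= 100).
#' @return An object of class `axis_profile`: positions `pos` (m, strictly
#'   increasing, ending at the half-length), normalized positions `npos`
#'   and `values`.
#' @export
extract_profile <- function(field, axis = "LA", n_samples = 400, mesh = NULL) {
  if (inherits(field, "pressure_field")) {
    mesh <- field$mesh; values <- field$P; what <- "pressure_Pa"
  } else if (inherits(field, "concentration_field")) {
    mesh <- field$mesh; values <- field$C; what <- "concentration_mol_m3"
  } else {
    stopifnot(inherits(mesh, "nodule_mesh"), is.numeric(field))
    values <- field; what <- "value"
  }
  if (n_samples < 100) stop("extract_profile: n_samples must be >= 100")
  ax <- mesh$axes[[axis]]
  if (is.null(ax))
    stop("extract_profile: mesh has no axis '", axis, "' (available: ",
         paste(names(mesh$axes), collapse = ", "), ")")
  ord <- order(ax$pos)
  pos <- ax$pos[ord]; val <- values[ax$node_idx][ord]
  out_pos <- seq(0, ax$half_length, length.out = n_samples)
  out_val <- stats::approx(pos, val, xout = out_pos, rule = 2)$y
  structure(list(axis = ax$name, half_length = ax$half_length,
                 pos = out_pos, npos = out_pos / ax$half_length,
                 values = out_val, what = what),
            class = "axis_profile")
}

#' LP50: normalized half-maximum distance of a pressure profile
#'
#' The normalized distance from the centre (fraction of the axis
#' half-length) at which the pressure first drops below 50% of the profile
#' maximum, moving outward, with linear interpolation between samples.
#'
#' @param p an `axis_profile` of pressure.
#' @return Dimensionless LP50 in \[0, 1\].
#' @export
lp50 <- function(p) {
  stopifnot(inherits(p, "axis_profile"))
  m <- max(p$values)
  if (m <= 0) stop("lp50: pressure profile never exceeds 0")
  half <- 0.5 * m
  below <- which(p$values < half)
  if (length(below) == 0L) return(1)
  k <- below[1]
  if (k == 1L) return(0)
  x1 <- p$npos[k - 1L]; x2 <- p$npos[k]
  y1 <- p$values[k - 1L]; y2 <- p$values[k]
  x1 + (half - y1) * (x2 - x1) / (y2 - y1)
}

#' APD: absolute penetration depth
#'
#' The depth, measured inward from the outer surface, to the innermost
#' position where the drug concentration reaches the drug's IC50.  Zero
#' when even the surface stays below IC50; the full half-length when the
#' whole axis is above it.  If the profile crosses IC50 more than once
#' (possible only through numerical oscillation in the supported
#' configurations), the innermost crossing is used and a warning is
#' emitted.
#'
#' @param p an `axis_profile` of concentration.
#' @param drug a [drug_params] (its `IC50` is the threshold).
#' @return Penetration depth in m.
#' @export
apd <- function(p, drug) {
  stopifnot(inherits(p, "axis_profile"), inherits(drug, "drug_params"))
  ok <- p$values >= drug$IC50
  if (!any(ok)) return(0)
  if (all(ok)) return(p$half_length)
  k <- which(ok)[1]
  if (!all(ok[k:length(ok)]))
    warning("apd: profile crosses IC50 more than once; using the innermost crossing")
  if (k == 1L) return(p$half_length)
  x1 <- p$pos[k - 1L]; x2 <- p$pos[k]
  y1 <- p$values[k - 1L]; y2 <- p$values[k]
  x_cross <- x1 + (drug$IC50 - y1) * (x2 - x1) / (y2 - y1)
  p$half_length - x_cross
}

#' PD%: relative penetration depth
#'
#' @param apd_value penetration depth, m (see [apd()]).
#' @param axis an axis list with a `half_length` field, or the half-length
#'   itself (m).
#' @return Percentage of the axis half-length penetrated.
#' @export
pd_percent <- function(apd_value, axis) {
  L <- if (is.list(axis)) axis$half_length else axis
  stopifnot(is.numeric(L), L > 0, apd_value <= L * (1 + 1e-9))
  100 * apd_value / L
}

#' Global Peclet number
#'
#' `Pe = L u / D` with `L` the half-length of the axis of interest and `u`
#' the maximal interstitial fluid velocity magnitude.  Pe > 1 means the
#' outward convective transport dominates the inward diffusion of drug.
#'
#' @param axis an axis list (or half-length in m).
#' @param vel a `velocity_field`.
#' @param drug a [drug_params].
#' @return Dimensionless Peclet number.
#' @export
global_peclet <- function(axis, vel, drug) {
  L <- if (is.list(axis)) axis$half_length else axis
  if (drug$D <= 0) stop("global_peclet: D must be positive")
  L * vel$IFV_max / drug$D
}

#' @export
print.axis_profile <- function(x, ...) {
  cat(sprintf("axis_profile [%s, %s]: %d samples over %.3g mm, range [%.4g, %.4g]\n",
              x$axis, x$what, length(x$pos), 1e3 * x$half_length,
              min(x$values), max(x$values)))
  invisible(x)
}
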
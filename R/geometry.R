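## Nodule discretizations.
##
## Spheres are solved on a 1-D radial grid (vertex-centred finite volumes);
## ellipsoid and cropped nodules on a 2-D axisymmetric triangulation of the
## meridional quarter cross-section (piecewise-linear finite elements with
## the cylindrical r-weight).  Both discretizations are interface-fitted:
## the necrotic/viable interface coincides with mesh faces, so property
## jumps are never smeared across cells.
##
## Coordinate convention: nodule centre at the origin.  For the ellipsoid
## the axis of rotational symmetry (z) is the long axis; for the cropped
## nodule z is perpendicular to the flat face, which lies in z = 0, and the
## long axis is the in-plane radial direction.  With a zero-flux flat face
## (the default; the face rests on the peritoneum), the cropped dome is the
## upper half of an oblate spheroid and z = 0 acts as a symmetry plane.

## geometric half-axes in meridional (r, z) coordinates and axis metadata
.mesh_layout <- function(spec) {
  switch(spec$shape,
    sphere = list(A_r = spec$r_l, A_z = spec$r_l,
                  B_r = spec$r_ln, B_z = spec$r_ln,
                  axes = list(LA = "row"), sym_factor = 2),
    ellipsoid = list(A_r = spec$r_s, A_z = spec$r_l,
                     B_r = spec$r_sn, B_z = spec$r_ln,
                     axes = list(LA = "col", SA = "row"), sym_factor = 2),
    cropped = list(A_r = spec$r_l, A_z = spec$r_s,
                   B_r = spec$r_ln, B_z = spec$r_sn,
                   axes = list(LA = "row", SA = "col"), sym_factor = 1))
}

## geometric step sequence from h0 growing by `ratio` up to hmax
.geom_steps <- function(h0, hmax, ratio) {
  h <- h0; out <- numeric(0)
  while (h < hmax) { out <- c(out, h); h <- h * ratio }
  out
}

## points in [0, 1] with spacing ~h0 at 0 and ~h1 at 1, coarsening to hmax
## in the middle; spacings are rescaled so the points fit [0, 1] exactly
.graded01 <- function(h0, h1, hmax, ratio = 1.2) {
  if (h0 >= 0.5 && h1 >= 0.5) return(c(0, 1))
  left <- .geom_steps(min(h0, hmax), hmax, ratio)
  right <- .geom_steps(min(h1, hmax), hmax, ratio)
  mid <- 1 - sum(left) - sum(right)
  n_mid <- max(0L, ceiling(mid / hmax))
  steps <- c(left, rep(if (n_mid > 0) mid / n_mid else hmax, n_mid), rev(right))
  if (mid < 0) steps <- c(left, rev(right))   # overlap: just rescale
  pos <- c(0, cumsum(steps))
  pos / pos[length(pos)]
}

#' Build a computational mesh for a nodule geometry
#'
#' Sphere specifications return a 1-D radial mesh; ellipsoid and cropped
#' specifications an axisymmetric 2-D triangulation (a full-3D discretization
#' is deliberately not provided: all supported shapes are exactly
#' axisymmetric).  `target_h` is the characteristic cell size near the outer
#' surface and the necrotic interface, where the pressure and concentration
#' boundary layers live; cells coarsen geometrically away from both.
#'
#' @param spec a [geometry_spec].
#' @param target_h characteristic fine cell size, m.  Default `r_s / 400`
#'   for 2-D meshes and `r_s / 1000` (uniform) for radial meshes.
#' @param n_theta number of angular intervals of the quarter cross-section
#'   (2-D meshes only).
#' @param mode `"auto"` (radial for spheres, axisymmetric otherwise) or an
#'   explicit `"radial_1d"` / `"axisymmetric_2d"`; the latter also accepts
#'   sphere specs, which is used as a cross-backend check.
#' @return An object of class `nodule_mesh`.
#' @export
build_mesh <- function(spec, target_h = NULL, n_theta = 48,
                       mode = c("auto", "radial_1d", "axisymmetric_2d")) {
  stopifnot(inherits(spec, "geometry_spec"))
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (spec$shape == "sphere") "radial_1d" else "axisymmetric_2d"
  if (mode == "radial_1d" && spec$shape != "sphere")
    stop("radial_1d meshes are only available for spheres")
  if (is.null(target_h))
    target_h <- if (mode == "radial_1d") spec$r_s / 1000 else spec$r_s / 400
  h_lim <- if (spec$has_necrotic_core)
    min(spec$r_sn, spec$r_s - spec$r_sn) / 4 else spec$r_s / 10
  if (target_h >= h_lim)
    stop(sprintf(paste0("build_mesh: target_h = %.3g m is too coarse to ",
                        "resolve both zones; use target_h < %.3g m"),
                 target_h, h_lim))
  if (mode == "radial_1d") .radial_mesh(spec, target_h)
  else .axisym_mesh(spec, target_h, n_theta)
}

.radial_mesh <- function(spec, target_h) {
  R <- spec$r_l
  n <- max(20L, ceiling(R / target_h))
  r <- seq(0, R, length.out = n + 1L)
  if (spec$has_necrotic_core) {
    ## snap the nearest interior node onto the interface
    i <- which.min(abs(r - spec$r_ln))
    i <- min(max(i, 2L), n)    # never move an end point
    r[i] <- spec$r_ln
  }
  cell_mid <- (r[-1] + r[-length(r)]) / 2
  region <- if (spec$has_necrotic_core)
    ifelse(cell_mid <= spec$r_ln, "necrotic", "viable")
  else rep("viable", length(cell_mid))
  axes <- list(LA = list(name = "LA", node_idx = seq_along(r), pos = r,
                         half_length = R))
  structure(list(mode = "radial_1d", spec = spec, target_h = target_h,
                 r = r, n_nodes = length(r), cell_region = region,
                 axes = axes, sym_factor = 2,
                 outer_nodes = length(r), h = diff(r)),
            class = "nodule_mesh")
}

.axisym_mesh <- function(spec, target_h, n_theta) {
  lay <- .mesh_layout(spec)
  A_r <- lay$A_r; A_z <- lay$A_z; B_r <- lay$B_r; B_z <- lay$B_z
  has_core <- spec$has_necrotic_core

  ## radial (rho) levels in [0, 1]; interface fitted at rho = 0.5
  if (has_core) {
    hc <- target_h / max(B_r, B_z)
    s_core <- 0.5 * .graded01(h0 = 0.1, h1 = hc, hmax = 0.1)
    hv <- target_h / max(A_r - B_r, A_z - B_z)
    s_via <- 0.5 + 0.5 * .graded01(h0 = hv, h1 = hv, hmax = 10 * hv)
    s_lv <- c(s_core, s_via[-1])
    iface_level <- length(s_core) - 1L       # ring index of the interface
  } else {
    hv <- target_h / max(A_r, A_z)
    s_lv <- .graded01(h0 = 0.08, h1 = hv, hmax = 10 * hv)
    iface_level <- 0L
  }
  n_s <- length(s_lv) - 1L                   # number of rings
  theta <- seq(0, pi / 2, length.out = n_theta + 1L)

  ## node coordinates; node 1 is the centre, then ring-major ordering
  idx <- function(i, j) 1L + (i - 1L) * (n_theta + 1L) + j + 1L
  ct <- cos(theta); st <- sin(theta)
  n_nodes <- 1L + n_s * (n_theta + 1L)
  nodes <- matrix(0, n_nodes, 2L)
  for (i in seq_len(n_s)) {
    s <- s_lv[i + 1L]
    if (has_core && s <= 0.5 + 1e-12) {
      f <- s / 0.5
      rr <- f * B_r * ct; zz <- f * B_z * st
    } else if (has_core) {
      f <- (s - 0.5) / 0.5
      rr <- B_r * ct + f * (A_r - B_r) * ct
      zz <- B_z * st + f * (A_z - B_z) * st
    } else {
      rr <- s * A_r * ct; zz <- s * A_z * st
    }
    nodes[idx(i, 0:n_theta), ] <- cbind(rr, zz)
  }

  ## triangles: centre fan + split quads
  tri <- matrix(0L, 2L * n_s * n_theta - n_theta, 3L)
  ring <- integer(nrow(tri))
  k <- 0L
  for (j in seq_len(n_theta) - 1L) {          # fan, ring 1
    k <- k + 1L
    tri[k, ] <- c(1L, idx(1L, j), idx(1L, j + 1L)); ring[k] <- 1L
  }
  for (i in seq_len(n_s - 1L)) for (j in seq_len(n_theta) - 1L) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    tri[k + 1L, ] <- c(a, b, c2)
    tri[k + 2L, ] <- c(a, c2, d)
    ring[k + 1L] <- ring[k + 2L] <- i + 1L
    k <- k + 2L
  }
  region <- if (has_core) ifelse(ring <= iface_level, "necrotic", "viable")
            else rep("viable", nrow(tri))

  ## signed areas (must all be positive for a valid mapping)
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  if (any(area <= 0)) stop("axisym mesh: degenerate mapping (non-positive cell area)")
  r_c <- (x1 + x2 + x3) / 3

  outer_nodes <- idx(n_s, 0:n_theta)
  row_nodes <- c(1L, idx(seq_len(n_s), 0L))        # theta = 0 (z = 0 plane)
  col_nodes <- c(1L, idx(seq_len(n_s), n_theta))   # theta = pi/2 (r = 0 axis)
  mk_axis <- function(name, which) {
    if (which == "row")
      list(name = name, node_idx = row_nodes, pos = nodes[row_nodes, 1],
           half_length = A_r)
    else
      list(name = name, node_idx = col_nodes, pos = nodes[col_nodes, 2],
           half_length = A_z)
  }
  axes <- lapply(names(lay$axes), function(nm) mk_axis(nm, lay$axes[[nm]]))
  names(axes) <- names(lay$axes)

  structure(list(mode = "axisymmetric_2d", spec = spec, target_h = target_h,
                 nodes = nodes, tri = tri, area = area, r_c = r_c,
                 cell_region = region, n_nodes = n_nodes,
                 outer_nodes = outer_nodes,
                 flat_face_nodes = if (spec$shape == "cropped")
                   setdiff(row_nodes, outer_nodes) else integer(0),
                 axes = axes, sym_factor = lay$sym_factor,
                 n_s = n_s, n_theta = n_theta),
            class = "nodule_mesh")
}

#' Region membership of a point
#'
#' @param point for spheres, a radius (single number) or meridional
#'   coordinates `c(r, z)`; for 2-D shapes, meridional coordinates
#'   `c(r, z)` with `r` the distance from the symmetry axis.
#' @param spec a [geometry_spec].
#' @return `"necrotic"` or `"viable"`; points outside the nodule are an
#'   error.
#' @export
region_of <- function(point, spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (length(point) == 1L) point <- c(abs(point), 0)
  r <- abs(point[1]); z <- point[2]
  lay <- .mesh_layout(spec)
  if (spec$shape != "cropped") z <- abs(z)
  if (spec$shape == "cropped" && z < -1e-12 * spec$r_s)
    stop("region_of: point lies outside the nodule (below the flat face)")
  q_out <- (r / lay$A_r)^2 + (z / lay$A_z)^2
  if (q_out > 1 + 1e-9) stop("region_of: point lies outside the nodule")
  if (!spec$has_necrotic_core) return("viable")
  q_in <- (r / lay$B_r)^2 + (z / lay$B_z)^2
  if (q_in <= 1 + 1e-12) "necrotic" else "viable"
}

#' Nodule axes
#'
#' The axes along which the pressure and concentration profiles are
#' analyzed: a single radial axis for spheres; long (LA) and short (SA)
#' axes for ellipsoid and cropped shapes.  Positions are reported as
#' distance from the nodule centre.
#'
#' @param spec a [geometry_spec].
#' @return A named list of axes, each a list with `name` and `half_length`
#'   (m).
#' @export
axes_of <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (spec$shape == "sphere")
    return(list(LA = list(name = "LA", half_length = spec$r_l)))
  list(LA = list(name = "LA", half_length = spec$r_l),
       SA = list(name = "SA", half_length = spec$r_s))
}

## cell measures: the volume represented by each cell after symmetry
## expansion (4*pi*r^2 dr shells in 1-D; 2*pi*r_c*area per triangle in 2-D,
## doubled when the meridional quarter represents half of a mirrored shape)
.cell_volumes <- function(mesh) {
  if (mesh$mode == "radial_1d") {
    r <- mesh$r
    (4 * pi / 3) * diff(r^3)
  } else {
    mesh$sym_factor * 2 * pi * mesh$r_c * mesh$area
  }
}

#' Total mesh volume after symmetry expansion
#' @param mesh a `nodule_mesh`.
#' @return Volume in m^3.
#' @export
mesh_volume <- function(mesh) sum(.cell_volumes(mesh))

#' Analytic volume of a geometry specification
#' @param spec a [geometry_spec].
#' @param core if `TRUE`, the necrotic-core volume instead.
#' @return Volume in m^3.
#' @export
analytic_volume <- function(spec, core = FALSE) {
  a <- if (core) spec$r_ln else spec$r_l
  b <- if (core) spec$r_sn else spec$r_s
  switch(spec$shape,
    sphere = 4 / 3 * pi * a^3,
    ellipsoid = 4 / 3 * pi * a * b^2,
    cropped = 2 / 3 * pi * a^2 * b)
}

#' Necrotic volume fraction of a mesh
#' @param mesh a `nodule_mesh`.
#' @return Fraction of the nodule volume tagged necrotic.
#' @export
necrotic_fraction <- function(mesh) {
  v <- .cell_volumes(mesh)
  sum(v[mesh$cell_region == "necrotic"]) / sum(v)
}

#' @export
print.nodule_mesh <- function(x, ...) {
  cat(sprintf("nodule_mesh [%s] for %s: %d nodes", x$mode,
              if (nzchar(x$spec$label)) x$spec$label else x$spec$shape,
              x$n_nodes))
  if (x$mode == "axisymmetric_2d")
    cat(sprintf(", %d triangles (%d rings x %d sectors)", nrow(x$tri),
                x$n_s, x$n_theta))
  cat(sprintf("; target_h = %.3g m; necrotic fraction %.1f%%\n",
              x$target_h, 100 * necrotic_fraction(x)))
  invisible(x)
}
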
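## Steady interstitial fluid pressure (IFP).
##
## Continuity + Darcy with a Starling transvascular source and no
## lymphatics:
##     div(u) = F_v,   u = -K grad(P_i)
##     F_v    = 0                                   (necrotic core)
##     F_v    = L_p (S/V) (P_v - P_i - c (pi_v - pi_i))   (viable tissue)
## i.e. the elliptic problem -div(K grad P) + a P = a P_ss in the viable
## zone (a = L_p S/V, P_ss the Starling effective pressure) and Laplace's
## equation in the core, with P fixed on the outer surface and natural
## zero-flux conditions on symmetry facets.  The source is linear in P, so
## one sparse direct solve suffices; the algebraic residual drop is
## recorded and must reach 4 orders of magnitude.

#' Starling transvascular fluid source
#'
#' Volumetric fluid gain from the microvasculature per unit tissue volume.
#' Zero in the necrotic core (no functional vasculature); in viable tissue
#' `L_p (S/V) (P_v - P_i - c (pi_v - pi_i))`.  Lymphatic drainage is
#' identically zero (solid tumors lack functional lymphatics).
#'
#' @param P_i interstitial fluid pressure, Pa (vectorized).
#' @param tissue a [tissue_params].
#' @param region `"necrotic"` or `"viable"` (recycled against `P_i`).
#' @return Fluid gain F_v, 1/s.
#' @examples
#' starling_source(0, baseline_tissue(), "viable")   # 6.43e-4 1/s
#' @export
starling_source <- function(P_i, tissue, region) {
  stopifnot(inherits(tissue, "tissue_params"))
  P_ss <- effective_pressure(tissue)
  a <- tissue$L_p * tissue$S_over_V
  ifelse(region == "necrotic", 0, a * (P_ss - P_i))
}

## assemble the linear system for the 1-D radial finite-volume scheme;
## returns (A, b) without boundary conditions applied plus bookkeeping
.radial_ifp_system <- function(mesh, tissue, region) {
  r <- mesh$r; n <- length(r)
  dr <- diff(r)
  face_r <- (r[-1] + r[-n]) / 2                       # interior faces
  K <- tissue$K
  Tr <- K * face_r^2 / dr                             # transmissibilities
  ## control-volume moments, split at the node into left/right half-cells
  cv_lo <- c(0, face_r); cv_hi <- c(face_r, r[n])
  m3 <- function(a, b) (b^3 - a^3) / 3                # int r^2 dr
  v_left  <- c(0, m3(face_r, r[-1]))                  # part in cell i-1
  v_right <- c(m3(r[-n], face_r), 0)                  # part in cell i
  a_coef <- ifelse(region == "viable", tissue$L_p * tissue$S_over_V, 0)
  a_node <- c(0, a_coef) * v_left + c(a_coef, 0) * v_right
  P_ss <- effective_pressure(tissue)

  ## diffusion: node i couples to i+1 with Tr[i]
  diag_diff <- numeric(n)
  diag_diff[seq_len(n - 1L)] <- diag_diff[seq_len(n - 1L)] + Tr
  diag_diff[2:n] <- diag_diff[2:n] + Tr
  A <- Matrix::sparseMatrix(
    i = c(seq_len(n), seq_len(n - 1L), 2:n),
    j = c(seq_len(n), 2:n, seq_len(n - 1L)),
    x = c(a_node + diag_diff, -Tr, -Tr), dims = c(n, n))
  b <- a_node * P_ss
  list(A = A, b = b, cv_vol = 4 * pi * (v_left + v_right))
}

## assemble stiffness + reaction for the axisymmetric P1 FEM;
## one-point (centroid) quadrature with the cylindrical r-weight and a
## lumped reaction matrix
.axisym_gradients <- function(mesh) {
  tri <- mesh$tri; nd <- mesh$nodes
  x1 <- nd[tri[, 1], 1]; y1 <- nd[tri[, 1], 2]
  x2 <- nd[tri[, 2], 1]; y2 <- nd[tri[, 2], 2]
  x3 <- nd[tri[, 3], 1]; y3 <- nd[tri[, 3], 2]
  A2 <- 2 * mesh$area
  list(bx = cbind((y2 - y3) / A2, (y3 - y1) / A2, (y1 - y2) / A2),
       by = cbind((x3 - x2) / A2, (x1 - x3) / A2, (x2 - x1) / A2))
}

.axisym_stiffness <- function(mesh, coef) {
  g <- .axisym_gradients(mesh)
  w <- coef * mesh$area * mesh$r_c           # cylindrical weight (2*pi dropped)
  tri <- mesh$tri
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- tri[, a]; jj[[k]] <- tri[, b]
    xx[[k]] <- w * (g$bx[, a] * g$bx[, b] + g$by[, a] * g$by[, b])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(mesh$n_nodes, mesh$n_nodes))
}

## lumped (diagonal) mass with per-cell coefficient
.axisym_lumped_mass <- function(mesh, coef) {
  w <- coef * mesh$area * mesh$r_c / 3
  m <- numeric(mesh$n_nodes)
  for (a in 1:3) {
    s <- tapply(w, mesh$tri[, a], sum)
    m[as.integer(names(s))] <- m[as.integer(names(s))] + as.numeric(s)
  }
  m
}

## advection matrix for cellwise-constant velocity u (nt x 2):
## row i gets area*r_c/3 * (u . grad phi_j)
.axisym_advection <- function(mesh, u) {
  g <- .axisym_gradients(mesh)
  w <- mesh$area * mesh$r_c / 3
  tri <- mesh$tri
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- tri[, a]; jj[[k]] <- tri[, b]
    xx[[k]] <- w * (u[, 1] * g$bx[, b] + u[, 2] * g$by[, b])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(mesh$n_nodes, mesh$n_nodes))
}

## row equilibration: the assembled systems mix O(1) Dirichlet rows with
## O(1e-20) flux rows, which trips sparse-LU condition estimates; scaling
## every row by its diagonal is exact and fixes the conditioning
.row_scale <- function(A, b) {
  d <- abs(Matrix::diag(A))
  d[d <= 0] <- 1
  list(A = Matrix::Diagonal(x = 1 / d) %*% A, b = b / d, d = d)
}

## impose Dirichlet rows: A[d, ] = I, b[d] = value
.apply_dirichlet <- function(A, b, idx, value) {
  if (length(idx) == 0L) stop("singular system: no Dirichlet boundary facet")
  A[idx, ] <- 0
  A[cbind(idx, idx)] <- 1
  b[idx] <- value
  list(A = A, b = b)
}

#' Solve the steady interstitial-fluid-pressure problem
#'
#' @param mesh a [build_mesh()] mesh.
#' @param tissue a [tissue_params].
#' @param boundary_pressure pressure imposed on the outer surface, Pa
#'   (default 0: the 0-20 Pa instillate pressure range has negligible
#'   influence compared to the ~1.5 kPa interstitial values).
#' @param region optional per-cell region override (e.g. all `"viable"` to
#'   emulate the omission of the necrotic core without re-meshing).
#' @param bath_flat_face cropped shapes only: if `TRUE` the flat face also
#'   receives the Dirichlet pressure; default `FALSE` (zero flux; the face
#'   rests on the peritoneum).
#' @return An object of class `pressure_field`: nodal pressures `P` (Pa),
#'   `IFP_max`, the residual history and a `converged` flag.
#' @export
solve_ifp <- function(mesh, tissue, boundary_pressure = 0, region = NULL,
                      bath_flat_face = FALSE) {
  stopifnot(inherits(mesh, "nodule_mesh"), inherits(tissue, "tissue_params"))
  if (is.null(region)) region <- mesh$cell_region
  dir_idx <- mesh$outer_nodes
  if (bath_flat_face && length(mesh$flat_face_nodes))
    dir_idx <- sort(unique(c(dir_idx, mesh$flat_face_nodes)))

  if (mesh$mode == "radial_1d") {
    sys <- .radial_ifp_system(mesh, tissue, region)
    A0 <- sys$A; b0 <- sys$b
  } else {
    a_coef <- ifelse(region == "viable", tissue$L_p * tissue$S_over_V, 0)
    S <- .axisym_stiffness(mesh, tissue$K)
    m_a <- .axisym_lumped_mass(mesh, a_coef)
    A0 <- S + Matrix::Diagonal(mesh$n_nodes, m_a)
    b0 <- m_a * effective_pressure(tissue)
  }
  bc <- .apply_dirichlet(A0, b0, dir_idx, boundary_pressure)
  sc <- .row_scale(bc$A, bc$b)
  res0 <- sqrt(sum(sc$b^2))
  P <- as.numeric(Matrix::solve(sc$A, sc$b))
  res1 <- sqrt(sum((sc$b - as.numeric(sc$A %*% P))^2))
  drop <- if (res0 > 0) res1 / res0 else 0
  if (!is.finite(drop) || drop > 1e-4)
    stop("solve_ifp did not converge: residual drop ", format(drop),
         " (history: ", format(res0), " -> ", format(res1), ")")
  structure(list(P = P, mesh = mesh, tissue = tissue, region = region,
                 IFP_max = max(P), boundary_pressure = boundary_pressure,
                 dirichlet = dir_idx, A_raw = A0, b_raw = b0,
                 residuals = c(res0, res1), converged = TRUE),
            class = "pressure_field")
}

#' Darcy velocity from a pressure field
#'
#' `u = -K grad(P_i)` evaluated by the discretization's gradient: two-point
#' face gradients on radial meshes, cellwise-constant P1 gradients on
#' axisymmetric meshes.
#'
#' @param p a `pressure_field` from [solve_ifp()].
#' @param tissue a [tissue_params]; defaults to the one used in the solve.
#' @return An object of class `velocity_field` with the velocity samples
#'   and `IFV_max`, the maximal interstitial fluid velocity magnitude (m/s).
#' @export
velocity_from_pressure <- function(p, tissue = p$tissue) {
  stopifnot(inherits(p, "pressure_field"))
  mesh <- p$mesh
  if (mesh$mode == "radial_1d") {
    u_face <- -tissue$K * diff(p$P) / diff(mesh$r)
    u_node <- c(0, (u_face[-1] + u_face[-length(u_face)]) / 2,
                u_face[length(u_face)])
    out <- list(u_face = u_face, u_node = u_node,
                IFV_max = max(abs(u_face)))
  } else {
    g <- .axisym_gradients(mesh)
    tri <- mesh$tri
    Px <- p$P[tri[, 1]] * g$bx[, 1] + p$P[tri[, 2]] * g$bx[, 2] +
      p$P[tri[, 3]] * g$bx[, 3]
    Pz <- p$P[tri[, 1]] * g$by[, 1] + p$P[tri[, 2]] * g$by[, 2] +
      p$P[tri[, 3]] * g$by[, 3]
    u <- cbind(-tissue$K * Px, -tissue$K * Pz)
    out <- list(u_cell = u, IFV_max = max(sqrt(rowSums(u^2))))
  }
  structure(c(out, list(mesh = mesh, mode = mesh$mode)),
            class = "velocity_field")
}

#' Closed-form spherical pressure solution
#'
#' Exact solution of the radial Starling/Darcy problem on a sphere of
#' radius `R` with a concentric necrotic core of radius `r_n`: constant
#' pressure in the core (zero source, zero flux at the interface), and in
#' the viable shell
#' `P = P_ss + (A sinh(alpha r) + B cosh(alpha r)) / r` with
#' `alpha = sqrt(L_p (S/V) / K)`, `P(R) = 0` and `P'(r_n) = 0`.  For
#' `r_n = 0` this reduces to
#' `P(r) = P_ss (1 - (R/r) sinh(alpha r)/sinh(alpha R))`.
#'
#' Used as the independent verification oracle for the mesh solvers.
#'
#' @param R nodule radius, m.
#' @param r_n necrotic-core radius, m (0 for no core).
#' @param tissue a [tissue_params].
#' @param r radii at which to evaluate, m (in `[0, R]`).
#' @return Pressure(s), Pa.
#' @export
analytic_sphere_ifp <- function(R, r_n, tissue, r) {
  stopifnot(inherits(tissue, "tissue_params"), R > 0, r_n >= 0, r_n < R)
  if (any(r < 0 | r > R * (1 + 1e-12)))
    stop("analytic_sphere_ifp: r outside [0, R]")
  P_ss <- effective_pressure(tissue)
  alpha <- sqrt(tissue$L_p * tissue$S_over_V / tissue$K)
  if (r_n == 0) {
    P <- ifelse(r == 0,
                P_ss * (1 - alpha * R / sinh(alpha * R)),
                P_ss * (1 - (R / r) * sinh(alpha * r) / sinh(alpha * R)))
    return(P)
  }
  ## shifted basis P = P_ss + (A sinh(a(r - r_n)) + B cosh(a(r - r_n))) / r:
  ## the zero-flux condition at r_n gives B = alpha r_n A directly, which
  ## stays well conditioned at large alpha R (the sinh/cosh basis at r = 0
  ## is numerically singular there)
  L <- alpha * (R - r_n)
  A <- -P_ss * R / (sinh(L) + alpha * r_n * cosh(L))
  B <- alpha * r_n * A
  P_core <- P_ss + alpha * A
  shell <- function(x) {
    s <- alpha * (x - r_n)
    P_ss + (A * sinh(s) + B * cosh(s)) / x
  }
  ifelse(r <= r_n, P_core, shell(pmin(r, R)))
}

#' Global fluid balance of a pressure solve
#'
#' Steady incompressibility requires the transvascular source integrated
#' over the nodule to equal the Darcy outflow through the outer surface.
#' Both sides are evaluated from the discrete solution: the source by
#' quadrature of F_v, the outflow as the discrete flux residual on the
#' Dirichlet boundary.
#'
#' @param p a `pressure_field`.
#' @return A list with `source_m3_s`, `outflow_m3_s` and `rel_imbalance`.
#' @export
fluid_budget <- function(p) {
  stopifnot(inherits(p, "pressure_field"))
  mesh <- p$mesh
  ## discrete boundary flux: residual of the unconstrained system on the
  ## Dirichlet rows (variationally consistent flux).  The radial system is
  ## written per steradian (r^2 dr measure), the axisymmetric one with the
  ## 2*pi weight dropped; rescale both to the full expanded nodule.
  resid <- as.numeric(p$A_raw %*% p$P) - p$b_raw
  sym <- if (mesh$mode == "radial_1d") 4 * pi else mesh$sym_factor * 2 * pi
  outflow <- -sym * sum(resid[p$dirichlet])
  ## source by independent midpoint-rule quadrature over cells
  if (mesh$mode == "radial_1d") {
    r <- mesh$r
    P_mid <- (p$P[-1] + p$P[-length(p$P)]) / 2
    r_mid <- (r[-1] + r[-length(r)]) / 2
    Fv <- starling_source(P_mid, p$tissue, p$region)
    source <- sum(Fv * 4 * pi * r_mid^2 * diff(r))
  } else {
    tri <- mesh$tri
    P_c <- (p$P[tri[, 1]] + p$P[tri[, 2]] + p$P[tri[, 3]]) / 3
    Fv <- starling_source(P_c, p$tissue, p$region)
    source <- sum(Fv * mesh$sym_factor * 2 * pi * mesh$r_c * mesh$area)
  }
  list(source_m3_s = source, outflow_m3_s = outflow,
       rel_imbalance = abs(source - outflow) / max(abs(source), 1e-300))
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("pressure_field: IFP_max = %.2f Pa on %d nodes (residual drop %.1e)\n",
              x$IFP_max, length(x$P), x$residuals[2] / max(x$residuals[1], 1e-300)))
  invisible(x)
}
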
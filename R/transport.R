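## Interstitial drug transport.
##
## Mass conservation of the free interstitial drug on the frozen Darcy
## velocity field:
##     dC/dt = D lap(C) - div(u C) - S_cell - S_bl
## with first-order cellular elimination S_cell = beta C and vascular
## resorption S_bl = P_c (S/V) C Pe_v / (exp(Pe_v) - 1) in the viable zone
## (vascular drug concentration taken as negligible over the 30-60 min
## procedure), both zero in the necrotic core.  Since div(u) = F_v != 0,
## the full divergence form div(uC) = u.grad(C) + C F_v is used.  The
## boundary concentration is held at the instillate value C0; the interior
## starts drug-free.  Time stepping is implicit Euler (unconditionally
## stable); the system matrix is constant, so it is factorized once.

#' The Peclet flux factor x / (exp(x) - 1)
#'
#' Evaluated via `expm1` with a series branch near zero (limit 1).
#'
#' @param x transvascular Peclet number(s).
#' @return The factor, in (0, Inf).
#' @export
peclet_factor <- function(x) {
  out <- ifelse(abs(x) < 1e-6, 1 - x / 2 + x^2 / 12, x / expm1(x))
  out[x == 0] <- 1
  out
}

#' Transvascular Peclet number
#'
#' Ratio of convective to diffusive drug transport across the microvessel
#' wall: `Pe_v = F_v (1 - sigma) / (P_c S/V)`.
#'
#' @param F_v transvascular fluid gain, 1/s (vectorized).
#' @param drug a [drug_params].
#' @param tissue a [tissue_params].
#' @return Dimensionless Peclet number(s).
#' @export
vascular_peclet <- function(F_v, drug, tissue) {
  denom <- drug$P_c * tissue$S_over_V
  if (denom == 0) stop("vascular_peclet: P_c * S/V must be positive")
  F_v * (1 - drug$sigma) / denom
}

#' Vascular resorption sink
#'
#' Loss rate of interstitial drug to the microvasculature,
#' `P_c (S/V) C_i Pe_v / (exp(Pe_v) - 1)`, zero in the necrotic core.
#'
#' @param C_i interstitial drug concentration, mol/m^3.
#' @param Pe_v transvascular Peclet number (see [vascular_peclet()]).
#' @param drug a [drug_params].
#' @param tissue a [tissue_params].
#' @param region `"necrotic"` or `"viable"`.
#' @return Sink rate, mol/(m^3 s) (a positive number is a loss).
#' @export
vascular_sink <- function(C_i, Pe_v, drug, tissue, region) {
  ifelse(region == "necrotic", 0,
         drug$P_c * tissue$S_over_V * C_i * peclet_factor(Pe_v))
}

#' Cellular uptake sink
#'
#' First-order elimination `beta * C` in viable tissue; zero in the
#' necrotic core, where no viable cells take up drug.
#'
#' @param C interstitial drug concentration, mol/m^3.
#' @param drug a [drug_params].
#' @param region `"necrotic"` or `"viable"`.
#' @return Sink rate, mol/(m^3 s).
#' @export
cellular_sink <- function(C, drug, region) {
  ifelse(region == "necrotic", 0, drug$beta * C)
}

## per-cell sink coefficients given cell pressures
.sink_coefficients <- function(P_cell, tissue, drug, region) {
  Fv <- starling_source(P_cell, tissue, region)
  if (drug$P_c * tissue$S_over_V == 0) {
    ## impermeable vessel wall: no transvascular drug exchange at all
    z <- rep(0, length(Fv))
    return(list(F_v = Fv, Pe_v = z, k_bl = z,
                k_cell = ifelse(region == "necrotic", 0, drug$beta)))
  }
  Pe_v <- vascular_peclet(Fv, drug, tissue)
  k_bl <- ifelse(region == "necrotic", 0,
                 drug$P_c * tissue$S_over_V * peclet_factor(Pe_v))
  k_cell <- ifelse(region == "necrotic", 0, drug$beta)
  list(F_v = Fv, Pe_v = Pe_v, k_bl = k_bl, k_cell = k_cell)
}

## ---- discrete operators --------------------------------------------------

## 1-D radial conservative finite volumes.  Faces carry the diffusive and
## (central-weighted) advective fluxes; the conservative divergence of u*C
## absorbs the C*F_v term exactly because the discrete velocity satisfies
## the same continuity equation.
.radial_transport_operator <- function(mesh, vel, press, drug, tissue, region) {
  r <- mesh$r; n <- length(r)
  dr <- diff(r)
  face_r <- (r[-1] + r[-n]) / 2
  u_f <- vel$u_face
  Td <- drug$D * face_r^2 / dr                 # diffusive transmissibility
  Ta <- face_r^2 * u_f                         # advective face velocity
  ## face flux F_i = Ta_i * (C_i + C_{i+1})/2 - Td_i * (C_{i+1} - C_i)
  ## row i accumulates +(F_i - F_{i-1})
  diag_v <- numeric(n)
  diag_v[seq_len(n - 1L)] <- diag_v[seq_len(n - 1L)] + (Td + Ta / 2)
  diag_v[2:n] <- diag_v[2:n] + (Td - Ta / 2)
  A_flux <- Matrix::sparseMatrix(
    i = c(seq_len(n), seq_len(n - 1L), 2:n),
    j = c(seq_len(n), 2:n, seq_len(n - 1L)),
    x = c(diag_v, Ta / 2 - Td, -(Ta / 2 + Td)), dims = c(n, n))

  ## sinks per half-cell, lumped at nodes (k_bl + k_cell; F_v handled by
  ## the conservative advection)
  P_mid <- (press$P[-1] + press$P[-n]) / 2
  sc <- .sink_coefficients(P_mid, tissue, drug, region)
  k_cell_rate <- sc$k_bl + sc$k_cell
  m3 <- function(a, b) (b^3 - a^3) / 3
  v_left  <- c(0, m3(face_r, r[-1]))
  v_right <- c(m3(r[-n], face_r), 0)
  k_node <- c(0, k_cell_rate) * v_left + c(k_cell_rate, 0) * v_right
  vol <- v_left + v_right
  list(A = A_flux + Matrix::Diagonal(n, k_node), M = vol,
       sink_diag = k_node, measure = 4 * pi,
       peclet_cell = max(abs(u_f) * dr / drug$D))
}

## 2-D axisymmetric P1 operator in non-divergence form:
## u.grad(C) + (F_v + beta + k_bl) C - D lap(C)
.axisym_transport_operator <- function(mesh, vel, press, drug, tissue, region) {
  tri <- mesh$tri
  P_c <- (press$P[tri[, 1]] + press$P[tri[, 2]] + press$P[tri[, 3]]) / 3
  sc <- .sink_coefficients(P_c, tissue, drug, region)
  S <- .axisym_stiffness(mesh, drug$D)
  Adv <- .axisym_advection(mesh, vel$u_cell)
  m_react <- .axisym_lumped_mass(mesh, sc$F_v + sc$k_bl + sc$k_cell)
  m_sink <- .axisym_lumped_mass(mesh, sc$k_bl + sc$k_cell)
  M <- .axisym_lumped_mass(mesh, rep(1, nrow(tri)))
  edge_len <- function(a, b) sqrt(rowSums((mesh$nodes[tri[, a], , drop = FALSE] -
                                           mesh$nodes[tri[, b], , drop = FALSE])^2))
  h_cell <- pmax(edge_len(1, 2), edge_len(2, 3), edge_len(1, 3))
  u_mag <- sqrt(rowSums(vel$u_cell^2))
  list(A = S + Adv + Matrix::Diagonal(mesh$n_nodes, m_react), M = M,
       sink_diag = m_sink, measure = mesh$sym_factor * 2 * pi,
       peclet_cell = max(u_mag * h_cell / drug$D))
}

.transport_operator <- function(mesh, vel, press, drug, tissue, region) {
  op <- if (mesh$mode == "radial_1d")
    .radial_transport_operator(mesh, vel, press, drug, tissue, region)
  else
    .axisym_transport_operator(mesh, vel, press, drug, tissue, region)
  if (op$peclet_cell > 2)
    stop(sprintf(paste0("cell Peclet number %.2f exceeds 2: the unstabilized ",
                        "central scheme needs a finer mesh (reduce target_h)"),
         op$peclet_cell))
  op
}

#' Solve the transient drug-transport problem
#'
#' Advances the interstitial drug concentration from a drug-free initial
#' state with the instillate concentration `C0` held on the outer surface,
#' on the frozen pressure/velocity fields, by implicit Euler steps of `dt`.
#'
#' @param mesh a [build_mesh()] mesh.
#' @param vel a `velocity_field` from [velocity_from_pressure()].
#' @param press the `pressure_field` the velocity came from.
#' @param drug a [drug_params].
#' @param tissue a [tissue_params].
#' @param t_end end time, s (default 3600, the upper end of the 30-60 min
#'   instillation window).
#' @param dt time step, s (default 30).
#' @param region optional per-cell region override.
#' @param C0 boundary concentration, mol/m^3 (default `drug$C0`).
#' @param bath_flat_face cropped shapes: bathe the flat face too (default
#'   `FALSE`).
#' @param store_every store every k-th step in addition to the final state.
#' @return An object of class `concentration_field` with the final nodal
#'   concentrations `C`, stored `snapshots` (one column per stored time)
#'   and the `times` vector.
#' @export
solve_transport <- function(mesh, vel, press, drug, tissue,
                            t_end = 3600, dt = 30, region = NULL,
                            C0 = drug$C0, bath_flat_face = FALSE,
                            store_every = 10L) {
  stopifnot(inherits(mesh, "nodule_mesh"), inherits(drug, "drug_params"))
  if (is.null(region)) region <- mesh$cell_region
  dir_idx <- mesh$outer_nodes
  if (bath_flat_face && length(mesh$flat_face_nodes))
    dir_idx <- sort(unique(c(dir_idx, mesh$flat_face_nodes)))
  op <- .transport_operator(mesh, vel, press, drug, tissue, region)

  n <- length(op$M)
  nsteps <- max(1L, ceiling(t_end / dt - 1e-9))
  A_sys <- Matrix::Diagonal(n, op$M / dt) + op$A
  b0 <- numeric(n)
  bc <- .apply_dirichlet(A_sys, b0, dir_idx, C0)
  sc <- .row_scale(bc$A, bc$b)
  lu <- Matrix::lu(sc$A)

  C <- numeric(n)
  keep <- unique(c(seq(store_every, nsteps, by = store_every), nsteps))
  snapshots <- matrix(NA_real_, n, length(keep))
  times <- keep * dt
  C_prev <- C
  for (s in seq_len(nsteps)) {
    rhs <- op$M / dt * C
    rhs[dir_idx] <- C0
    C_prev <- C
    C <- as.numeric(Matrix::solve(lu, rhs / sc$d))
    if (min(C) < -1e-6 * C0)
      stop("solve_transport: negative concentrations beyond tolerance (",
           format(min(C)), "); the scheme was violated")
    if (s %in% keep) snapshots[, match(s, keep)] <- C
  }
  structure(list(C = C, snapshots = snapshots, times = times, dt = dt,
                 t_end = nsteps * dt, mesh = mesh, drug = drug,
                 tissue = tissue, region = region, C0 = C0,
                 dirichlet = dir_idx, op = op, C_prev = C_prev,
                 steady = FALSE),
            class = "concentration_field")
}

#' Solve the steady drug-transport problem
#'
#' The time-independent balance of diffusion, convection and the two sinks;
#' with the loss rates of the baseline parameterization the transient
#' solution is quasi-steady well before 30 min, so this agrees with
#' [solve_transport()] at large `t_end` to well under 1%.
#'
#' @inheritParams solve_transport
#' @return A `concentration_field` with `steady = TRUE` and a single
#'   stored state.
#' @export
steady_transport <- function(mesh, vel, press, drug, tissue, region = NULL,
                             C0 = drug$C0, bath_flat_face = FALSE) {
  if (is.null(region)) region <- mesh$cell_region
  dir_idx <- mesh$outer_nodes
  if (bath_flat_face && length(mesh$flat_face_nodes))
    dir_idx <- sort(unique(c(dir_idx, mesh$flat_face_nodes)))
  op <- .transport_operator(mesh, vel, press, drug, tissue, region)
  bc <- .apply_dirichlet(op$A, numeric(length(op$M)), dir_idx, C0)
  sc <- .row_scale(bc$A, bc$b)
  C <- as.numeric(Matrix::solve(sc$A, sc$b))
  structure(list(C = C, snapshots = matrix(C, ncol = 1), times = Inf,
                 dt = NA_real_, t_end = Inf, mesh = mesh, drug = drug,
                 tissue = tissue, region = region, C0 = C0,
                 dirichlet = dir_idx, op = op, steady = TRUE),
            class = "concentration_field")
}

#' Discrete mass budget of the last transport step
#'
#' Balances the stored-mass change against the boundary (diffusive +
#' advective) influx and the integrated sinks, all evaluated from the
#' discrete operators; the imbalance is relative to the largest term.
#'
#' @param cf a transient `concentration_field`.
#' @return A list with `dM_dt`, `boundary_influx`, `sink_total`
#'   (mol/s) and `rel_imbalance`.
#' @export
mass_budget <- function(cf) {
  stopifnot(inherits(cf, "concentration_field"), !cf$steady)
  op <- cf$op
  meas <- op$measure
  dMdt <- meas * sum(op$M * (cf$C - cf$C_prev)) / cf$dt
  resid <- as.numeric(op$A %*% cf$C) + op$M / cf$dt * (cf$C - cf$C_prev)
  influx <- -meas * sum(resid[cf$dirichlet])
  sinks <- meas * sum(op$sink_diag * cf$C)
  ## advective boundary outflow and F_v dilution are inside op$A; report
  ## closure of dM/dt = influx - sinks - (those terms), i.e. the residual
  scale <- max(abs(influx), abs(sinks), abs(dMdt), 1e-300)
  list(dM_dt = dMdt, boundary_influx = influx, sink_total = sinks,
       rel_imbalance = abs(sum(resid[-cf$dirichlet])) * meas / scale)
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("concentration_field (%s): %d nodes, C in [%.3g, %.3g] mol/m^3",
              if (x$steady) "steady" else sprintf("t = %g s", x$t_end),
              length(x$C), min(x$C), max(x$C)))
  cat("\n")
  invisible(x)
}
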
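test_that("the Starling source vanishes in the core and at P_ss", {
  t <- baseline_tissue()
  expect_equal(starling_source(123, t, "necrotic"), 0)
  expect_equal(starling_source(effective_pressure(t), t, "viable"), 0)
  expect_equal(starling_source(0, t, "viable"),
               2.1e-11 * 2.0e4 * 1530.6)     # 6.43e-4 1/s
  ## linear in P
  expect_equal(starling_source(765.3, t, "viable"),
               starling_source(0, t, "viable") / 2)
})

test_that("the closed-form spherical pressure behaves as required", {
  t <- baseline_tissue()
  expect_equal(analytic_sphere_ifp(0.01, 0, t, 0.01), 0)
  ## no-core centre limit: P_ss (1 - aR/sinh(aR)) ~ P_ss at aR ~ 37
  a <- sqrt(t$L_p * t$S_over_V / t$K)
  expect_equal(analytic_sphere_ifp(0.01, 0, t, 1e-9),
               1530.6 * (1 - a * 0.01 / sinh(a * 0.01)), tolerance = 1e-6)
  ## monotone decreasing
  r <- seq(0, 0.01, length.out = 50)
  expect_true(all(diff(analytic_sphere_ifp(0.01, 0.005, t, r)) < 1e-9))
  ## zero-flux core flattens the profile: core pressure with r_n > 0 is
  ## >= the centre pressure without a core at equal R (small sphere where
  ## the difference is visible)
  expect_gte(analytic_sphere_ifp(0.002, 0, t, 0) + 1e-9,
             0)  # sanity
  expect_lt(analytic_sphere_ifp(0.002, 0.001, t, 0),
            analytic_sphere_ifp(0.002, 0, t, 0))
  expect_error(analytic_sphere_ifp(0.01, 0, t, 0.02), "outside")
})

test_that("the mesh pressure solve matches the spherical oracle", {
  tol <- verification_tolerances()
  t <- baseline_tissue()
  ## with core (baseline SS) and without (no-core variant), at 20 radii
  for (rn in c(0.001, 0)) {
    spec <- geometry_spec("sphere", r_l = 0.002, r_ln = rn,
                          has_necrotic_core = rn > 0, label = "SSx")
    m <- build_mesh(spec)
    p <- solve_ifp(m, t)
    rr <- seq(0, 0.002, length.out = 20)
    pex <- analytic_sphere_ifp(0.002, rn, t, rr)
    pnum <- stats::approx(m$r, p$P, xout = rr)$y
    expect_lt(max(abs(pnum - pex)) / max(pex), tol$pressure_oracle)
  }
})

test_that("pressure fields satisfy bounds, boundary values and residual drop", {
  t <- baseline_tissue()
  P_ss <- effective_pressure(t)
  for (lab in c("LS", "LE", "ST")) {
    fit <- cached_case(lab, scenario(lab))
    p <- fit$pressure
    expect_true(p$converged)
    expect_lt(p$residuals[2], 1e-4 * p$residuals[1])
    expect_gte(min(p$P), -1e-9 * P_ss)
    expect_lte(max(p$P), P_ss * (1 + 1e-9))
    expect_equal(max(abs(p$P[p$mesh$outer_nodes])), 0, tolerance = 1e-9)
  }
})

test_that("a dead vasculature yields the trivial pressure field", {
  t0 <- avascular_tissue()
  m <- build_mesh(geometry_preset("SS"))
  p <- solve_ifp(m, t0)
  expect_lt(max(abs(p$P)), 1e-6)
  v <- velocity_from_pressure(p)
  expect_lt(v$IFV_max, 1e-20)
})

test_that("velocity is the Darcy gradient and points outward at the surface", {
  t <- baseline_tissue()
  fit <- cached_case("LS", scenario("LS"))
  v <- fit$velocity
  ## linear ramp check: u = K * slope
  m <- fit$mesh
  slope <- 1e5
  pf <- fit$pressure
  pf$P <- slope * (m$r[length(m$r)] - m$r)
  vr <- velocity_from_pressure(pf, t)
  expect_equal(vr$u_face, rep(t$K * slope, length(vr$u_face)),
               tolerance = 1e-12)
  ## outward at the outer surface (pressure decreases outward)
  expect_gt(v$u_face[length(v$u_face)], 0)
  ## ~0 at the centre by symmetry
  expect_equal(v$u_node[1], 0)
  ## uniform pressure: u identically 0
  pf$P <- rep(7, length(pf$P))
  expect_equal(velocity_from_pressure(pf, t)$IFV_max, 0)
})

test_that("fluid gained from the vasculature leaves through the surface", {
  tol <- verification_tolerances()
  for (lab in c("LS", "LE")) {
    fit <- cached_case(lab, scenario(lab))
    fb <- fluid_budget(fit$pressure)
    expect_lt(fb$rel_imbalance, tol$budget)
    expect_gt(fb$outflow_m3_s, 0)
  }
  ## 1-D: surface outflow also equals 4 pi R^2 u(R) from the velocity field
  fit <- cached_case("LS", scenario("LS"))
  m <- fit$mesh; v <- fit$velocity
  uR <- v$u_face[length(v$u_face)]
  fb <- fluid_budget(fit$pressure)
  expect_equal(4 * pi * 0.01^2 * uR, fb$outflow_m3_s, tolerance = 0.01)
})

test_that("smaller nodules never exceed their large counterpart's IFP_max", {
  st <- cached_study("baseline")
  m <- st$metrics
  ifp <- tapply(m$IFP_max_Pa, m$geometry, max)
  for (fam in c("S", "E", "T"))
    expect_lte(ifp[[paste0("S", fam)]], ifp[[paste0("L", fam)]] + 1e-6)
})

test_that("the radial scheme converges at second order to the oracle", {
  tol <- verification_tolerances()
  t <- baseline_tissue()
  spec <- geometry_preset("SS")
  hs <- 0.002 / c(250, 500, 1000)
  errs <- vapply(hs, function(h) {
    m <- build_mesh(spec, target_h = h)
    p <- solve_ifp(m, t)
    rr <- seq(0, 0.002, length.out = 40)
    max(abs(stats::approx(m$r, p$P, xout = rr)$y -
              analytic_sphere_ifp(0.002, 0.001, t, rr)))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_gte(mean(orders), tol$order_min)
})
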
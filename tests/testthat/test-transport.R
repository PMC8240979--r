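test_that("the transvascular Peclet number and flux factor are exact", {
  t <- baseline_tissue()
  cis <- drug_preset("cisplatin")
  expect_equal(vascular_peclet(0, cis, t), 0)
  pe <- vascular_peclet(6.43e-4, cis, t)
  expect_equal(pe, 6.43e-4 * (1 - 8.17e-5) / (1.43e-6 * 2.0e4))
  expect_equal(pe, 0.0225, tolerance = 2e-3)
  ## doubling P_c halves Pe_v
  cis2 <- cis; cis2$P_c <- 2 * cis$P_c
  expect_equal(vascular_peclet(6.43e-4, cis2, t), pe / 2)
  ## x/(e^x - 1): exact limits and series branch
  expect_equal(peclet_factor(0), 1)
  expect_equal(peclet_factor(1e-9), 1 - 5e-10, tolerance = 1e-12)
  expect_equal(peclet_factor(1), 1 / (exp(1) - 1))
})

test_that("sink closures match hand-computed rates and vanish in the core", {
  t <- baseline_tissue()
  cis <- drug_preset("cisplatin")
  expect_equal(vascular_sink(0, 0.0225, cis, t, "viable"), 0)
  expect_equal(vascular_sink(0.8, 0, cis, t, "viable"),
               1.43e-6 * 2e4 * 0.8)               # Pe_v -> 0 limit
  s <- vascular_sink(0.8, 0.0225, cis, t, "viable")
  expect_equal(s, 1.43e-6 * 2e4 * 0.8 * 0.0225 / expm1(0.0225))
  expect_equal(s, 2.26e-2, tolerance = 2e-3)
  expect_equal(vascular_sink(0.8, 0.0225, cis, t, "necrotic"), 0)
  expect_equal(cellular_sink(0.8, cis, "viable"), 7.32e-4 * 0.8)
  expect_equal(cellular_sink(0.8, cis, "necrotic"), 0)
  expect_equal(cellular_sink(0, cis, "viable"), 0)
})

test_that("pure diffusion into a sphere matches the series solution", {
  g <- geometry_spec("sphere", r_l = 0.01, has_necrotic_core = FALSE)
  m <- build_mesh(g)
  t0 <- avascular_tissue()
  d0 <- drug_params("tracer", D = 2.5e-10, beta = 0, sigma = 0, P_c = 0,
                    IC50 = 1e-3, C0 = 0.8)
  p <- solve_ifp(m, t0)
  v <- velocity_from_pressure(p)
  cf <- solve_transport(m, v, p, d0, t0, t_end = 600, dt = 2)
  rr <- seq(0.004, 0.0099, length.out = 12)
  ser <- diffusion_sphere_series(rr, 600, 0.01, 2.5e-10, 0.8)
  num <- stats::approx(m$r, cf$C, xout = rr)$y
  expect_lt(max(abs(num - ser)) / 0.8, 0.01)
})

test_that("steady reaction-diffusion matches the sinh oracle", {
  tol <- verification_tolerances()
  g <- geometry_spec("sphere", r_l = 0.01, has_necrotic_core = FALSE)
  m <- build_mesh(g)
  t0 <- avascular_tissue()        # u = 0; vascular sink still active
  cis <- drug_preset("cisplatin")
  p <- solve_ifp(m, t0)
  v <- velocity_from_pressure(p)
  cs <- steady_transport(m, v, p, cis, t0)
  k_e <- cis$beta + cis$P_c * t0$S_over_V       # Pe_v = 0 at F_v = 0
  oracle <- sphere_reaction_diffusion_oracle(0.01, cis$D, k_e, 0.8)
  rr <- seq(0.0085, 0.01, length.out = 30)
  num <- stats::approx(m$r, cs$C, xout = rr)$y
  expect_lt(max(abs(num - oracle(rr)) / oracle(rr)), tol$rd_oracle)
})

test_that("concentrations respect the maximum principle and grow in time", {
  tol <- verification_tolerances()
  for (lab in c("LS", "LE", "ST")) {
    fit <- cached_case(lab, scenario(lab))
    sn <- fit$transport$snapshots
    C0 <- fit$transport$C0
    expect_gte(min(sn), -tol$maxprin * C0)
    expect_lte(max(sn), C0 * (1 + tol$maxprin))
    ## monotone approach to steady state at every node
    expect_true(all(apply(sn, 1, function(x) all(diff(x) > -tol$maxprin * C0))))
    ## interior strictly below C0 once sinks act
    expect_lt(max(fit$transport$C[-fit$transport$dirichlet]), C0)
  }
})

test_that("transient and steady solutions agree after many loss timescales", {
  fit <- cached_case("LS", scenario("LS"))
  ## loss rate ~ 2.9e-2 1/s: 3600 s is ~100 e-foldings
  expect_lt(max(abs(fit$transport$C - fit$steady$C)) / fit$transport$C0,
            0.01)
  ## and the per-axis metrics coincide
  expect_equal(fit$metrics$APD_mm, fit$metrics_steady$APD_mm,
               tolerance = 1e-3)
})

test_that("the discrete mass budget closes", {
  tol <- verification_tolerances()
  for (lab in c("LS", "SE")) {
    fit <- cached_case(lab, scenario(lab))
    mb <- mass_budget(fit$transport)
    expect_lt(mb$rel_imbalance, tol$budget)
    ## the stored mass is essentially stationary once quasi-steady
    expect_gt(mb$sink_total, 0)
    expect_lt(abs(mb$dM_dt), 0.01 * mb$sink_total)
  }
})

test_that("removing the vascular sink deepens the steady penetration", {
  g <- geometry_preset("SS")
  m <- build_mesh(g)
  t <- baseline_tissue()
  cis <- drug_preset("cisplatin")
  p <- solve_ifp(m, t); v <- velocity_from_pressure(p)
  full <- steady_transport(m, v, p, cis, t)
  no_bl <- cis; no_bl$P_c <- 0
  open <- steady_transport(m, v, p, no_bl, t)
  apd_full <- apd(extract_profile(full, "LA"), cis)
  apd_open <- apd(extract_profile(open, "LA"), cis)
  ## P_c S/V (~2.9e-2 1/s) dominates beta (7.3e-4 1/s)
  expect_gt(cis$P_c * t$S_over_V, cis$beta)
  expect_gt(apd_open, apd_full)
})

test_that("a diffusion-dominated drug floods the nodule", {
  g <- geometry_preset("SS")
  m <- build_mesh(g)
  t <- baseline_tissue()
  fast <- drug_params("fast", D = 1e-5, beta = 7.32e-4, sigma = 8.17e-5,
                      P_c = 1.43e-6, IC50 = 6.2e-3, C0 = 0.8)
  p <- solve_ifp(m, t); v <- velocity_from_pressure(p)
  cs <- steady_transport(m, v, p, fast, t)
  expect_gt(min(cs$C), 0.99 * 0.8)
})
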
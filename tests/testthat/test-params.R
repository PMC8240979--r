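test_that("baseline presets reproduce the printed parameter tables", {
  t <- baseline_tissue()
  expect_equal(t$K, 3.10e-14)
  expect_equal(t$k_intrinsic, 3.10e-17)
  expect_equal(t$L_p, 2.10e-11)
  expect_equal(t$S_over_V, 2.00e4)
  expect_equal(t$c_osm, 0.82)
  expect_lt(abs(t$K * t$mu - t$k_intrinsic), 0.01 * t$k_intrinsic)

  cis <- drug_preset("cisplatin")
  pac <- drug_preset("paclitaxel")
  expect_equal(cis$D, 2.5e-10)
  expect_equal(pac$D, 0.77e-10)
  expect_equal(cis$IC50, 6.2e-3)
  expect_equal(pac$IC50, 1.4e-6)
  expect_equal(cis$P_c, 1.43e-6)        # 1.43e-4 cm/s in SI
  ## every non-listed drug parameter keeps its baseline value
  for (f in c("beta", "sigma", "P_c", "C0"))
    expect_identical(cis[[f]], pac[[f]])
})

test_that("geometry presets match the stated shapes and the 1/5 scaling", {
  ls <- geometry_preset("LS")
  expect_equal(c(ls$r_l, ls$r_ln), c(0.01, 0.005))
  expect_identical(ls$shape, "sphere")
  ss <- geometry_preset("SS")
  expect_equal(c(ss$r_l, ss$r_ln), c(0.002, 0.001))
  lt <- geometry_preset("LT")
  expect_identical(lt$shape, "cropped")
  expect_equal(c(lt$r_l, lt$r_s, lt$r_ln, lt$r_sn),
               c(0.02, 0.01, 0.0087, 0.00453))
  for (lab in c("LE", "LT")) {
    big <- geometry_preset(lab)
    small <- geometry_preset(sub("L", "S", lab))
    expect_equal(small$r_l, big$r_l / 5)
    expect_equal(small$r_sn, big$r_sn / 5)
  }
  expect_error(geometry_preset("XX"), "LS, LE, LT, SS, SE, ST")
  expect_error(preset_case("QQ"), "valid labels")
})

test_that("unit conversion is explicit and rejects unknown units", {
  expect_equal(to_si(1.43e-4, "cm/s"), 1.43e-6)
  expect_equal(to_si(2.08e3, "Pa"), 2.08e3)
  expect_equal(to_si(1, "mmHg"), 133.322)
  expect_equal(to_si(3.1e-13, "cm2/s"), 3.1e-17)
  expect_error(to_si(1.43e-4, "furlong/s"), "unrecognized unit")
  expect_error(to_si(1), "unit string is required")
})

test_that("vascular normalization interpolates linearly between the endpoints", {
  t0 <- normalize_vasculature(baseline_tissue(), 0)
  t5 <- normalize_vasculature(baseline_tissue(), 0.5)
  t1 <- normalize_vasculature(baseline_tissue(), 1)
  expect_equal(t0$S_over_V, 2.00e4)
  expect_equal(t0$L_p, 2.10e-11)
  expect_equal(t1$S_over_V, 7.00e3)
  expect_equal(t1$L_p, 2.70e-12)
  expect_equal(t1$c_osm, 0.91)
  expect_equal(t5$S_over_V, 1.35e4)
  ## the table prints the rounded midpoint 1.19e-11; exact is 1.185e-11
  expect_lt(abs(t5$L_p - 1.19e-11) / 1.19e-11, 0.01)
  expect_equal(t5$c_osm, 0.865)
  ## linearity field-wise
  for (f in c("L_p", "S_over_V", "c_osm"))
    expect_equal(t5[[f]], (t0[[f]] + t1[[f]]) / 2)
  ## non-vascular fields untouched
  expect_equal(t1$K, baseline_tissue()$K)
  expect_error(normalize_vasculature(baseline_tissue(), 1.2), "\\[0, 1\\]")
})

test_that("effective pressure is the zero of the Starling source", {
  t <- baseline_tissue()
  expect_equal(effective_pressure(t), 2080 - 0.82 * (2670 - 2000))
  expect_equal(effective_pressure(t), 1530.6)
  t1 <- normalize_vasculature(t, 1)
  expect_equal(effective_pressure(t1), 2080 - 0.91 * 670)
  t$c_osm <- 0
  expect_equal(effective_pressure(t), t$P_v)
})

test_that("permeability overrides keep K = k/mu", {
  ks <- permeability_sweep_values()
  expect_equal(unname(ks), c(6.4e-18, 3.1e-17, 6.4e-17))
  for (k in ks) {
    t <- with_permeability(baseline_tissue(), k)
    expect_equal(t$K * t$mu, k)
  }
})

test_that("parameter validation rejects inconsistent values", {
  expect_error(tissue_params(K = 1e-14, L_p = 2e-11, S_over_V = 2e4,
                             P_v = 2080, pi_v = 2670, pi_i = 2000,
                             c_osm = 0.82, k_intrinsic = 3.1e-17),
               "within 1%")
  expect_error(tissue_params(K = 3.1e-14, L_p = 2e-11, S_over_V = 2e4,
                             P_v = 2080, pi_v = 2670, pi_i = 2000,
                             c_osm = 1.5), "\\[0, 1\\]")
  expect_error(drug_params("x", D = -1, beta = 1e-4, sigma = 0.1,
                           P_c = 1e-6, IC50 = 1e-3, C0 = 0.8), "positive")
  expect_error(geometry_spec("sphere", r_l = 0.01, r_s = 0.02), "r_l == r_s")
  expect_error(geometry_spec("ellipsoid", r_l = 0.02, r_s = 0.01,
                             r_ln = 0.03, r_sn = 0.005), "strictly inside")
})

test_that("presets survive a serialization round trip", {
  p <- preset_case("LT", "paclitaxel")
  q <- unserialize(serialize(p, NULL))
  expect_identical(p, q)
  ## and through the YAML config reader
  cfg <- read_case_config(system.file("extdata", "example-case.yaml",
                                      package = "ipchemo"))
  expect_s3_class(cfg$scenario, "ip_scenario")
  expect_s3_class(cfg$control, "solver_control")
  expect_identical(cfg$scenario$geometry$label, "SS")
})
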
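test_that("a scenario run is deterministic and carries full provenance", {
  ctrl <- solver_control(target_h = 2e-5, n_theta = 16)
  s <- scenario("SE", t_end = 300)
  f1 <- run_case(s, ctrl)
  f2 <- run_case(s, ctrl)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$transport$C, f2$transport$C)
  expect_match(f1$metrics$scenario[1], "SE/cisplatin")
})

test_that("study matrices have the documented shape", {
  st <- cached_study("baseline")
  ## 1 axis x 2 spheres + 2 axes x 4 other geometries = 10 rows
  expect_equal(nrow(st$metrics), 10)
  expect_length(st$cases, 6)
  expect_error(run_study("frobnicate"))

  dr <- cached_study("drug")
  expect_true(all(c("cisplatin", "paclitaxel") %in% dr$metrics$drug))
  ## clinical-dose paclitaxel sphere present
  expect_true(any(grepl("C0=0.14", dr$metrics$scenario)))
  ## deltas reference a matched baseline row
  expect_true(all(!is.na(dr$deltas$dAPD_mm)))
})

test_that("swapping the drug leaves the pressure problem untouched", {
  dr <- cached_study("drug")
  m <- dr$metrics
  cis <- m[m$scenario %in% paste0(c("LS", "LE", "LT", "SS", "SE", "ST"),
                                  "/cisplatin"), ]
  pac <- m[grepl("/paclitaxel$", m$scenario), ]
  key <- function(d) paste(d$geometry, d$axis)
  i <- match(key(cis), key(pac))
  expect_identical(cis$IFP_max_Pa, pac$IFP_max_Pa[i])
  expect_identical(cis$LP50, pac$LP50[i])
  expect_identical(cis$IFV_max_m_s, pac$IFV_max_m_s[i])
})

test_that("cisplatin concentrations dominate paclitaxel pointwise, yet paclitaxel penetrates deeper", {
  dr <- cached_study("drug")
  for (lab in c("LS", "ST")) {
    fc <- dr$cases[[paste0(lab, "/cisplatin")]]
    fp <- dr$cases[[paste0(lab, "/paclitaxel")]]
    expect_true(all(fc$transport$C - fp$transport$C > -1e-9))
    ## at all stored times
    expect_true(all(fc$transport$snapshots - fp$transport$snapshots > -1e-9))
  }
  m <- dr$metrics
  cis <- m[m$scenario %in% paste0(c("LS", "LE", "LT", "SS", "SE", "ST"),
                                  "/cisplatin"), ]
  pac <- m[grepl("/paclitaxel$", m$scenario), ]
  i <- match(paste(cis$geometry, cis$axis), paste(pac$geometry, pac$axis))
  expect_true(all(pac$APD_mm[i] >= cis$APD_mm))
})

test_that("vascular normalization improves penetration monotonically", {
  no <- cached_study("normalization")
  m <- no$metrics
  key <- function(d) paste(d$geometry, d$axis)
  b <- m[!grepl("norm", m$scenario), ]
  n5 <- m[grepl("norm50", m$scenario), ]
  n1 <- m[grepl("norm100", m$scenario), ]
  i5 <- match(key(b), key(n5)); i1 <- match(key(b), key(n1))
  expect_true(all(n5$APD_mm[i5] >= b$APD_mm - 1e-9))
  expect_true(all(n1$APD_mm[i1] >= n5$APD_mm[i5] - 1e-9))
  ## and lowers the interstitial pressure
  expect_true(all(n1$IFP_max_Pa[i1] < b$IFP_max_Pa))
})

test_that("small geometries penetrate relatively deeper than large ones", {
  st <- cached_study("baseline")
  m <- st$metrics
  for (fam in c("S", "E", "T")) {
    small <- m[m$geometry == paste0("S", fam), ]
    large <- m[m$geometry == paste0("L", fam), ]
    i <- match(small$axis, large$axis)
    expect_true(all(small$PD_percent >= large$PD_percent[i]))
  }
  ## ellipsoid/cropped shapes: deeper relative penetration along the SA
  two_ax <- m[m$geometry %in% c("LE", "LT", "SE", "ST"), ]
  for (g in unique(two_ax$geometry)) {
    gg <- two_ax[two_ax$geometry == g, ]
    expect_gte(gg$PD_percent[gg$axis == "SA"], gg$PD_percent[gg$axis == "LA"])
  }
})

test_that("omitting the necrotic core raises IFP only where it can rise", {
  ne <- cached_study("necrotic")
  m <- ne$metrics
  key <- function(d) paste(d$geometry, d$axis)
  b <- m[!grepl("no-core", m$scenario), ]
  nc <- m[grepl("no-core", m$scenario), ]
  i <- match(key(b), key(nc))
  ## IFP never drops when the core is filled in ...
  expect_true(all(nc$IFP_max_Pa[i] >= b$IFP_max_Pa - 1e-6))
  ## ... and visibly rises in the small geometries
  small <- substr(b$geometry, 1, 1) == "S"
  expect_true(all(nc$IFP_max_Pa[i][small] > b$IFP_max_Pa[small] + 1))
})

test_that("lower permeability raises IFP and slows the interstitial flow", {
  pe <- cached_study("permeability")
  m <- pe$metrics
  lowk <- m[grepl("k=6.4e-18", m$scenario), ]
  base <- m[m$scenario %in% paste0(c("LS", "LE", "LT", "SS", "SE", "ST"),
                                   "/cisplatin"), ]
  i <- match(paste(base$geometry, base$axis), paste(lowk$geometry, lowk$axis))
  expect_true(all(lowk$IFP_max_Pa[i] >= base$IFP_max_Pa - 1e-6))
  expect_true(all(lowk$IFV_max_m_s[i] < base$IFV_max_m_s))
})

test_that("study summaries aggregate by size group", {
  st <- cached_study("baseline")
  sm <- summary(st)
  expect_named(sm$PD_percent_average, c("large", "small"))
  expect_gt(sm$PD_percent_average[["small"]], sm$PD_percent_average[["large"]])
  expect_lt(sm$IFP_max_average_Pa[["small"]], sm$IFP_max_average_Pa[["large"]])
  expect_s3_class(sm$APD_min, "data.frame")
})

test_that("the fitted-case object supports the standard methods", {
  fit <- cached_case("SS", scenario("SS"))
  expect_s3_class(fit, "ip_nodule")
  expect_output(print(fit), "IFP_max")
  co <- coef(fit)
  expect_true(all(c("IFP_max_Pa", "APD_mm.LA") %in% names(co)))
  ## predict interpolates the axis profiles
  expect_equal(predict(fit, 0.002, what = "pressure"), 0, tolerance = 1e-9)
  expect_equal(predict(fit, 0.002, what = "concentration"),
               fit$transport$C0, tolerance = 1e-6)
  expect_error(predict(fit, 0.01), "outside")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
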
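## Shared fixtures.  Studies are expensive enough to be worth caching
## across test files; everything is deterministic, so caching is safe.

.case_cache <- new.env(parent = emptyenv())

cached_study <- function(name) {
  if (!exists(name, envir = .case_cache)) {
    base <- if (name != "baseline") cached_study("baseline") else NULL
    assign(name, run_study(name, baseline = base), envir = .case_cache)
  }
  get(name, envir = .case_cache)
}

cached_case <- function(key, s, control = solver_control()) {
  if (!exists(key, envir = .case_cache))
    assign(key, run_case(s, control), envir = .case_cache)
  get(key, envir = .case_cache)
}

## hand-built axis profile for metric unit tests
mk_profile <- function(pos, values, half_length = max(pos)) {
  structure(list(axis = "LA", half_length = half_length, pos = pos,
                 npos = pos / half_length, values = values, what = "test"),
            class = "axis_profile")
}

## tissue with (effectively) no vasculature: u ~ 0 everywhere
avascular_tissue <- function() {
  tissue_params(K = 3.1e-14, L_p = 1e-30, S_over_V = 2e4, P_v = 2.08e3,
                pi_v = 2.67e3, pi_i = 2.00e3, c_osm = 0.82)
}

paper <- list(
  IFP_max_large = 1533.88, P_ss = 1530.6,
  LP50_LE_LA = 0.99, LP50_ST_SA = 0.89,
  APD_min = 0.36, APD_max = 0.49,
  PD_min = 1.81, PD_max = 21.29,
  APD_pac_max = 0.75,
  IFP_SS_norm100 = 259.4, PD_ST_SA_norm100 = 51.64,
  APD_pac_clinical = 0.64, APD_cis_clinical = 0.40,
  IFP_small_avg = 1477.1, PD_small_avg = 17.83, PD_large_avg = 3.24,
  tol_pressure = 0.01,   # relative
  tol_APD = 0.05,        # mm
  tol_LP50 = 0.02,
  tol_PD = 1.5)          # percentage points
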
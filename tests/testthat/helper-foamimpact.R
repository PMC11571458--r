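# shared fixtures: built in code, cached across test files within a run

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache, inherits = FALSE)) {
    assign(name, expr, envir = .test_cache)
  }
  get(name, envir = .test_cache, inherits = FALSE)
}

# noise-free, deterministic parameter set (frozen package defaults
# otherwise)
quiet_params <- function(...) {
  foam_params(specimen_cv = 0, noise_force_sd = 0, noise_disp_sd = 0, ...)
}

# linear-spring limit of the foam law: k (N/m) for a single 18-mm layer
linear_params <- function(k = 2e5, h = 0.018, b_f = 1e-3, ...) {
  quiet_params(a_f = k * h / b_f, b_f = b_f, c_d = 0, n_u = 1.001,
               kappa = 0, delta_d = 0, ...)
}

# calibrated parameters and the full seeded synthetic study, shared by the
# acceptance tests
calibrated_params <- function() {
  cached("calibrated_params", {
    p <- calibrate_defaults(ref_force_table())
    p
  })
}

full_study <- function() {
  cached("full_study", {
    run_full_study(study_config(seed = 42L), calibrated_params())
  })
}

# a small deterministic loading curve for metric tests
linear_loading <- function(k = 1e6, x_max = 0.01, n = 400) {
  x <- seq(0, x_max, length.out = n)
  tibble::tibble(disp_m = x, force_n = k * x)
}
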
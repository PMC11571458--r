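test_that("loading force law matches its closed form", {
  p <- foam_params(a_f = 100, b_f = 5, c_d = 0)
  expect_equal(foam_force(0, p), 0)
  expect_equal(foam_force(0.5, p), 100 * (exp(2.5) - 1), tolerance = 1e-12)
  # monotone in strain for assorted parameter sets
  for (pp in list(foam_params(), foam_params(a_f = 50, b_f = 2, c_d = 10),
                  foam_params(c_d = 200))) {
    f <- foam_force(seq(0, 0.97, by = 0.01), pp)
    expect_true(all(diff(f) > 0))
  }
  expect_error(foam_force(1, p), "strain")
  expect_error(foam_force(-0.1, p), "non-negative")
})

test_that("unloading branch is a power law between plastic set and peak", {
  p <- foam_params(n_u = 2)
  ctx <- list(strain_peak = 0.8, force_peak = 5000, strain_plastic = 0.3)
  expect_equal(foam_force(0.3, p, phase = "unloading", peak_context = ctx), 0)
  expect_equal(foam_force(0.8, p, phase = "unloading", peak_context = ctx), 5000)
  expect_equal(foam_force(0.55, p, phase = "unloading", peak_context = ctx),
               5000 * 0.5^2, tolerance = 1e-12)
  expect_equal(foam_force(0.1, p, phase = "unloading", peak_context = ctx), 0)
  expect_error(foam_force(0.5, p, phase = "unloading"), "peak_context")
})

test_that("degrade accumulates plastic energy into the multiplier", {
  p <- foam_params(kappa = 0.01)
  s <- foam_state(p, 1)
  expect_equal(degrade(s, 0, p)$stiffness_multiplier, 1)
  expect_equal(degrade(s, 20, p)$stiffness_multiplier, 1.2)
  expect_error(degrade(s, -1, p), "non-negative")
  # multiplier non-decreasing over successive cycles
  mults <- numeric(5)
  for (i in 1:5) {
    s <- degrade(s, 7.5, p)
    mults[i] <- s$stiffness_multiplier
  }
  expect_true(all(diff(mults) >= 0))
  # thicker specimens damage more slowly for the same energy
  s3 <- degrade(foam_state(p, 3), 20, p)
  expect_equal(s3$stiffness_multiplier, 1 + 0.01 / 3 * 20)
})

test_that("simulated peak matches the linear-spring energy-balance oracle", {
  k <- 2e5 # N/m over an 18-mm layer
  p <- linear_params(k = k)
  cfg <- study_config()
  m <- cfg$impactor_mass; g <- cfg$gravity; hd <- 0.1
  sim <- simulate_drop(test_condition(hd, 1), p, config = cfg)
  cyc <- attr(sim$trace, "cycle")
  # m g (h + x) = 1/2 k x^2  =>  closed-form x, F = k x
  x_oracle <- (m * g + sqrt((m * g)^2 + 2 * k * m * g * hd)) / k
  expect_equal(cyc$x_peak, x_oracle, tolerance = 5e-3)
  expect_equal(cyc$F_peak, k * x_oracle, tolerance = 5e-3)
  # nearly elastic in the n_u -> 1 limit
  expect_lt(cyc$E_P, 0.01 * cyc$E)
})

test_that("zero drop height settles at static equilibrium", {
  sim <- simulate_drop(test_condition(0, 1), quiet_params())
  expect_equal(max(sim$trace$force_n), 8 * 9.81, tolerance = 0.01)
})

test_that("cycle energy bookkeeping balances drop energy", {
  p <- quiet_params()
  for (cond in list(test_condition(0.5, 1), test_condition(0.25, 2),
                    test_condition(0.15, 3))) {
    cyc <- attr(simulate_drop(cond, p)$trace, "cycle")
    expect_equal(cyc$E, cyc$E_balance, tolerance = 0.01)
    expect_lte(cyc$E_E, cyc$E)
    expect_gt(cyc$eps_plastic, 0) # n_u > 1 leaves permanent set
  }
})

test_that("peak force decreases with layer count at fixed height", {
  p <- quiet_params()
  for (hd in c(0.15, 0.50)) {
    peaks <- vapply(1:3, function(nl) {
      attr(simulate_drop(test_condition(hd, nl), p)$trace, "cycle")$F_peak
    }, 0)
    expect_true(all(diff(peaks) < 0))
  }
})

test_that("force at 30 J is non-decreasing across repetitions", {
  p <- quiet_params()
  for (nl in 1:3) {
    st <- NULL
    f30 <- numeric(5)
    for (r in 1:5) {
      sim <- simulate_drop(test_condition(0.5, nl, repetition = r), p, st)
      st <- sim$state
      f30[r] <- force_at_energy(process_trace(sim$trace)$loading, 30)
    }
    expect_true(all(diff(f30) > -1e-3 * f30[-5]))
  }
})

test_that("generated dataset is complete, reproducible and seeded", {
  cfg <- study_config(seed = 5L)
  ds1 <- generate_dataset(cfg, foam_params())
  expect_length(ds1$traces, 126)
  expect_equal(nrow(ds1$manifest), 126)
  ds2 <- generate_dataset(cfg, foam_params())
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(ds1$traces[[1]], ds2$traces[[1]])
  expect_identical(ds1$traces[[126]], ds2$traces[[126]])
  # different seed changes the noise
  ds3 <- generate_dataset(study_config(seed = 6L), foam_params())
  expect_false(identical(ds3$traces[[1]]$force_n, ds1$traces[[1]]$force_n))
})

test_that("zero variability makes specimens of a condition identical", {
  cfg <- study_config(drop_heights = 0.25, layer_counts = 1L,
                      specimens_per_condition = 2L,
                      extra_specimens_50cm = 0L, seed = 1L)
  ds <- generate_dataset(cfg, quiet_params())
  tr <- ds$traces
  expect_equal(tr[[1]]$force_n, tr[[4]]$force_n) # same rep, other specimen
})

test_that("dataset writes trace CSVs and a manifest that read back", {
  dir <- withr::local_tempdir()
  cfg <- study_config(drop_heights = 0.5, layer_counts = 1:2,
                      specimens_per_condition = 1L,
                      extra_specimens_50cm = 0L, seed = 2L)
  ds <- generate_dataset(cfg, foam_params(), out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  f <- ds$manifest$file[1]
  back <- read_trace(file.path(dir, f))
  expect_equal(back$force_n, ds$traces[[f]]$force_n, tolerance = 1e-6)
})
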
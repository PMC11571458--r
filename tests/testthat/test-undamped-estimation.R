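test_that("exponential fit recovers noise-free parameters", {
  x <- c(0.013, 0.028, 0.044)
  pts <- tibble::tibble(peak_disp_m = x,
                        peak_force_n = 25000 * exp(-60 * x))
  fit <- fit_exponential(pts)
  expect_equal(fit$a, 25000, tolerance = 1e-3)
  expect_equal(fit$b, -60, tolerance = 1e-3)
})

test_that("two points reproduce the closed-form solution exactly", {
  pts <- tibble::tibble(peak_disp_m = c(0.01, 0.03),
                        peak_force_n = c(9000, 2500))
  fit <- fit_exponential(pts)
  b <- log(2500 / 9000) / 0.02
  expect_equal(fit$b, b, tolerance = 1e-12)
  expect_equal(fit$a, 9000 * exp(-b * 0.01), tolerance = 1e-12)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
})

test_that("constant forces give the flat fit and errors are raised", {
  pts <- tibble::tibble(peak_disp_m = c(0.01, 0.02, 0.03),
                        peak_force_n = rep(4000, 3))
  fit <- fit_exponential(pts)
  expect_equal(fit$b, 0)
  expect_equal(fit$a, 4000)
  expect_error(fit_exponential(pts[1, ]), "2 peak points")
  expect_error(fit_exponential(
    tibble::tibble(peak_disp_m = c(0.01, 0.02), peak_force_n = c(-1, 5))
  ), "positive")
  expect_error(fit_exponential(
    tibble::tibble(peak_disp_m = c(0.01, 0.01), peak_force_n = c(1, 5))
  ), "degenerate")
})

test_that("fit residuals are orthogonal to the Jacobian at convergence", {
  set.seed(11)
  x <- seq(0.005, 0.05, length.out = 10)
  f <- 30000 * exp(-55 * x) * exp(rnorm(10, 0, 0.03))
  fit <- fit_exponential(tibble::tibble(peak_disp_m = x, peak_force_n = f))
  r <- f - fit$a * exp(fit$b * x)
  j1 <- exp(fit$b * x)
  j2 <- fit$a * x * exp(fit$b * x)
  scale <- sqrt(sum(r^2)) * sqrt(sum(j1^2))
  expect_lt(abs(sum(r * j1)) / scale, 1e-6)
  expect_lt(abs(sum(r * j2)) / (sqrt(sum(r^2)) * sqrt(sum(j2^2))), 1e-6)
})

test_that("undamped table recovers exact per-group exponentials", {
  grid <- tidyr::expand_grid(drop_height = c(0.2, 0.4), repetition = 1:2,
                             n_layers = 1:3)
  a_true <- function(h, r) 20000 * h * 10 + 1000 * r
  metrics <- dplyr::mutate(
    grid,
    peak_disp_m = 0.012 * n_layers,
    peak_force_n = a_true(drop_height, repetition) * exp(-50 * peak_disp_m)
  )
  tab <- undamped_force_table(metrics)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$undamped_force_n,
               a_true(tab$drop_height, tab$repetition), tolerance = 1e-6)
  expect_equal(tab$b_per_m, rep(-50, 4), tolerance = 1e-6)
})

test_that("groups without layer contrast are skipped with a warning", {
  metrics <- tibble::tibble(drop_height = 0.2, repetition = 1L,
                            n_layers = c(1L, 1L),
                            peak_disp_m = c(0.01, 0.011),
                            peak_force_n = c(5000, 4900))
  expect_warning(tab <- undamped_force_table(metrics), "skipped")
  expect_equal(nrow(tab), 0)
  expect_equal(nrow(undamped_force_table(metrics[0, ])), 0)
})

test_that("transfer fit matches exact proportionality and the grid oracle", {
  m <- c(1000, 2000, 3000, 4000)
  exact <- fit_transfer_function(
    tibble::tibble(measured_n = m, undamped_n = 2.8 * m), n_layers = 1L
  )
  expect_equal(exact$slope, 2.8, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_equal(diff(exact$ci95), 0, tolerance = 1e-9)

  pairs <- tibble::tibble(
    measured_n = c(1200, 2100, 2900, 4100, 5200),
    undamped_n = c(3600, 5600, 8600, 11000, 15400)
  )
  fit <- fit_transfer_function(pairs)
  kg <- seq(1, 5, by = 1e-4)
  sse <- vapply(kg, function(k) sum((pairs$undamped_n - k * pairs$measured_n)^2), 0)
  expect_equal(fit$slope, kg[which.min(sse)], tolerance = 2e-4)
  # closed form
  expect_equal(fit$slope,
               sum(pairs$measured_n * pairs$undamped_n) / sum(pairs$measured_n^2),
               tolerance = 1e-12)
  expect_true(fit$ci95[1] < fit$slope && fit$slope < fit$ci95[2])
  expect_error(fit_transfer_function(pairs[1, ]), "2 pairs")
})

test_that("undamped predictions preserve units and round as reported", {
  expect_equal(round(predict_undamped(2.9, 2.8), 1), 8.1)
  expect_equal(round(predict_undamped(3.8, 2.8), 1), 10.6)
  expect_equal(predict_undamped(0, 2.8), 0)
  expect_error(predict_undamped(-1, 2.8), "non-negative")
  tf <- fit_transfer_function(
    tibble::tibble(measured_n = c(1, 2), undamped_n = c(2.8, 5.6))
  )
  expect_equal(predict_undamped(1000, tf), 2800, tolerance = 1e-9)
})

test_that("attenuation ratios reproduce the reported comparisons", {
  expect_equal(round(attenuation_ratio(6.1, 2.8), 1), 2.2)
  expect_equal(round(attenuation_ratio(11.1, 2.8), 1), 4.0)
  expect_equal(attenuation_ratio(3, 3), 1)
  expect_error(attenuation_ratio(2, 0), "positive")
})

test_that("tidiers expose fit parameters as tibbles", {
  pts <- tibble::tibble(peak_disp_m = c(0.01, 0.03),
                        peak_force_n = c(9000, 2500))
  fit <- fit_exponential(pts)
  expect_equal(tidy(fit)$term, c("a", "b"))
  expect_equal(glance(fit)$n_points, 2L)
  tf <- fit_transfer_function(
    tibble::tibble(measured_n = c(1000, 2000, 3100),
                   undamped_n = c(2900, 5500, 9000)), n_layers = 2L
  )
  expect_equal(glance(tf)$n_layers, 2L)
  expect_equal(tidy(tf)$estimate, tf$slope)
})
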
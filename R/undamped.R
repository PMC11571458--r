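#' Fit an exponential decay through peak-force points
#'
#' Fits `F(x) = a * exp(b * x)` to peak (displacement, force) points by
#' nonlinear least squares, with starting values from the log-linear
#' regression of `log(F)` on `x`. The intercept `a = F(0)` is the undamped
#' force: the force the load cell would register with no specimen present.
#' `b` carries no sign constraint; across layer stacks it is expected
#' negative, since thicker stacks compress further and measure lower peak
#' forces.
#'
#' Two points admit the closed form `b = log(F2/F1) / (x2 - x1)`,
#' `a = F1 * exp(-b * x1)`, which is used directly; identical forces give
#' the constant fit `b = 0`.
#'
#' @param points A tibble with columns `peak_disp_m` and `peak_force_n`
#'   (all forces > 0, displacements not all identical).
#' @return An object of class `exp_fit`: list with `a` (N), `b` (1/m),
#'   `n_points`, `rss` (N^2), `fitted` function.
#' @examples
#' pts <- tibble::tibble(peak_disp_m = c(0.013, 0.028, 0.044),
#'                       peak_force_n = 25000 * exp(-60 * c(0.013, 0.028, 0.044)))
#' fit_exponential(pts)$a # ~25000
#' @export
fit_exponential <- function(points) {
  x <- points$peak_disp_m
  f <- points$peak_force_n
  if (length(x) < 2) stop("need at least 2 peak points.", call. = FALSE)
  if (any(f <= 0)) stop("peak forces must be positive.", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("degenerate fit: all displacements identical.", call. = FALSE)
  }

  new_fit <- function(a, b) {
    structure(
      list(a = a, b = b, n_points = length(x),
           rss = sum((f - a * exp(b * x))^2),
           fitted = function(xx) a * exp(b * xx),
           data = tibble::tibble(peak_disp_m = x, peak_force_n = f)),
      class = "exp_fit"
    )
  }

  if (diff(range(f)) == 0) return(new_fit(f[1], 0))
  if (length(x) == 2) {
    b <- log(f[2] / f[1]) / (x[2] - x[1])
    return(new_fit(f[1] * exp(-b * x[1]), b))
  }

  ll <- stats::lm(log(f) ~ x)
  start <- list(a = exp(unname(stats::coef(ll)[1])),
                b = unname(stats::coef(ll)[2]))
  fit <- minpack.lm::nlsLM(
    f ~ a * exp(b * x),
    data = data.frame(x = x, f = f),
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  new_fit(unname(cf["a"]), unname(cf["b"]))
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> F(x) = %.1f * exp(%.2f x), n = %d, rss = %.3g\n",
              x$a, x$b, x$n_points, x$rss))
  invisible(x)
}

#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, rss = x$rss, n_points = x$n_points)
}

#' Undamped force per drop height and repetition
#'
#' For each (drop height, repetition) group, pools the peak points of all
#' layer counts and specimens tested under that impact condition, fits the
#' exponential decay of peak force with peak displacement, and extrapolates
#' to zero displacement. The extrapolation spans the displacement range
#' covered by the different stack thicknesses; its intercept is the
#' estimated force of the bare impact. Groups containing fewer than two
#' distinct layer counts are skipped with a warning. Setting
#' `per_layer = TRUE` additionally stratifies the groups by layer count
#' (a documented non-default reading; extrapolation then spans only the
#' specimen scatter of one stack).
#'
#' @param metrics Per-test metrics tibble from [compute_metrics()] (needs
#'   `drop_height`, `repetition`, `n_layers`, `peak_disp_m`,
#'   `peak_force_n`).
#' @param per_layer Stratify fits by layer count instead of pooling across
#'   layers.
#' @return A tibble: `drop_height`, `repetition`, (`n_layers`,)
#'   `undamped_force_n` (the fitted `a`), `b_per_m`, `n_points`, `rss`.
#' @export
undamped_force_table <- function(metrics, per_layer = FALSE) {
  if (nrow(metrics) == 0) {
    return(tibble::tibble(drop_height = numeric(), repetition = integer(),
                          undamped_force_n = numeric(), b_per_m = numeric(),
                          n_points = integer(), rss = numeric()))
  }
  keys <- c("drop_height", "repetition", if (per_layer) "n_layers")
  grouped <- dplyr::group_by(metrics, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::group_modify(grouped, function(d, k) {
    if (!per_layer && dplyr::n_distinct(d$n_layers) < 2) {
      warning(sprintf(
        "group (height %.2f m, repetition %d) has < 2 layer conditions; skipped.",
        k$drop_height, k$repetition), call. = FALSE)
      return(tibble::tibble())
    }
    fit <- fit_exponential(
      tibble::tibble(peak_disp_m = d$peak_disp_m,
                     peak_force_n = d$peak_force_n)
    )
    tibble::tibble(undamped_force_n = fit$a, b_per_m = fit$b,
                   n_points = fit$n_points, rss = fit$rss)
  })
  dplyr::ungroup(out)
}

#' Zero-intercept transfer function between measured and undamped force
#'
#' Fits the linear transfer `undamped = k * measured` through the origin by
#' least squares: `k = sum(m * u) / sum(m^2)`. The slope is the factor by
#' which a force measured through the protective stack must be multiplied
#' to recover the undamped force. The coefficient of determination uses the
#' uncentered convention standard for through-origin models,
#' `R^2 = 1 - RSS / sum(u^2)`, and the 95% CI is
#' `k +/- t(0.975, n - 1) * SE(k)`.
#'
#' @param pairs A tibble with columns `measured_n` and `undamped_n`
#'   (positive forces; at least 2 pairs).
#' @param n_layers Optional layer count recorded in the result.
#' @return An object of class `transfer_fn`: list with `n_layers`, `slope`,
#'   `r_squared`, `ci95` (length-2), `se`, `n_points`, `data`.
#' @export
fit_transfer_function <- function(pairs, n_layers = NA_integer_) {
  m <- pairs$measured_n; u <- pairs$undamped_n
  if (length(m) < 2) stop("need at least 2 pairs.", call. = FALSE)
  if (any(m <= 0) || any(u <= 0)) {
    stop("forces must be positive.", call. = FALSE)
  }
  k <- sum(m * u) / sum(m^2)
  res <- u - k * m
  rss <- sum(res^2)
  n <- length(m)
  se <- sqrt(rss / (n - 1) / sum(m^2))
  tq <- stats::qt(0.975, n - 1)
  structure(
    list(
      n_layers = n_layers,
      slope = k,
      r_squared = 1 - rss / sum(u^2),
      ci95 = c(k - tq * se, k + tq * se),
      se = se,
      n_points = n,
      data = tibble::tibble(measured_n = m, undamped_n = u)
    ),
    class = "transfer_fn"
  )
}

#' @export
print.transfer_fn <- function(x, ...) {
  cat(sprintf(
    "<transfer_fn>%s undamped = %.2f * measured (R^2 = %.3f, 95%% CI [%.2f, %.2f], n = %d)\n",
    if (is.na(x$n_layers)) "" else sprintf(" %d layer(s):", x$n_layers),
    x$slope, x$r_squared, x$ci95[1], x$ci95[2], x$n_points
  ))
  invisible(x)
}

#' @method tidy transfer_fn
#' @export
tidy.transfer_fn <- function(x, ...) {
  tibble::tibble(term = "slope", estimate = x$slope, std.error = x$se,
                 conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' @method glance transfer_fn
#' @export
glance.transfer_fn <- function(x, ...) {
  tibble::tibble(n_layers = x$n_layers, slope = x$slope,
                 r.squared = x$r_squared, ci_lo = x$ci95[1],
                 ci_hi = x$ci95[2], n = x$n_points)
}

#' Transfer functions for every layer count
#'
#' Pairs each measured specimen-level peak force with the undamped force of
#' its (drop height, repetition) group and fits one zero-intercept transfer
#' function per layer count.
#'
#' @param metrics Per-test metrics tibble.
#' @param undamped Result of [undamped_force_table()] (pooled mode).
#' @return A named list of `transfer_fn`, one per layer count.
#' @export
fit_all_transfer_functions <- function(metrics, undamped) {
  joined <- dplyr::inner_join(metrics, undamped,
                              by = c("drop_height", "repetition"))
  by_layer <- split(joined, joined$n_layers)
  purrr::imap(by_layer, function(d, nl) {
    fit_transfer_function(
      tibble::tibble(measured_n = d$peak_force_n,
                     undamped_n = d$undamped_force_n),
      n_layers = as.integer(nl)
    )
  })
}

#' Predict the undamped force from a measured force
#'
#' Multiplies a measured peak force by the transfer-function slope. Units
#' are preserved (N in, N out; kN in, kN out).
#'
#' @param measured_force Measured peak force (>= 0), any consistent unit.
#' @param tf A `transfer_fn`, or a bare numeric slope.
#' @return Predicted undamped force in the unit of `measured_force`.
#' @examples
#' predict_undamped(2.9, 2.8) # 8.12 kN
#' @export
predict_undamped <- function(measured_force, tf) {
  if (any(measured_force < 0)) {
    stop("measured force must be non-negative.", call. = FALSE)
  }
  slope <- if (inherits(tf, "transfer_fn")) tf$slope else as.numeric(tf)
  slope * measured_force
}

#' Relative attenuation of a multi-layer stack
#'
#' Ratio of transfer slopes: how many times more a multi-layer stack
#' attenuates the force compared to the single layer.
#'
#' @param tf_multi,tf_single `transfer_fn` objects or bare slopes.
#' @return Dimensionless ratio.
#' @examples
#' attenuation_ratio(6.1, 2.8) # ~2.2
#' @export
attenuation_ratio <- function(tf_multi, tf_single) {
  s_m <- if (inherits(tf_multi, "transfer_fn")) tf_multi$slope else as.numeric(tf_multi)
  s_s <- if (inherits(tf_single, "transfer_fn")) tf_single$slope else as.numeric(tf_single)
  if (s_s <= 0) stop("single-layer slope must be positive.", call. = FALSE)
  s_m / s_s
}
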
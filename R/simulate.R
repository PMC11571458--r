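#' A single test condition
#'
#' @param drop_height Drop height in m.
#' @param n_layers Number of foam layers.
#' @param specimen_id Specimen label.
#' @param repetition 1-based repetition number.
#' @return A one-row tibble usable as the `condition` of [simulate_drop()].
#' @export
test_condition <- function(drop_height, n_layers, specimen_id = "S1",
                           repetition = 1L) {
  stopifnot(drop_height >= 0, n_layers >= 1, repetition >= 1)
  tibble::tibble(
    drop_height = drop_height, n_layers = as.integer(n_layers),
    specimen_id = specimen_id, repetition = as.integer(repetition)
  )
}

new_impact_trace <- function(time, disp_a, disp_b, force, condition,
                             truth = NULL, cycle = NULL) {
  out <- tibble::tibble(
    time_s = time, disp_a_m = disp_a, disp_b_m = disp_b, force_n = force
  )
  attr(out, "condition") <- condition
  attr(out, "truth") <- truth
  attr(out, "cycle") <- cycle
  class(out) <- c("impact_trace", class(out))
  out
}

#' Simulate one falling-weight drop onto a foam specimen
#'
#' Integrates the impactor's equation of motion `m x'' = m g - F(x/h)` from
#' first contact (`x = 0`, velocity `sqrt(2 g h_drop)`) with a fixed-step
#' 4th-order Runge-Kutta scheme at ten times the output sampling rate. The
#' loading branch of [foam_force()] applies until the force maximum (zero
#' velocity); the cycle's absorbed energy then fixes the plastic set strain
#' so that the unloading branch returns the state's elastic fraction of the
#' absorbed energy, and integration continues on the unloading branch until
#' the impactor separates (force back to zero). The emitted trace contains a
#' short pre-contact and post-separation roll, is resampled to
#' `params$sample_rate`, and carries independent Gaussian noise on the force
#' channel and on each of the two displacement channels (both lasers see the
#' same true displacement). A zero drop height is treated as a quasi-static
#' placement that settles at the static equilibrium force `m g`.
#'
#' @param condition A [test_condition()] (one row).
#' @param params A [foam_params()].
#' @param state A [foam_state()]; fresh if `NULL`.
#' @param config A [study_config()].
#' @param seed Optional integer seed for the measurement noise.
#' @param noise If `FALSE`, emit noise-free channels regardless of the noise
#'   standard deviations in `params`.
#' @return A list with elements `trace` (an `impact_trace` tibble with
#'   columns `time_s`, `disp_a_m`, `disp_b_m`, `force_n` and attributes
#'   `condition`, `truth`, `cycle`) and `state` (the degraded
#'   [foam_state()]).
#' @export
simulate_drop <- function(condition, params, state = NULL,
                          config = study_config(), seed = NULL,
                          noise = TRUE) {
  stopifnot(inherits(params, "foam_params"))
  cond <- tibble::as_tibble(condition)
  stopifnot(nrow(cond) == 1)
  if (is.null(state)) state <- foam_state(params, cond$n_layers, config)
  if (!is.null(seed)) set.seed(seed)

  h <- state$thickness
  m <- config$impactor_mass
  g <- config$gravity
  if (cond$drop_height == 0) {
    return(quasistatic_settle(cond, params, state, config, noise))
  }
  v0 <- impact_velocity(cond$drop_height, g)

  mult <- state$stiffness_multiplier
  onset <- densification_onset(params, state)
  a_f <- params$a_f; b_f <- params$b_f; c_d <- params$c_d
  f_load <- function(x) {
    eps <- x / h
    if (eps >= 0.99) stop("strain >= 0.99: parameterization outside the ",
                          "supported regime.", call. = FALSE)
    if (eps <= 0) return(0)
    d <- if (eps > onset) 1 + c_d * (eps - onset)^2 / (1 - eps) else 1
    mult * a_f * expm1(b_f * eps) * d
  }

  oversample <- 10L
  dt <- 1 / (oversample * params$sample_rate)
  max_steps <- as.integer(2 / dt) # 2 s of contact is far beyond any impact

  # loading phase -----------------------------------------------------------
  xs <- numeric(4096); fs <- numeric(4096)
  x <- 0; v <- v0; work <- 0; f_prev <- 0; i <- 0L
  accel <- function(x) g - f_load(x) / m
  while (v > 0) {
    i <- i + 1L
    if (i > max_steps) stop("loading phase did not converge.", call. = FALSE)
    if (i > length(xs)) { xs <- c(xs, numeric(length(xs))); fs <- c(fs, numeric(length(fs))) }
    k1x <- v;                 k1v <- accel(x)
    k2x <- v + dt / 2 * k1v;  k2v <- accel(x + dt / 2 * k1x)
    k3x <- v + dt / 2 * k2v;  k3v <- accel(x + dt / 2 * k2x)
    k4x <- v + dt * k3v;      k4v <- accel(x + dt * k3x)
    x_new <- x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    v <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    f_new <- f_load(x_new)
    work <- work + (f_prev + f_new) / 2 * (x_new - x)
    x <- x_new; f_prev <- f_new
    xs[i] <- x; fs[i] <- f_new
  }
  n_load <- i
  eps_pk <- x / h
  f_pk <- f_prev
  e_cycle <- work

  # unloading branch parameters ---------------------------------------------
  phi <- elastic_fraction(params, state)
  e_elastic <- phi * e_cycle
  eps_rec <- min((params$n_u + 1) * e_elastic / (f_pk * h), eps_pk)
  eps_p <- eps_pk - eps_rec
  peak_ctx <- list(strain_peak = eps_pk, force_peak = f_pk,
                   strain_plastic = eps_p)
  f_unload <- function(x) {
    eps <- x / h
    if (eps <= eps_p) return(0)
    f_pk * min((eps - eps_p) / eps_rec, 1)^params$n_u
  }

  # unloading phase ----------------------------------------------------------
  accel_u <- function(x) g - f_unload(x) / m
  v <- 0
  stalled <- FALSE
  while (x > eps_p * h + 1e-12) {
    i <- i + 1L
    if (i > max_steps) stop("unloading phase did not converge.", call. = FALSE)
    if (i > length(xs)) { xs <- c(xs, numeric(length(xs))); fs <- c(fs, numeric(length(fs))) }
    k1x <- v;                 k1v <- accel_u(x)
    k2x <- v + dt / 2 * k1v;  k2v <- accel_u(x + dt / 2 * k1x)
    k3x <- v + dt / 2 * k2v;  k3v <- accel_u(x + dt / 2 * k2x)
    k4x <- v + dt * k3v;      k4v <- accel_u(x + dt * k3x)
    x <- x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    v <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    xs[i] <- x; fs[i] <- f_unload(x)
    if (v >= 0 && i > n_load + 2L) { stalled <- TRUE; break }
  }
  if (stalled) {
    warning("impactor stalled during unloading; trace truncated at rest.",
            call. = FALSE)
  }
  v_sep <- v

  # assemble internal-rate signal with pre/post rolls ------------------------
  n_pre <- as.integer(round(0.003 / dt))
  n_post <- as.integer(round(0.002 / dt))
  t_pre <- -(n_pre:1) * dt
  x_pre <- v0 * t_pre
  x_post <- if (stalled) rep(x, n_post) else {
    tp <- (1:n_post) * dt
    x + v_sep * tp + g * tp^2 / 2 # ballistic rebound (x measured downward)
  }
  x_all <- c(x_pre, xs[seq_len(i)], x_post)
  f_all <- c(rep(0, n_pre), fs[seq_len(i)], rep(0, n_post))

  keep <- seq(1, length(x_all), by = oversample)
  x_out <- x_all[keep]; f_out <- f_all[keep]
  t_out <- (seq_along(keep) - 1) / params$sample_rate

  n <- length(t_out)
  sd_f <- if (noise) params$noise_force_sd else 0
  sd_d <- if (noise) params$noise_disp_sd else 0
  trace <- new_impact_trace(
    time = t_out,
    disp_a = x_out + stats::rnorm(n, 0, sd_d),
    disp_b = x_out + stats::rnorm(n, 0, sd_d),
    force = f_out + stats::rnorm(n, 0, sd_f),
    condition = cond,
    truth = tibble::tibble(time_s = t_out, disp_m = x_out, force_n = f_out),
    cycle = tibble::tibble(
      E = e_cycle, E_E = e_elastic, E_P = e_cycle - e_elastic,
      eps_peak = eps_pk, x_peak = eps_pk * h, F_peak = f_pk,
      eps_plastic = eps_p, v_impact = v0, v_sep = v_sep,
      E_balance = m * g * (cond$drop_height + eps_pk * h)
    )
  )
  state <- degrade(state, e_cycle - e_elastic, params,
                   residual_set = eps_p * h)
  list(trace = trace, state = state)
}

# effective densification onset: collapsed cells (accumulated plastic
# energy) bring compaction forward, saturating on the e_cap scale
densification_onset <- function(params, state) {
  adv <- params$delta_d *
    (1 - exp(-state$cumulative_plastic_energy / params$e_cap))
  max(params$eps_d - adv, 0.05)
}

# gentle placement at zero drop height: settles at F = m g
quasistatic_settle <- function(cond, params, state, config, noise) {
  h <- state$thickness
  m <- config$impactor_mass; g <- config$gravity
  f_static <- function(eps) {
    foam_force(eps, params, state, phase = "loading")
  }
  eps_eq <- stats::uniroot(function(e) f_static(e) - m * g,
                           c(1e-9, 0.98), tol = 1e-12)$root
  sr <- params$sample_rate
  n_ramp <- as.integer(0.040 * sr); n_hold <- as.integer(0.010 * sr)
  eps_t <- c(eps_eq * (1 - cos(pi * seq_len(n_ramp) / n_ramp)) / 2,
             rep(eps_eq, n_hold))
  x_out <- eps_t * h
  f_out <- vapply(eps_t, f_static, 0)
  t_out <- (seq_along(x_out) - 1) / sr
  grid <- seq(0, eps_eq, length.out = 512)
  e_cycle <- h * sum(diff(grid) * (f_static(grid)[-1] + f_static(grid)[-512]) / 2)
  phi <- elastic_fraction(params, state)
  n <- length(t_out)
  sd_f <- if (noise) params$noise_force_sd else 0
  sd_d <- if (noise) params$noise_disp_sd else 0
  trace <- new_impact_trace(
    time = t_out,
    disp_a = x_out + stats::rnorm(n, 0, sd_d),
    disp_b = x_out + stats::rnorm(n, 0, sd_d),
    force = f_out + stats::rnorm(n, 0, sd_f),
    condition = cond,
    truth = tibble::tibble(time_s = t_out, disp_m = x_out, force_n = f_out),
    cycle = tibble::tibble(
      E = e_cycle, E_E = phi * e_cycle, E_P = (1 - phi) * e_cycle,
      eps_peak = eps_eq, x_peak = eps_eq * h, F_peak = m * g,
      eps_plastic = NA_real_, v_impact = 0, v_sep = 0,
      E_balance = e_cycle
    )
  )
  state <- degrade(state, (1 - phi) * e_cycle, params)
  list(trace = trace, state = state)
}

#' Simulate the full factorial study
#'
#' Runs [simulate_drop()] for every test of [enumerate_design()]. Each
#' specimen draws its own stress scale `a_f` from a mean-preserving
#' lognormal with coefficient of variation `params$specimen_cv`, and its
#' [foam_state()] persists across that specimen's repetitions (no recovery
#' between repetitions) and resets between specimens. Fully reproducible
#' from `seed`.
#'
#' @param config A [study_config()].
#' @param params A [foam_params()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param out_dir Optional directory: when given, one CSV per trace plus a
#'   `manifest.csv` are written there.
#' @return A list with `traces` (named list of `impact_trace` objects) and
#'   `manifest` (a tibble: one row per test with condition fields, `file`
#'   and `seed`).
#' @export
generate_dataset <- function(config = study_config(),
                             params = foam_params(),
                             seed = config$seed, out_dir = NULL) {
  design <- enumerate_design(config)
  set.seed(seed)
  traces <- vector("list", nrow(design))
  sigma <- sqrt(log(1 + params$specimen_cv^2))

  specs <- split(seq_len(nrow(design)), design$specimen_id)
  # iterate specimens in first-appearance order for reproducibility
  spec_order <- unique(design$specimen_id)
  for (sid in spec_order) {
    rows <- specs[[sid]]
    rows <- rows[order(design$repetition[rows])]
    a_mult <- exp(stats::rnorm(1, -sigma^2 / 2, sigma))
    p_spec <- params
    p_spec$a_f <- params$a_f * a_mult
    st <- foam_state(p_spec, design$n_layers[rows[1]], config)
    for (r in rows) {
      sim <- simulate_drop(design[r, ], p_spec, st, config)
      traces[[r]] <- sim$trace
      st <- sim$state
    }
  }
  manifest <- dplyr::mutate(
    design,
    file = sprintf("%s_R%d.csv", .data$specimen_id, .data$repetition),
    seed = seed
  )
  names(traces) <- manifest$file
  if (!is.null(out_dir)) {
    write_dataset(traces, manifest, out_dir)
  }
  list(traces = traces, manifest = tibble::as_tibble(manifest))
}

#' Read and write impact-trace CSV files
#'
#' Traces use a four-column CSV schema: `time_s, disp_a_m, disp_b_m,
#' force_n`. `write_dataset()` writes one file per trace plus a
#' `manifest.csv` mapping files to test conditions.
#'
#' @param traces Named list of `impact_trace` objects.
#' @param manifest Manifest tibble from [generate_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return `write_dataset()` returns `out_dir` invisibly.
#' @export
write_dataset <- function(traces, manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in names(traces)) {
    readr::write_csv(tibble::as_tibble(unclass(traces[[f]]))[
      c("time_s", "disp_a_m", "disp_b_m", "force_n")
    ], file.path(out_dir, f))
  }
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(out_dir)
}

#' @rdname write_dataset
#' @param path Path of a single trace CSV.
#' @param condition Optional [test_condition()] to attach.
#' @return `read_trace()` returns an `impact_trace`.
#' @export
read_trace <- function(path, condition = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("time_s", "disp_a_m", "disp_b_m", "force_n")
  if (!all(req %in% names(df))) {
    stop("trace file ", path, " lacks required columns ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  }
  new_impact_trace(df$time_s, df$disp_a_m, df$disp_b_m, df$force_n,
                   condition = condition)
}
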
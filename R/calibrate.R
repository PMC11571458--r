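# Quasi-static engine used by the calibration: the force at a given
# absorbed energy depends only on the loading curve, and the absorbed
# energy of a cycle follows from the energy balance m g (h_drop + x_pk) =
# E(x_pk), so calibration never needs the time integration. The dynamic
# simulator reproduces these values to well within the calibration
# tolerance (see the simulator tests).
static_cycle_seq <- function(a, b, c, kap, nu, del, ecap, eps_d, n_layers,
                             h1, m, g, drop_height, n_reps,
                             target_energy = 30, n_grid = 1200) {
  eps <- seq(0, 0.985, length.out = n_grid)
  base <- a * expm1(b * eps)
  h <- n_layers * h1
  C <- 0
  f_at_e <- numeric(n_reps)
  f_peak <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    mult <- 1 + kap / n_layers * C
    onset <- max(eps_d - del * (1 - exp(-C / ecap)), 0.05)
    force <- mult * base * (1 + c * pmax(0, eps - onset)^2 / (1 - eps))
    energy <- c(0, cumsum((force[-1] + force[-n_grid]) / 2 * diff(eps))) * h
    if (max(energy) < target_energy) return(NULL)
    f_at_e[r] <- stats::approx(energy, force, target_energy)$y
    balance <- m * g * (drop_height + eps * h) - energy
    i <- which(balance < 0)[1]
    if (is.na(i) || i < 2) return(NULL)
    w <- balance[i - 1] / (balance[i - 1] - balance[i])
    eps_pk <- eps[i - 1] + w * (eps[i] - eps[i - 1])
    f_peak[r] <- stats::approx(eps, force, eps_pk)$y
    e_cycle <- m * g * (drop_height + eps_pk * h)
    phi <- 1 - (1 - 1 / nu) * exp(-C / ecap)
    C <- C + (1 - phi) * e_cycle
  }
  list(f_at_e = f_at_e, f_peak = f_peak)
}

#' Calibrate default foam parameters to reference forces
#'
#' Least-squares search over the material parameters (`a_f`, `b_f`, `c_d`,
#' `kappa`, `n_u`, `delta_d`, `e_cap`) so that noise-free simulated forces at the
#' reference absorbed energy match a target table of per-layer forces and
#' relative per-repetition increases. The targets must contain at least
#' the one- and two-layer repetition-1 forces; those two must be matched
#' within 5 % or the search fails with an error. The three-layer
#' repetition-1 force is deliberately held out of the fit and reported as
#' a validation error. Relative force increases (repetition r vs 1) of all
#' layers present in the targets enter the objective, with the earliest
#' repetition weighted highest; a penalty keeps the force at the reference
#' energy non-decreasing across repetitions, and a soft envelope term keeps
#' the single-layer first-impact peak force near the 10 kN force threshold
#' the experiment was designed around.
#'
#' The search evaluates the loading law quasi-statically (force at a fixed
#' absorbed energy depends only on the loading curve; each cycle's
#' absorbed energy follows from the impact energy balance), which the
#' dynamic simulator reproduces to a fraction of a percent.
#'
#' @param targets A tibble like [ref_force_table()]: columns `n_layers`,
#'   `repetition`, `force_n`, optionally `increase_pct`.
#' @param config A [study_config()]; the calibration drop height is the
#'   maximum height and the reference energy is
#'   `impact_energy` at that height times 30/39.24 (i.e. 30 J under the
#'   default configuration).
#' @param e_ref Reference absorbed energy in J at which target forces were
#'   read (default 30).
#' @param base_params A [foam_params()] supplying the non-searched fields
#'   (densification onset strain, noise, sampling).
#' @param n_starts Number of multi-start points of the bounded
#'   quasi-Newton search (deterministic grid).
#' @return A [foam_params()] whose searched fields are replaced by the
#'   calibrated values, with attribute `calibration`: a list holding the
#'   achieved objective, the per-target relative errors and the held-out
#'   three-layer validation error.
#' @export
calibrate_defaults <- function(targets, config = study_config(),
                               e_ref = 30, base_params = foam_params(),
                               n_starts = 12L) {
  stopifnot(is.data.frame(targets))
  if (nrow(targets) == 0) stop("empty target table.", call. = FALSE)
  req <- c("n_layers", "repetition", "force_n")
  if (!all(req %in% names(targets))) {
    stop("targets need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  t1 <- dplyr::filter(targets, .data$repetition == 1L)
  if (!all(c(1, 2) %in% t1$n_layers)) {
    stop("targets must contain the 1- and 2-layer repetition-1 forces.",
         call. = FALSE)
  }
  f_tgt <- function(nl) t1$force_n[t1$n_layers == nl][1]
  # per-repetition relative increases, from the increase column when
  # present, otherwise derived from the forces
  inc_tgt <- dplyr::group_by(targets, .data$n_layers)
  inc_tgt <- dplyr::mutate(
    inc_tgt,
    increase = 100 * (.data$force_n /
                        .data$force_n[.data$repetition == 1L][1] - 1)
  )
  inc_tgt <- dplyr::ungroup(inc_tgt)
  if ("increase_pct" %in% names(targets)) {
    inc_tgt$increase <- dplyr::coalesce(targets$increase_pct,
                                        inc_tgt$increase)
  }
  inc_tgt <- dplyr::filter(inc_tgt, .data$repetition > 1L,
                           !is.na(.data$increase), .data$increase != 0)

  h1 <- config$layer_thickness
  m <- config$impactor_mass
  g <- config$gravity
  hd <- max(config$drop_heights)
  eps_d <- base_params$eps_d
  layers <- sort(unique(targets$n_layers))
  n_reps <- max(targets$repetition)

  objective <- function(lp) {
    p <- exp(lp)
    seqs <- lapply(layers, function(nl) {
      static_cycle_seq(p[1], p[2], p[3], p[4], p[5], p[6], p[7], eps_d,
                       nl, h1, m, g, hd, n_reps, target_energy = e_ref)
    })
    if (any(vapply(seqs, is.null, TRUE))) return(1e3)
    names(seqs) <- layers
    val <- 0
    # repetition-1 forces: layers 1 and 2 only (3 layers held out); the
    # single layer anchors the reference energy and is weighted hardest
    val <- val + 300 * ((seqs[["1"]]$f_at_e[1] - f_tgt(1)) / f_tgt(1))^2
    val <- val + 100 * ((seqs[["2"]]$f_at_e[1] - f_tgt(2)) / f_tgt(2))^2
    # relative increases
    for (i in seq_len(nrow(inc_tgt))) {
      nl <- as.character(inc_tgt$n_layers[i])
      r <- inc_tgt$repetition[i]
      if (!nl %in% names(seqs) || r > length(seqs[[nl]]$f_at_e)) next
      inc <- 100 * (seqs[[nl]]$f_at_e[r] / seqs[[nl]]$f_at_e[1] - 1)
      w <- if (r == 2L) 3 else 1
      val <- val + w * ((inc - inc_tgt$increase[i]) / inc_tgt$increase[i])^2
    }
    # monotonicity of the force at the reference energy
    mono <- sum(vapply(seqs, function(s) {
      f <- s$f_at_e
      sum(pmax(0, -diff(f) / f[-length(f)] - 1e-3)^2)
    }, 0))
    # soft envelope: the single-layer first-impact peak at the calibration
    # height should stay near the force threshold (~10 kN)
    pk1 <- seqs[["1"]]$f_peak[1]
    val + 3000 * mono + 1.5 * log(pk1 / config$force_threshold)^2
  }

  lo <- log(c(5, 1.2, 0.01, 1e-4, 1.35, 0.02, 4))
  hi <- log(c(2000, 8, 500, 0.3, 4, 0.45, 60))
  grid <- expand.grid(a = c(120, 400), b = c(3.2, 4.2), c = c(0.5, 8),
                      kap = 0.003, nu = c(1.6, 2.5), del = 0.3,
                      ecap = c(9, 18))
  grid <- grid[seq(1, nrow(grid), length.out = min(n_starts, nrow(grid))), ,
               drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    o <- tryCatch(
      stats::optim(pmin(pmax(log(as.numeric(grid[i, ])), lo), hi), objective,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 600)),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("calibration search failed from all starts.",
                          call. = FALSE)
  p <- exp(best$par)

  fitted <- lapply(layers, function(nl) {
    static_cycle_seq(p[1], p[2], p[3], p[4], p[5], p[6], p[7], eps_d,
                     nl, h1, m, g, hd, n_reps, target_energy = e_ref)
  })
  names(fitted) <- layers
  fitted_f <- lapply(fitted, `[[`, "f_at_e")
  err1 <- fitted_f[["1"]][1] / f_tgt(1) - 1
  err2 <- fitted_f[["2"]][1] / f_tgt(2) - 1
  if (abs(err1) > 0.05 || abs(err2) > 0.05) {
    stop(sprintf(
      paste0("calibration missed the 5%% tolerance on repetition-1 forces ",
             "(1 layer: %+.1f%%, 2 layers: %+.1f%%); widen the search bounds."),
      100 * err1, 100 * err2), call. = FALSE)
  }
  validation3 <- if ("3" %in% names(fitted) && !is.na(f_tgt(3))) {
    fitted_f[["3"]][1] / f_tgt(3) - 1
  } else {
    NA_real_
  }

  out <- base_params
  out$a_f <- p[1]; out$b_f <- p[2]; out$c_d <- p[3]
  out$kappa <- p[4]; out$n_u <- p[5]; out$delta_d <- p[6]
  out$e_cap <- p[7]
  attr(out, "calibration") <- list(
    objective = best$value,
    rep1_error = c(`1` = err1, `2` = err2),
    validation_3layer_error = validation3,
    force_at_eref = fitted_f,
    peak_force = lapply(fitted, `[[`, "f_peak"),
    e_ref = e_ref
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quasi-static loading curve of the foam law
#'
#' Evaluates the loading branch of [foam_force()] on a strain grid and its
#' cumulative absorbed energy for a specimen of `n_layers` layers; useful
#' for inspecting calibrations and as the static reference in tests.
#'
#' @param params A [foam_params()].
#' @param n_layers Layer count.
#' @param config A [study_config()].
#' @param state Optional [foam_state()] (fresh if `NULL`).
#' @param eps_max,n Grid extent and size.
#' @return A tibble: `strain`, `disp_m`, `force_n`, `energy_j`.
#' @export
static_loading_curve <- function(params, n_layers = 1L,
                                 config = study_config(), state = NULL,
                                 eps_max = 0.985, n = 2000) {
  if (is.null(state)) state <- foam_state(params, n_layers, config)
  eps <- seq(0, eps_max, length.out = n)
  force <- foam_force(eps, params, state, phase = "loading")
  h <- state$thickness
  energy <- c(0, cumsum((force[-1] + force[-n]) / 2 * diff(eps))) * h
  tibble::tibble(strain = eps, disp_m = eps * h, force_n = force,
                 energy_j = energy)
}
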
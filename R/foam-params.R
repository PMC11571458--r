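#' Elastoplastic foam material parameters
#'
#' Parameters of the synthetic foam model used by the drop simulator. The
#' loading branch is an exponential stress law with a densification term that
#' switches on above the onset strain `eps_d`; the unloading branch is a
#' power law from the peak down to a plastic set strain. Repetition
#' degradation enters through a stiffness multiplier proportional to the
#' accumulated plastic energy and through the advance of the densification
#' onset by the permanent set.
#'
#' The default values are the package's frozen calibration of the model to
#' the reference forces reached at 30 J on one, two and three layers of an
#' 18-mm cross-linked polyethylene mat (see [calibrate_defaults()] and
#' [ref_force_table()]).
#'
#' @param a_f Stress-scale force in N (> 0).
#' @param b_f Dimensionless exponential strain coefficient (> 0).
#' @param eps_d Densification onset strain in (0, 1); closed cells start to
#'   collapse above roughly 75 % compression.
#' @param c_d Dimensionless densification stiffening coefficient (>= 0).
#' @param n_u Unloading shape exponent (> 1). Its reciprocal is the elastic
#'   fraction of the absorbed energy returned by a fresh specimen, so `n_u`
#'   controls the hysteresis of the cycle.
#' @param kappa Degradation rate in 1/J: a single-layer specimen stiffens by
#'   the factor `1 + kappa * E_P` after accumulating plastic energy `E_P`;
#'   thicker specimens spread the same energy over more material, so their
#'   effective rate is `kappa / n_layers`.
#' @param e_cap Plastic capacity scale in J: the crushable-cell reservoir
#'   depletes as `exp(-E_P / e_cap)`, which makes the degradation saturate
#'   over repetitions.
#' @param delta_d Maximum advance (in strain) of the densification onset:
#'   accumulated crushing brings compaction forward by
#'   `delta_d * (1 - exp(-E_P / e_cap))`.
#' @param specimen_cv Coefficient of variation of `a_f` across specimens
#'   (lognormal, mean-preserving).
#' @param noise_force_sd Gaussian load-cell noise, N.
#' @param noise_disp_sd Gaussian laser-channel noise, m.
#' @param sample_rate Output sampling rate, Hz.
#'
#' @return An object of class `foam_params` (a named list).
#' @export
foam_params <- function(a_f = 178.659,
                        b_f = 4.09316,
                        eps_d = 0.75,
                        c_d = 1.53769,
                        n_u = 1.35,
                        kappa = 1e-4,
                        e_cap = 8.74899,
                        delta_d = 0.288852,
                        specimen_cv = 0.04,
                        noise_force_sd = 25,
                        noise_disp_sd = 5e-5,
                        sample_rate = 10000) {
  stopifnot(
    a_f > 0, b_f > 0, eps_d > 0, eps_d < 1, c_d >= 0, n_u > 1,
    kappa >= 0, e_cap > 0, delta_d >= 0, delta_d < 1, specimen_cv >= 0,
    noise_force_sd >= 0, noise_disp_sd >= 0, sample_rate > 0
  )
  structure(
    list(
      a_f = a_f, b_f = b_f, eps_d = eps_d, c_d = c_d, n_u = n_u,
      kappa = kappa, e_cap = e_cap, delta_d = delta_d,
      specimen_cv = specimen_cv,
      noise_force_sd = noise_force_sd, noise_disp_sd = noise_disp_sd,
      sample_rate = sample_rate
    ),
    class = "foam_params"
  )
}

#' @export
print.foam_params <- function(x, ...) {
  cat("<foam_params>\n")
  cat(sprintf("  loading: a_f = %.4g N, b_f = %.4g, densification c_d = %.4g above strain %.2f\n",
              x$a_f, x$b_f, x$c_d, x$eps_d))
  cat(sprintf("  unloading exponent n_u = %.4g (elastic fraction %.2f)\n",
              x$n_u, 1 / x$n_u))
  cat(sprintf("  degradation: kappa = %.4g /J, onset advance %.3g, capacity %.3g J\n",
              x$kappa, x$delta_d, x$e_cap))
  cat(sprintf("  specimen CV %.3g, noise %.3g N / %.3g mm, %g Hz\n",
              x$specimen_cv, x$noise_force_sd, x$noise_disp_sd * 1000,
              x$sample_rate))
  invisible(x)
}

#' Loading history of a foam specimen
#'
#' Mutable-by-copy record of a specimen's accumulated damage, created fresh
#' per specimen and threaded through its repetitions. The stiffness
#' multiplier is `1 + kappa_eff * cumulative_plastic_energy`, where
#' `kappa_eff = kappa / n_layers` spreads damage over the specimen's
#' material volume.
#'
#' @param params A [foam_params()] object.
#' @param n_layers Number of foam layers in the specimen.
#' @param config A [study_config()]; provides the per-layer thickness.
#' @return An object of class `foam_state` with fields
#'   `cumulative_plastic_energy` (J), `permanent_set` (m),
#'   `stiffness_multiplier` (>= 1), `thickness` (m), `kappa_eff` (1/J) and
#'   `n_cycles`.
#' @export
foam_state <- function(params, n_layers = 1L, config = study_config()) {
  stopifnot(inherits(params, "foam_params"), n_layers >= 1)
  structure(
    list(
      cumulative_plastic_energy = 0,
      permanent_set = 0,
      stiffness_multiplier = 1,
      thickness = n_layers * config$layer_thickness,
      kappa_eff = params$kappa / n_layers,
      n_cycles = 0L
    ),
    class = "foam_state"
  )
}

#' @export
print.foam_state <- function(x, ...) {
  cat(sprintf(
    "<foam_state> %d cycle(s): E_P = %.3g J, set = %.3g mm, stiffness x%.3f\n",
    x$n_cycles, x$cumulative_plastic_energy, x$permanent_set * 1000,
    x$stiffness_multiplier
  ))
  invisible(x)
}

#' Quasi-static force of the foam at a given compression strain
#'
#' Closed-form material law of the simulator. On loading,
#' `F = M a_f (exp(b_f e) - 1) D(e)` where `M` is the state's stiffness
#' multiplier and `D(e) = 1 + c_d max(0, e - eps_d')^2 / (1 - e)` is the
#' densification term; the effective onset `eps_d'` is `eps_d` advanced in
#' proportion to the accumulated plastic energy (saturating on the `e_cap`
#' scale), so a crushed specimen compacts earlier. On
#' unloading, `F = F_peak ((e - e_p) / (e_peak - e_p))^n_u` between the
#' plastic set strain `e_p` and the peak strain, and 0 below `e_p`.
#'
#' @param strain Compression strain x/h in \[0, 1); vectorised.
#' @param params A [foam_params()].
#' @param state A [foam_state()] (fresh state if omitted).
#' @param phase `"loading"` or `"unloading"`.
#' @param peak_context For unloading: a list with `strain_peak`,
#'   `force_peak` and `strain_plastic`.
#' @return Force in N.
#' @export
foam_force <- function(strain, params, state = NULL,
                       phase = c("loading", "unloading"),
                       peak_context = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(params, "foam_params"))
  if (any(strain >= 1)) {
    stop("strain >= 1: full compaction is outside the supported regime.",
         call. = FALSE)
  }
  if (any(strain < 0)) stop("strain must be non-negative.", call. = FALSE)
  if (is.null(state)) state <- foam_state(params)
  if (phase == "loading") {
    onset <- densification_onset(params, state)
    dens <- 1 + params$c_d * pmax(0, strain - onset)^2 / (1 - strain)
    state$stiffness_multiplier * params$a_f *
      (exp(params$b_f * strain) - 1) * dens
  } else {
    if (is.null(peak_context)) {
      stop("unloading requires `peak_context`.", call. = FALSE)
    }
    ep <- peak_context$strain_plastic
    span <- peak_context$strain_peak - ep
    stopifnot(span > 0)
    xi <- pmax(0, (strain - ep) / span)
    ifelse(strain <= ep, 0,
           peak_context$force_peak * pmin(xi, 1)^params$n_u)
  }
}

#' Accumulate plastic damage into a foam state
#'
#' Adds one cycle's plastic energy (and optionally its residual deformation)
#' to the state and recomputes the stiffness multiplier
#' `1 + kappa_eff * cumulative_plastic_energy`.
#'
#' @param state A [foam_state()].
#' @param plastic_energy_increment Plastic energy of the cycle in J (>= 0).
#' @param params A [foam_params()] (kept for interface symmetry; the
#'   effective rate is stored in the state).
#' @param residual_set Residual deformation of the cycle in m (>= 0).
#' @return The updated `foam_state`.
#' @examples
#' s <- foam_state(foam_params(kappa = 0.01), 1)
#' degrade(s, 20, foam_params(kappa = 0.01))$stiffness_multiplier # 1.2
#' @export
degrade <- function(state, plastic_energy_increment, params,
                    residual_set = 0) {
  stopifnot(inherits(state, "foam_state"))
  if (plastic_energy_increment < 0) {
    stop("plastic energy increment must be non-negative.", call. = FALSE)
  }
  if (residual_set < 0) stop("residual set must be non-negative.", call. = FALSE)
  state$cumulative_plastic_energy <-
    state$cumulative_plastic_energy + plastic_energy_increment
  state$stiffness_multiplier <-
    1 + state$kappa_eff * state$cumulative_plastic_energy
  state$permanent_set <- min(state$permanent_set + residual_set,
                             0.95 * state$thickness)
  state$n_cycles <- state$n_cycles + 1L
  state
}

# Elastic fraction of the current cycle: a fresh specimen returns 1/n_u of
# the absorbed energy; as the crushable-cell reservoir depletes the cycle
# becomes more elastic, saturating the degradation across repetitions.
elastic_fraction <- function(params, state) {
  1 - (1 - 1 / params$n_u) *
    exp(-state$cumulative_plastic_energy / params$e_cap)
}

#' Reference forces at 30 J for the Trocellen-type mat
#'
#' Published characterization of the WKF tatami cross-linked polyethylene
#' foam mat in a falling-weight impact test: the force (mean and standard
#' deviation over three specimens) reached at 30 J of absorbed energy at
#' 50-cm drop height, by layer count and repetition, together with the
#' percentage force increase relative to repetition 1. These values are the
#' calibration targets of [calibrate_defaults()].
#'
#' @return A tibble with columns `n_layers`, `repetition`, `force_n`,
#'   `sd_n`, `increase_pct`.
#' @export
ref_force_table <- function() {
  tibble::tibble(
    n_layers = rep(1:3, each = 5),
    repetition = rep(1:5, times = 3),
    force_n = c(10017, 12867, 13642, 13967, 14250,
                3858, 4525, 4683, 4767, 4833,
                2342, 2558, 2608, 2600, 2617),
    sd_n = c(739, 781, 946, 775, 786,
             124, 121, 133, 104, 161,
             20, 38, 38, 0, 29),
    increase_pct = c(NA, 28, 36, 39, 42,
                     NA, 17, 21, 24, 25,
                     NA, 9, 11, 11, 12)
  )
}

#' Reference transfer-function slopes for the Trocellen-type mat
#'
#' Published zero-intercept transfer slopes relating the measured peak force
#' to the undamped force for one, two and three 18-mm layers of the WKF
#' tatami foam mat: the undamped force is about 2.8, 6.1 and 11.1 times the
#' measured force, respectively.
#'
#' @return A tibble with columns `n_layers` and `slope`.
#' @export
ref_transfer_slopes <- function() {
  tibble::tibble(n_layers = 1:3, slope = c(2.8, 6.1, 11.1))
}
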
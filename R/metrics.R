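#' Energy absorbed along the loading curve
#'
#' Total absorbed energy is the area under the loading portion of the
#' displacement-force curve, computed with the trapezoidal rule on the
#' sampled points (no smoothing, unbiased under refinement). Duplicate
#' displacements (ties produced by noise) are dropped keep-first so the
#' cumulative energy is a function of displacement.
#'
#' @param loading A tibble with columns `disp_m` and `force_n` (the loading
#'   portion of a [segment_curve()] result), displacement essentially
#'   non-decreasing: sensor noise may step backwards by a small fraction of
#'   the stroke (`backtrack_tol`), beyond which the curve is rejected.
#' @param backtrack_tol Largest tolerated single backward displacement
#'   step, as a fraction of the displacement range.
#' @return A list with `E` (total energy, J), `cumulative` (a function
#'   displacement (m) -> energy (J), linear interpolation within range),
#'   `inverse` (energy -> displacement), and the monotone sample envelope
#'   `disp`, `force`, `energy`.
#' @examples
#' x <- seq(0, 0.01, length.out = 200)
#' absorbed_energy(tibble::tibble(disp_m = x, force_n = 1e6 * x))$E # ~50 J
#' @export
absorbed_energy <- function(loading, backtrack_tol = 0.02) {
  stopifnot(all(c("disp_m", "force_n") %in% names(loading)))
  keep <- !duplicated(loading$disp_m)
  x <- loading$disp_m[keep]
  f <- loading$force_n[keep]
  if (length(x) < 2) {
    stop("need at least 2 distinct loading points.", call. = FALSE)
  }
  dx <- diff(x)
  rng <- diff(range(x))
  if (any(dx < -backtrack_tol * rng)) {
    stop("loading displacement must be non-decreasing.", call. = FALSE)
  }
  # signed trapezoid in sample order; noise-induced micro-backtracks cancel
  e_cum <- c(0, cumsum(dx * (f[-1] + f[-length(f)]) / 2))
  # monotone envelope: first attainment of each new maximum displacement
  runmax <- cummax(x)
  adv <- x >= runmax & !duplicated(runmax)
  xs <- x[adv]; fs <- f[adv]; es <- cummax(e_cum[adv])
  if (length(xs) < 2) {
    stop("need at least 2 distinct loading points.", call. = FALSE)
  }
  list(
    E = es[length(es)],
    cumulative = stats::approxfun(xs, es, rule = 1, ties = "ordered"),
    inverse = stats::approxfun(es, xs, rule = 1, ties = "ordered"),
    disp = xs, force = fs, energy = es
  )
}

#' Elastic energy released along the unloading curve
#'
#' Area under the unloading portion (taken positive); the energy returned
#' to the impactor as rebound. An empty unloading curve releases nothing.
#'
#' @param unloading A tibble with columns `disp_m` and `force_n`; may be
#'   empty.
#' @return Energy in J.
#' @export
elastic_energy <- function(unloading) {
  if (is.null(unloading) || nrow(unloading) < 2) return(0)
  o <- order(unloading$disp_m)
  x <- unloading$disp_m[o]
  f <- unloading$force_n[o]
  keep <- !duplicated(x)
  x <- x[keep]; f <- f[keep]
  if (length(x) < 2) return(0)
  abs(sum(diff(x) * (f[-1] + f[-length(f)]) / 2))
}

#' Plastic (dissipated) energy of a cycle
#'
#' The energy not returned on unloading, `E_P = E - E_E`, expended in
#' permanent deformation. Tiny negative differences from integration
#' round-off are clipped to zero; larger ones indicate a segmentation or
#' integration fault upstream.
#'
#' @param E Total absorbed energy, J.
#' @param E_E Elastic energy, J.
#' @param tol Clipping tolerance in J.
#' @return Energy in J (>= 0).
#' @export
plastic_energy <- function(E, E_E, tol = 1e-6) {
  stopifnot(E >= 0, E_E >= 0)
  d <- E - E_E
  if (d < -tol) {
    stop(sprintf("elastic energy exceeds total energy by %.3g J.", -d),
         call. = FALSE)
  }
  max(d, 0)
}

#' Energy absorbed when a force threshold is first reached
#'
#' Linearly interpolates the displacement at which the loading force first
#' crosses `threshold` and evaluates the cumulative absorbed energy there.
#'
#' @param loading Loading-portion tibble (`disp_m`, `force_n`).
#' @param threshold Force threshold, N.
#' @return Energy in J, or an error of class `foamimpact_not_reached` if
#'   the loading curve never reaches the threshold.
#' @export
energy_at_force_threshold <- function(loading, threshold) {
  ae <- absorbed_energy(loading)
  f <- ae$force; x <- ae$disp
  if (max(f) < threshold) {
    stop(structure(
      class = c("foamimpact_not_reached", "error", "condition"),
      list(message = sprintf("force threshold %.0f N not reached (max %.0f N).",
                             threshold, max(f)),
           call = NULL)
    ))
  }
  i <- which(f >= threshold)[1]
  if (i == 1L) return(ae$cumulative(x[1]))
  w <- (threshold - f[i - 1]) / (f[i] - f[i - 1])
  x_cross <- x[i - 1] + w * (x[i] - x[i - 1])
  # energy up to the interpolated crossing
  ae$energy[i - 1] + (f[i - 1] + threshold) / 2 * (x_cross - x[i - 1])
}

#' Force at a given absorbed energy
#'
#' Inverts the cumulative-energy function by monotone interpolation and
#' returns the linearly interpolated force at the displacement where
#' `target_energy` has been absorbed.
#'
#' @param loading Loading-portion tibble (`disp_m`, `force_n`).
#' @param target_energy Absorbed energy, J.
#' @return Force in N, or an error of class `foamimpact_not_reached` if the
#'   curve absorbs less than `target_energy` in total.
#' @export
force_at_energy <- function(loading, target_energy) {
  ae <- absorbed_energy(loading)
  if (ae$E < target_energy) {
    stop(structure(
      class = c("foamimpact_not_reached", "error", "condition"),
      list(message = sprintf("energy %.3g J not reached (total %.3g J).",
                             target_energy, ae$E),
           call = NULL)
    ))
  }
  x_t <- ae$inverse(target_energy)
  stats::approx(ae$disp, ae$force, x_t, ties = "ordered")$y
}

#' Energy profile of one segmented curve
#'
#' @param seg A `segmented_curve`.
#' @return A one-row tibble: `E`, `E_E`, `E_P` (J), `peak_force_n`,
#'   `peak_disp_m`.
#' @export
energy_profile <- function(seg) {
  stopifnot(inherits(seg, "segmented_curve"))
  E <- absorbed_energy(seg$loading)$E
  EE <- elastic_energy(seg$unloading)
  tibble::tibble(
    E = E, E_E = EE, E_P = plastic_energy(E, EE, tol = max(1e-6, 0.02 * E)),
    peak_force_n = seg$peak$peak_force,
    peak_disp_m = seg$peak$peak_displacement
  )
}

#' Per-test metrics for a whole simulated dataset
#'
#' Segments every trace and computes peak point and energy decomposition;
#' optionally the force at a reference absorbed energy for the tests that
#' reach it.
#'
#' @param dataset A list as returned by [generate_dataset()] (elements
#'   `traces`, `manifest`).
#' @param e_ref Optional reference energy in J at which to evaluate the
#'   force (`NA` where not reached).
#' @param force_floor,sustain Passed to [extract_contact_window()].
#' @return A tibble: one row per test with the condition columns of the
#'   manifest plus `peak_force_n`, `peak_disp_m`, `E_j`, `EE_j`, `EP_j`
#'   and, when `e_ref` is given, `force_at_eref_n`.
#' @export
compute_metrics <- function(dataset, e_ref = NULL, force_floor = 20,
                            sustain = 5L) {
  traces <- dataset$traces
  manifest <- dataset$manifest
  rows <- purrr::map(seq_along(traces), function(i) {
    seg <- process_trace(traces[[i]], force_floor, sustain)
    prof <- energy_profile(seg)
    out <- tibble::tibble(
      peak_force_n = prof$peak_force_n,
      peak_disp_m = prof$peak_disp_m,
      E_j = prof$E, EE_j = prof$E_E, EP_j = prof$E_P
    )
    if (!is.null(e_ref)) {
      out$force_at_eref_n <- tryCatch(
        force_at_energy(seg$loading, e_ref),
        foamimpact_not_reached = function(e) NA_real_
      )
    }
    out
  })
  dplyr::bind_cols(manifest, dplyr::bind_rows(rows))
}

#' Reference energy of the study
#'
#' The reference energy is the energy absorbed when the force threshold is
#' first reached in the reference tests: single layer, maximum drop height,
#' first repetition. The mean over those specimens is rounded to the
#' nearest joule, mirroring the use of a round reference value in practice.
#'
#' @param metrics_or_dataset Either the metrics tibble (unused here) or the
#'   dataset list from [generate_dataset()]; the traces are needed to
#'   evaluate the crossing.
#' @param config A [study_config()]; supplies the force threshold and the
#'   reference condition.
#' @param force_floor,sustain Passed to [extract_contact_window()].
#' @return Reference energy in J (integer-valued), with attribute
#'   `unrounded`.
#' @export
reference_energy <- function(metrics_or_dataset, config = study_config(),
                             force_floor = 20, sustain = 5L) {
  dataset <- metrics_or_dataset
  stopifnot(is.list(dataset), !is.null(dataset$manifest))
  mf <- dataset$manifest
  ref <- which(
    mf$n_layers == min(config$layer_counts) &
      mf$drop_height == max(config$drop_heights) &
      mf$repetition == 1L
  )
  if (length(ref) == 0) {
    stop("no reference tests (1 layer, max height, repetition 1) present.",
         call. = FALSE)
  }
  vals <- purrr::map_dbl(ref, function(i) {
    seg <- process_trace(dataset$traces[[i]], force_floor, sustain)
    tryCatch(
      energy_at_force_threshold(seg$loading, config$force_threshold),
      foamimpact_not_reached = function(e) NA_real_
    )
  })
  if (all(is.na(vals))) {
    stop("force threshold never reached in any reference test.",
         call. = FALSE)
  }
  m <- mean(vals, na.rm = TRUE)
  structure(round(m), unrounded = m, n = sum(!is.na(vals)))
}
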
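#' Average the two laser displacement channels
#'
#' The rig measures impactor travel with one laser at each end of the
#' horizontal beam; the specimen compression is their element-wise mean,
#' which cancels symmetric noise and beam tilt.
#'
#' @param trace An `impact_trace` (or any data frame with `disp_a_m` and
#'   `disp_b_m` columns of equal length).
#' @return Numeric vector of displacements in m.
#' @export
average_displacement <- function(trace) {
  if (!all(c("disp_a_m", "disp_b_m") %in% names(trace))) {
    stop("trace must contain `disp_a_m` and `disp_b_m`.", call. = FALSE)
  }
  a <- trace$disp_a_m; b <- trace$disp_b_m
  if (length(a) != length(b)) {
    stop("displacement channels differ in length; corrupt trace.",
         call. = FALSE)
  }
  (a + b) / 2
}

#' Extract the contact window of an impact trace
#'
#' Only the portion of the record corresponding to compression and release
#' of the specimen is analysed; everything before first contact and after
#' separation is discarded. The load-cell baseline is estimated as the
#' median force before the first crossing and subtracted. Contact is the
#' first *sustained* excursion above `force_floor` (`sustain` consecutive
#' samples, to reject noise spikes); the window ends at the last sample
#' before the force falls back below the floor after the maximum.
#' Displacement is re-zeroed at the window start, so compression is
#' measured from first contact.
#'
#' @param trace An `impact_trace`.
#' @param force_floor Contact threshold in N, above the noise floor and far
#'   below any signal of interest.
#' @param sustain Number of consecutive above-floor samples that counts as
#'   contact.
#' @return A tibble with columns `time_s`, `disp_m`, `force_n` and
#'   attributes `baseline` (the subtracted force offset in N) and
#'   `disp_offset` (the subtracted displacement at the window start, m).
#' @export
extract_contact_window <- function(trace, force_floor = 20, sustain = 5L) {
  disp <- average_displacement(trace)
  force <- trace$force_n
  n <- length(force)

  above <- force > force_floor
  run <- 0L; start <- NA_integer_
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= sustain) { start <- i - sustain + 1L; break }
  }
  if (is.na(start)) {
    stop("no sustained force excursion above ", force_floor,
         " N: empty or failed test.", call. = FALSE)
  }

  baseline <- if (start > 1) stats::median(force[seq_len(start - 1L)]) else 0
  force <- force - baseline

  i_max <- which.max(force)
  below <- which(force[seq(max(i_max, start), n)] < force_floor)
  end <- if (length(below) == 0) n else max(i_max, start) + min(below) - 2L
  end <- max(end, start)

  idx <- start:end
  out <- tibble::tibble(
    time_s = trace$time_s[idx],
    disp_m = disp[idx] - disp[idx[1]],
    force_n = force[idx]
  )
  attr(out, "baseline") <- baseline
  attr(out, "disp_offset") <- disp[idx[1]]
  attr(out, "condition") <- attr(trace, "condition")
  out
}

#' Segment a contact window into loading and unloading portions
#'
#' The loading portion runs from the start of the curve up to and including
#' the global force maximum. In the remainder, samples whose displacement
#' exceeds the displacement at maximum force (material creep past the peak)
#' are discarded; what is left is the unloading portion. If several samples
#' tie at the global maximum the first is used.
#'
#' @param window A tibble from [extract_contact_window()] (columns
#'   `disp_m`, `force_n`, optionally `time_s`).
#' @return An object of class `segmented_curve`: a list with tibbles
#'   `loading` and `unloading`, one-row tibble `peak` (`peak_force`,
#'   `peak_displacement`), and `discarded_count`.
#' @export
segment_curve <- function(window) {
  stopifnot(all(c("disp_m", "force_n") %in% names(window)),
            nrow(window) >= 1)
  force <- window$force_n
  i_max <- which.max(force)
  if (sum(force == force[i_max]) > 1) {
    warning("multiple samples tie at the global force maximum; ",
            "using the first occurrence.", call. = FALSE)
  }
  x_pk <- window$disp_m[i_max]

  loading <- window[seq_len(i_max), , drop = FALSE]
  rest <- if (i_max < nrow(window)) {
    window[(i_max + 1L):nrow(window), , drop = FALSE]
  } else {
    window[0, , drop = FALSE]
  }
  keep <- rest$disp_m <= x_pk
  structure(
    list(
      loading = tibble::as_tibble(loading),
      unloading = tibble::as_tibble(rest[keep, , drop = FALSE]),
      discarded = tibble::as_tibble(rest[!keep, , drop = FALSE]),
      peak = tibble::tibble(peak_force = force[i_max],
                            peak_displacement = x_pk),
      discarded_count = sum(!keep)
    ),
    class = "segmented_curve"
  )
}

#' @export
print.segmented_curve <- function(x, ...) {
  cat(sprintf(
    "<segmented_curve> peak %.1f N at %.2f mm; %d loading / %d unloading / %d discarded samples\n",
    x$peak$peak_force, x$peak$peak_displacement * 1000,
    nrow(x$loading), nrow(x$unloading), x$discarded_count
  ))
  invisible(x)
}

#' Tidy a segmented curve into one long tibble
#'
#' @param x A `segmented_curve`.
#' @param ... Unused.
#' @return A tibble with columns `disp_m`, `force_n`, `phase`
#'   (`loading` / `unloading` / `discarded`).
#' @method tidy segmented_curve
#' @export
tidy.segmented_curve <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$loading, phase = "loading"),
    dplyr::mutate(x$unloading, phase = "unloading"),
    dplyr::mutate(x$discarded, phase = "discarded")
  )
}

#' Process a raw trace into a segmented displacement-force curve
#'
#' Convenience wrapper: channel averaging, contact-window extraction and
#' curve segmentation in one call.
#'
#' @inheritParams extract_contact_window
#' @return A `segmented_curve`.
#' @export
process_trace <- function(trace, force_floor = 20, sustain = 5L) {
  seg <- segment_curve(extract_contact_window(trace, force_floor, sustain))
  attr(seg, "condition") <- attr(trace, "condition")
  seg
}
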
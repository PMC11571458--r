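#' Study configuration for a falling-weight impact experiment
#'
#' Bundles the physical constants and the factorial design of the drop-test
#' study: an 8-kg impactor released from three heights onto specimens built
#' from one, two or three 18-mm foam layers. The standard block tests three
#' specimens per (height, layers) cell for three repetitions; an extra block
#' adds, for the highest drop only, three further specimens per layer count
#' tested for five repetitions, which feed the repeated-loading analysis.
#'
#' @param impactor_mass Impactor mass in kg.
#' @param gravity Gravitational acceleration in m/s^2.
#' @param drop_heights Drop heights in m.
#' @param layer_counts Numbers of foam layers per specimen (distinct positive
#'   integers).
#' @param layer_thickness Thickness of a single foam layer in m.
#' @param specimen_diameter Specimen diameter in m (recorded for provenance;
#'   the material law is per-specimen, not per-area).
#' @param specimens_per_condition Specimens tested in each (height, layers)
#'   cell of the standard block.
#' @param repetitions_standard Repetitions per specimen in the standard block.
#' @param extra_specimens_50cm Additional specimens per layer count tested at
#'   the highest drop height only.
#' @param repetitions_extra Repetitions per specimen in the extra block.
#' @param significance_level Alpha used by the statistical module.
#' @param force_threshold Force threshold in N defining the reference energy.
#' @param seed Integer seed used when the configuration drives simulation.
#'
#' @return An object of class `study_config` (a named list).
#' @examples
#' cfg <- study_config()
#' enumerate_design(cfg)
#' @export
study_config <- function(impactor_mass = 8,
                         gravity = 9.81,
                         drop_heights = c(0.15, 0.25, 0.50),
                         layer_counts = c(1L, 2L, 3L),
                         layer_thickness = 0.018,
                         specimen_diameter = 0.074,
                         specimens_per_condition = 3L,
                         repetitions_standard = 3L,
                         extra_specimens_50cm = 3L,
                         repetitions_extra = 5L,
                         significance_level = 0.05,
                         force_threshold = 10000,
                         seed = 1L) {
  stopifnot(
    impactor_mass > 0, gravity > 0, layer_thickness > 0,
    specimen_diameter > 0,
    all(drop_heights > 0) || length(drop_heights) == 0,
    all(layer_counts > 0), !anyDuplicated(layer_counts),
    layer_counts == as.integer(layer_counts),
    repetitions_standard >= 1, repetitions_extra >= 1,
    specimens_per_condition >= 0, extra_specimens_50cm >= 0,
    significance_level > 0, significance_level < 1,
    force_threshold > 0
  )
  structure(
    list(
      impactor_mass = impactor_mass,
      gravity = gravity,
      drop_heights = drop_heights,
      layer_counts = as.integer(layer_counts),
      layer_thickness = layer_thickness,
      specimen_diameter = specimen_diameter,
      specimens_per_condition = as.integer(specimens_per_condition),
      repetitions_standard = as.integer(repetitions_standard),
      extra_specimens_50cm = as.integer(extra_specimens_50cm),
      repetitions_extra = as.integer(repetitions_extra),
      significance_level = significance_level,
      force_threshold = force_threshold,
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  d <- enumerate_design(x)
  cat("<study_config>\n")
  cat(sprintf("  impactor: %.3g kg, g = %.3g m/s^2\n", x$impactor_mass, x$gravity))
  cat(sprintf("  drop heights: %s m\n", paste(x$drop_heights, collapse = ", ")))
  cat(sprintf("  layers: %s x %.0f mm\n", paste(x$layer_counts, collapse = ", "),
              x$layer_thickness * 1000))
  cat(sprintf("  design: %d specimens, %d tests\n",
              attr(d, "n_specimens"), nrow(d)))
  invisible(x)
}

#' Serialize / read a study configuration
#'
#' The configuration round-trips through a flat key-value YAML file with keys
#' named exactly as the `study_config()` arguments, all values in SI units.
#'
#' @param config A `study_config`.
#' @param path File path.
#' @return `write_study_config()` returns `path` invisibly;
#'   `read_study_config()` returns a `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals)
}

#' Enumerate every individual test of the design
#'
#' Expands the factorial design into one row per (specimen, repetition).
#' The standard block crosses drop heights, layer counts and specimens at
#' `repetitions_standard` repetitions; the extra block adds
#' `extra_specimens_50cm` specimens per layer count at the maximum drop
#' height for `repetitions_extra` repetitions. Specimen identifiers are
#' deterministic strings built from (height, layers, index) so reruns are
#' reproducible. With the defaults this yields 36 specimens and 126 tests.
#'
#' @param config A `study_config`.
#' @return A tibble with columns `drop_height`, `n_layers`, `specimen_id`,
#'   `repetition` and `block` (`"standard"` or `"extra"`); the number of
#'   distinct specimens is attached as attribute `n_specimens`.
#' @examples
#' nrow(enumerate_design(study_config())) # 126
#' @export
enumerate_design <- function(config) {
  stopifnot(inherits(config, "study_config"))
  spec_id <- function(h, l, i, block) {
    sprintf("%s%.0fcm_L%d_S%d", if (block == "extra") "X" else "", h * 100, l, i)
  }
  std <- tidyr::expand_grid(
    drop_height = config$drop_heights,
    n_layers = config$layer_counts,
    specimen = seq_len(config$specimens_per_condition),
    repetition = seq_len(config$repetitions_standard)
  )
  std$block <- "standard"
  if (length(config$drop_heights) > 0 && config$extra_specimens_50cm > 0) {
    extra <- tidyr::expand_grid(
      drop_height = max(config$drop_heights),
      n_layers = config$layer_counts,
      specimen = seq_len(config$extra_specimens_50cm),
      repetition = seq_len(config$repetitions_extra)
    )
    extra$block <- "extra"
  } else {
    extra <- std[0, ]
  }
  out <- dplyr::bind_rows(std, extra)
  out <- dplyr::mutate(
    out,
    specimen_id = mapply(spec_id, .data$drop_height, .data$n_layers,
                         .data$specimen, .data$block)
  )
  out <- dplyr::select(out, "drop_height", "n_layers", "specimen_id",
                       "repetition", "block")
  out <- tibble::as_tibble(out)
  attr(out, "n_specimens") <- length(unique(out$specimen_id))
  out
}

#' Impact velocity of a free-falling impactor
#'
#' Contact speed after a free fall from `drop_height`, `sqrt(2 g h)`.
#' A 0.15-m drop gives 1.7 m/s (to one decimal).
#'
#' @param drop_height Drop height in m (vectorised, must be >= 0).
#' @param gravity Gravitational acceleration in m/s^2.
#' @return Speed in m/s.
#' @examples
#' impact_velocity(0.15) # ~1.72
#' @export
impact_velocity <- function(drop_height, gravity = 9.81) {
  if (any(drop_height < 0)) {
    stop("`drop_height` must be non-negative.", call. = FALSE)
  }
  sqrt(2 * gravity * drop_height)
}

#' Gravitational potential energy of the drop
#'
#' Impact energy `m g h` delivered by a mass falling from `drop_height`.
#'
#' @param mass Impactor mass in kg (> 0).
#' @param drop_height Drop height in m (>= 0).
#' @param gravity Gravitational acceleration in m/s^2.
#' @return Energy in J.
#' @examples
#' impact_energy(8, 0.50) # 39.24 J
#' @export
impact_energy <- function(mass, drop_height, gravity = 9.81) {
  if (any(mass <= 0)) stop("`mass` must be positive.", call. = FALSE)
  if (any(drop_height < 0)) {
    stop("`drop_height` must be non-negative.", call. = FALSE)
  }
  mass * gravity * drop_height
}
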
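#' Percentage force increase relative to the first repetition
#'
#' @param means Vector of per-repetition mean forces (repetition 1 first,
#'   `means[1] > 0`).
#' @param digits Rounding for reporting; `NULL` leaves values unrounded.
#' @return Percentages, first element 0.
#' @examples
#' force_increase_table(c(10017, 12867)) # 0 28
#' @export
force_increase_table <- function(means, digits = 0) {
  if (means[1] <= 0) stop("baseline mean must be positive.", call. = FALSE)
  pct <- 100 * (means / means[1] - 1)
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] guarding its 3 <= n <= 50
#' support and degenerate (constant) samples.
#'
#' @param sample Numeric vector of forces.
#' @return A tibble with `W` and `p_value`.
#' @export
shapiro_wilk <- function(sample) {
  n <- length(sample)
  if (n < 3 || n > 50) {
    stop("Shapiro-Wilk requires 3 <= n <= 50.", call. = FALSE)
  }
  if (stats::sd(sample) == 0) {
    stop("constant sample: normality test is degenerate.", call. = FALSE)
  }
  sw <- stats::shapiro.test(sample)
  tibble::tibble(W = unname(sw$statistic), p_value = sw$p.value)
}

#' One-way repeated-measures ANOVA on a force matrix
#'
#' Within-subject one-way ANOVA: specimens are subjects, repetitions the
#' within factor. The subject effect is removed and
#' `F = MS_treatment / MS_error`; the effect size is
#' `eta^2 = SS_treatment / (SS_treatment + SS_error)`. Computed via
#' [stats::aov()] with an `Error(specimen)` stratum. Sphericity is neither
#' tested nor corrected.
#'
#' @param force_matrix Numeric matrix, specimens x repetitions, complete.
#' @return A tibble with `F`, `p_value`, `eta_squared`, `df1`, `df2`.
#' @export
rm_anova <- function(force_matrix) {
  fm <- as.matrix(force_matrix)
  if (any(!is.finite(fm))) stop("force matrix has missing cells.", call. = FALSE)
  if (nrow(fm) < 2 || ncol(fm) < 2) {
    stop("need >= 2 specimens and >= 2 repetitions.", call. = FALSE)
  }
  d <- tibble::tibble(
    specimen = factor(rep(seq_len(nrow(fm)), times = ncol(fm))),
    repetition = factor(rep(seq_len(ncol(fm)), each = nrow(fm))),
    force = as.vector(fm)
  )
  fit <- stats::aov(force ~ repetition + Error(specimen), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_treat <- tab["repetition", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  tibble::tibble(
    F = tab["repetition", "F value"],
    p_value = tab["repetition", "Pr(>F)"],
    eta_squared = ss_treat / (ss_treat + ss_err),
    df1 = tab["repetition", "Df"],
    df2 = tab["Residuals", "Df"]
  )
}

#' One-sided post hoc paired t tests between consecutive repetitions
#'
#' For each consecutive pair (r vs r-1) a paired t test with alternative
#' "repetition r exceeds repetition r-1" (stiffening under repeated
#' loading raises the force at a given absorbed energy). P values are
#' reported raw, without multiplicity correction. Pairs whose differences
#' are constant (zero variance) are degenerate and flagged with `NA`.
#'
#' @param force_matrix Numeric matrix, specimens x repetitions.
#' @return A tibble with `comparison`, `t`, `p_value`, `mean_diff_n`.
#' @examples
#' m <- cbind(c(10, 11, 9), c(12, 13.1, 10.9))
#' posthoc_consecutive_t(m)
#' @export
posthoc_consecutive_t <- function(force_matrix) {
  fm <- as.matrix(force_matrix)
  if (ncol(fm) < 2) stop("need at least 2 repetitions.", call. = FALSE)
  purrr::map_dfr(2:ncol(fm), function(r) {
    d <- fm[, r] - fm[, r - 1]
    if (stats::sd(d) == 0) {
      warning(sprintf(
        "repetitions %d vs %d: constant paired differences; t undefined.",
        r, r - 1), call. = FALSE)
      return(tibble::tibble(
        comparison = sprintf("%d vs %d", r, r - 1),
        t = NA_real_, p_value = NA_real_, mean_diff_n = mean(d)
      ))
    }
    tt <- stats::t.test(fm[, r], fm[, r - 1], paired = TRUE,
                        alternative = "greater")
    tibble::tibble(
      comparison = sprintf("%d vs %d", r, r - 1),
      t = unname(tt$statistic),
      p_value = tt$p.value,
      mean_diff_n = mean(d)
    )
  })
}

#' Repeated-loading summary per layer count
#'
#' Assembles, for each layer count, the specimens x repetitions matrix of
#' forces at the reference energy from the five-repetition block at the
#' maximum drop height, and computes the summary statistics of the
#' repeated-loading analysis: per-repetition means and SDs, percentage
#' increases over repetition 1 (from unrounded means; rounded only for
#' reporting), per-cell Shapiro-Wilk normality, the repeated-measures
#' ANOVA, and the one-sided consecutive post hoc t tests.
#'
#' @param metrics Per-test metrics tibble from [compute_metrics()]
#'   including a `force_at_eref_n` column.
#' @param e_ref Reference energy (J), recorded in the result.
#' @param config A [study_config()].
#' @return A list of `repeated_loading_result` objects, one per layer
#'   count, each with fields `n_layers`, `e_ref`, `force_matrix`,
#'   `summary` (tibble: repetition, mean_n, sd_n, increase_pct,
#'   shapiro_p, p_value), `anova` (tibble from [rm_anova()]), `posthoc`.
#' @export
build_table1 <- function(metrics, e_ref, config = study_config()) {
  block <- dplyr::filter(
    metrics,
    .data$block == "extra",
    .data$drop_height == max(config$drop_heights)
  )
  if (nrow(block) == 0) {
    stop("no extra five-repetition block at the maximum drop height.",
         call. = FALSE)
  }
  missing <- dplyr::filter(block, is.na(.data$force_at_eref_n))
  if (nrow(missing) > 0) {
    stop("reference energy not reached in: ",
         paste(sprintf("%s R%d", missing$specimen_id, missing$repetition),
               collapse = ", "), call. = FALSE)
  }
  by_layer <- split(block, block$n_layers)
  purrr::map(by_layer, function(d) {
    wide <- tidyr::pivot_wider(
      d[c("specimen_id", "repetition", "force_at_eref_n")],
      names_from = "repetition", values_from = "force_at_eref_n"
    )
    fm <- as.matrix(wide[-1])
    rownames(fm) <- wide$specimen_id
    if (any(!is.finite(fm))) {
      stop("incomplete force matrix for layer ", d$n_layers[1], call. = FALSE)
    }
    means <- colMeans(fm)
    n_rep <- ncol(fm)
    shapiro_p <- apply(fm, 2, function(col) {
      tryCatch(shapiro_wilk(col)$p_value, error = function(e) NA_real_)
    })
    anova <- if (n_rep >= 2) rm_anova(fm) else NULL
    posthoc <- if (n_rep >= 2) posthoc_consecutive_t(fm) else NULL
    structure(
      list(
        n_layers = d$n_layers[1],
        e_ref = e_ref,
        force_matrix = fm,
        summary = tibble::tibble(
          repetition = seq_len(n_rep),
          mean_n = unname(means),
          sd_n = unname(apply(fm, 2, stats::sd)),
          increase_pct = unname(force_increase_table(means, digits = NULL)),
          shapiro_p = unname(shapiro_p),
          p_value = c(NA_real_, if (!is.null(posthoc)) posthoc$p_value)
        ),
        anova = anova,
        posthoc = posthoc
      ),
      class = "repeated_loading_result"
    )
  })
}

#' @export
print.repeated_loading_result <- function(x, ...) {
  cat(sprintf("<repeated_loading_result> %d layer(s), E_ref = %.0f J\n",
              x$n_layers, x$e_ref))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  rep %d: %5.0f +/- %4.0f N  %+3.0f%%  %s\n",
                s$repetition[i], s$mean_n[i], s$sd_n[i],
                round(s$increase_pct[i]),
                if (is.na(s$p_value[i])) "" else sprintf("p = %.3g", s$p_value[i])))
  }
  if (!is.null(x$anova)) {
    cat(sprintf("  RM-ANOVA: F(%d,%d) = %.2f, p = %.3g, eta^2 = %.3f\n",
                x$anova$df1, x$anova$df2, x$anova$F, x$anova$p_value,
                x$anova$eta_squared))
  }
  invisible(x)
}

#' @method tidy repeated_loading_result
#' @export
tidy.repeated_loading_result <- function(x, ...) {
  dplyr::mutate(x$summary, n_layers = x$n_layers, .before = 1)
}

#' @method glance repeated_loading_result
#' @export
glance.repeated_loading_result <- function(x, ...) {
  tibble::tibble(n_layers = x$n_layers, e_ref = x$e_ref,
                 F = x$anova$F, p_value = x$anova$p_value,
                 eta_squared = x$anova$eta_squared)
}
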
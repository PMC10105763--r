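#' Tidy a method-comparison regression
#'
#' @param x An `lsfg_regression` from [fit_line()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @export
tidy.lsfg_regression <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(s[, 1]), std.error = unname(s[, 2]),
                 statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @rdname tidy.lsfg_regression
#' @export
glance.lsfg_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, residual_sd = x$residual_sd,
                 n = x$n)
}

#' Tidy a bias experiment
#'
#' @param x An `lsfg_bias_experiment` from [bias_experiment()].
#' @param ... Unused.
#' @return `tidy()`: the per-replicate tibble (`bom_rb`, `bom_sp`, `diff`).
#'   `glance()`: one row with `mean_diff`, the one-sided sign-test
#'   `p_value`, and the configuration.
#' @export
tidy.lsfg_bias_experiment <- function(x, ...) {
  x$replicates
}

#' @rdname tidy.lsfg_bias_experiment
#' @export
glance.lsfg_bias_experiment <- function(x, ...) {
  safe_cov <- function(v) if (mean(v) > 0) coefficient_of_variation(v)
                          else NA_real_
  tibble::tibble(n_replicates = x$n_replicates,
                 noise_shape = x$noise_shape, S = x$S,
                 mean_diff = x$mean_diff, p_value = x$p_value,
                 cov_rb = safe_cov(x$replicates$bom_rb),
                 cov_sp = safe_cov(x$replicates$bom_sp))
}

#' Tidy a waveform result
#'
#' @param x An `lsfg_waveform` from [bom()].
#' @param ... Unused.
#' @return A one-row tibble with `mbr_avg`, `bs`, `bom`, `peak_freq_hz`,
#'   `C` and the band limits.
#' @export
tidy.lsfg_waveform <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}
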
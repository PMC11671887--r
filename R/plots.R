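#' Plot an intensity-pattern profile
#'
#' Shows, per intensity bin, either the standardised contribution
#' (square-root selectivity fraction) or the unstandardised pattern
#' (multivariate covariance, min/day units) of the activity composite, with
#' percentile bootstrap ribbons when available.
#'
#' @param object A [pattern_profile()] result.
#' @param type `"sqrt_selectivity"` or `"mv_covariance"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pls_pattern <- function(object,
                                 type = c("sqrt_selectivity", "mv_covariance"),
                                 ...) {
  type <- match.arg(type)
  df <- as_tibble(object)
  df$indicator <- factor(df$indicator, levels = df$indicator)
  df$value <- df[[type]]
  lab <- if (type == "sqrt_selectivity") {
    "Square-root selectivity fraction"
  } else {
    "Multivariate covariance (min/day)"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$indicator, y = .data$value,
                                        group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Intensity bin", y = lab,
                  title = sprintf("Activity pattern of construct `%s`",
                                  attr(object, "construct"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  lo <- paste0(type, "_low"); hi <- paste0(type, "_high")
  if (all(c(lo, hi) %in% names(df))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[lo]], ymax = .data[[hi]]), alpha = 0.2
    )
  }
  p
}

#' Plot the structural path coefficients of a fit
#'
#' @param object A `pls_sem` fit.
#' @param ... Unused.
#' @return A ggplot object (point estimates with bootstrap intervals when
#'   present).
#' @export
autoplot.pls_sem <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                        y = stats::reorder(.data$term,
                                                           .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Standardised path coefficient", y = NULL) +
    ggplot2::theme_minimal()
  if (all(c("conf.low", "conf.high") %in% names(df))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    )
  }
  p
}

#' Plot cohort-mean minutes per day across the intensity spectrum
#'
#' @param spectrum A spectrum table ([summarize_days()] schema).
#' @param log_scale Use a log10 y axis (the upper bins hold very few
#'   minutes).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, log_scale = TRUE) {
  bins <- intersect(pa_block(), names(spectrum))
  df <- spectrum |>
    select(all_of(bins)) |>
    summarise(across(everything(), ~ mean(.x, na.rm = TRUE))) |>
    tidyr::pivot_longer(everything(), names_to = "bin", values_to = "min_day")
  df$bin <- factor(df$bin, levels = bins)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$min_day)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Intensity bin", y = "Minutes per day (cohort mean)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}
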
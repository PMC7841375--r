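#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a kinematic series
#'
#' One panel per axis against time.
#'
#' @param object a [kin_series()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kin_series <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("x", "y", "z"),
                            names_to = "axis", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = object$kind)
}

#' Plot a SPARC spectrum with its adaptive cut-off
#'
#' @param object a `sparc_result` from [sparc()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sparc_result <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$freq_hz, y = .data$magnitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$omega_c / (2 * pi),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "frequency [Hz]", y = "normalised magnitude",
      title = sprintf("SPARC = %.3f (cut-off %.2f Hz)",
                      object$sal, object$omega_c / (2 * pi))
    )
}

#' Scatter of reconstructed vs. true smoothness
#'
#' One point per grid record with the identity line; the departure from
#' `y = x` visualises how orientation reconstruction error corrupts each
#' measure.
#'
#' @param records a tibble from [run_grid()].
#' @param measure one of `"sparc"`, `"ldljv"`, `"ldlja"`.
#' @return a ggplot object.
#' @export
plot_true_vs_recon <- function(records, measure = c("ldlja", "ldljv", "sparc")) {
  measure <- match.arg(measure)
  col <- c(sparc = "sal", ldljv = "ldljv", ldlja = "ldlja")[[measure]]
  df <- tibble::tibble(
    true = records[[paste0(col, "_true")]],
    recon = records[[paste0(col, "_recon")]],
    theta_max_deg = factor(records$theta_max_deg)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$recon,
                                   colour = .data$theta_max_deg)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "true smoothness", y = "reconstructed smoothness",
                  colour = expression(theta[max] * " [deg]"),
                  title = toupper(gsub("ldlj", "LDLJ-", measure)))
}

#' Plot an SGR threshold sweep
#'
#' Correlation and mean absolute relative error per smoothness measure as a
#' function of the SGR threshold.
#'
#' @param object an `sgr_correlation` from [correlation_analysis()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sgr_correlation <- function(object, ...) {
  df <- tidyr::pivot_longer(object$by_threshold,
                            c("r", "mean_abs_rel_error"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "SGR threshold", y = NULL)
}

#' Bland-Altman plot of an agreement analysis
#'
#' @param object an `agreement` from [agreement_analysis()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.agreement <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean, y = .data$diff_pct)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$bias_pct, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower_pct,
                                       object$loa_upper_pct),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "mean of paired values",
                  y = "difference [% of reference]")
}

#' @importFrom rlang .data
NULL
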
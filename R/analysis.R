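#' Signed relative error between smoothness values
#'
#' `epsilon = (lambda_hat - lambda) / |lambda|`. Smoothness values are
#' negative, so a positive epsilon means the reconstruction *overestimates*
#' smoothness (is closer to zero than the truth).
#'
#' @param lambda_hat reconstructed smoothness value(s).
#' @param lambda_true true smoothness value(s), nonzero.
#' @return numeric vector of relative errors.
#' @examples
#' relative_error(-2, -4)  # 0.5: overestimated smoothness
#' @export
relative_error <- function(lambda_hat, lambda_true) {
  if (any(lambda_true == 0)) {
    stop("relative error is undefined for a zero true value", call. = FALSE)
  }
  (lambda_hat - lambda_true) / abs(lambda_true)
}

#' Percentage errors in the jerk integral and acceleration peak
#'
#' The two terms of LDLJ-A compared between a reconstructed and a true
#' acceleration signal on the same clock:
#' `100 (Ij_hat - Ij) / Ij` for the integrated squared jerk magnitude and
#' `100 (a_peak_hat - a_peak) / a_peak` for the peak of the mean-subtracted
#' acceleration norm. A constant reconstruction bias (e.g. a fixed
#' orientation offset acting on gravity) leaves the jerk term untouched but
#' inflates the peak term.
#'
#' @param recon,truth [kin_series()] of kind `acceleration` with matching
#'   `N` and `fs`.
#' @return a one-row tibble with `jerk_error_pct` and `accl_peak_error_pct`.
#' @export
jerk_and_peak_errors <- function(recon, truth) {
  stopifnot(inherits(recon, "kin_series"), inherits(truth, "kin_series"))
  if (n_samples(recon) != n_samples(truth) || recon$fs != truth$fs) {
    stop("reconstructed and true series must share N and fs", call. = FALSE)
  }
  term <- function(a) {
    fs <- a$fs
    dur <- duration(a)
    abar <- apply(a$values, 2L, function(col) .trapz(col, fs)) / dur
    centred <- sweep(a$values, 2L, abar)
    list(
      ij = .trapz(norm_series(differentiate(a))^2, fs),
      peak = max(sqrt(rowSums(centred^2)))
    )
  }
  r <- term(recon)
  t <- term(truth)
  tibble::tibble(
    jerk_error_pct = 100 * (r$ij - t$ij) / t$ij,
    accl_peak_error_pct = 100 * (r$peak - t$peak) / t$peak
  )
}

#' True-vs-reconstructed correlation across SGR thresholds
#'
#' For each sensor-to-gravity-ratio threshold, restricts the grid records to
#' `sgr >= threshold` and computes, per smoothness measure, the Pearson
#' correlation between true and reconstructed values together with the mean
#' (and mean absolute) relative error. A second table stratifies the
#' correlations by movement duration and orientation error magnitude.
#' Thresholds whose subset holds fewer than 3 records are skipped with a
#' warning; non-finite pairs are excluded and counted.
#'
#' @param records a tibble from [run_grid()].
#' @param sgr_thresholds numeric thresholds to sweep.
#' @return a list of class `sgr_correlation` with tibbles `by_threshold`
#'   (`threshold`, `measure`, `n`, `r`, `mean_rel_error`,
#'   `mean_abs_rel_error`) and `by_condition` (`duration_s`,
#'   `theta_max_deg`, `measure`, `n`, `r`).
#' @export
correlation_analysis <- function(records,
                                 sgr_thresholds = c(1, 1.05, 1.1, 1.2,
                                                    1.5, 1.75, 2, 2.5)) {
  measures <- c(sparc = "sal", ldljv = "ldljv", ldlja = "ldlja")
  one <- function(df, measure, col) {
    tv <- df[[paste0(col, "_true")]]
    rv <- df[[paste0(col, "_recon")]]
    eps <- df[[paste0("rel_error_", measure)]]
    ok <- is.finite(tv) & is.finite(rv)
    tibble::tibble(
      measure = measure, n = sum(ok),
      r = if (sum(ok) >= 3L && stats::sd(tv[ok]) > 0 && stats::sd(rv[ok]) > 0) {
        stats::cor(tv[ok], rv[ok])
      } else NA_real_,
      mean_rel_error = mean(eps[ok]),
      mean_abs_rel_error = mean(abs(eps[ok]))
    )
  }
  by_threshold <- purrr::map_dfr(sgr_thresholds, function(thr) {
    sub <- dplyr::filter(records, .data$sgr >= thr)
    if (nrow(sub) < 3L) {
      warning(sprintf(
        "SGR threshold %g skipped: only %d record(s)", thr, nrow(sub)
      ), call. = FALSE)
      return(tibble::tibble())
    }
    dplyr::bind_cols(
      tibble::tibble(threshold = thr),
      purrr::map2_dfr(names(measures), unname(measures),
                      function(m, col) one(sub, m, col))
    )
  })
  by_condition <- records |>
    dplyr::group_by(.data$duration_s, .data$theta_max_deg) |>
    dplyr::group_modify(function(df, key) {
      purrr::map2_dfr(names(measures), unname(measures),
                      function(m, col) one(df, m, col))
    }) |>
    dplyr::ungroup()
  structure(
    list(by_threshold = by_threshold, by_condition = by_condition),
    class = "sgr_correlation"
  )
}

#' @export
print.sgr_correlation <- function(x, ...) {
  cat("<sgr_correlation>\nBy SGR threshold:\n")
  print(x$by_threshold, n = Inf)
  cat("\nBy duration x orientation error:\n")
  print(x$by_condition, n = Inf)
  invisible(x)
}

#' @rdname correlation_analysis
#' @param x an `sgr_correlation` object.
#' @param ... unused.
#' @export
tidy.sgr_correlation <- function(x, ...) x$by_threshold

#' Bland-Altman agreement between two smoothness estimates
#'
#' Quantifies the agreement of paired smoothness values from two measurement
#' routes (e.g. motion capture vs. IMU) as percentage differences relative to
#' the reference: `d_i = 100 (b_i - a_i) / a_i`. Reports the mean bias, the
#' 95% limits of agreement `bias +/- 1.96 sd(d)` and 95% confidence
#' intervals for all three (normal-theory standard errors,
#' `se(bias) = sd/sqrt(n)`, `se(limit) = sd sqrt(3/n)`).
#'
#' @param values_a reference values (must be nonzero), length >= 3.
#' @param values_b comparison values, same length.
#' @return a one-row tibble of class `agreement` with columns `n`,
#'   `bias_pct`, `bias_lo`, `bias_hi`, `loa_lower_pct`, `loa_lower_lo`,
#'   `loa_lower_hi`, `loa_upper_pct`, `loa_upper_lo`, `loa_upper_hi`,
#'   `sd_pct`; the per-pair differences are attached as attribute `pairs`
#'   (tibble with `mean` and `diff_pct`).
#' @examples
#' a <- c(-5, -4.5, -6, -5.2)
#' agreement_analysis(a, 1.1 * a)  # uniform +10% difference
#' @export
agreement_analysis <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 3L)
  if (any(values_a == 0)) {
    stop("reference values must be nonzero", call. = FALSE)
  }
  d <- 100 * (values_b - values_a) / values_a
  n <- length(d)
  bias <- mean(d)
  s <- stats::sd(d)
  tcrit <- stats::qt(0.975, n - 1L)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  lower <- bias - 1.96 * s
  upper <- bias + 1.96 * s
  out <- tibble::tibble(
    n = n, bias_pct = bias,
    bias_lo = bias - tcrit * se_bias, bias_hi = bias + tcrit * se_bias,
    loa_lower_pct = lower,
    loa_lower_lo = lower - tcrit * se_loa, loa_lower_hi = lower + tcrit * se_loa,
    loa_upper_pct = upper,
    loa_upper_lo = upper - tcrit * se_loa, loa_upper_hi = upper + tcrit * se_loa,
    sd_pct = s
  )
  attr(out, "pairs") <- tibble::tibble(
    mean = (values_a + values_b) / 2, diff_pct = d
  )
  class(out) <- c("agreement", class(out))
  out
}
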
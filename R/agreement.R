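#' Intraclass correlation coefficient for method agreement
#'
#' Single-measure ICC from a two-way ANOVA decomposition of an n-subject x
#' k-method table. The default form is absolute agreement in a two-way
#' model — ICC(A,1) in the McGraw & Wong taxonomy — which penalises
#' systematic differences between methods and is the standard choice for
#' method-comparison studies; `form = "consistency"` gives ICC(C,1).
#' Confidence limits use the F-based interval with Satterthwaite degrees
#' of freedom for the agreement form; the p-value tests ICC = 0 via
#' F = MS_rows / MS_error.
#'
#' @param pairs Data frame (or matrix) whose first two numeric columns are
#'   the paired measurements; extra columns (e.g. `id`) are ignored.
#' @param form `"agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An `avc_icc`: `estimate`, `conf_low`, `conf_high`, `p_value`,
#'   `statistic` (F), `form`, `n`.
#' @examples
#' icc(make_agreement_cohort(n = 20, icc = 0.9, seed = 7)[c("a", "b")])
#' @export
icc <- function(pairs, form = c("agreement", "consistency"),
                conf_level = 0.95) {
  form <- match.arg(form)
  m <- agreement_matrix(pairs)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5) abort("ICC needs at least 5 subject pairs.")
  if (all(m == m[1, 1])) abort("ICC undefined: measurements have zero total variance.")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  alpha <- 1 - conf_level
  if (form == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    fl <- f_obs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f_obs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse == 0 && msc == 0) {
      # perfect agreement: the interval degenerates to the point estimate
      return(structure(
        list(estimate = est, conf_low = est, conf_high = est,
             p_value = 0, statistic = Inf, form = form,
             conf_level = conf_level, n = n, k = k,
             ms = c(rows = msr, cols = msc, error = mse)),
        class = "avc_icc"
      ))
    }
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    f_obs <- msr / mse
  }
  p <- pf(f_obs, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(
    list(estimate = est, conf_low = lo, conf_high = hi,
         p_value = p, statistic = f_obs, form = form,
         conf_level = conf_level, n = n, k = k,
         ms = c(rows = msr, cols = msc, error = mse)),
    class = "avc_icc"
  )
}

# first two numeric columns of a pairs table, as an n x 2 matrix
agreement_matrix <- function(pairs) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs)
  num <- pairs[vapply(pairs, is.numeric, logical(1))]
  if (ncol(num) < 2) abort("`pairs` must contain two numeric measurement columns.")
  m <- as.matrix(num[, 1:2])
  if (anyNA(m)) abort("Paired measurements must not contain NA.")
  m
}

#' @export
print.avc_icc <- function(x, ...) {
  cat(sprintf("<icc> %s single-measure ICC = %.3f, %g%% CI (%.3f-%.3f), p = %.3g\n",
              x$form, x$estimate, 100 * x$conf_level, x$conf_low, x$conf_high,
              x$p_value))
  invisible(x)
}

#' @export
tidy.avc_icc <- function(x, ...) {
  tibble(estimate = x$estimate, conf.low = x$conf_low, conf.high = x$conf_high,
         statistic = x$statistic, p.value = x$p_value, form = x$form, n = x$n)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = A - B` against means `m = (A + B) / 2`: mean
#' difference (bias), SD of differences, limits of agreement
#' `bias +/- 1.96 SD`, and a proportional-bias test (two-sided t-test on
#' the slope of the OLS regression of d on m). A slope p-value above the
#' significance level means no evidence that the disagreement grows with
#' the magnitude of the measurement.
#'
#' @param pairs Data frame whose first two numeric columns are methods A
#'   and B (difference convention A - B).
#' @param loa_mult Multiplier for the limits of agreement (1.96 for 95%
#'   normal limits).
#' @return An `avc_bland_altman`: `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `prop_bias_slope`, `prop_bias_p`, `n`, and the per-pair
#'   `data` tibble for plotting. The slope p-value is `NA` when the
#'   regression is degenerate (constant differences or constant means).
#' @export
bland_altman <- function(pairs, loa_mult = 1.96) {
  m <- agreement_matrix(pairs)
  n <- nrow(m)
  if (n < 3) abort("Bland-Altman analysis needs at least 3 pairs.")
  d <- m[, 1] - m[, 2]
  avg <- rowMeans(m)
  bias <- mean(d)
  sd_d <- sd(d)
  slope <- 0
  slope_p <- NA_real_
  if (var(avg) > 0) {
    # a perfect fit (zero residuals) is a legitimate degenerate input here;
    # its slope test is undefined and reported as NA, so silence lm's warning
    fit <- lm(d ~ avg)
    slope <- unname(coef(fit)[2])
    sm <- suppressWarnings(summary(fit))$coefficients
    # residual variance of exactly 0 leaves the t-statistic undefined
    if (nrow(sm) == 2 && is.finite(sm[2, 4])) slope_p <- sm[2, 4]
  }
  structure(
    list(bias = bias, sd_diff = sd_d,
         loa_lower = bias - loa_mult * sd_d,
         loa_upper = bias + loa_mult * sd_d,
         loa_mult = loa_mult,
         prop_bias_slope = slope, prop_bias_p = slope_p, n = n,
         data = tibble(mean = avg, diff = d)),
    class = "avc_bland_altman"
  )
}

#' @export
print.avc_bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, LoA (%.3f, %.3f), n = %d\n",
              x$bias, x$loa_lower, x$loa_upper, x$n))
  cat(sprintf("  proportional bias: slope %.4f, p = %s\n",
              x$prop_bias_slope,
              ifelse(is.na(x$prop_bias_p), "NA", format(x$prop_bias_p, digits = 3))))
  invisible(x)
}

#' @export
tidy.avc_bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         loa_lower = x$loa_lower, loa_upper = x$loa_upper,
         prop_bias_slope = x$prop_bias_slope, prop_bias_p = x$prop_bias_p,
         n = x$n)
}

#' @param object An `avc_bland_altman`.
#' @param ... Unused.
#' @rdname bland_altman
#' @export
autoplot.avc_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (A - B)",
                  title = sprintf("Bias %.1f, LoA (%.1f, %.1f)",
                                  object$bias, object$loa_lower,
                                  object$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Validate a conversion model against a paired cohort
#'
#' Applies the conversion to the cohort's CECT calcium volumes and
#' compares the calculated scores with the native Agatston reference:
#' single-measure absolute-agreement ICC with 95% CI, squared Pearson
#' correlation (goodness of fit), and Bland-Altman bias statistics with
#' the proportional-bias test. Differences follow the
#' native - calculated convention.
#'
#' @param cohort Data frame with `native_agatston` and `cect_volume_mm3`.
#' @param model A `conversion_model`.
#' @param icc_form ICC variant, see [icc].
#' @return An `avc_agreement` report; serialize with [write_report], plot
#'   with [autoplot()].
#' @examples
#' coh <- make_paired_cohort(n = 20, seed = 42)
#' validate_conversion(coh, default_conversion_model())
#' @export
validate_conversion <- function(cohort, model = default_conversion_model(),
                                icc_form = "agreement") {
  need <- c("native_agatston", "cect_volume_mm3")
  if (!all(need %in% names(cohort))) {
    abort("Cohort must have columns native_agatston and cect_volume_mm3.")
  }
  calc <- apply_conversion(cohort$cect_volume_mm3, model)
  pairs <- tibble(native = cohort$native_agatston, calculated = calc)
  icc_res <- icc(pairs, form = icc_form)
  ba <- bland_altman(pairs)
  r2 <- stats::cor(pairs$native, pairs$calculated)^2
  structure(
    list(icc = icc_res, bland_altman = ba, r2 = r2,
         n = nrow(pairs), model = model, pairs = pairs),
    class = "avc_agreement"
  )
}

#' @export
print.avc_agreement <- function(x, ...) {
  cat(sprintf("<agreement report> n = %d\n", x$n))
  cat(sprintf("  ICC (%s, single measure): %.3f, CI (%.3f-%.3f), p = %.3g\n",
              x$icc$form, x$icc$estimate, x$icc$conf_low, x$icc$conf_high,
              x$icc$p_value))
  cat(sprintf("  R2 = %.3f\n", x$r2))
  cat(sprintf("  Bland-Altman (native - calculated): bias %.1f, LoA (%.1f, %.1f), prop-bias p = %s\n",
              x$bland_altman$bias, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper,
              ifelse(is.na(x$bland_altman$prop_bias_p), "NA",
                     format(x$bland_altman$prop_bias_p, digits = 3))))
  invisible(x)
}

#' @export
glance.avc_agreement <- function(x, ...) {
  tibble(
    n = x$n, icc = x$icc$estimate, icc_conf_low = x$icc$conf_low,
    icc_conf_high = x$icc$conf_high, icc_p = x$icc$p_value,
    r2 = x$r2, bias = x$bland_altman$bias,
    loa_lower = x$bland_altman$loa_lower,
    loa_upper = x$bland_altman$loa_upper,
    prop_bias_slope = x$bland_altman$prop_bias_slope,
    prop_bias_p = x$bland_altman$prop_bias_p
  )
}

#' @param object An `avc_agreement`.
#' @param ... Unused.
#' @rdname validate_conversion
#' @export
autoplot.avc_agreement <- function(object, ...) {
  autoplot(object$bland_altman) +
    ggplot2::labs(x = "Mean of native and calculated score (AU)",
                  y = "Native - calculated (AU)")
}
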
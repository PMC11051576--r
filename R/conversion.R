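#' Linear volume-to-Agatston conversion model
#'
#' Calculated Agatston units = `intercept + slope * volume_mm3`. The
#' intercept is deliberately free: cohorts restricted to severe aortic
#' stenosis contain no low-calcium subjects, so the line of best fit does
#' not pass through the origin.
#'
#' @param intercept Intercept, Agatston units.
#' @param slope Slope, Agatston units per mm^3 of CECT calcium volume.
#' @param r_squared Goodness of fit when calibrated (NA for presets).
#' @param n Calibration cohort size (NA for presets).
#' @param name Optional preset name.
#' @return A `conversion_model`.
#' @export
conversion_model <- function(intercept, slope, r_squared = NA_real_,
                             n = NA_integer_, name = NULL) {
  if (!is.finite(slope)) abort("Slope must be finite.")
  if (!is.finite(intercept)) abort("Intercept must be finite.")
  structure(
    list(intercept = as.numeric(intercept), slope = as.numeric(slope),
         r_squared = as.numeric(r_squared), n = n, name = name,
         data = NULL),
    class = "conversion_model"
  )
}

#' Shipped conversion presets
#'
#' `"ref-2024"` carries the reference constants (intercept 691, slope 1.83
#' Agatston units per mm^3) derived from a 45-subject TAVI derivation
#' cohort with a four-SD dynamic threshold. Conversion constants are
#' centre- and protocol-specific; recalibrate with [calibrate] before
#' using another acquisition protocol.
#'
#' @return Named list of `conversion_model` objects.
#' @export
conversion_presets <- function() {
  list(
    "ref-2024" = conversion_model(691, 1.83, name = "ref-2024")
  )
}

#' Default conversion model
#'
#' The `"ref-2024"` preset: calculated Agatston units = 691 + 1.83 x
#' AVC_CECT (mm^3).
#'
#' @return A `conversion_model`.
#' @examples
#' apply_conversion(1000, default_conversion_model())  # 2521
#' @export
default_conversion_model <- function() conversion_presets()[["ref-2024"]]

#' Convert CECT calcium volume to calculated Agatston units
#'
#' @param volume_mm3 Numeric vector of CECT calcium volumes (mm^3, >= 0).
#' @param model A `conversion_model` (default: the shipped preset).
#' @return Calculated Agatston units, same length as `volume_mm3`.
#' @export
apply_conversion <- function(volume_mm3, model = default_conversion_model()) {
  stopifnot(inherits(model, "conversion_model"))
  if (any(volume_mm3 < 0)) abort("Calcium volumes must be >= 0.")
  model$intercept + model$slope * volume_mm3
}

#' Calibrate a conversion model from a paired cohort
#'
#' Ordinary least squares of the native Agatston score on the
#' contrast-enhanced calcium volume, intercept free. Zero-intercept fits
#' (the approach of some earlier work) are available behind
#' `zero_intercept = TRUE` for comparison but are not the default, since
#' severe-stenosis cohorts give regression lines well away from the
#' origin.
#'
#' @param cohort Data frame with columns `native_agatston` and
#'   `cect_volume_mm3` (see [read_cohort], [make_paired_cohort]).
#' @param zero_intercept Force the line through the origin.
#' @return A `conversion_model` with `r_squared` and `n` filled in and the
#'   cohort attached for plotting.
#' @examples
#' calibrate(tibble::tibble(native_agatston = c(5, 25),
#'                          cect_volume_mm3 = c(0, 10)))  # a = 5, b = 2
#' @export
calibrate <- function(cohort, zero_intercept = FALSE) {
  need <- c("native_agatston", "cect_volume_mm3")
  if (!all(need %in% names(cohort))) {
    abort("Cohort must have columns native_agatston and cect_volume_mm3.")
  }
  v <- cohort$cect_volume_mm3
  y <- cohort$native_agatston
  if (length(unique(v)) < 2) {
    abort("Calibration is degenerate: calcium volumes have zero variance.")
  }
  fit <- if (zero_intercept) {
    lm(y ~ v - 1)
  } else {
    lm(y ~ v)
  }
  cf <- coef(fit)
  model <- conversion_model(
    intercept = if (zero_intercept) 0 else unname(cf[1]),
    slope = unname(cf[length(cf)]),
    r_squared = suppressWarnings(summary(fit))$r.squared,  # noise-free cohorts fit perfectly

    n = length(v),
    name = if (zero_intercept) "calibrated-zero-intercept" else "calibrated"
  )
  model$data <- as_tibble(cohort)
  model
}

#' @export
print.conversion_model <- function(x, ...) {
  cat(sprintf(
    "<conversion_model%s> calculated AU = %.4g + %.4g x volume(mm3)\n",
    if (is.null(x$name)) "" else paste0(": ", x$name), x$intercept, x$slope
  ))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R2 = %.3f, n = %d\n", x$r_squared, x$n))
  }
  invisible(x)
}

#' @export
tidy.conversion_model <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         units = c("Agatston units", "Agatston units / mm3"))
}

#' @export
glance.conversion_model <- function(x, ...) {
  tibble(intercept = x$intercept, slope = x$slope,
         r.squared = x$r_squared, n = if (is.null(x$n)) NA_integer_ else x$n)
}

#' Calibration scatter plot
#'
#' Native Agatston score against CECT calcium volume with the fitted (or
#' preset) conversion line. Requires a calibrated model (one carrying its
#' cohort) or an explicit `data` argument.
#'
#' @param object A `conversion_model`.
#' @param data Optional cohort to plot instead of the one attached at
#'   calibration.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conversion_model <- function(object, data = NULL, ...) {
  data <- data %||% object$data
  if (is.null(data)) abort("No cohort attached to this model; pass `data`.")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$cect_volume_mm3,
                                     y = .data$native_agatston)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(
      x = expression("CECT calcium volume (mm"^3 * ")"),
      y = "Native Agatston score (AU)",
      title = sprintf("Calculated AU = %.3g + %.3g x volume",
                      object$intercept, object$slope)
    ) +
    ggplot2::theme_minimal()
}
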
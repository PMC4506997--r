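# broom-style methods for the fitted-object classes

#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, including the derived
#'   constants (`k_obs`, `k_on`, `k_off`, `K_D`, half-time) where defined.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  d <- x$derived
  extra <- tibble(
    term = c("k_obs", "k_on", "k_off", "K_D", "half_time"),
    estimate = c(d$k_obs, d$k_on, d$k_off, d$K_D, d$half_time),
    std_error = NA_real_
  )
  dplyr::bind_rows(x$estimates, extra[is.finite(extra$estimate), ])
}

#' @rdname tidy.kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  d <- x$derived
  tibble(kind = x$kind, k_obs = d$k_obs, k_on = d$k_on, k_off = d$k_off,
         kd_molar = d$K_D, kd_pm = d$K_D_pM, half_time_min = d$half_time,
         rss = d$rss, n = nrow(x$data))
}

#' Tidy a Patlak fit
#'
#' @param x A `patlak_fit`.
#' @param ... Unused.
#' @export
tidy.patlak_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit)$coefficients)
  tibble(term = c("V", "Ki"), estimate = c(x$V, x$Ki),
         std_error = unname(s[, "Std. Error"]))
}

#' @rdname tidy.patlak_fit
#' @export
glance.patlak_fit <- function(x, ...) {
  tibble(Ki = x$Ki, V = x$V, r_squared = x$r_squared,
         t_start_min = x$t_start, n_points = x$n_points)
}

#' Tidy a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @export
tidy.calibration_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit)$coefficients)
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std_error = unname(s[, "Std. Error"]))
}

#' @rdname tidy.calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         n = nrow(x$data))
}

#' Tidy a plasma fit
#'
#' @param x A `plasma_fit`.
#' @param ... Unused.
#' @export
tidy.plasma_fit <- function(x, ...) x$estimates

#' @rdname tidy.plasma_fit
#' @export
glance.plasma_fit <- function(x, ...) {
  m <- x$model
  peak <- if (is.null(m)) NA_real_ else plasma_value(m, 0)
  frac60 <- if (is.null(m)) NA_real_ else plasma_value(m, 60) / peak
  tibble(degenerate = is.null(m), value_60min_over_peak = frac60,
         n = nrow(x$data), notes = paste(x$diagnostics, collapse = "; "))
}
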
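# Running integral of a positive input function sampled at strictly
# increasing times, from t = 0 to every sample time.
cumulative_input_integral <- function(t, v, quadrature = "spline-exp") {
  n <- length(t)
  if (quadrature == "trapezoid" || n < 3) {
    dt <- diff(c(0, t))
    mids <- (v + c(v[1], v[-n])) / 2
    return(cumsum(mids * dt))
  }
  # leading segment [0, t1]: quadratic through the first three samples
  qc <- tryCatch(solve(cbind(1, t[1:3], t[1:3]^2), v[1:3]),
                 error = function(e) NULL)
  head_area <- if (!is.null(qc)) {
    qc[1] * t[1] + qc[2] * t[1]^2 / 2 + qc[3] * t[1]^3 / 3
  } else NA_real_
  if (!is.finite(head_area) || head_area < 0) head_area <- v[1] * t[1]
  # piecewise-exponential interpolant: cubic spline in log space
  lsf <- stats::splinefun(t, log(v), method = if (n >= 4) "fmm" else "natural")
  segs <- vapply(seq(2, n), function(i) {
    stats::integrate(function(u) exp(lsf(u)), t[i - 1], t[i],
                     rel.tol = 1e-10, subdivisions = 500L)$value
  }, numeric(1))
  head_area + c(0, cumsum(segs))
}

as_tac <- function(tac, time_col = "time_min", value_col = NULL) {
  if (!is.data.frame(tac)) abort("a time-activity curve must be a data frame")
  value_col <- value_col %||% intersect(c("value", "bound"), names(tac))[1]
  if (is.na(value_col) || !time_col %in% names(tac)) {
    abort("time-activity curve needs a `time_min` column and a `value` (or `bound`) column")
  }
  out <- tibble(time_min = as.numeric(tac[[time_col]]),
                value = as.numeric(tac[[value_col]]))
  if (any(!is.finite(out$time_min)) || any(!is.finite(out$value))) {
    abort("time-activity curve contains non-finite entries")
  }
  if (is.unsorted(out$time_min, strictly = TRUE)) {
    abort("times must be strictly increasing")
  }
  out
}

new_kinetic_fit <- function(kind, estimates, derived, fit, data) {
  structure(
    list(kind = kind, estimates = estimates, derived = derived,
         fit = fit, data = data),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit: ", x$kind, ">\n", sep = "")
  print(x$estimates)
  d <- x$derived
  if (!is.null(d$k_obs)) cat("  k_obs: ", signif(d$k_obs, 4), " min^-1\n", sep = "")
  if (!is.null(d$k_on) && is.finite(d$k_on)) {
    cat("  k_on: ", signif(d$k_on, 4), " M^-1 min^-1\n", sep = "")
  }
  if (!is.null(d$k_off) && is.finite(d$k_off)) {
    cat("  k_off: ", signif(d$k_off, 4), " min^-1\n", sep = "")
  }
  if (!is.null(d$K_D_pM) && is.finite(d$K_D_pM)) {
    cat("  K_D: ", signif(d$K_D_pM, 4), " pM\n", sep = "")
  }
  cat("  half-time: ", signif(d$half_time, 4), " min\n", sep = "")
  invisible(x)
}

nls_or_abort <- function(formula, data, start, lower, what) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0(what, " fit did not converge (", conditionMessage(e),
                   "); initial values: ",
                   paste(names(start), signif(unlist(start), 4),
                         sep = " = ", collapse = ", ")))
    }
  )
  fit
}

se_of <- function(fit) {
  s <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(s)) return(setNames(rep(NA_real_, length(coef(fit))), names(coef(fit))))
  setNames(s[, "Std. Error"], rownames(s))
}

#' Fit a one-site association time course
#'
#' Nonlinear least squares of `B_eq * (1 - exp(-k_obs * t))` to an uptake
#' curve (Levenberg-Marquardt, initialized from the half-plateau crossing).
#' Given the ligand concentration and a dissociation rate constant (supplied,
#' e.g. from [fit_dissociation()]), the association rate constant follows as
#' `k_on = (k_obs - k_off) / L` together with `K_D = k_off / k_on`; without
#' `k_off_known` only `k_obs` and the association half-time are reported.
#'
#' @param tac Data frame with `time_min` and `value` (or `bound`), at least 4
#'   points including one near zero.
#' @param ligand_conc Free ligand concentration in molar (> 0).
#' @param k_off_known Optional dissociation rate constant, min^-1.
#' @return A `kinetic_fit`.
#' @export
fit_association <- function(tac, ligand_conc, k_off_known = NULL) {
  d <- as_tac(tac)
  if (nrow(d) < 4) abort("association fit needs at least 4 time points")
  if (min(d$time_min) > 1e-6 * max(d$time_min)) {
    abort("association fit needs a point near t = 0")
  }
  if (!is_scalar_number(ligand_conc) || ligand_conc <= 0) {
    abort("`ligand_conc` must be > 0")
  }
  if (max(d$value) <= 0 || sd(d$value) == 0) {
    abort("association fit did not converge: curve carries no signal")
  }
  beq0 <- max(d$value)
  above <- d$time_min[d$value >= beq0 / 2 & d$time_min > 0]
  kobs0 <- if (length(above)) log(2) / min(above) else 1 / median(d$time_min[-1])
  fit <- nls_or_abort(value ~ beq * (1 - exp(-kobs * time_min)), d,
                      start = list(beq = beq0, kobs = kobs0),
                      lower = c(0, 0), what = "association")
  cf <- coef(fit)
  se <- se_of(fit)
  kobs <- unname(cf["kobs"])
  koff <- if (is.null(k_off_known)) NA_real_ else k_off_known
  if (!is.na(koff) && kobs <= koff) {
    abort("fitted k_obs does not exceed k_off; implied k_on would be negative")
  }
  kon <- if (is.na(koff)) NA_real_ else (kobs - koff) / ligand_conc
  kd <- if (is.na(koff)) NA_real_ else koff / kon
  est <- tibble(
    term = c("B_eq", "k_obs"),
    estimate = unname(cf[c("beq", "kobs")]),
    std_error = unname(se[c("beq", "kobs")])
  )
  new_kinetic_fit(
    "association", est,
    derived = list(k_obs = kobs, k_on = kon, k_off = koff,
                   K_D = kd, K_D_pM = kd * 1e12,
                   half_time = log(2) / kobs,
                   ligand_conc = ligand_conc,
                   rss = sum(stats::resid(fit)^2)),
    fit = fit, data = d
  )
}

#' Fit a mono-exponential dissociation time course
#'
#' Nonlinear least squares of `B0 * exp(-k_off * t)` to a washout curve,
#' initialized from the log-slope of the last two points. Reports `k_off` and
#' the dissociation half-time `ln(2) / k_off`.
#'
#' @param tac Data frame with `time_min` and `value` (or `bound`), at least 4
#'   points, positive at t = 0.
#' @return A `kinetic_fit`.
#' @export
fit_dissociation <- function(tac) {
  d <- as_tac(tac)
  if (nrow(d) < 4) abort("dissociation fit needs at least 4 time points")
  if (d$value[1] <= 0) abort("dissociation fit needs a positive initial value")
  n <- nrow(d)
  if (sd(d$value) == 0) {
    # perfectly flat washout: the irreversible limit, k_off = 0
    est <- tibble(term = c("B0", "k_off"),
                  estimate = c(d$value[1], 0),
                  std_error = c(0, 0))
    return(new_kinetic_fit(
      "dissociation", est,
      derived = list(k_obs = NA_real_, k_on = NA_real_, k_off = 0,
                     K_D = NA_real_, K_D_pM = NA_real_, half_time = Inf,
                     rss = 0),
      fit = NULL, data = d
    ))
  }
  b00 <- d$value[1]
  koff0 <- if (all(d$value[c(n - 1, n)] > 0)) {
    max((log(d$value[n - 1]) - log(d$value[n])) /
          (d$time_min[n] - d$time_min[n - 1]), 1e-6)
  } else 1e-3
  fit <- nls_or_abort(value ~ b0 * exp(-koff * time_min), d,
                      start = list(b0 = b00, koff = koff0),
                      lower = c(0, 0), what = "dissociation")
  cf <- coef(fit)
  se <- se_of(fit)
  koff <- unname(cf["koff"])
  est <- tibble(
    term = c("B0", "k_off"),
    estimate = unname(cf[c("b0", "koff")]),
    std_error = unname(se[c("b0", "koff")])
  )
  new_kinetic_fit(
    "dissociation", est,
    derived = list(k_obs = NA_real_, k_on = NA_real_, k_off = koff,
                   K_D = NA_real_, K_D_pM = NA_real_,
                   half_time = log(2) / koff,
                   rss = sum(stats::resid(fit)^2)),
    fit = fit, data = d
  )
}

#' Equilibrium dissociation constant from rate constants
#'
#' `K_D = k_off / k_on`, reported in molar and picomolar. With the measured
#' carotid constants (k_on 4.5e9 M^-1 min^-1, k_off 0.0027 min^-1) this gives
#' 0.6 pM.
#'
#' @param k_on Association rate constant, M^-1 min^-1 (> 0).
#' @param k_off Dissociation rate constant, min^-1 (>= 0).
#' @return One-row tibble with `k_on`, `k_off`, `kd_molar`, `kd_pm`.
#' @examples
#' derive_kd(4.5e9, 0.0027)
#' @export
derive_kd <- function(k_on, k_off) {
  if (!is_scalar_number(k_on) || k_on <= 0) abort("`k_on` must be > 0")
  if (!is_scalar_number(k_off) || k_off < 0) abort("`k_off` must be >= 0")
  kd <- k_off / k_on
  tibble(k_on = k_on, k_off = k_off, kd_molar = kd, kd_pm = kd * 1e12)
}

#' Log-log concentration-response calibration
#'
#' Ordinary least squares of `log10(activity)` on `log10(concentration)` —
#' the calibration line relating bound radioactivity to incubation
#' concentration, a slope of 1 meaning strict proportionality.
#'
#' @param data Data frame with columns `conc` (molar, > 0) and `activity`
#'   (> 0); at least 3 points.
#' @return Object of class `calibration_fit` with `slope`, `intercept`,
#'   `r_squared` and the underlying `lm` fit.
#' @export
fit_concentration_response <- function(data) {
  if (!all(c("conc", "activity") %in% names(data))) {
    abort("`data` needs columns `conc` and `activity`")
  }
  if (nrow(data) < 3) abort("calibration fit needs at least 3 points")
  if (any(data$conc <= 0)) abort("concentrations must be > 0")
  if (any(data$activity <= 0)) abort("activities must be > 0 for a log-log fit")
  d <- tibble(lx = log10(data$conc), ly = log10(data$activity))
  fit <- lm(ly ~ lx, data = d)
  cf <- coef(fit)
  structure(
    list(slope = unname(cf["lx"]), intercept = unname(cf["(Intercept)"]),
         r_squared = suppressWarnings(summary(fit)$r.squared), fit = fit, data = d),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> log10(activity) = ", signif(x$slope, 4),
      " * log10(conc) + ", signif(x$intercept, 4),
      "  (r^2 = ", signif(x$r_squared, 4), ")\n", sep = "")
  invisible(x)
}

#' Patlak graphical analysis
#'
#' Linearization for irreversibly trapped tracers: plotting
#' `C_t(t) / C_b(t)` against `integral(C_b, 0, t) / C_b(t)` yields, after the
#' tissue-plasma equilibration time, a line whose slope is the net influx
#' constant Ki and whose intercept is the effective distribution volume V.
#'
#' The running plasma integral is computed, by default, as the exact integral
#' of a cubic-spline interpolant of log-concentration (piecewise-exponential
#' interpolation — the natural model for a decaying input function, and the
#' generalization of the log-down trapezoid of pharmacokinetic practice),
#' with the leading segment back to t = 0 integrated from a quadratic through
#' the first three samples. Plain linear trapezoidal cumulation (constant
#' extension to t = 0) is available via `quadrature = "trapezoid"`; on
#' sparse late frames its quadrature error is roughly 1% of Ki, which is why
#' it is not the default.
#'
#' @param tissue Either a data frame with `time_min` and `value`, or a
#'   `dynamic_study` tibble (with `t_mid_min`, `plasma`, `tissue` columns), in
#'   which case `plasma` may be omitted.
#' @param plasma Data frame with `time_min` and `value`; must be positive on
#'   all used points. Tissue values are interpolated onto the plasma times if
#'   the grids differ.
#' @param t_start Equilibrium cutoff in minutes (default 10): only points
#'   with `t >= t_start` enter the regression.
#' @param quadrature `"spline-exp"` (default) or `"trapezoid"`; see Details.
#' @return Object of class `patlak_fit`: `Ki`, `V`, `r_squared`, `t_start`,
#'   `n_points`, plot coordinates in `$data`, and the underlying `lm`.
#' @export
patlak <- function(tissue, plasma = NULL, t_start = 10,
                   quadrature = c("spline-exp", "trapezoid")) {
  quadrature <- match.arg(quadrature)
  if (is.null(plasma)) {
    if (!all(c("t_mid_min", "plasma", "tissue") %in% names(tissue))) {
      abort("supply `plasma`, or a dynamic study with t_mid_min/plasma/tissue columns")
    }
    plasma <- tibble(time_min = tissue$t_mid_min, value = tissue$plasma)
    tissue <- tibble(time_min = tissue$t_mid_min, value = tissue$tissue)
  }
  ts <- as_tac(tissue)
  pl <- as_tac(plasma)
  if (!isTRUE(all.equal(ts$time_min, pl$time_min))) {
    ts <- tibble(time_min = pl$time_min,
                 value = approx(ts$time_min, ts$value, xout = pl$time_min,
                                rule = 2)$y)
  }
  if (any(pl$value <= 0)) abort("plasma curve must be positive at every used point")
  t <- pl$time_min
  cum <- cumulative_input_integral(t, pl$value, quadrature)
  x <- cum / pl$value
  y <- ts$value / pl$value
  use <- t >= t_start
  if (sum(use) < 3) abort("fewer than 3 points at or after `t_start`")
  fit <- lm(y ~ x, data = tibble(x = x[use], y = y[use]))
  cf <- coef(fit)
  structure(
    list(Ki = unname(cf["x"]), V = unname(cf["(Intercept)"]),
         r_squared = suppressWarnings(summary(fit)$r.squared), t_start = t_start,
         n_points = sum(use),
         data = tibble(time_min = t, x = x, y = y, used = use),
         fit = fit),
    class = "patlak_fit"
  )
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat("<patlak_fit> Ki = ", signif(x$Ki, 4), " ml cm^-3 min^-1; V = ",
      signif(x$V, 4), "; r^2 = ", signif(x$r_squared, 4), " (", x$n_points,
      " points, t >= ", x$t_start, " min)\n", sep = "")
  invisible(x)
}

#' Fit a biexponential plasma model to a sampled curve
#'
#' Least squares of `A1 * exp(-lambda1 * t) + A2 * exp(-lambda2 * t)`,
#' initialized by curve peeling (tail log-fit for the slow phase, early
#' residual for the fast phase); phases are ordered `lambda1 > lambda2` after
#' fitting. Near-degenerate fits (vanishing slow amplitude or nearly equal
#' rates) are flagged in `$diagnostics`.
#'
#' @param tac Data frame with `time_min` and `value`, at least 5 positive
#'   points.
#' @return A `plasma_fit`: the fitted [plasma_model()] in `$model`, estimate
#'   table in `$estimates`, `$diagnostics`, and the `nls` object.
#' @export
fit_plasma_biexponential <- function(tac) {
  d <- as_tac(tac)
  if (nrow(d) < 5) abort("plasma fit needs at least 5 points")
  if (any(d$value <= 0)) abort("plasma fit needs positive values")
  n <- nrow(d)
  tail_idx <- seq(max(2, n - max(3, n %/% 3) + 1), n)
  tail_fit <- lm(log(value) ~ time_min, data = d[tail_idx, ])
  l2 <- max(-unname(coef(tail_fit)[2]), 1e-4)
  a2 <- exp(unname(coef(tail_fit)[1]))
  resid_early <- pmax(d$value - a2 * exp(-l2 * d$time_min), 1e-12)
  early_idx <- seq_len(max(2, n %/% 3))
  early_fit <- lm(log(resid_early[early_idx]) ~ d$time_min[early_idx])
  l1 <- max(-unname(coef(early_fit)[2]), l2 * 3)
  a1 <- max(exp(unname(coef(early_fit)[1])), 1e-6)
  fit <- nls_or_abort(value ~ A1 * exp(-l1 * time_min) + A2 * exp(-l2 * time_min),
                      d, start = list(A1 = a1, l1 = l1, A2 = a2, l2 = l2),
                      lower = rep(0, 4), what = "biexponential plasma")
  cf <- coef(fit)
  se <- se_of(fit)
  ord <- if (cf["l1"] >= cf["l2"]) c("A1", "l1", "A2", "l2") else c("A2", "l2", "A1", "l1")
  A1 <- unname(cf[ord[1]]); lambda1 <- unname(cf[ord[2]])
  A2 <- unname(cf[ord[3]]); lambda2 <- unname(cf[ord[4]])
  diagnostics <- character(0)
  if (A2 < 1e-3 * max(A1, 1e-300)) {
    diagnostics <- c(diagnostics, "slow-phase amplitude ~ 0 (single exponential)")
  }
  if (A1 < 1e-3 * max(A2, 1e-300)) {
    diagnostics <- c(diagnostics, "fast-phase amplitude ~ 0 (single exponential)")
  }
  if (lambda2 > 0 && lambda1 / max(lambda2, 1e-300) < 1.05) {
    diagnostics <- c(diagnostics, "rates nearly equal (single exponential)")
  }
  model <- if (lambda1 > lambda2 && lambda2 > 0) {
    plasma_model(A1 = A1, A2 = A2, lambda1 = lambda1, lambda2 = lambda2)
  } else NULL
  if (is.null(model)) {
    diagnostics <- c(diagnostics, "degenerate rates; no valid plasma_model")
  }
  structure(
    list(model = model,
         estimates = tibble(
           term = c("A1", "lambda1", "A2", "lambda2"),
           estimate = c(A1, lambda1, A2, lambda2),
           std_error = unname(se[ord])
         ),
         diagnostics = diagnostics,
         fit = fit, data = d),
    class = "plasma_fit"
  )
}

#' @export
print.plasma_fit <- function(x, ...) {
  cat("<plasma_fit>\n")
  print(x$estimates)
  if (length(x$diagnostics)) cat("  note:", paste(x$diagnostics, collapse = "; "), "\n")
  invisible(x)
}
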
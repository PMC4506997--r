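paper_params <- kinetic_parameters(4.5e9, 0.0027, 1e-11)

test_that("association fitting inverts the forward model exactly when noiseless", {
  tac <- association_timecourse(paper_params, c(0, 5, 15, 30, 60))
  fit <- fit_association(tac, 1e-11, k_off_known = 0.0027)
  expect_equal(fit$derived$k_obs, 0.0477, tolerance = 1e-6)
  expect_equal(fit$derived$k_on, 4.5e9, tolerance = 1e-6)
  # half-time lands inside the printed 14.3 +/- 1.9 min
  expect_lt(abs(fit$derived$half_time - 14.3), 1.9)
  expect_error(fit_association(tibble::tibble(time_min = c(0, 5, 15, 30),
                                              value = rep(0, 4)), 1e-11),
               "converge|signal")
})

test_that("dissociation fitting recovers the washout constant and half-time", {
  t_wash <- c(0, 5, 10, 15, 30, 45, 60, 90, 120)
  tac <- dissociation_timecourse(paper_params, 1, t_wash)
  fit <- fit_dissociation(tac)
  expect_equal(fit$derived$k_off, 0.0027, tolerance = 1e-6)
  # half-time lands inside the printed 254 +/- 43 min
  expect_lt(abs(fit$derived$half_time - 254), 43)
  # constant curve: k_off indistinguishable from zero
  const <- tibble::tibble(time_min = t_wash, value = rep(2, 9))
  expect_lt(fit_dissociation(const)$derived$k_off, 1e-8)
})

test_that("affinity constant follows from the rate constants", {
  kd <- derive_kd(4.5e9, 0.0027)
  expect_equal(kd$kd_molar, 6e-13)
  expect_equal(kd$kd_pm, 0.6)
  expect_equal(derive_kd(1e9, 0)$kd_molar, 0)
  expect_equal(derive_kd(1e9, 1e-3)$kd_molar, 1e-12)
  expect_error(derive_kd(-1, 0.001), "k_on")
})

test_that("kinetic fits are internally consistent", {
  tac <- association_timecourse(paper_params, c(0, 5, 15, 30, 60))
  fit <- fit_association(tac, 1e-11, k_off_known = 0.0027)
  expect_equal(fit$derived$K_D * fit$derived$k_on, fit$derived$k_off)
  expect_equal(fit$derived$half_time * fit$derived$k_obs, log(2))
  g <- glance(fit)
  expect_equal(g$kd_pm, fit$derived$K_D * 1e12)
  td <- tidy(fit)
  expect_true(all(c("B_eq", "k_obs", "k_on") %in% td$term))
})

test_that("the log-log calibration refit returns the generating line", {
  concs <- 10^seq(-12, -7)
  cal <- fit_concentration_response(
    data.frame(conc = concs, activity = 10^(0.92 * log10(concs) + 13))
  )
  expect_equal(cal$slope, 0.92, tolerance = 1e-12)
  expect_equal(cal$intercept, 13, tolerance = 1e-10)
  prop <- fit_concentration_response(
    data.frame(conc = concs, activity = 5 * concs)
  )
  expect_equal(prop$slope, 1, tolerance = 1e-10)
  flat <- fit_concentration_response(
    data.frame(conc = concs, activity = rep(3, 6))
  )
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_error(fit_concentration_response(
    data.frame(conc = concs, activity = c(-1, 2, 3, 4, 5, 6))
  ), "> 0")
})

test_that("Patlak inverts the irreversible-trapping forward model", {
  st <- simulate_dynamic_study(0.06, 0.3)
  pk <- patlak(st)
  expect_equal(pk$Ki, 0.06, tolerance = 1e-3)
  expect_equal(pk$V, 0.3, tolerance = 1e-3)
  expect_gt(pk$r_squared, 0.9999)
  # zero influx: flat Patlak plot at height V
  pk0 <- patlak(simulate_dynamic_study(0, 0.25))
  expect_lt(abs(pk0$Ki), 1e-10)
  expect_equal(pk0$V, 0.25, tolerance = 1e-10)
  # plaque-like influx recovered inside the clinically observed range
  pk_plaque <- patlak(simulate_dynamic_study(0.003, 0.3))
  expect_gte(pk_plaque$Ki, 0.0005)
  expect_lte(pk_plaque$Ki, 0.007)
  expect_equal(pk_plaque$Ki, 0.003, tolerance = 1e-3)
})

test_that("Patlak input validation catches unusable curves", {
  st <- simulate_dynamic_study(0.01, 0.3)
  expect_error(patlak(st, t_start = 60), "fewer than 3")
  bad <- tibble::tibble(time_min = c(1, 2, 11, 12, 13),
                        value = c(1, 1, 0, 1, 1))
  tis <- tibble::tibble(time_min = c(1, 2, 11, 12, 13), value = 1:5)
  expect_error(patlak(tis, bad), "positive")
})

test_that("plasma biexponential fitting recovers generating parameters", {
  pm <- plasma_model(A1 = 0.8, A2 = 0.2, lambda1 = 0.3, lambda2 = 0.01)
  tac <- plasma_curve(pm, seq(0.25, 60, by = 0.75))
  fit <- fit_plasma_biexponential(tac)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(unname(est["A1"]), 0.8, tolerance = 1e-4)
  expect_equal(unname(est["lambda1"]), 0.3, tolerance = 1e-4)
  expect_equal(unname(est["A2"]), 0.2, tolerance = 1e-4)
  expect_equal(unname(est["lambda2"]), 0.01, tolerance = 1e-4)
  # default preset: 60-min value sits in the observed 4-8% of peak band
  g <- glance(fit_plasma_biexponential(plasma_curve(plasma_model(),
                                                    seq(0.5, 70, 0.5))))
  expect_gte(g$value_60min_over_peak, 0.04)
  expect_lte(g$value_60min_over_peak, 0.08)
})

test_that("single-exponential plasma data are flagged as degenerate", {
  tac <- tibble::tibble(time_min = seq(1, 50, by = 2),
                        value = 0.7 * exp(-0.05 * seq(1, 50, by = 2)))
  fit <- fit_plasma_biexponential(tac)
  expect_true(length(fit$diagnostics) > 0 || {
    est <- setNames(fit$estimates$estimate, fit$estimates$term)
    abs(est["lambda1"] - est["lambda2"]) / est["lambda1"] < 0.2
  })
})

test_that("fitted k_obs is affine in ligand concentration with intercept k_off", {
  concs <- c(5e-12, 1e-11, 2e-11, 4e-11)
  kobs_hat <- vapply(concs, function(L) {
    p <- kinetic_parameters(4.5e9, 0.0027, L)
    fit_association(association_timecourse(p, c(0, 5, 15, 30, 60)), L,
                    k_off_known = 0.0027)$derived$k_obs
  }, numeric(1))
  line <- lm(kobs_hat ~ concs)
  expect_equal(unname(coef(line)[2]), 4.5e9, tolerance = 1e-5)
  expect_equal(unname(coef(line)[1]), 0.0027, tolerance = 1e-5)
})

test_that("rate constants are recovered from noisy replicates without bias", {
  # 5% multiplicative noise; medians should sit within one printed s.e.
  kons <- kofs <- numeric(60)
  for (i in seq_len(60)) {
    withr::with_seed(1000 + i, {
      a <- association_timecourse(paper_params, c(0, 5, 15, 30, 60))
      a$bound <- a$bound * (1 + rnorm(nrow(a), 0, 0.05))
      d <- dissociation_timecourse(paper_params, 1,
                                   c(0, 5, 10, 15, 30, 45, 60, 90, 120))
      d$bound <- d$bound * (1 + rnorm(nrow(d), 0, 0.05))
    })
    kons[i] <- fit_association(a, 1e-11, k_off_known = 0.0027)$derived$k_on
    kofs[i] <- fit_dissociation(d)$derived$k_off
  }
  expect_lt(abs(median(kons) - 4.5e9), 0.6e9)
  expect_lt(abs(median(kofs) - 0.0027), 0.0005)
})
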
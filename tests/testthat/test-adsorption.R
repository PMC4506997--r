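params_paper <- kinetic_parameters(k_on = 4.5e9, k_off = 0.0027,
                                   ligand_conc = 1e-11)

test_that("association time course follows the closed one-site form", {
  tc <- association_timecourse(params_paper, c(0, 5, 15, 30, 60))
  expect_equal(tc$bound[1], 0)
  expect_true(all(diff(tc$bound) > 0))
  kobs <- 4.5e9 * 1e-11 + 0.0027
  expect_equal(kobs, 0.0477)
  # half-time of approach to equilibrium
  expect_equal(log(2) / kobs, 14.53, tolerance = 1e-3)
  # plateau at 20 half-times, within 1e-6 relative of the equilibrium level
  beq <- 1e-11 / (1e-11 + 0.0027 / 4.5e9)
  far <- association_timecourse(params_paper, 20 * log(2) / kobs)$bound
  expect_equal(far, beq, tolerance = 1e-6)
  expect_error(association_timecourse(params_paper, -1), "non-negative")
})

test_that("dissociation time course is mono-exponential washout", {
  t_wash <- c(0, 5, 10, 15, 30, 45, 60, 90, 120)
  tc <- dissociation_timecourse(params_paper, 1, t_wash)
  expect_equal(tc$bound, exp(-0.0027 * t_wash))
  expect_true(all(diff(tc$bound) < 0))
  # half-time ~ 256.7 min from the printed rate constant
  expect_equal(log(2) / 0.0027, 256.72, tolerance = 1e-4)
  # irreversible limit: k_off = 0 leaves binding constant
  p0 <- kinetic_parameters(k_off = 0)
  expect_true(all(dissociation_timecourse(p0, 2, t_wash)$bound == 2))
  expect_true(all(dissociation_timecourse(params_paper, 0, t_wash)$bound == 0))
  expect_error(dissociation_timecourse(params_paper, -1, t_wash), ">= 0")
})

test_that("sectioned-first uptake labels every calcified voxel uniformly", {
  ph <- generate_phantom(
    phantom_config(domain_size = c(2000, 2000), voxel_size = 5,
                   n_micro = 10, n_macro = 1,
                   macro_radius_range = c(200, 300)),
    seed = 1
  )
  am <- simulate_uptake(ph, params_paper, sectioned_first = TRUE)
  vals <- am$grid[ph$grid == 2L]
  expect_true(all(vals > 0))
  expect_equal(length(unique(vals)), 1L)
  expect_true(all(am$grid[ph$grid != 2L] == 0))
})

test_that("intact-tissue uptake labels only the accessible shell of macros", {
  ph <- single_macro_phantom_3d(radius = 500, voxel = 10, seed = 1)
  am <- simulate_uptake(ph, params_paper, penetration_depth = 20)
  frac <- sum(am$grid > 0) / sum(ph$grid == 2L)
  expect_lt(abs(frac - 0.115) / 0.115, 0.15)
  expect_error(simulate_uptake(ph, params_paper, penetration_depth = 0), "> 0")
})

test_that("a phantom without calcification yields an all-zero map", {
  ph <- generate_phantom(phantom_config(domain_size = c(300, 300),
                                        voxel_size = 5, n_micro = 0,
                                        n_macro = 0), seed = 1)
  am <- simulate_uptake(ph, params_paper)
  expect_true(all(am$grid == 0))
})

test_that("signal per volume is exact for fully labelled micros and falls with macro radius", {
  s_t <- 1 - exp(-0.0477 * 60)
  expected_full <- params_paper$site_density * 1e-11 * s_t
  ratios <- vapply(c(100, 200, 400), function(r) {
    ph <- single_macro_phantom_3d(radius = r, voxel = 10, seed = 1)
    am <- simulate_uptake(ph, params_paper, penetration_depth = 20)
    signal_per_volume(am, ph)$signal_per_volume
  }, numeric(1))
  expect_true(ratios[1] > ratios[2] && ratios[2] > ratios[3])
  # a micro deposit (radius <= depth) is labelled throughout: exact ratio
  phm <- generate_phantom(
    phantom_config(domain_size = c(300, 300, 300), voxel_size = 5,
                   n_micro = 1, n_macro = 0,
                   micro_radius_range = c(15, 15)),
    seed = 2
  )
  amm <- simulate_uptake(phm, params_paper, penetration_depth = 20)
  expect_equal(signal_per_volume(amm, phm)$signal_per_volume, expected_full)
  # sectioned-first: every deposit shares the same ratio
  ams <- simulate_uptake(phm, params_paper, sectioned_first = TRUE)
  expect_equal(signal_per_volume(ams, phm)$signal_per_volume, expected_full)
})

test_that("micro deposits are hotter per volume than macros in intact tissue", {
  for (seed in 1:3) {
    ph <- generate_phantom(
      phantom_config(domain_size = c(3000, 3000), voxel_size = 5,
                     n_micro = 15, n_macro = 2,
                     macro_radius_range = c(150, 400)),
      seed = seed
    )
    spv <- signal_per_volume(simulate_uptake(ph, params_paper), ph)
    expect_gt(mean(spv$signal_per_volume[spv$class == "micro"]),
              mean(spv$signal_per_volume[spv$class == "macro"]))
  }
})

test_that("activity is proportional to ligand concentration at equilibrium", {
  ph <- generate_phantom(
    phantom_config(domain_size = c(1500, 1500), voxel_size = 5,
                   n_micro = 5, n_macro = 1,
                   macro_radius_range = c(150, 250)),
    seed = 5
  )
  # at plateau (t >> t1/2 for both concentrations) doubling L doubles activity
  p1 <- kinetic_parameters(ligand_conc = 1e-11)
  p2 <- kinetic_parameters(ligand_conc = 2e-11)
  a1 <- simulate_uptake(ph, p1, incubation_time = 1e5)
  a2 <- simulate_uptake(ph, p2, incubation_time = 1e5)
  expect_equal(a2$grid, 2 * a1$grid, tolerance = 1e-9)
  # at the 60-min protocol the kinetic factor leaves only a small excess
  b1 <- simulate_uptake(ph, p1, incubation_time = 60)
  b2 <- simulate_uptake(ph, p2, incubation_time = 60)
  ratio <- max(b2$grid) / max(b1$grid)
  expect_gt(ratio, 2)
  expect_lt(ratio, 2.2)
})

test_that("sectioning before incubation never decreases per-deposit activity", {
  ph <- generate_phantom(
    phantom_config(domain_size = c(2500, 2500), voxel_size = 5,
                   n_micro = 10, n_macro = 2,
                   macro_radius_range = c(150, 350)),
    seed = 6
  )
  intact <- signal_per_volume(simulate_uptake(ph, params_paper), ph)
  cut <- signal_per_volume(
    simulate_uptake(ph, params_paper, sectioned_first = TRUE), ph
  )
  expect_true(all(cut$total_activity >= intact$total_activity))
})
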
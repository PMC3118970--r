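test_that("identical configurations reproduce bit-identical results", {
  s1 <- run_simulation(short_config())
  s2 <- run_simulation(short_config())
  expect_identical(s1$records, s2$records)
  expect_identical(s1$final_spine$vertebrae, s2$final_spine$vertebrae)
})

test_that("the config rejects inconsistent stepping", {
  cs <- case_spec(3, 10, 10)
  pr <- growth_profile("ais")
  expect_error(simulation_config(cs, pr, dt = 3), "report")
  expect_error(simulation_config(cs, pr, dt = 0.3), "multiple")
  expect_error(simulation_config(cs, pr, report_interval = 3), "divide")
})

test_that("without modulation the column grows by the closed-form integral", {
  pr <- growth_profile("ais")
  sim <- run_simulation(simulation_config(case_spec(5, 20, 10), pr,
                                          params = growth_params(beta = 0)))
  expected <- 360 + profile_growth_integral(pr, 8, 18)
  expect_lt(abs(spine_length(sim$final_spine) - expected), 1e-6)
  expect_lt(max(abs(sim$final_spine$vertebrae$wedge_cor)), 1e-9)
  expect_lt(max(abs(sim$final_spine$vertebrae$wedge_sag)), 1e-9)
  expect_angle_equal(dplyr::last(sim$records$coronal_cobb),
                     sim$records$coronal_cobb[1])
  expect_angle_equal(dplyr::last(sim$records$kyphosis),
                     sim$records$kyphosis[1])
})

test_that("records cover every report age and start at the case angles", {
  sim <- run_simulation(short_config(age_end = 12))
  expect_equal(sim$records$age, c(8, 10, 12))
  expect_angle_equal(sim$records$coronal_cobb[1], 10)
  expect_angle_equal(sim$records$kyphosis[1], 10)
})

test_that("the coronal curve is non-decreasing under the vicious cycle", {
  sim <- run_simulation(short_config(age_end = 14))
  expect_true(all(diff(sim$records$coronal_cobb) > -1e-9))
})

test_that("mirrored initial curves follow mirrored trajectories", {
  sp <- run_simulation(short_config(case_spec(9, 12, 10)))
  sm <- run_simulation(short_config(case_spec(9, -12, 10)))
  expect_equal(sm$records$coronal_cobb, sp$records$coronal_cobb,
               tolerance = 1e-6)
  expect_equal(sm$records$kyphosis, sp$records$kyphosis, tolerance = 1e-6)
})

test_that("halving the step changes the short-run outcome by little", {
  f1 <- dplyr::last(run_simulation(short_config(dt = 0.25))$records$coronal_cobb)
  f2 <- dplyr::last(run_simulation(short_config(dt = 0.125))$records$coronal_cobb)
  expect_lt(abs(f2 - f1) / f1, 0.05)
})

test_that("geometric blow-up halts with a diagnostic and flagged partials", {
  dims <- spine_dims(radii = rep(6, 17))  # deliberately frail column
  cfg <- simulation_config(case_spec(5, 20, 10), growth_profile("ais"),
                           dims = dims)
  expect_warning(sim <- run_simulation(cfg), "blow-up")
  expect_true(sim$halted)
  expect_false(is.na(sim$halt_age))
  expect_lt(dplyr::last(sim$records$age), 18)
})

test_that("the equilibrium audit trail stays at solver precision", {
  sim <- run_simulation(short_config(), audit = TRUE)
  expect_equal(nrow(sim$audit), 8)
  expect_lt(max(sim$audit$max_dN, sim$audit$max_dMc, sim$audit$max_dMs), 0.005)
})

test_that("case comparison flags a degenerate normal arm instead of a ratio", {
  cmp <- run_case_comparison(case_spec(3, 10, 10),
                             params = growth_params(beta = 0), age_end = 10)
  expect_true(cmp$unstable)
  expect_true(is.na(cmp$cobb_ratio))
})

test_that("the sensitivity grid reports every requested condition", {
  out <- run_sensitivity_suite(cases = default_cases()[3, ], betas = 0.4,
                               load_modes = "follower", gm_scales = c(1, 1.15),
                               age_end = 10)
  expect_equal(nrow(out), 2)
  expect_setequal(out$gm_scale, c(1, 1.15))
  expect_true(all(c("cobb_ratio", "dkyph_ais", "beta") %in% names(out)))
})
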
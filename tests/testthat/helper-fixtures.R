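# shared fixtures: small geometries and short simulation configs

straight_spine <- function(dims = spine_dims()) {
  build_spine(case_spec(0, 0, 0, 0), dims)
}

short_config <- function(case = case_spec(3, 10, 10),
                         kind = "ais", age_end = 10, dt = 0.25, ...) {
  simulation_config(case, growth_profile(kind), age_end = age_end,
                    dt = dt, report_interval = 2, ...)
}

expect_angle_equal <- function(actual, expected, tol = 0.5) {
  expect_lt(abs(actual - expected), tol)
}
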
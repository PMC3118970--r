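test_that("the modulation law matches its closed-form arithmetic", {
  p <- growth_params(beta = 0.4, sigma_m = 0.5)
  # at exactly the reference compressive stress the regularizer vanishes
  expect_equal(modulated_growth(2.5, -0.5, p, dt = 0.5), 1.25)
  # beta = 0 disables modulation for any stress
  expect_equal(modulated_growth(1.7, c(-3, 0, 2), growth_params(beta = 0), dt = 1),
               rep(1.7, 3))
  # G_m = 1 mm/yr, dt = 1, beta = 0.4, sigma = -1.0 -> 0.8 mm
  expect_equal(modulated_growth(1, -1, p, dt = 1), 0.8)
  # deep compression floors at zero rather than resorbing
  expect_equal(modulated_growth(1, -10, p, dt = 1), 0)
  expect_lt(modulated_growth(1, -10, p, dt = 1, floor = FALSE), 0)
})

test_that("baseline growth distributes the column rate over plates", {
  sp <- straight_spine()
  pr <- growth_profile("normal", knots = tibble::tibble(age = c(8, 18),
                                                        pct_per_year = c(2, 2)))
  bg <- baseline_growth(pr, 12, sp)
  expect_equal(sum(bg$vertebra_rate), 0.02 * 360, tolerance = 1e-9)
  expect_equal(bg$plate_rate, bg$vertebra_rate / 2)
  # proportional to vertebral height share
  expect_equal(bg$vertebra_rate / sp$vertebrae$height,
               rep(7.2 / sum(sp$vertebrae$height), 17), tolerance = 1e-9)
  # scaling is exact
  pr85 <- growth_profile("normal", scale = 0.85,
                         knots = pr$knots)
  expect_equal(baseline_growth(pr85, 12, sp)$vertebra_rate,
               bg$vertebra_rate * 0.85, tolerance = 1e-12)
  expect_error(baseline_growth(pr, 19, sp), "age")
})

test_that("constant regional mode uses the fixed thoracic/lumbar rates", {
  sp <- straight_spine()
  pr <- growth_profile("constant_regional")
  bg <- baseline_growth(pr, 14, sp)
  expect_equal(unique(bg$vertebra_rate[startsWith(bg$level, "T")]), 0.8)
  expect_equal(unique(bg$vertebra_rate[startsWith(bg$level, "L")]), 1.1)
  expect_equal(bg$vertebra_rate, baseline_growth(pr, 9, sp)$vertebra_rate)
})

test_that("AIS velocity curve starts earlier, peaks higher, ends later", {
  ais <- growth_profile("ais")
  nor <- growth_profile("normal")
  expect_gt(max(ais$knots$pct_per_year), max(nor$knots$pct_per_year))
  expect_lt(ais$knots$age[which.max(ais$knots$pct_per_year)],
            nor$knots$age[which.max(nor$knots$pct_per_year)])
  ages <- seq(8, 18, by = 0.25)
  expect_true(all(vertegrow:::profile_velocity(ais, ages) >= 0))
  expect_true(all(vertegrow:::profile_velocity(nor, ages) >= 0))
})

test_that("the analytic growth integral matches numeric quadrature", {
  for (kind in c("ais", "normal")) {
    pr <- growth_profile(kind, scale = 1.1)
    num <- stats::integrate(function(a)
      pr$scale * vertegrow:::profile_velocity(pr, a) / 100 * pr$baseline_length,
      8, 17.9, subdivisions = 2000, rel.tol = 1e-10)$value
    expect_equal(profile_growth_integral(pr, 8, 17.9), num, tolerance = 1e-6)
  }
})

test_that("growth application recovers affine increment fields exactly", {
  sp <- straight_spine()
  g <- discretize_plate(sp$vertebrae$radius[7], 1, 3, 12)
  # uniform increment on both plates: height grows, wedges untouched
  incr <- dplyr::bind_rows(
    dplyr::mutate(g, idx = 7L, face = "superior", g = 0.3),
    dplyr::mutate(g, idx = 7L, face = "inferior", g = 0.3))
  sp2 <- apply_growth(sp, incr)
  expect_equal(sp2$vertebrae$height[7], sp$vertebrae$height[7] + 0.6,
               tolerance = 1e-12)
  expect_equal(sp2$vertebrae$wedge_cor[7], 0)
  m <- measure_alignment(sp2)
  expect_lt(m$coronal_cobb, 1e-9)
  # exactly linear field: slope tan(1 deg) across y tilts the wedge by 1 deg
  incr2 <- dplyr::mutate(g, idx = 5L, face = "superior",
                         g = 0.4 + tan(vertegrow:::deg2rad(1)) * y)
  sp3 <- apply_growth(sp, incr2)
  expect_lt(abs(sp3$vertebrae$wedge_cor[5] - 1), 1e-6)
  # zero increments leave the spine bit-identical
  incr0 <- dplyr::mutate(incr, g = 0)
  expect_identical(apply_growth(sp, incr0)$vertebrae, sp$vertebrae)
})

test_that("lower compression on the convex side grows strictly faster", {
  # laterally loaded plate: moment puts the +y (convex) half in relative tension
  g <- discretize_plate(12, 1, 3, 12)
  s <- plate_stress(g, N = -150, Mc = 900, Ms = 0)
  incr <- modulated_growth(0.5, s$sigma, growth_params(), dt = 0.25)
  orig <- order(round(s$x, 9), round(s$y, 9))
  flip <- order(round(s$x, 9), -round(s$y, 9))
  up <- s$y[orig] > 1e-9  # each +y element vs its mirrored -y partner
  expect_true(all(incr[orig][up] > incr[flip][up]))
  # the area-mean modulation is neutral when mean stress equals -sigma_m
  sN <- plate_stress(g, N = -0.5 * sum(g$area), 0, 0)
  gN <- modulated_growth(1, sN$sigma, growth_params(), dt = 1)
  expect_equal(weighted.mean(gN, g$area), 1, tolerance = 1e-9)
})
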
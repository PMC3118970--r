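test_that("the built column has the canonical structure and total length", {
  for (i in c(1, 3, 6)) {
    sp <- build_spine(default_cases()[i, ])
    expect_equal(nrow(sp$vertebrae), 17)
    expect_equal(nrow(sp$discs), 16)
    expect_equal(sp$vertebrae$level[c(1, 17)], c("T1", "L5"))
    expect_lt(abs(spine_length(sp) - 360), 0.1)
  }
})

test_that("chain continuity holds: disc gaps equal disc heights exactly", {
  sp <- build_spine(default_cases()[6, ])
  ch <- vertegrow:::chain_poses(sp)
  for (j in 1:16) {
    gap <- sqrt(sum((ch$p_inf[j, ] - ch$p_sup[j + 1, ])^2))
    expect_lt(abs(gap - sp$discs$height[j]), 1e-6)
  }
})

test_that("the six default cases encode the intended contrasts", {
  cs <- default_cases()
  expect_equal(cs$cobb[1], 0)
  expect_equal(cs$cobb[2], 0)
  expect_lt(cs$kyphosis[2], cs$kyphosis[1])
  expect_true(all(cs$cobb[3:6] > 0))
  expect_equal(nrow(cs), 6)
})

test_that("measured initial angles invert the requested case (round trip)", {
  grid <- expand.grid(cobb = c(0, 10, 20, 25), kyph = c(10, 30))
  for (r in seq_len(nrow(grid))) {
    cs <- case_spec(9, grid$cobb[r], grid$kyph[r], 45)
    m <- measure_alignment(build_spine(cs))
    expect_angle_equal(m$coronal_cobb, grid$cobb[r])
    expect_angle_equal(m$kyphosis, grid$kyph[r])
    expect_angle_equal(m$lordosis, 45)
  }
  expect_error(case_spec(9, 95, 10), "feasible")
  expect_error(case_spec(9, 10, 10, apex_level = "S1"), "apex")
})

test_that("negating the coronal curve mirrors the geometry", {
  sp_p <- build_spine(case_spec(9, 15, 20))
  sp_m <- build_spine(case_spec(9, -15, 20))
  lp <- spine_landmarks(sp_p)
  lm <- spine_landmarks(sp_m)
  expect_equal(lm$cy, -lp$cy, tolerance = 1e-9)
  expect_equal(lm$cx, lp$cx, tolerance = 1e-9)
  expect_equal(lm$cz, lp$cz, tolerance = 1e-9)
  expect_equal(measure_alignment(sp_m)$coronal_cobb,
               measure_alignment(sp_p)$coronal_cobb, tolerance = 1e-9)
})

test_that("uniform scaling doubles length and preserves every angle", {
  sp <- build_spine(case_spec(9, 20, 30))
  m0 <- measure_alignment(sp)
  sp$vertebrae$height <- sp$vertebrae$height * 2
  sp$vertebrae$radius <- sp$vertebrae$radius * 2
  sp$discs$height <- sp$discs$height * 2
  m2 <- measure_alignment(sp)
  expect_equal(spine_length(sp), 720, tolerance = 1e-9)
  expect_lt(abs(m2$coronal_cobb - m0$coronal_cobb), 1e-6)
  expect_lt(abs(m2$kyphosis - m0$kyphosis), 1e-6)
  expect_lt(abs(m2$lordosis - m0$lordosis), 1e-6)
})

test_that("plate discretization conserves area and flags the cortical ring", {
  g <- discretize_plate(10, 1, 3, 12)
  expect_lt(abs(sum(g$area) - pi * 100) / (pi * 100), 0.01)
  cort <- sum(g$area[g$zone == "cortical"])
  expect_lt(abs(cort - pi * (100 - 81)) / (pi * 19), 0.05)
  expect_true(all(sqrt(g$x^2 + g$y^2) <= 10))
  expect_equal(nrow(discretize_plate(10, 1, 2, 8)), 16)
  expect_setequal(unique(g$E), c(14500, 400))
  expect_error(discretize_plate(0), "radius")
  expect_error(discretize_plate(10, 1, 1, 8), "resolution")
})

test_that("material table carries the published constants", {
  tab <- material_table()
  expect_equal(young_modulus(c("cortical", "cancellous", "sensitive")),
               c(14500, 400, 12))
  expect_true(all(tab$poisson_ratio >= 0 & tab$poisson_ratio < 0.5))
  expect_true(all(tab$young_modulus > 0))
})

test_that("geometry snapshots serialize to JSON", {
  sp <- build_spine(default_cases()[3, ])
  path <- withr::local_tempfile(fileext = ".json")
  write_spine_json(sp, path)
  js <- jsonlite::read_json(path)
  expect_length(js$vertebrae, 17)
  expect_length(js$discs, 16)
  q <- unlist(js$vertebrae[[8]]$quaternion)
  expect_equal(sum(q^2), 1, tolerance = 1e-9)
})
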
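test_that("homogeneous circular section reproduces F/A + M*y/I", {
  g <- discretize_plate(10, 1, 12, 48)
  g$E <- rep(1000, nrow(g))
  s <- plate_stress(g, N = -200, Mc = 2000, Ms = 0)
  A <- pi * 100
  I <- pi * 1e4 / 4
  pred <- -200 / A + 2000 * s$y / I
  expect_lt(max(abs(s$sigma - pred)) / max(abs(pred)), 0.01)
  # extremes at the +/- y rim
  expect_equal(which.max(s$sigma), which.max(s$y))
  expect_equal(which.min(s$sigma), which.min(s$y))
})

test_that("discrete stress sums reproduce the resultants to machine precision", {
  g <- discretize_plate(12, 1, 3, 12)  # composite: cortical ring + core
  for (loads in list(c(-150, 0, 0), c(-150, 800, -300), c(0, 1200, 0))) {
    s <- plate_stress(g, loads[1], loads[2], loads[3])
    r <- vertegrow:::equilibrium_residual(s, loads[1], loads[2], loads[3])
    expect_lt(max(abs(r)), 1e-10)
  }
})

test_that("pure bending is antisymmetric with zero net force", {
  g <- discretize_plate(10, 1, 4, 16)
  s <- plate_stress(g, N = 0, Mc = 1500, Ms = 0)
  expect_lt(abs(sum(s$sigma * s$area)), 1e-10)
  flip <- order(round(s$x, 9), -round(s$y, 9))
  orig <- order(round(s$x, 9), round(s$y, 9))
  expect_equal(s$sigma[orig], -s$sigma[flip], tolerance = 1e-9)
})

test_that("resultants match an independent brute-force lever-arm sum", {
  sp <- build_spine(case_spec(9, 20, 25, 40))
  pr <- schultz_profile(400, "gravity")
  res <- internal_resultants(sp, resolve_directions(sp, pr))
  ch <- vertegrow:::chain_poses(sp)
  for (i in c(5, 9, 14)) {
    cp <- ch$p_sup[i, ]
    Rp <- ch$R_sup[[i]]
    M <- c(0, 0, 0)
    N <- 0
    for (j in 1:i) {
      Fj <- c(0, 0, -pr$table$increment[j])
      M <- M + vertegrow:::cross3(ch$p_sup[j, ] - cp, Fj)
      N <- N + sum(Fj * Rp[, 3])
    }
    row <- dplyr::filter(res, idx == i, face == "superior")
    expect_equal(row$N, N, tolerance = 1e-9)
    expect_equal(row$m_cor, sum(M * Rp[, 1]), tolerance = 1e-9)
    expect_equal(row$m_sag, -sum(M * Rp[, 2]), tolerance = 1e-9)
  }
})

test_that("mirror-image spines produce mirror-image stress fields", {
  pr <- schultz_profile(400, "gravity")
  sp_p <- build_spine(case_spec(9, 15, 20))
  sp_m <- build_spine(case_spec(9, -15, 20))
  rp <- internal_resultants(sp_p, resolve_directions(sp_p, pr))
  rm <- internal_resultants(sp_m, resolve_directions(sp_m, pr))
  expect_equal(rm$m_cor, -rp$m_cor, tolerance = 1e-8)
  expect_equal(rm$N, rp$N, tolerance = 1e-8)
  g <- discretize_plate(15, 1, 3, 12)
  i <- which(rp$idx == 8 & rp$face == "superior")
  s_p <- plate_stress(g, rp$N[i], rp$m_cor[i], rp$m_sag[i])
  s_m <- plate_stress(g, rm$N[i], rm$m_cor[i], rm$m_sag[i])
  flip <- order(round(s_p$x, 9), -round(s_p$y, 9))
  orig <- order(round(s_p$x, 9), round(s_p$y, 9))
  expect_equal(s_m$sigma[orig], s_p$sigma[flip], tolerance = 1e-8)
})

test_that("grid refinement leaves the strain solution stable within 1%", {
  for (resn in list(c(5, 20), c(10, 40))) {
    g <- discretize_plate(14, 1, resn[1], resn[2])
    s <- section_state(g)
    sol <- s$inv_E %*% c(-150, 900, -400)
    if (resn[1] == 5) sol_coarse <- sol else sol_fine <- sol
  }
  expect_lt(max(abs(sol_fine - sol_coarse) / abs(sol_fine)), 0.01)
})

test_that("degenerate sections are rejected", {
  g <- discretize_plate(10, 1, 3, 12)
  g$area <- g$area * 0
  expect_error(section_state(g), "singular")
})
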
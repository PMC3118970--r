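# Stress-modulated growth (Hueter-Volkmann law in Stokes' formulation):
#   G = G_m * [1 + beta * (sigma - sigma_ref)],   sigma_ref = -sigma_m
# with tension-positive stress, so compression beyond the reference
# magnitude slows growth and compression below it accelerates growth.
# Baseline velocities come from adolescent growth-velocity curves
# (percentage of the age-8 column length per year), with an AIS variant
# having earlier onset, higher peak and later cessation than the normal
# variant, or from fixed regional rates (thoracic/lumbar mm per year).

#' Growth-modulation parameters
#'
#' @param beta Stress sensitivity of growth modulation, 1/MPa.
#' @param sigma_m Reference compressive stress magnitude, MPa.
#' @return A `growth_params` list.
#' @export
growth_params <- function(beta = 0.4, sigma_m = 0.5) {
  stopifnot(beta >= 0, sigma_m > 0)
  structure(list(beta = beta, sigma_m = sigma_m), class = "growth_params")
}

default_velocity_knots <- function(kind) {
  # piecewise-linear (age, % per year) knots; assumptions emulating
  # published adolescent growth-velocity curves: the AIS spurt starts
  # earlier, peaks higher and ceases later than the normal spurt
  switch(kind,
    normal = tibble::tibble(age = c(8, 12.5, 16.5, 18),
                            pct_per_year = c(1.4, 2.6, 0, 0)),
    ais = tibble::tibble(age = c(8, 11.5, 17.5, 18),
                         pct_per_year = c(1.8, 3.2, 0, 0)))
}

#' Baseline growth-velocity profile
#'
#' @param kind `"ais"`, `"normal"` or `"constant_regional"`.
#' @param scale Multiplier on the velocity curve (e.g. 0.85 or 1.15 for the
#'   +/- 15 percent sensitivity analysis).
#' @param baseline_length Column length (mm) that the percentage velocities
#'   refer to (the age-8 baseline, 360 mm).
#' @param knots Optional tibble `(age, pct_per_year)` overriding the
#'   default piecewise-linear velocity curve.
#' @param regional_rates Named vector `c(thoracic =, lumbar =)` of fixed
#'   per-vertebra rates (mm/yr) for `constant_regional` mode.
#' @return A `growth_profile` object.
#' @export
#' @examples
#' growth_profile("ais")
growth_profile <- function(kind = c("ais", "normal", "constant_regional"),
                           scale = 1, baseline_length = 360, knots = NULL,
                           regional_rates = c(thoracic = 0.8, lumbar = 1.1)) {
  kind <- match.arg(kind)
  stopifnot(scale > 0, baseline_length > 0)
  if (kind != "constant_regional" && is.null(knots))
    knots <- default_velocity_knots(kind)
  if (!is.null(knots)) {
    stopifnot(all(diff(knots$age) > 0), all(knots$pct_per_year >= 0))
  }
  structure(list(kind = kind, scale = scale,
                 baseline_length = baseline_length, knots = knots,
                 regional_rates = regional_rates),
            class = "growth_profile")
}

#' @export
print.growth_profile <- function(x, ...) {
  cat("<growth_profile>", x$kind, "scale", x$scale, "\n")
  if (!is.null(x$knots)) print(x$knots)
  invisible(x)
}

# velocity in % of baseline length per year at a given age
profile_velocity <- function(profile, age) {
  if (any(age < 8 - 1e-9) || any(age > 18 + 1e-9))
    abort("age outside the simulated range [8, 18]")
  k <- profile$knots
  stats::approx(k$age, k$pct_per_year, xout = pmin(pmax(age, min(k$age)),
                                                   max(k$age)))$y
}

#' Total column growth between two ages (analytic integral)
#'
#' Exact integral of the piecewise-linear velocity curve times the baseline
#' length and scale factor.
#'
#' @param profile A [growth_profile()] (`ais` or `normal` kind).
#' @param from,to Age interval in years.
#' @return Column length increase in mm.
#' @export
profile_growth_integral <- function(profile, from, to) {
  if (profile$kind == "constant_regional")
    abort("constant_regional growth has no percentage curve")
  k <- profile$knots
  grid <- sort(unique(c(from, to, k$age[k$age > from & k$age < to])))
  if (length(grid) < 2) return(0)
  v <- stats::approx(k$age, k$pct_per_year, xout = grid)$y
  seg <- diff(grid) * (utils::head(v, -1) + utils::tail(v, -1)) / 2
  profile$scale * sum(seg) / 100 * profile$baseline_length
}

#' Baseline growth rate per vertebra and per plate
#'
#' The total column growth rate (scale x velocity x baseline length) is
#' distributed over vertebrae proportionally to each vertebra's share of
#' the total vertebral (non-disc) height and split equally between the two
#' growth plates. In `constant_regional` mode each vertebra instead grows
#' at its fixed regional rate regardless of age.
#'
#' @param profile A [growth_profile()].
#' @param age Age in years (must lie in `[8, 18]`).
#' @param spine A spine object (supplies current vertebral heights).
#' @return Tibble per vertebra: `idx`, `level`, `vertebra_rate` (mm/yr) and
#'   `plate_rate` (mm/yr per plate).
#' @export
baseline_growth <- function(profile, age, spine) {
  v <- spine$vertebrae
  if (profile$kind == "constant_regional") {
    if (any(age < 8 - 1e-9) || any(age > 18 + 1e-9))
      abort("age outside the simulated range [8, 18]")
    rate <- ifelse(startsWith(v$level, "T"),
                   profile$regional_rates[["thoracic"]],
                   profile$regional_rates[["lumbar"]]) * profile$scale
  } else {
    total <- profile$scale * profile_velocity(profile, age) / 100 *
      profile$baseline_length
    rate <- total * v$height / sum(v$height)
  }
  tibble::tibble(idx = v$idx, level = v$level,
                 vertebra_rate = rate, plate_rate = rate / 2)
}

# column growth over one step [age, age + dt], exact in the velocity curve
step_growth_per_plate <- function(profile, age, dt, spine) {
  v <- spine$vertebrae
  if (profile$kind == "constant_regional") {
    rate <- ifelse(startsWith(v$level, "T"),
                   profile$regional_rates[["thoracic"]],
                   profile$regional_rates[["lumbar"]]) * profile$scale
    return(rate * dt / 2)
  }
  total <- profile_growth_integral(profile, age, age + dt)
  total * v$height / sum(v$height) / 2
}

#' Stress-modulated growth increment
#'
#' Applies the growth-modulation law
#' `increment = G_m * dt * (1 + beta * (sigma + sigma_m))` with
#' tension-positive stress: at exactly the reference compressive stress
#' `-sigma_m` growth is unmodulated; stronger compression slows it, weaker
#' compression accelerates it. Negative increments are floored at zero
#' (growth plates do not resorb) unless `floor = FALSE`.
#'
#' @param G_m Baseline growth rate, mm/yr (per plate).
#' @param sigma Element stress(es), MPa, tension positive.
#' @param params A [growth_params()].
#' @param dt Time step in years.
#' @param floor Floor negative increments at zero.
#' @return Growth increment(s), mm.
#' @export
#' @examples
#' modulated_growth(1, -1, growth_params(beta = 0.4, sigma_m = 0.5), 1)
modulated_growth <- function(G_m, sigma, params = growth_params(), dt,
                             floor = TRUE) {
  stopifnot(dt > 0)
  g <- G_m * dt * (1 + params$beta * (sigma + params$sigma_m))
  if (floor) g <- pmax(g, 0)
  g
}

# area-weighted least-squares plane g(x, y) = g0 + a*y + b*x through the
# per-element increments; exact for affine fields
fit_growth_plane <- function(x, y, area, g, inv_A = NULL) {
  if (is.null(inv_A)) {
    M <- matrix(c(sum(area), sum(area * y), sum(area * x),
                  sum(area * y), sum(area * y^2), sum(area * x * y),
                  sum(area * x), sum(area * x * y), sum(area * x^2)), 3, 3)
    inv_A <- solve(M)
  }
  as.numeric(inv_A %*% c(sum(area * g), sum(area * g * y), sum(area * g * x)))
}

#' Apply per-element growth increments to the spine geometry
#'
#' For each plate the increments are reduced to an area-weighted
#' least-squares plane `g0 + a*y + b*x`: `g0` adds to the vertebral height
#' at that face, and the slopes become wedge-angle increments
#' (`atan(a)` coronal, `atan(b)` sagittal) of that endplate. Poses of all
#' superior structures follow automatically because geometry is
#' reconstructed from the intrinsic chain state, preserving chain
#' continuity; the total column length grows by the sum of the `g0` terms
#' exactly.
#'
#' @param spine A spine object.
#' @param increments Long tibble with columns `idx` (vertebra), `face`
#'   (`"superior"`/`"inferior"`), element coordinates `x`, `y`, `area` and
#'   increment `g` (mm, finite and non-negative).
#' @return The updated spine.
#' @export
apply_growth <- function(spine, increments) {
  stopifnot(all(is.finite(increments$g)), all(increments$g >= -1e-12))
  upd <- increments |>
    dplyr::group_by(.data$idx, .data$face) |>
    dplyr::summarise(
      fit = list(fit_growth_plane(.data$x, .data$y, .data$area, .data$g)),
      .groups = "drop")
  for (r in seq_len(nrow(upd))) {
    i <- upd$idx[r]
    cf <- upd$fit[[r]]
    spine$vertebrae$height[i] <- spine$vertebrae$height[i] + cf[1]
    spine$vertebrae$wedge_cor[i] <- spine$vertebrae$wedge_cor[i] +
      rad2deg(atan(cf[2]))
    spine$vertebrae$wedge_sag[i] <- spine$vertebrae$wedge_sag[i] +
      rad2deg(atan(cf[3]))
  }
  spine
}
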
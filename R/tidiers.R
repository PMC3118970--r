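#' Tidy the alignment time series of a simulation
#'
#' @param x A `spine_sim` object.
#' @param ... Unused.
#' @return Tibble of per-report-age alignment records annotated with the
#'   case, profile, growth constant and load mode.
#' @exportS3Method generics::tidy
tidy.spine_sim <- function(x, ...) {
  cfg <- x$config
  x$records |>
    dplyr::mutate(case_id = cfg$case$case_id, profile = cfg$profile$kind,
                  gm_scale = cfg$profile$scale, beta = cfg$params$beta,
                  load_mode = cfg$load_mode, .before = 1)
}

#' One-row summary of a simulation
#'
#' @param x A `spine_sim` object.
#' @param ... Unused.
#' @return One-row tibble: final angles, changes from the initial state,
#'   final column length and the halt flag.
#' @exportS3Method generics::glance
glance.spine_sim <- function(x, ...) {
  r <- x$records
  cfg <- x$config
  tibble::tibble(
    case_id = cfg$case$case_id, profile = cfg$profile$kind,
    beta = cfg$params$beta, load_mode = cfg$load_mode,
    gm_scale = cfg$profile$scale,
    final_cobb = dplyr::last(r$coronal_cobb),
    delta_cobb = dplyr::last(r$coronal_cobb) - r$coronal_cobb[1],
    final_kyphosis = dplyr::last(r$kyphosis),
    delta_kyphosis = dplyr::last(r$kyphosis) - r$kyphosis[1],
    final_lordosis = dplyr::last(r$lordosis),
    delta_lordosis = dplyr::last(r$lordosis) - r$lordosis[1],
    max_axial_rotation = max(r$max_axial_rotation),
    final_length = spine_length(x$final_spine),
    halted = x$halted
  )
}

#' Plot the angle trajectories of one simulation
#'
#' @param object A `spine_sim` object.
#' @param ... Unused.
#' @return A ggplot: coronal Cobb, kyphosis and lordosis versus age.
#' @exportS3Method ggplot2::autoplot
autoplot.spine_sim <- function(object, ...) {
  cfg <- object$config
  long <- object$records |>
    dplyr::select("age", "coronal_cobb", "kyphosis", "lordosis") |>
    tidyr::pivot_longer(-"age", names_to = "measure", values_to = "degrees")
  ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$degrees)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(
      title = sprintf("Case %d, %s growth profile", cfg$case$case_id,
                      cfg$profile$kind),
      x = "age (years)", y = "angle (degrees)") +
    ggplot2::theme_minimal()
}

#' Plot AIS-vs-normal trajectories for a set of simulations
#'
#' @param sims A list of `spine_sim` objects (e.g. both arms of several
#'   cases).
#' @return A ggplot faceted by case and measure, coloured by profile.
#' @export
plot_profile_comparison <- function(sims) {
  long <- purrr::map(sims, tidy) |>
    purrr::list_rbind() |>
    dplyr::select("case_id", "profile", "age", "coronal_cobb", "kyphosis",
                  "lordosis") |>
    tidyr::pivot_longer(c("coronal_cobb", "kyphosis", "lordosis"),
                        names_to = "measure", values_to = "degrees")
  ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$degrees,
                                     colour = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(measure ~ case_id, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "age (years)", y = "angle (degrees)",
                  colour = "growth profile") +
    ggplot2::theme_minimal()
}
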
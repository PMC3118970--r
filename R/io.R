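# Light configuration and export helpers: YAML simulation configs, CSV
# dumps of alignment records and load states.

#' Read a simulation configuration from YAML
#'
#' Recognized keys (all optional except `case`): `case` (either a case id
#' 1-6 or a mapping with `case_id`, `cobb`, `kyphosis`, `lordosis`,
#' `apex_level`), `profile` (`kind`, `scale`, `knots`), `beta`, `sigma_m`,
#' `load_mode`, `body_weight`, `age_start`, `age_end`, `dt`,
#' `report_interval`.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  case <- if (is.numeric(y$case) || is.character(y$case)) {
    default_cases()[as.integer(y$case), ]
  } else {
    do.call(case_spec, y$case[c("case_id", "cobb", "kyphosis",
                                "lordosis", "apex_level")] |>
              Filter(f = Negate(is.null)))
  }
  pk <- y$profile$kind %||% "ais"
  knots <- if (!is.null(y$profile$knots))
    tibble::as_tibble(do.call(rbind, y$profile$knots) |> as.data.frame() |>
                        setNames(c("age", "pct_per_year")))
  dims <- spine_dims(body_weight = y$body_weight %||% 400)
  simulation_config(
    case = case,
    profile = growth_profile(pk, scale = y$profile$scale %||% 1,
                             baseline_length = dims$total_length,
                             knots = knots),
    params = growth_params(y$beta %||% 0.4, y$sigma_m %||% 0.5),
    load_mode = y$load_mode %||% "follower",
    age_start = y$age_start %||% 8, age_end = y$age_end %||% 18,
    dt = y$dt %||% 0.25, report_interval = y$report_interval %||% 2,
    dims = dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the alignment time series of simulations to CSV
#'
#' @param sims A `spine_sim` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_alignment_csv <- function(sims, path) {
  if (inherits(sims, "spine_sim")) sims <- list(sims)
  tab <- purrr::map(sims, tidy) |> purrr::list_rbind()
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write per-level load vectors and plate resultants to CSV
#'
#' @param spine A spine object.
#' @param profile A [schultz_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_load_csv <- function(spine, profile, path) {
  loads <- resolve_directions(spine, profile)
  res <- internal_resultants(spine, loads)
  tab <- dplyr::left_join(res, loads$forces, by = c("idx", "level"))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
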
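# Schultz-type per-level spinal loading: cumulative load grows from 14% of
# body weight at T1 by 2.6% per level caudally. Two load modes: "gravity"
# (all force vectors along global -Z) and "follower" (sagittal component of
# the transmitted resultant kept tangent to the sagittal curve of the
# column, coronal component kept vertical), re-resolved at every iteration.

#' Schultz per-level load profile
#'
#' @param body_weight Body weight in N.
#' @param mode Load mode, `"follower"` (default) or `"gravity"`.
#' @return A `load_profile` list: `body_weight`, `mode`, and a tibble
#'   `table` with per-level cumulative `fraction` of body weight, the
#'   per-level `increment` force (N) and the `cum_force` (N) transmitted
#'   across that vertebra's plates.
#' @export
#' @examples
#' schultz_profile(400)$table
schultz_profile <- function(body_weight = 400,
                            mode = c("follower", "gravity")) {
  mode <- match.arg(mode)
  if (!is.finite(body_weight) || body_weight <= 0)
    abort("body_weight must be positive")
  fraction <- 0.14 + 0.026 * (0:16)
  increment <- c(fraction[1], diff(fraction)) * body_weight
  structure(
    list(body_weight = body_weight, mode = mode,
         table = tibble::tibble(idx = 1:17, level = spinal_levels(),
                                fraction = fraction, increment = increment,
                                cum_force = fraction * body_weight)),
    class = "load_profile")
}

#' Incremental force introduced at one spinal level
#'
#' The per-level force increments are defined so that the cumulative load
#' transmitted across any vertebra's growth plates equals that level's
#' Schultz fraction of body weight.
#'
#' @param profile A [schultz_profile()].
#' @param level Spinal level label (e.g. `"T1"`, `"L3"`).
#' @return Force magnitude in N.
#' @export
incremental_level_force <- function(profile, level) {
  i <- match(level, profile$table$level)
  if (is.na(i)) abort(paste("unknown level:", level))
  profile$table$increment[i]
}

# unit load directions per level; follower directions follow the sagittal
# cubic spline through the vertebral centroids (zero coronal component)
load_directions <- function(centroids, mode) {
  n <- nrow(centroids)
  if (mode == "gravity")
    return(matrix(rep(c(0, 0, -1), each = n), n, 3))
  s <- seq_len(n)
  fx <- splinefun(s, centroids[, 1])
  fz <- splinefun(s, centroids[, 3])
  tx <- fx(s, deriv = 1)
  tz <- fz(s, deriv = 1)
  nrm <- sqrt(tx^2 + tz^2)
  if (any(nrm < 1e-9)) abort("degenerate sagittal tangent (coincident centroids)")
  # idx increases caudally, so the tangent already points downward
  cbind(tx / nrm, 0, tz / nrm)
}

#' Resolve the load profile into applied per-level force vectors
#'
#' In gravity mode every vector is global -Z. In follower mode each vector
#' lies in the plane spanned by the local sagittal tangent and global Z,
#' with zero coronal component; tangents come from a cubic spline through
#' the vertebral centroids and are re-fit on the current geometry.
#'
#' @param spine A spine object.
#' @param profile A [schultz_profile()].
#' @return A `load_state` list: the profile, and a tibble `forces` with the
#'   application point (the superior endplate centre) and force vector
#'   (`fx`, `fy`, `fz`, N) per level.
#' @export
resolve_directions <- function(spine, profile) {
  ch <- chain_poses(spine)
  dirs <- load_directions(ch$centroid, profile$mode)
  tab <- profile$table
  structure(
    list(profile = profile,
         forces = tibble::tibble(
           idx = tab$idx, level = tab$level,
           ax = ch$p_sup[, 1], ay = ch$p_sup[, 2], az = ch$p_sup[, 3],
           fx = tab$increment * dirs[, 1],
           fy = tab$increment * dirs[, 2],
           fz = tab$increment * dirs[, 3])),
    class = "load_state")
}

#' Boundary conditions of the column
#'
#' L5 is fixed in all six degrees of freedom (the chain root); T1 is
#' restrained in the transverse plane, which the simulation realizes as a
#' rigid postural rebalance returning the T1 centroid to the vertical axis
#' through the L5 base after each growth update.
#'
#' @return Tibble of constrained degrees of freedom per level.
#' @export
boundary_conditions <- function() {
  tibble::tibble(
    level = c(rep("L5", 6), rep("T1", 2)),
    dof = c("TX", "TY", "TZ", "RX", "RY", "RZ", "TX", "TY"),
    constrained = TRUE
  )
}
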
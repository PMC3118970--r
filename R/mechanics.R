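# Composite-section equilibrium mechanics. The volumetric mesh of a full
# finite-element model is replaced by beam-type combined axial + bending
# stress over each growth-plate cross-section: an affine axial strain field
# e(x, y) = e0 + kc*y + ks*x is solved from the three equilibrium equations
# of the E-weighted section, and each sensitive-layer element is assigned
# the local axial traction of the bone column behind it. This keeps exactly
# the ingredient the growth loop consumes - the signed normal-stress
# distribution over the sensitive layer - while staying desk-scale.
# Elastic displacements are not fed back into the geometry; growth is the
# only geometry-update mechanism.

#' Composite-section state of a growth-plate grid
#'
#' Precomputes the E-weighted section matrix (axial stiffness and bending
#' stiffnesses about the two in-plane axes) and the unweighted area-moment
#' matrix used for least-squares plane fits of growth increments.
#'
#' @param grid A plate grid from [discretize_plate()].
#' @return A `section_state` list with the 3x3 matrices, their inverses and
#'   the per-element modulus vector.
#' @export
section_state <- function(grid) {
  a <- grid$area; x <- grid$x; y <- grid$y; E <- grid$E
  if (sum(a) <= 0) abort("singular section: zero area")
  wE <- E * a
  M_E <- matrix(c(sum(wE), sum(wE * y), sum(wE * x),
                  sum(wE * y), sum(wE * y^2), sum(wE * x * y),
                  sum(wE * x), sum(wE * x * y), sum(wE * x^2)), 3, 3)
  M_A <- matrix(c(sum(a), sum(a * y), sum(a * x),
                  sum(a * y), sum(a * y^2), sum(a * x * y),
                  sum(a * x), sum(a * x * y), sum(a * x^2)), 3, 3)
  structure(list(M_E = M_E, M_A = M_A,
                 inv_E = solve(M_E), inv_A = solve(M_A),
                 axial_stiffness = M_E[1, 1],
                 bending_stiffness = c(coronal = M_E[2, 2],
                                       sagittal = M_E[3, 3])),
            class = "section_state")
}

#' Internal force and moment resultants at every growth plate
#'
#' For each plate, the axial force is the sum of all level forces at or
#' above that plate projected on the plate normal (compression negative),
#' and the coronal/sagittal moments are the first moments of those force
#' lines of action about the plate centroid, expressed about the plate's
#' in-plane anterior and left axes. In follower mode the transmitted
#' resultant is redirected tangentially in the sagittal plane, so the
#' sagittal moment vanishes by construction while the coronal moment equals
#' the gravity-mode value (the coronal component stays vertical).
#'
#' @param spine A spine object.
#' @param loads A `load_state` from [resolve_directions()].
#' @return Tibble with one row per plate: `idx`, `level`, `face`, axial
#'   force `N` (N), coronal moment `m_cor` and sagittal moment `m_sag`
#'   (N mm). Sign convention: `m_cor > 0` produces tension on the +Y (left)
#'   half, `m_sag > 0` tension on the +X (anterior) half.
#' @export
internal_resultants <- function(spine, loads) {
  ch <- chain_poses(spine)
  mode <- loads$profile$mode
  tab <- loads$profile$table
  dF <- tab$increment
  ax <- loads$forces$ax; ay <- loads$forces$ay
  cumF <- cumsum(dF)
  cumFax <- cumsum(dF * ax)
  cumFay <- cumsum(dF * ay)
  dirs <- cbind(loads$forces$fx, loads$forces$fy, loads$forces$fz) /
    dF  # unit directions
  out <- vector("list", 34)
  k <- 0
  for (face in c("superior", "inferior")) {
    P <- if (face == "superior") ch$p_sup else ch$p_inf
    Rl <- if (face == "superior") ch$R_sup else ch$R_inf
    for (i in 1:17) {
      Rp <- Rl[[i]]
      cp <- P[i, ]
      # moment of vertical unit lines of action about the plate centroid
      Mx <- -(cumFay[i] - cumF[i] * cp[2])
      My <- (cumFax[i] - cumF[i] * cp[1])
      m_cor <- Mx * Rp[1, 1] + My * Rp[2, 1]
      if (mode == "gravity") {
        N <- -cumF[i] * Rp[3, 3]
        m_sag <- -(Mx * Rp[1, 2] + My * Rp[2, 2])
      } else {
        N <- cumF[i] * sum(dirs[i, ] * Rp[, 3])
        m_sag <- 0
      }
      k <- k + 1
      out[[k]] <- c(i, N, m_cor, m_sag)
    }
  }
  res <- do.call(rbind, out)
  tibble::tibble(
    idx = as.integer(res[, 1]),
    level = spinal_levels()[res[, 1]],
    face = rep(c("superior", "inferior"), each = 17),
    N = res[, 2], m_cor = res[, 3], m_sag = res[, 4]
  )
}

#' Per-element axial stress over a growth-plate section
#'
#' Solves the 3x3 composite-section equilibrium system for the affine
#' strain field and returns the element stresses. By construction the
#' discrete sums of `sigma * area` and its first moments reproduce `N`,
#' `Mc`, `Ms` to machine precision.
#'
#' @param grid Plate grid from [discretize_plate()].
#' @param section Optional precomputed [section_state()] for `grid`.
#' @param N Axial force (N; compression negative).
#' @param Mc Coronal moment (N mm; positive = tension on +Y half).
#' @param Ms Sagittal moment (N mm; positive = tension on +X half).
#' @param output `"traction"` (default): the local axial traction of the
#'   bone column behind each element, which a thin soft layer in series
#'   must carry; `"sensitive"`: the sensitive-layer modulus times the local
#'   strain instead.
#' @return `grid` with a `sigma` column (MPa, tension positive).
#' @export
#' @examples
#' g <- discretize_plate(10, 1, 4, 16)
#' g$E[] <- 1000  # homogeneous section
#' s <- plate_stress(g, N = -200, Mc = 2000, Ms = 0)
#' range(s$sigma)
plate_stress <- function(grid, N, Mc = 0, Ms = 0, section = NULL,
                         output = c("traction", "sensitive")) {
  output <- match.arg(output)
  if (is.null(section)) section <- section_state(grid)
  sol <- section$inv_E %*% c(N, Mc, Ms)
  eps <- sol[1] + sol[2] * grid$y + sol[3] * grid$x
  grid$sigma <- if (output == "traction") grid$E * eps
                else young_modulus("sensitive") * eps
  grid
}

# equilibrium residuals of a stress field against its target resultants,
# relative to the load magnitude (used by the audit trail and tests)
equilibrium_residual <- function(grid, N, Mc, Ms) {
  ref <- max(abs(c(N, Mc, Ms)), 1e-9)
  c(dN = (sum(grid$sigma * grid$area) - N) / max(abs(N), ref),
    dMc = (sum(grid$sigma * grid$area * grid$y) - Mc) / ref,
    dMs = (sum(grid$sigma * grid$area * grid$x) - Ms) / ref)
}
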
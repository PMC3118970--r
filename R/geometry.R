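# Parametric T1-L5 geometry: 17 wedged-cylinder vertebral bodies, 16 discs,
# 34 growth-plate grids, plus the six standard initial cases.
#
# The spine is stored intrinsically: per-vertebra heights, radii and wedge
# angles, per-disc heights and joint angles, and a root orientation at the
# fixed L5 base. All 3D poses are recomputed from this state by forward
# kinematics, so chain continuity holds by construction and growth updates
# only ever touch heights and wedges.

spinal_levels <- function() c(paste0("T", 1:12), paste0("L", 1:5))

#' Anthropometric and discretization defaults for the spine model
#'
#' @param total_length Total T1-L5 column length (vertebrae plus discs) at
#'   the starting age, mm. Default 360 (36 cm at age 8).
#' @param disc_ratio Disc height as a fraction of the mean height of the two
#'   adjacent vertebrae.
#' @param height_gradient Ratio of the L5 to the T1 vertebral height; heights
#'   grade linearly in between.
#' @param cortical_thickness Cortical shell thickness, mm.
#' @param body_weight Body weight, N, used for the Schultz load profile and
#'   (by default) the cross-section calibration.
#' @param sigma_m Reference compressive stress magnitude, MPa (recorded
#'   with the dimensions; the growth law's reference stress).
#' @param radius_t1,radius_l5 Vertebral cross-section radii at T1 and L5,
#'   mm; radii grade linearly in between (anatomic morphometry for an
#'   adolescent column).
#' @param radii Optional explicit vector of 17 vertebral radii (mm),
#'   overriding the grading.
#' @param n_radial,n_angular Growth-plate grid resolution (radial rings
#'   including the dedicated cortical ring; angular sectors).
#' @return A named list of dimensions.
#' @export
spine_dims <- function(total_length = 360, disc_ratio = 0.25,
                       height_gradient = 1.5, cortical_thickness = 1,
                       body_weight = 400, sigma_m = 0.5,
                       radius_t1 = 10, radius_l5 = 20, radii = NULL,
                       n_radial = 5, n_angular = 20) {
  stopifnot(total_length > 0, disc_ratio > 0, height_gradient > 0,
            cortical_thickness > 0, body_weight > 0, sigma_m > 0,
            radius_t1 > 0, radius_l5 > 0)
  if (is.null(radii))
    radii <- seq(radius_t1, radius_l5, length.out = 17)
  stopifnot(length(radii) == 17, all(radii > cortical_thickness))
  list(total_length = total_length, disc_ratio = disc_ratio,
       height_gradient = height_gradient,
       cortical_thickness = cortical_thickness,
       body_weight = body_weight, sigma_m = sigma_m, radii = radii,
       n_radial = n_radial, n_angular = n_angular)
}

#' Specify an initial spine configuration case
#'
#' @param case_id Integer case label.
#' @param cobb Initial coronal Cobb angle, degrees (magnitude; the coronal
#'   curve is constructed as a balanced single arc bulging toward +Y).
#' @param kyphosis Initial thoracic kyphosis (T1 superior to T12 inferior
#'   endplate), degrees.
#' @param lordosis Initial lumbar lordosis (L1 superior to L5 inferior
#'   endplate), degrees.
#' @param apex_level Spinal level of the coronal curve apex.
#' @return One-row tibble describing the case.
#' @export
case_spec <- function(case_id, cobb, kyphosis, lordosis = 45,
                      apex_level = "T8") {
  if (!apex_level %in% spinal_levels()) abort("unknown apex level")
  if (abs(cobb) >= 90 || kyphosis >= 90 || lordosis >= 90)
    abort("requested initial angles are outside the feasible arc range")
  tibble::tibble(case_id = as.integer(case_id), cobb = cobb,
                 kyphosis = kyphosis, lordosis = lordosis,
                 apex_level = apex_level)
}

#' The six standard initial cases
#'
#' Case 1 is a normally aligned spine; case 2 is hypokyphotic with no
#' coronal curve; cases 3-6 combine an initial coronal curve of 10 or 20
#' degrees with a kyphosis of 10 or 30 degrees. The exact angles are
#' configurable assumptions chosen so that the case contrasts isolate
#' (i) absence of a coronal curve, (ii) hypokyphosis alone and
#' (iii) coronal-sagittal combinations.
#'
#' @param apex_level Apex of the coronal curve for the deformity cases.
#' @return Tibble with one row per case.
#' @export
#' @examples
#' default_cases()
default_cases <- function(apex_level = "T8") {
  dplyr::bind_rows(
    case_spec(1, 0, 30, apex_level = apex_level),
    case_spec(2, 0, 10, apex_level = apex_level),
    case_spec(3, 10, 10, apex_level = apex_level),
    case_spec(4, 10, 30, apex_level = apex_level),
    case_spec(5, 20, 10, apex_level = apex_level),
    case_spec(6, 20, 30, apex_level = apex_level)
  )
}

new_spine <- function(vertebrae, discs, root, case, dims) {
  structure(list(vertebrae = vertebrae, discs = discs, root = root,
                 case = case, dims = dims),
            class = "spine")
}

#' @export
print.spine <- function(x, ...) {
  m <- measure_alignment(x)
  cat("<spine> 17 vertebrae T1-L5, 16 discs; length",
      sprintf("%.1f mm\n", spine_length(x)))
  cat(sprintf("  coronal Cobb %.2f deg (%s-%s), kyphosis %.2f deg, lordosis %.2f deg\n",
              m$coronal_cobb, m$upper_end, m$lower_end, m$kyphosis, m$lordosis))
  invisible(x)
}

#' Total column length (vertebral heights plus disc heights)
#'
#' @param spine A spine object.
#' @return Length in mm.
#' @export
spine_length <- function(spine) {
  sum(spine$vertebrae$height) + sum(spine$discs$height)
}

# Forward kinematics: poses of vertebral mid-frames and endplates.
# Returns a list of plain matrices/lists for speed; `spine_poses()` wraps
# it in tibbles for the user surface.
chain_poses <- function(spine) {
  v <- spine$vertebrae
  d <- spine$discs
  n <- nrow(v)
  cent <- matrix(0, n, 3)
  Rmid <- vector("list", n)
  p_inf <- matrix(0, n, 3); R_inf <- vector("list", n)
  p_sup <- matrix(0, n, 3); R_sup <- vector("list", n)
  p <- c(0, 0, 0)
  R <- spine$root
  for (i in n:1) {
    wc <- deg2rad(v$wedge_cor[i]) / 2
    ws <- deg2rad(v$wedge_sag[i]) / 2
    half <- rot_x(wc) %*% rot_y(-ws)
    Rm <- R %*% half
    pm <- p + (v$height[i] / 2) * Rm[, 3]
    Rs <- Rm %*% half
    ps <- pm + (v$height[i] / 2) * Rm[, 3]
    cent[i, ] <- pm
    Rmid[[i]] <- Rm
    p_inf[i, ] <- p; R_inf[[i]] <- R
    p_sup[i, ] <- ps; R_sup[[i]] <- Rs
    if (i > 1) {
      j <- i - 1  # disc between vertebra i (below) and i-1 (above)
      ac <- deg2rad(d$angle_cor[j])
      as_ <- deg2rad(d$angle_sag[j])
      Rdm <- Rs %*% rot_x(ac / 2) %*% rot_y(as_ / 2)
      p <- ps + d$height[j] * Rdm[, 3]
      R <- Rs %*% rot_x(ac) %*% rot_y(as_)
    }
  }
  list(centroid = cent, R_mid = Rmid,
       p_inf = p_inf, R_inf = R_inf, p_sup = p_sup, R_sup = R_sup)
}

#' 3D poses of all vertebrae and endplates
#'
#' @param spine A spine object.
#' @return A list with tibbles `vertebrae` (centroid coordinates and
#'   mid-frame rotation as a list-column) and `plates` (endplate centres and
#'   frames, one row per vertebra and face).
#' @export
spine_poses <- function(spine) {
  ch <- chain_poses(spine)
  v <- spine$vertebrae
  vert <- tibble::tibble(
    idx = v$idx, level = v$level,
    cx = ch$centroid[, 1], cy = ch$centroid[, 2], cz = ch$centroid[, 3],
    R = ch$R_mid
  )
  plates <- dplyr::bind_rows(
    tibble::tibble(idx = v$idx, level = v$level, face = "superior",
                   px = ch$p_sup[, 1], py = ch$p_sup[, 2], pz = ch$p_sup[, 3],
                   R = ch$R_sup),
    tibble::tibble(idx = v$idx, level = v$level, face = "inferior",
                   px = ch$p_inf[, 1], py = ch$p_inf[, 2], pz = ch$p_inf[, 3],
                   R = ch$R_inf)
  )
  list(vertebrae = vert, plates = plates)
}

# Rigid postural rebalance about the fixed L5 base: rotate the whole chain
# so the T1 centroid returns to the vertical axis through the base (the
# kinematic counterpart of the transverse-plane restraint at T1), then
# remove any net axial spin so the column faces +X. This canonical standing
# posture is the frame in which the projection measures (Cobb, kyphosis,
# lordosis) are defined, mirroring upright radiographs.
rebalance_spine <- function(spine) {
  ch <- chain_poses(spine)
  v <- ch$centroid[1, ]
  if (sqrt(sum(v^2)) > 1e-12)
    spine$root <- rotation_between(v, c(0, 0, 1)) %*% spine$root
  for (it in 1:10) {
    spin <- mean(axial_rotation(spine)$rotation, na.rm = TRUE)
    if (!is.finite(spin) || abs(spin) < 1e-10) break
    spine$root <- rot_z(deg2rad(-spin)) %*% spine$root
  }
  spine
}

# Distribute the target coronal Cobb over the disc joints as a smooth,
# balanced single arc (raised-cosine lateral displacement bump centred at
# the apex). `amp` is the bump amplitude in mm; returns per-disc chain
# rotation angles (degrees) about +X.
coronal_joint_angles <- function(heights, disc_heights, apex_idx, amp) {
  n <- length(heights)
  # ascending coordinate of each vertebral centroid (straight stack)
  seg <- numeric(0)
  z <- numeric(n)
  pos <- 0
  for (i in n:1) {
    z[i] <- pos + heights[i] / 2
    pos <- pos + heights[i]
    if (i > 1) pos <- pos + disc_heights[i - 1]
  }
  z_apex <- z[apex_idx]
  halfw <- 4 * (pos / n)  # bump half-width: four vertebral pitches
  dwdz <- function(zz) {
    u <- (zz - z_apex) / halfw
    ifelse(abs(u) < 1, -(pi / (2 * halfw)) * sin(pi * u), 0)
  }
  phi <- atan(amp * dwdz(z))  # lateral lean (+Y) of the tangent, ascending
  # chain rotation about +X across disc j (between vertebra j+1 and j):
  # leaning +Y by phi corresponds to rot_x(-phi)
  rad2deg(-(phi[1:(n - 1)] - phi[2:n]))
}

build_spine_raw <- function(case, dims, amp, thoracic_total, lumbar_total) {
  levels <- spinal_levels()
  n <- 17
  u <- 1 + (dims$height_gradient - 1) * (0:(n - 1)) / (n - 1)
  ud <- dims$disc_ratio * (u[-n] + u[-1]) / 2
  scale <- dims$total_length / (sum(u) + sum(ud))
  heights <- u * scale
  disc_heights <- ud * scale

  vertebrae <- tibble::tibble(
    idx = 1:n, level = levels, height = heights, radius = dims$radii,
    cortical = dims$cortical_thickness,
    wedge_cor = 0, wedge_sag = 0
  )

  apex_idx <- match(case$apex_level, levels)
  angle_cor <- if (abs(amp) > 0) {
    coronal_joint_angles(heights, disc_heights, apex_idx, amp)
  } else rep(0, n - 1)

  # sagittal: uniform arc over the 11 thoracic joints (kyphosis) and the 4
  # lumbar joints (lordosis); the thoracolumbar joint is the inflection
  angle_sag <- rep(0, n - 1)
  angle_sag[1:11] <- thoracic_total / 11
  angle_sag[13:16] <- -lumbar_total / 4

  discs <- tibble::tibble(
    idx = 1:(n - 1),
    lower = levels[2:n], upper = levels[1:(n - 1)],
    height = disc_heights,
    angle_cor = angle_cor, angle_sag = angle_sag,
    nucleus_modulus = young_modulus("nucleus"),
    annulus_modulus = young_modulus("annulus")
  )

  new_spine(vertebrae, discs, diag(3), case, dims)
}

#' Build the parametric spine geometry for a case
#'
#' Constructs the 17-vertebra, 16-disc column at the configured total
#' length, with a smooth balanced coronal arc centred at the apex level and
#' uniform kyphotic/lordotic sagittal arcs, then calibrates the joint angles
#' so that the measured initial angles reproduce the case specification
#' within 0.05 degrees. The built spine is posturally balanced (T1 centroid
#' vertically above the L5 base).
#'
#' @param case A one-row case tibble from [case_spec()] or [default_cases()].
#' @param dims Dimension configuration from [spine_dims()].
#' @return A `spine` object.
#' @export
#' @examples
#' sp <- build_spine(case_spec(3, 10, 10))
#' measure_alignment(sp)
build_spine <- function(case, dims = spine_dims()) {
  stopifnot(nrow(case) == 1)
  # initial guesses: bump amplitude from the small-angle relation
  # max tangent lean = atan(amp * pi / (2 * halfw)) at the inflections
  halfw <- 4 * dims$total_length / 17
  cobb_mag <- abs(case$cobb)  # the curve bulges toward sign(cobb) * Y
  amp <- sign(case$cobb) * tan(deg2rad(cobb_mag) / 2) * 2 * halfw / pi
  thor <- case$kyphosis
  lumb <- case$lordosis
  sp <- NULL
  for (iter in 1:25) {
    sp <- rebalance_spine(build_spine_raw(case, dims, amp, thor, lumb))
    m <- measure_alignment(sp)
    ok_c <- cobb_mag == 0 || abs(m$coronal_cobb - cobb_mag) < 0.01
    ok_k <- abs(m$kyphosis - case$kyphosis) < 0.01
    ok_l <- abs(m$lordosis - case$lordosis) < 0.01
    if (ok_c && ok_k && ok_l) break
    if (cobb_mag != 0) {
      if (m$coronal_cobb < 1e-6) abort("coronal arc construction infeasible")
      amp <- amp * tan(deg2rad(cobb_mag) / 2) / tan(deg2rad(m$coronal_cobb) / 2)
    }
    if (abs(m$kyphosis) > 1e-9) thor <- thor * case$kyphosis / m$kyphosis
    if (abs(m$lordosis) > 1e-9) lumb <- lumb * case$lordosis / m$lordosis
  }
  m <- measure_alignment(sp)
  if ((cobb_mag != 0 && abs(m$coronal_cobb - cobb_mag) > 0.5) ||
      abs(m$kyphosis - case$kyphosis) > 0.5 ||
      abs(m$lordosis - case$lordosis) > 0.5)
    abort("angle calibration did not converge: requested case is infeasible")
  sp
}

#' Discretize a growth-plate cross-section into a polar element grid
#'
#' The circular section is split into `n_radial - 1` equal-width inner rings
#' of cancellous-backed elements plus one dedicated cortical ring of width
#' `cortical_thickness`, each divided into `n_angular` sectors. Element
#' positions are exact area centroids, so the grid conserves total area
#' exactly and first moments to high accuracy.
#'
#' @param radius Section radius, mm.
#' @param cortical_thickness Cortical ring width, mm.
#' @param n_radial Number of radial rings (>= 2, including the cortical ring).
#' @param n_angular Number of angular sectors (>= 8).
#' @return Tibble with element centroid coordinates `x`, `y` (mm, in the
#'   plate plane; x anterior, y left), `area` (mm^2), `zone`
#'   (cortical/cancellous) and backing-bone modulus `E` (MPa).
#' @export
#' @examples
#' g <- discretize_plate(10, 1, 5, 20)
#' sum(g$area) - pi * 100
discretize_plate <- function(radius, cortical_thickness = 1,
                             n_radial = 5, n_angular = 20) {
  if (!is.finite(radius) || radius <= 0) abort("degenerate radius")
  if (cortical_thickness <= 0 || cortical_thickness >= radius)
    abort("cortical thickness must lie in (0, radius)")
  if (n_radial < 2 || n_angular < 8)
    abort("grid resolution too coarse: need n_radial >= 2, n_angular >= 8")
  r_cort <- radius - cortical_thickness
  breaks <- c(seq(0, r_cort, length.out = n_radial), radius)
  r0 <- breaks[-length(breaks)]
  r1 <- breaks[-1]
  dtheta <- 2 * pi / n_angular
  theta_c <- (seq_len(n_angular) - 0.5) * dtheta
  ang_corr <- sin(dtheta / 2) / (dtheta / 2)
  ring <- rep(seq_along(r0), each = n_angular)
  th <- rep(theta_c, times = length(r0))
  rr0 <- r0[ring]; rr1 <- r1[ring]
  area <- dtheta / 2 * (rr1^2 - rr0^2)
  rc <- (2 / 3) * (rr1^3 - rr0^3) / (rr1^2 - rr0^2) * ang_corr
  zone <- ifelse(rr1 > r_cort + 1e-12, "cortical", "cancellous")
  tibble::tibble(
    x = rc * cos(th), y = rc * sin(th), area = area, zone = zone,
    E = ifelse(zone == "cortical", young_modulus("cortical"),
               young_modulus("cancellous"))
  )
}

#' Landmark coordinates of the spine for export and plotting
#'
#' @param spine A spine object.
#' @return Tibble with one row per vertebra: centroid and endplate-centre
#'   coordinates (mm).
#' @export
spine_landmarks <- function(spine) {
  ch <- chain_poses(spine)
  tibble::tibble(
    idx = spine$vertebrae$idx, level = spine$vertebrae$level,
    cx = ch$centroid[, 1], cy = ch$centroid[, 2], cz = ch$centroid[, 3],
    sup_x = ch$p_sup[, 1], sup_y = ch$p_sup[, 2], sup_z = ch$p_sup[, 3],
    inf_x = ch$p_inf[, 1], inf_y = ch$p_inf[, 2], inf_z = ch$p_inf[, 3]
  )
}

rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' Serialize a spine geometry snapshot to JSON
#'
#' Writes levels, centroid positions, orientations (unit quaternions,
#' w-x-y-z), heights, radii and wedge angles.
#'
#' @param spine A spine object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spine_json <- function(spine, path) {
  ch <- chain_poses(spine)
  v <- spine$vertebrae
  out <- list(
    frame = "right-handed; +X anterior, +Y subject-left, +Z cephalad; mm, degrees",
    vertebrae = purrr::map(seq_len(nrow(v)), function(i) {
      list(level = v$level[i],
           position = as.numeric(ch$centroid[i, ]),
           quaternion = as.numeric(rot_to_quat(ch$R_mid[[i]])),
           height = v$height[i], radius = v$radius[i],
           wedge_coronal = v$wedge_cor[i], wedge_sagittal = v$wedge_sag[i])
    }),
    discs = purrr::map(seq_len(nrow(spine$discs)), function(j) {
      d <- spine$discs[j, ]
      list(between = c(d$lower, d$upper), height = d$height,
           angle_coronal = d$angle_cor, angle_sagittal = d$angle_sag)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
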
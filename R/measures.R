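# Clinical alignment measures computed from the 3D geometry: coronal Cobb
# by endplate-inclination extremes, T1-T12 kyphosis, L1-L5 lordosis, and
# per-vertebra axial rotation against the fixed global sagittal plane.

# coronal inclination of an endplate: lean of its normal in the Y-Z plane,
# positive toward +Y; sagittal inclination: lean in X-Z, positive toward +X
plate_inclinations <- function(Rlist) {
  n <- length(Rlist)
  cor <- numeric(n); sag <- numeric(n)
  for (i in seq_len(n)) {
    nz <- Rlist[[i]][, 3]
    cor[i] <- atan2(nz[2], nz[3])
    sag[i] <- atan2(nz[1], nz[3])
  }
  list(cor = rad2deg(cor), sag = rad2deg(sag))
}

#' Coronal Cobb angle
#'
#' Projects every endplate onto the coronal plane and returns the maximum
#' absolute difference between the superior-endplate inclination of an upper
#' vertebra and the inferior-endplate inclination of a lower vertebra (the
#' clinical end-vertebra construction), together with the maximizing pair.
#'
#' @param spine A spine object.
#' @return A list with `angle` (degrees, >= 0), `upper_end` and `lower_end`
#'   (level labels).
#' @export
coronal_cobb <- function(spine) {
  ch <- chain_poses(spine)
  sup <- plate_inclinations(ch$R_sup)$cor
  inf <- plate_inclinations(ch$R_inf)$cor
  n <- length(sup)
  best <- 0; bu <- 1; bl <- n
  for (u in 1:n) {
    for (l in u:n) {
      d <- abs(sup[u] - inf[l])
      if (d > best) { best <- d; bu <- u; bl <- l }
    }
  }
  levels <- spine$vertebrae$level
  list(angle = best, upper_end = levels[bu], lower_end = levels[bl])
}

#' Thoracic kyphosis angle
#'
#' Sagittal-plane angle between the superior endplate of T1 and the inferior
#' endplate of T12, signed so that a normal (posterior-convex) thoracic
#' curve is positive.
#'
#' @param spine A spine object.
#' @return Angle in degrees.
#' @export
kyphosis <- function(spine) {
  ch <- chain_poses(spine)
  sup <- plate_inclinations(ch$R_sup)$sag
  inf <- plate_inclinations(ch$R_inf)$sag
  sup[1] - inf[12]
}

#' Lumbar lordosis angle
#'
#' Sagittal-plane angle between the superior endplate of L1 and the inferior
#' endplate of L5, signed so that a normal (anterior-convex) lumbar curve is
#' positive.
#'
#' @param spine A spine object.
#' @return Angle in degrees.
#' @export
lordosis <- function(spine) {
  ch <- chain_poses(spine)
  sup <- plate_inclinations(ch$R_sup)$sag
  inf <- plate_inclinations(ch$R_inf)$sag
  inf[17] - sup[13]
}

#' Per-vertebra axial rotation
#'
#' Rotation of each vertebra's local anterior axis about its cephalocaudal
#' axis, measured against the fixed global sagittal plane (the reference
#' direction is the projection of global +X onto the vertebra's transverse
#' plane). The global frame is fixed by convention; rigid reorientation of
#' the whole spine therefore changes this measure (but no inter-vertebral
#' measure).
#'
#' @param spine A spine object.
#' @return Tibble with `level` and `rotation` (degrees, signed; positive =
#'   anterior axis turned toward +Y).
#' @export
axial_rotation <- function(spine) {
  ch <- chain_poses(spine)
  n <- length(ch$R_mid)
  rot <- numeric(n)
  for (i in seq_len(n)) {
    R <- ch$R_mid[[i]]
    zl <- R[, 3]; a <- R[, 1]
    ref <- c(1, 0, 0) - zl[1] * zl
    nr <- sqrt(sum(ref^2))
    if (nr < 1e-9) { rot[i] <- NA_real_; next }
    ref <- ref / nr
    rot[i] <- rad2deg(atan2(sum(cross3(ref, a) * zl), sum(ref * a)))
  }
  tibble::tibble(level = spine$vertebrae$level, rotation = rot)
}

#' All alignment measures at once
#'
#' @param spine A spine object.
#' @param age Optional age (years) to annotate the record with.
#' @return One-row tibble: `age`, `coronal_cobb`, `kyphosis`, `lordosis`,
#'   `max_axial_rotation` (degrees) and the Cobb end vertebrae.
#' @export
measure_alignment <- function(spine, age = NA_real_) {
  cb <- coronal_cobb(spine)
  ax <- axial_rotation(spine)
  tibble::tibble(
    age = age,
    coronal_cobb = cb$angle,
    kyphosis = kyphosis(spine),
    lordosis = lordosis(spine),
    max_axial_rotation = max(abs(ax$rotation), na.rm = TRUE),
    upper_end = cb$upper_end,
    lower_end = cb$lower_end
  )
}
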
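# Small rigid-body helpers shared by the geometry and measurement code.
# Global frame convention (right-handed): +X anterior, +Y subject-left,
# +Z cephalad.  Angles at the user surface are degrees; internals radians.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_x <- function(theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  matrix(c(1, 0, 0,
           0, c1, s1,
           0, -s1, c1), 3, 3)
}

rot_y <- function(theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  matrix(c(c1, 0, -s1,
           0, 1, 0,
           s1, 0, c1), 3, 3)
}

rot_z <- function(theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  matrix(c(c1, s1, 0,
           -s1, c1, 0,
           0, 0, 1), 3, 3)
}

# Minimal rotation taking unit vector `from` onto unit vector `to`
# (Rodrigues). Identity when the two are (anti)parallel within tolerance.
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  s <- sqrt(sum(v^2))
  c0 <- sum(from * to)
  if (s < 1e-12) {
    if (c0 > 0) return(diag(3))
    # 180 degree flip: pick any perpendicular axis
    axis <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * from) * from
    axis <- axis / sqrt(sum(axis^2))
    return(2 * tcrossprod(axis) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2],
                 -v[3], 0, v[1],
                 v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
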
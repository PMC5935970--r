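# Internal 3D geometry utilities shared by the secondary-structure assigner
# and the synthetic coordinate generators. All coordinates are in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-9) stop("cannot normalise a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle between two vectors in degrees, clamped for numerical safety.
vec_angle_deg <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# Place atom D given three predecessors A-B-C, bond length |C-D|, bond angle
# B-C-D (degrees) and dihedral A-B-C-D (degrees). Standard internal-coordinate
# (NeRF) construction used to grow backbones from phi/psi/omega.
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  theta <- angle_deg * pi / 180
  chi <- dihedral_deg * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(theta),
          bond * sin(theta) * cos(chi),
          bond * sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Rotation matrix mapping unit vector `from` onto unit vector `to` by the
# minimal rotation; the antipodal case rotates 180 degrees about +z (or +x if
# `from` is along z) so the mapping stays deterministic.
rotation_between <- function(from, to) {
  f <- unitv(from); t <- unitv(to)
  d <- sum(f * t)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    ax <- if (abs(f[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
    return(rotation_axis_angle(ax, 180))
  }
  ax <- unitv(cross3(f, t))
  rotation_axis_angle(ax, acos(max(-1, min(1, d))) * 180 / pi)
}

rotation_axis_angle <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Apply rotation R then translation t to an n x 3 coordinate matrix
# (rows may be NA for absent atoms).
transform_coords <- function(xyz, R, t) {
  out <- xyz %*% t(R)
  out[, 1] <- out[, 1] + t[1]
  out[, 2] <- out[, 2] + t[2]
  out[, 3] <- out[, 3] + t[3]
  out
}
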
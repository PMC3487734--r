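# Small 3-vector helpers shared across the package. All lengths in Angstrom,
# all angles in degrees unless a name says otherwise.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle between two vectors in degrees
#' @param a,b numeric 3-vectors.
#' @return angle in `[0, 180]` degrees.
#' @keywords internal
vec_angle <- function(a, b) {
  ca <- sum(a * b) / (vec_norm(a) * vec_norm(b))
  rad2deg(acos(pmin(1, pmax(-1, ca))))
}

# Rotation matrix for a right-handed rotation by `angle_deg` about unit axis.
rotation_matrix <- function(axis, angle_deg) {
  u <- unit_vec(axis)
  th <- deg2rad(angle_deg)
  c_ <- cos(th); s_ <- sin(th); C <- 1 - c_
  x <- u[1L]; y <- u[2L]; z <- u[3L]
  matrix(c(
    c_ + x * x * C,     x * y * C - z * s_, x * z * C + y * s_,
    y * x * C + z * s_, c_ + y * y * C,     y * z * C - x * s_,
    z * x * C - y * s_, z * y * C + x * s_, c_ + z * z * C
  ), nrow = 3L, byrow = TRUE)
}

# Rotate an N x 3 coordinate block about a point.
rotate_about <- function(xyz, axis, angle_deg, origin = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  sweep(sweep(xyz, 2L, origin, "-") %*% t(R), 2L, origin, "+")
}

# Proper dihedral angle (IUPAC sign convention) for four points, degrees in
# (-180, 180]. Returns NA for degenerate (collinear) configurations.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (vec_norm(n1) < 1e-9 || vec_norm(n2) < 1e-9) return(NA_real_)
  m1 <- cross3(n1, unit_vec(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(-y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Run code with a local RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
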
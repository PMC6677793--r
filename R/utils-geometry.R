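# Small vector/rotation helpers shared by the geometry modules.
# All angles at the user surface are degrees; radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

## Angle between two vectors, degrees in [0, 180].
angle_between <- function(a, b) {
  ca <- sum(unit_vec(a) * unit_vec(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

## Signed angle from a to b about unit axis u (right-hand rule), degrees in (-180, 180].
signed_angle <- function(a, b, u) {
  u <- unit_vec(u)
  ang <- rad2deg(atan2(sum(crossprod3(a, b) * u), sum(a * b)))
  if (ang <= -180) ang <- ang + 360
  ang
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Rotation matrix for angle degrees about an arbitrary axis (Rodrigues).
rotation_about <- function(axis, angle_deg) {
  u <- unit_vec(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Minimal rotation taking unit vector a onto unit vector b.
rotation_aligning <- function(a, b) {
  a <- unit_vec(a); b <- unit_vec(b)
  v <- crossprod3(a, b)
  s <- vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- unit_vec(crossprod3(a, p))
    return(rotation_about(perp, 180))
  }
  rotation_about(v, rad2deg(atan2(s, c_)))
}

## Apply rigid transform to an n x 3 coordinate matrix.
transform_coords <- function(xyz, rot = diag(3), trans = c(0, 0, 0)) {
  sweep(xyz %*% t(rot), 2, -trans)
}

## Total-least-squares line fit through n x 3 points: list(center, direction).
fit_line <- function(xyz) {
  if (nrow(xyz) < 2) stop("need at least 2 points to fit a line", call. = FALSE)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(center = ctr, direction = sv$v[, 1])
}
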
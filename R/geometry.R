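# Small 3D geometry kernel shared by the trajectory modules.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a^2))

vunit <- function(a) a / vnorm(a)

# rotation matrix about z (degrees)
rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# rotation about an arbitrary axis through `origin` (Rodrigues)
rot_axis <- function(deg, axis, origin = c(0, 0, 0)) {
  u <- vunit(axis)
  t <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
  list(R = R, origin = origin)
}

apply_rot <- function(xyz, rot) {
  sweep(sweep(xyz, 2, rot$origin) %*% t(rot$R), 2, rot$origin, "+")
}

#' Dihedral angle over four points
#'
#' Standard signed torsion angle of the four points `p1`-`p4`, measured about
#' the `p2`-`p3` axis, in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# angle at `h` between `a` and `d`, degrees
angle_at <- function(a, h, d) {
  v1 <- a - h; v2 <- d - h
  cosv <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
  acos(max(-1, min(1, cosv))) * 180 / pi
}

# Kabsch: optimal rotation/translation of `mob` onto `ref` (n x 3 matrices)
kabsch_fit <- function(mob, ref) {
  cm <- colMeans(mob); cr <- colMeans(ref)
  H <- t(sweep(mob, 2, cm)) %*% sweep(ref, 2, cr)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, center_mob = cm, center_ref = cr)
}

kabsch_apply <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_mob) %*% t(fit$R), 2, fit$center_ref, "+")
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
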
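# Low-level vector/rotation machinery shared by all modules.
# Conventions: coordinates are plain numeric length-3 vectors or n x 3
# matrices in Angstrom; rotation matrices are 3x3, proper (det = +1), and act
# on column vectors; angles are degrees at every public surface, radians only
# inside a function body.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `theta` degrees about the (not necessarily unit)
#' axis `axis`.
#'
#' @param axis numeric length-3 axis vector.
#' @param theta rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rot_axis <- function(axis, theta) {
  u <- unitv(axis)
  th <- theta * DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) + st * K + (1 - ct) * (K %*% K)
}

rot_x <- function(theta) rot_axis(c(1, 0, 0), theta)
rot_y <- function(theta) rot_axis(c(0, 1, 0), theta)
rot_z <- function(theta) rot_axis(c(0, 0, 1), theta)

# Signed angle (degrees, in (-180, 180]) from vector a to vector b measured
# about the axis n (right-hand rule). a and b need not be perpendicular to n;
# their components along n are discarded.
signed_angle <- function(a, b, n) {
  n <- unitv(n)
  a <- a - sum(a * n) * n
  b <- b - sum(b * n) * n
  ang <- atan2(sum(cross3(a, b) * n), sum(a * b)) / DEG
  wrap_angle(ang)
}

# Map any angle in degrees into (-180, 180].
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

# Shortest signed angular difference a - b in degrees, in (-180, 180].
angle_diff <- function(a, b) wrap_angle(a - b)

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking from atom 2 toward atom 3, the dihedral is
#' the clockwise rotation carrying the 2->1 projection onto the 3->4
#' projection; cis = 0, trans = 180.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  wrap_angle(-atan2(sum(m1 * n2), sum(n1 * n2)) / DEG)
}

#' Bond angle of three points
#'
#' @param p1,p2,p3 numeric length-3 coordinates; the angle is at `p2`.
#' @return angle in degrees in `[0, 180]`.
#' @export
bond_angle <- function(p1, p2, p3) {
  a <- unitv(p1 - p2); b <- unitv(p3 - p2)
  acos(max(-1, min(1, sum(a * b)))) / DEG
}

# Place a new atom D given three reference atoms A, B, C and the internal
# coordinates bond |C-D|, angle B-C-D (deg) and dihedral A-B-C-D (deg).
# Standard NeRF construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * DEG; ph <- torsion * DEG
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `target`,
#' computed by SVD of the covariance matrix with the reflection guard, so a
#' proper rotation is always returned.
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows (n >= 3,
#'   not collinear).
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3x3), `translation` (length 3; the transform
#'   is `x %*% t(rotation) + translation`), and `rmsd` after the fit.
#' @export
kabsch <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 point pairs")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  # collinearity check: rank of the centred set
  if (svd(P)$d[2] < 1e-8 * max(1, svd(P)$d[1]))
    stop("point set is (near-)collinear; rotation is not determined")
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((moved - Q)^2)))
  list(rotation = R, translation = as.numeric(ct - R %*% cm), rmsd = rmsd)
}

# Apply a rigid transform (rotation R then translation t) to an n x 3 matrix.
apply_rigid <- function(xyz, R, t) {
  sweep(as.matrix(xyz) %*% t(R), 2, -t)
}

#' Root-mean-square deviation without refitting
#'
#' @param a,b matched n x 3 coordinate matrices.
#' @return RMSD in the same units as the coordinates.
#' @export
rmsd_no_fit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("matched coordinate sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}

# Deterministic orthonormalisation of a near-rotation matrix.
orthonormalize <- function(M) {
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  R
}
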
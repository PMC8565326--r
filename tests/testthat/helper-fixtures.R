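# Shared fixtures, generated in code. A few standard objects are cached per
# test run because building a duplex involves the backbone closure pass.

.fix_cache <- new.env(parent = emptyenv())

fix_cached <- function(key, builder) {
  if (!exists(key, envir = .fix_cache)) assign(key, builder(),
                                              envir = .fix_cache)
  get(key, envir = .fix_cache)
}

# ideal B-form 12-mer
fix_ideal12 <- function() fix_cached("ideal12", function()
  build_duplex("ATGCATGCATGC"))

# the consensus target heptamer with rel_pos numbering (+1 = first A)
fix_target <- function() fix_cached("target", function() {
  s <- build_duplex("TTTTTAA")
  assign_relative_numbering(s, c("A", 6))
})

# target duplex with the scissile phosphate in two conformations (a large
# coordinated flip, chosen so the two phosphate positions are well apart)
fix_two_conformer <- function() fix_cached("two_conformer", function()
  rotate_phosphate(fix_target(), c("A", 6), 140, -90, as_altloc = TRUE))

# random rotation matrix (uniform-ish via QR)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# rigidly transform a structure3d
transform_structure <- function(s, R, t) {
  set_coords3d(s, sweep(coords3d(s) %*% t(R), 2, -t))
}

# independent brute-force dihedral: rotate the frame so the central bond is
# +z, read the angle from projected xy coordinates (no code shared with
# dihedral()).
bf_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  bz <- b / sqrt(sum(b^2))
  # any perpendicular
  ref <- if (abs(bz[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  bx <- ref - sum(ref * bz) * bz
  bx <- bx / sqrt(sum(bx^2))
  by <- c(bz[2] * bx[3] - bz[3] * bx[2],
          bz[3] * bx[1] - bz[1] * bx[3],
          bz[1] * bx[2] - bz[2] * bx[1])
  M <- rbind(bx, by, bz)
  u <- as.numeric(M %*% (p1 - p2))
  v <- as.numeric(M %*% (p4 - p3))
  a1 <- atan2(u[2], u[1])
  a2 <- atan2(v[2], v[1])
  ang <- (a2 - a1) * 180 / pi
  ang <- ((ang + 180) %% 360) - 180
  if (ang == -180) 180 else ang
}

# brute-force rigid superposition: optimise Euler angles from many starts
bf_superpose_rmsd <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  obj <- function(e) {
    R <- euler_rot(e)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- Inf
  set.seed(99)
  starts <- rbind(c(0, 0, 0),
                  matrix(stats::runif(3 * 40, -180, 180), ncol = 3))
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

euler_rot <- function(e) {
  r <- e * pi / 180
  cz1 <- cos(r[1]); sz1 <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz2 <- cos(r[3]); sz2 <- sin(r[3])
  Rz1 <- matrix(c(cz1, -sz1, 0, sz1, cz1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz2 <- matrix(c(cz2, -sz2, 0, sz2, cz2, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}
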
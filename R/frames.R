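# Base reference frames and the mid-frame (CEHS-style) decomposition of
# rigid-body parameters between frames. A "frame" is a list(R = 3x3 rotation
# whose columns are the x/y/z axes, origin = length-3 vector). The same
# decomposition yields base-pair (intra) parameters and base-pair-step
# parameters; only the frame roles differ.

new_frame <- function(R, origin) {
  stopifnot(all(dim(R) == c(3, 3)))
  list(R = R, origin = as.numeric(origin))
}

frame_ok <- function(f, tol = 1e-8) {
  max(abs(t(f$R) %*% f$R - diag(3))) < tol && det(f$R) > 0
}

# Flip a frame for a strand-2 base: its own y and z axes are negated so the
# flipped frame is co-aligned with the strand-1 frame of the same pair.
flip_frame <- function(f) new_frame(f$R %*% diag(c(1, -1, -1)), f$origin)

# Mid-frame decomposition of frame2 relative to frame1.
# Returns translations (d1, d2, d3) along the mid-frame x/y/z and rotations
# (rho1 about x-like hinge component, rho2, rho3 = twist-like) in degrees,
# plus the mid frame itself. Mapping to named parameters:
#   step:  shift slide rise  tilt  roll  twist
#   intra: shear stretch stagger buckle propeller opening
frame_params <- function(f1, f2) {
  if (!frame_ok(f1) || !frame_ok(f2)) stop("frame axes are not orthonormal")
  R1 <- f1$R; R2 <- f2$R
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cz <- max(-1, min(1, sum(z1 * z2)))
  gamma <- acos(cz) / DEG
  hvec <- cross3(z1, z2)
  if (vnorm(hvec) < 1e-9) {
    # aligned (no bend) or exactly antiparallel (degenerate hinge: pick
    # the frame-1 x axis by convention)
    if (cz > 0) {
      R1p <- R1; R2p <- R2
      hinge <- NULL
      gamma <- 0
    } else {
      hinge <- R1[, 1]
      R1p <- rot_axis(hinge, +gamma / 2) %*% R1
      R2p <- rot_axis(hinge, -gamma / 2) %*% R2
    }
  } else {
    hinge <- unitv(hvec)
    R1p <- rot_axis(hinge, +gamma / 2) %*% R1
    R2p <- rot_axis(hinge, -gamma / 2) %*% R2
  }
  zm <- R1p[, 3]
  omega <- signed_angle(R1p[, 1], R2p[, 1], zm)
  xm <- unitv(R1p[, 1] + R2p[, 1])
  ym <- cross3(zm, xm)
  Rm <- cbind(xm, ym, zm)
  if (is.null(hinge)) {
    rho1 <- 0; rho2 <- 0
  } else {
    phi <- signed_angle(hinge, ym, zm)
    rho2 <- gamma * cos(phi * DEG)   # roll / propeller
    rho1 <- gamma * sin(phi * DEG)   # tilt / buckle
  }
  d <- f2$origin - f1$origin
  tr <- as.numeric(t(Rm) %*% d)
  list(d1 = tr[1], d2 = tr[2], d3 = tr[3],
       rho1 = rho1, rho2 = rho2, rho3 = omega,
       mid = new_frame(Rm, (f1$origin + f2$origin) / 2))
}

# Exact inverse of frame_params: given frame1 and the six parameters, build
# frame2 (and the mid frame).
frame_compose <- function(f1, d1, d2, d3, rho1, rho2, rho3) {
  gamma <- sqrt(rho1^2 + rho2^2)
  phi <- if (gamma < 1e-12) 0 else atan2(rho1, rho2) / DEG
  hm <- c(sin(phi * DEG), cos(phi * DEG), 0)
  Rh <- function(theta) if (gamma < 1e-12) diag(3) else rot_axis(hm, theta)
  Rm <- f1$R %*% rot_z(rho3 / 2) %*% Rh(gamma / 2)
  R2 <- f1$R %*% rot_z(rho3 / 2) %*% Rh(gamma) %*% rot_z(rho3 / 2)
  o2 <- f1$origin + as.numeric(Rm %*% c(d1, d2, d3))
  list(frame2 = new_frame(R2, o2),
       mid = new_frame(Rm, (f1$origin + o2) / 2))
}

# Build the two frames that sit symmetrically about a given mid frame with
# the stated parameters (used by the duplex builder).
frames_about_mid <- function(mid, d1, d2, d3, rho1, rho2, rho3) {
  gamma <- sqrt(rho1^2 + rho2^2)
  phi <- if (gamma < 1e-12) 0 else atan2(rho1, rho2) / DEG
  hm <- c(sin(phi * DEG), cos(phi * DEG), 0)
  Rh <- function(theta) if (gamma < 1e-12) diag(3) else rot_axis(hm, theta)
  R1 <- mid$R %*% Rh(-gamma / 2) %*% rot_z(-rho3 / 2)
  R2 <- mid$R %*% Rh(+gamma / 2) %*% rot_z(+rho3 / 2)
  half <- as.numeric(mid$R %*% c(d1, d2, d3)) / 2
  list(frame1 = new_frame(R1, mid$origin - half),
       frame2 = new_frame(R2, mid$origin + half))
}

#' Intra-base-pair parameters from two base frames
#'
#' Computes shear, stretch, stagger (Angstrom) and buckle, propeller, opening
#' (degrees) of a base pair from the reference frames of its two bases, using
#' the mid-frame decomposition after flipping the strand-2 frame. Parameters
#' describe the strand-1 base relative to the (flipped) strand-2 base.
#'
#' @param f1 frame of the strand-1 base (as from [fit_base_frame()]).
#' @param f2 frame of the strand-2 (complementary) base.
#' @return list of the six parameters plus `pair_frame`, the base-pair frame.
#' @export
basepair_params <- function(f1, f2) {
  p <- frame_params(flip_frame(f2), f1)
  list(shear = p$d1, stretch = p$d2, stagger = p$d3,
       buckle = p$rho1, propeller = p$rho2, opening = p$rho3,
       pair_frame = p$mid)
}

#' Base-pair-step parameters from two base-pair frames
#'
#' Computes shift, slide, rise (Angstrom) and tilt, roll, twist (degrees)
#' between consecutive base-pair frames by the mid-step-frame decomposition:
#' roll is the rotation about the mid-step y axis, twist about z.
#'
#' @param bp1,bp2 base-pair frames of consecutive pairs (5' to 3' on strand 1).
#' @return list of the six step parameters plus `mid_frame`.
#' @export
step_params <- function(bp1, bp2) {
  p <- frame_params(bp1, bp2)
  list(shift = p$d1, slide = p$d2, rise = p$d3,
       tilt = p$rho1, roll = p$rho2, twist = p$rho3,
       mid_frame = p$mid)
}

#' Fit the standard base reference frame to an observed nucleotide
#'
#' Least-squares rigid superposition of the embedded consensus base geometry
#' (standard reference frame convention) onto the observed ring atoms;
#' purines use the nine-atom, pyrimidines the six-atom ring set.
#'
#' @param coords named n x 3 matrix of observed heavy-atom coordinates for
#'   one nucleotide (row names are atom names, e.g. "N9", "C2").
#' @param base base identity ("DA", "DG", "DC", "DT" or one-letter).
#' @param min_atoms minimum number of ring atoms required (default 6).
#' @return a base frame: list with `R` (columns x,y,z axes), `origin`, and
#'   `fit_rmsd` (Angstrom).
#' @export
fit_base_frame <- function(coords, base, min_atoms = 6) {
  nb <- normalize_base_name(base)
  if (is.na(nb)) stop("not a recognised nucleotide base: ", base)
  std <- std_base(nb)
  ring <- ring_atom_names(nb)
  have <- intersect(ring, rownames(coords))
  if (length(have) < min_atoms)
    stop("too few ring atoms for frame fit (", length(have), " found, ",
         min_atoms, " required)")
  fit <- kabsch(std[have, , drop = FALSE], coords[have, , drop = FALSE])
  f <- new_frame(fit$rotation, fit$translation)
  f$fit_rmsd <- fit$rmsd
  f
}
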
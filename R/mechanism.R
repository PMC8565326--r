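# Catalytic-mechanism modeling: torsion-driven phosphate rotation paths,
# pentacoordinate (trigonal-bipyramidal) phosphorane transition-state
# construction, metal coordination-shell analysis, water displacement, and
# the restrained morph between apo+ion and DNA-bound conformations.

#' Drive a scissile phosphate between two conformers
#'
#' Linear interpolation (shortest angular route) of the alpha and gamma
#' backbone torsions between the start and end conformers in steps of
#' 1/`n_steps` of the total change. At each step the remaining linkage
#' torsions (epsilon, zeta, beta) are relaxed under (a) harmonic restraints
#' keeping the downstream sugar at its fixed position and (b) a harmonic
#' smoothness restraint to the previous step's values. Covalent bond
#' lengths and angles are taken from the start conformer and held fixed, so
#' the motion is torsion-only by construction.
#'
#' @param start,end `structure3d` conformers sharing atom identity (e.g. the
#'   two altloc conformers of a scissile phosphate, extracted with
#'   [resolve_altlocs()]).
#' @param nucleotide `c(chain, resseq)` of the nucleotide whose 5' phosphate
#'   is driven.
#' @param n_steps number of driving steps (default 100, giving
#'   `n_steps + 1` frames including both endpoints).
#' @param w_smooth smoothness restraint weight (A^2 per deg^2).
#' @return object of class `torsion_path`: per-frame driven torsions,
#'   mobile-atom coordinates, restraint energies, and the fixed context.
#' @export
torsion_drive <- function(start, end, nucleotide, n_steps = 100,
                          w_smooth = 1e-4) {
  chain <- as.character(nucleotide[1]); resseq <- as.integer(nucleotide[2])
  lk0 <- linkage_extract(start, chain, resseq)
  lk1 <- linkage_extract(end, chain, resseq)
  anchor_gap <- sqrt(max(rowSums((lk0$pos[c("C4'p", "C3'p", "O3'p", "C4'",
                                            "C3'", "O3'"), ] -
                                    lk1$pos[c("C4'p", "C3'p", "O3'p", "C4'",
                                              "C3'", "O3'"), ])^2)))
  if (anchor_gap > 0.5)
    stop("flanking sugar anchors differ by ", round(anchor_gap, 2),
         " A between conformers (> 0.5 A): not the same context")
  t0 <- lk0$torsions; t1 <- lk1$torsions
  d_alpha <- angle_diff(t1[["alpha"]], t0[["alpha"]])
  d_gamma <- angle_diff(t1[["gamma"]], t0[["gamma"]])
  # express the end conformer in the start conformer's internal-coordinate
  # system: recover the free torsions that best reproduce its mobile atoms
  # (the measured end torsions involve the fixed downstream sugar and can
  # sit in the other loop-closure basin)
  end_fit <- linkage_fit_free(
    lk0, t1[["alpha"]], t1[["gamma"]],
    lk1$pos[c("P", "O5'", "C5'"), , drop = FALSE],
    init = c(t1[["epsilon"]], t1[["zeta"]], t1[["beta"]]))
  f0 <- c(t0[["epsilon"]], t0[["zeta"]], t0[["beta"]])
  d_free <- angle_diff(end_fit$free, f0)
  mobile <- c("P", "OP1", "OP2", "O5'", "C5'")
  frames <- vector("list", n_steps + 1)
  driven <- data.frame(step = 0:n_steps, alpha = NA_real_, gamma = NA_real_,
                       epsilon = NA_real_, zeta = NA_real_, beta = NA_real_,
                       energy = NA_real_)
  prev_free <- c(t0[["epsilon"]], t0[["zeta"]], t0[["beta"]])
  for (k in 0:n_steps) {
    fr <- k / n_steps
    a_k <- wrap_angle(t0[["alpha"]] + fr * d_alpha)
    g_k <- wrap_angle(t0[["gamma"]] + fr * d_gamma)
    if (k == 0) {
      pos <- rbind(lk0$pos[c("P", "O5'", "C5'"), ],
                   linkage_rebuild(lk0, t0[["epsilon"]], t0[["zeta"]],
                                   t0[["alpha"]], t0[["beta"]],
                                   t0[["gamma"]])[c("OP1", "OP2"), ])
      pos <- pos[mobile, , drop = FALSE]
      dimnames(pos) <- list(mobile, NULL)
      frames[[k + 1]] <- pos
      driven[k + 1, 2:7] <- c(a_k, g_k, prev_free[1], prev_free[2],
                              prev_free[3], 0)
      next
    }
    init <- wrap_angle(f0 + fr * d_free)
    if (k == n_steps) {
      # the final frame is the end conformer itself
      rx <- list(free = end_fit$free,
                 value = linkage_anchor_ss(
                   lk0, linkage_rebuild(lk0, end_fit$free[1],
                                        end_fit$free[2], a_k,
                                        end_fit$free[3], g_k)))
    } else {
      rx <- linkage_relax(lk0, a_k, g_k, init = init, prev = prev_free,
                          w_s = w_smooth, target = init,
                          w_t = 10 * w_smooth)
    }
    free_k <- wrap_angle(rx$free)
    built <- linkage_rebuild(lk0, free_k[1], free_k[2], a_k, free_k[3],
                             g_k)
    frames[[k + 1]] <- built[mobile, , drop = FALSE]
    driven[k + 1, 2:7] <- c(a_k, g_k, free_k[1], free_k[2], free_k[3],
                            rx$value)
    prev_free <- free_k
  }
  out <- list(context = start, nucleotide = c(chain, resseq),
              mobile_atoms = mobile, frames = frames, driven = driven,
              alpha_range = c(t0[["alpha"]], t1[["alpha"]]),
              gamma_range = c(t0[["gamma"]], t1[["gamma"]]),
              n_steps = n_steps, linkage = lk0)
  class(out) <- "torsion_path"
  out
}

#' @export
print.torsion_path <- function(x, ...) {
  cat("torsion_path:", x$n_steps + 1, "frames; alpha",
      sprintf("%.1f -> %.1f", x$alpha_range[1], x$alpha_range[2]),
      "gamma", sprintf("%.1f -> %.1f", x$gamma_range[1], x$gamma_range[2]),
      "\n")
  invisible(x)
}

#' Convert a torsion path to a multi-model structure
#'
#' @param path a `torsion_path`.
#' @return a `structure3d` with one model per frame (for PDB animation
#'   export).
#' @export
path_to_structure <- function(path) {
  base <- path$context$atoms
  chain <- path$nucleotide[1]; resseq <- as.integer(path$nucleotide[2])
  per <- lapply(seq_along(path$frames), function(k) {
    at <- base
    at$model <- as.integer(k)
    for (nm in path$mobile_atoms) {
      r <- which(at$chain == chain & at$resseq == resseq & at$name == nm)
      at[r, c("x", "y", "z")] <- matrix(path$frames[[k]][nm, ], length(r),
                                        3, byrow = TRUE)
    }
    at
  })
  out <- structure3d(do.call(rbind, per), id = paste0(path$context$id,
                                                      "_path"))
  out$water_labels <- path$context$water_labels
  out
}

#' Per-frame distances from the driven phosphate to probe sites
#'
#' @param path a `torsion_path`.
#' @param probes named list of probe positions: atom specs resolved against
#'   the path context (e.g. "W5", "MG", "A:5:O3'") or length-3 vectors.
#' @return list with `table` (long data.frame: frame, probe, atom,
#'   distance) and `argmin` (frame of minimal P-probe distance per probe).
#' @export
path_distance_report <- function(path, probes) {
  if (!length(probes)) stop("no probes given")
  if (is.null(names(probes)) || any(!nzchar(names(probes))))
    stop("probes must be named")
  sites <- lapply(probes, function(p) {
    if (is.numeric(p) && length(p) == 3) as.numeric(p)
    else atom_xyz(resolve_atom(path$context, p))
  })
  atoms <- intersect(c("P", "OP1", "OP2", "O5'"), path$mobile_atoms)
  rows <- list()
  for (k in seq_along(path$frames)) {
    for (pn in names(sites)) {
      for (an in atoms) {
        rows[[length(rows) + 1]] <- data.frame(
          frame = k - 1, probe = pn, atom = an,
          distance = vnorm(path$frames[[k]][an, ] - sites[[pn]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  pp <- tab[tab$atom == "P", , drop = FALSE]
  argmin <- do.call(rbind, lapply(split(pp, pp$probe), function(g)
    data.frame(probe = g$probe[1], frame = g$frame[which.min(g$distance)],
               distance = min(g$distance), stringsAsFactors = FALSE)))
  rownames(argmin) <- NULL
  list(table = tab, argmin = argmin)
}

#' Build a pentacoordinate phosphorane transition-state model
#'
#' Places an ideal trigonal bipyramid at the phosphorus of the (rotated)
#' scissile phosphate: axial positions for the upstream O3' (leaving group)
#' and the attacking nucleophile oxygen, equatorial for O5', OP1 and OP2.
#' Internal geometry is fixed (axial P-O `ax_len`, equatorial `eq_len`,
#' angles exactly 180/120/90 degrees); only the rigid orientation about P
#' is optimized, minimizing the RMSD between the placed vertices and the
#' five existing/target oxygen directions.
#'
#' @param s a `structure3d` containing the rotated conformer.
#' @param nucleotide `c(chain, resseq)` of the scissile (+1) nucleotide.
#' @param attack position of the nucleophile oxygen (length-3 vector or an
#'   atom spec, e.g. a crystallographic water "W5").
#' @param ax_len,eq_len axial and equatorial P-O bond lengths (defaults
#'   1.76 / 1.60 A, small-molecule phosphorane values).
#' @param altloc altloc label of the conformer to use (e.g. "B").
#' @return object of class `phosphorane_model`: P position, the five O
#'   positions with axial/equatorial assignment, bond lengths/angles,
#'   placement residual (A), and `structure`, the context with OP1/OP2/O5'
#'   moved to the phosphorane vertices and the nucleophile added as a
#'   separate "NUC" oxygen.
#' @export
build_phosphorane <- function(s, nucleotide, attack, ax_len = 1.76,
                              eq_len = 1.60, altloc = NULL) {
  chain <- as.character(nucleotide[1]); resseq <- as.integer(nucleotide[2])
  lk <- linkage_extract(s, chain, resseq, altloc = altloc)
  p <- lk$pos["P", ]
  att <- if (is.numeric(attack) && length(attack) == 3) as.numeric(attack)
  else atom_xyz(resolve_atom(s, attack))
  cur <- res_coords(residue_atoms(s, chain, resseq), altloc = altloc)
  targets <- rbind("O3'p" = lk$pos["O3'p", ], NUC = att,
                   "O5'" = cur["O5'", ], OP1 = cur["OP1", ],
                   OP2 = cur["OP2", ])
  fit <- tbp_fit(p, targets["O3'p", ], targets["NUC", ], targets["O5'", ],
                 targets["OP1", ], targets["OP2", ], ax_len, eq_len)
  placed <- fit$placed
  rownames(placed) <- rownames(targets)
  residual <- fit$residual
  axial <- c("O3'p", "NUC"); equatorial <- c("O5'", "OP1", "OP2")
  bonds <- setNames(sqrt(rowSums(sweep(placed, 2, p)^2)), rownames(placed))
  angs <- outer(rownames(placed), rownames(placed),
                Vectorize(function(i, j)
                  if (i == j) NA_real_ else
                    bond_angle(placed[i, ], p, placed[j, ])))
  dimnames(angs) <- list(rownames(placed), rownames(placed))
  out_s <- s
  at <- out_s$atoms
  for (nm in equatorial) {
    r <- which(at$chain == chain & at$resseq == resseq & at$name == nm &
                 (is.null(altloc) | at$altloc %in% c("", altloc)))
    at[r, c("x", "y", "z")] <- matrix(placed[nm, ], length(r), 3,
                                      byrow = TRUE)
  }
  nuc_row <- data.frame(record = "HETATM", serial = max(at$serial) + 1L,
                        name = "O", altloc = "", resname = "NUC",
                        chain = chain, resseq = 9999L, icode = "",
                        x = placed["NUC", 1], y = placed["NUC", 2],
                        z = placed["NUC", 3], occ = 1, b = 0, element = "O",
                        model = 1L, rel_pos = NA_integer_,
                        stringsAsFactors = FALSE)
  out_s$atoms <- rbind(at, nuc_row)
  out <- list(P = p, vertices = placed, axial = axial,
              equatorial = equatorial, bonds = bonds, angles = angs,
              residual = residual, structure = out_s)
  class(out) <- "phosphorane_model"
  out
}

#' @export
print.phosphorane_model <- function(x, ...) {
  cat("phosphorane_model: axial", paste(x$axial, collapse = "/"),
      "equatorial", paste(x$equatorial, collapse = "/"),
      sprintf("placement residual %.3f A\n", x$residual))
  invisible(x)
}

# Rigid placement of an ideal trigonal bipyramid at phosphorus p: axial
# vertices toward o3/nuc, equatorial toward o5/op1/op2, assignment fixed;
# only the rotation is optimised (Procrustes on unit target directions).
tbp_fit <- function(p, o3, nuc, o5, op1, op2, ax_len = 1.76,
                    eq_len = 1.60) {
  ideal <- rbind(
    ax_len * c(0, 0, 1),
    ax_len * c(0, 0, -1),
    eq_len * c(1, 0, 0),
    eq_len * c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
    eq_len * c(cos(4 * pi / 3), sin(4 * pi / 3), 0))
  targets <- rbind(o3, nuc, o5, op1, op2)
  tv <- sweep(targets, 2, p)
  if (vnorm(cross3(unitv(tv[1, ]), unitv(tv[2, ]))) < 1e-6 &&
      sum(unitv(tv[1, ]) * unitv(tv[2, ])) > 0)
    stop("attack position is colinear with the leaving-group direction; ",
         "phosphorane placement is degenerate")
  U <- t(apply(tv, 1, unitv))
  V <- t(apply(ideal, 1, unitv))
  sv <- svd(t(V) %*% U)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  placed <- sweep(ideal %*% t(R), 2, -p)
  list(rotation = R, placed = placed,
       residual = sqrt(mean(rowSums((placed - targets)^2))))
}

#' Coordination shell of a metal ion
#'
#' Lists all O/N ligand atoms within `cutoff` of the ion, the coordination
#' number, and the octahedricity deviation: the RMS (degrees) of the
#' angular deviations of the ligand directions from the best-matching ideal
#' octahedron orientation (over all vertex assignments and rigid
#' rotations). Zero only for a perfect octahedral fragment.
#'
#' @param s a `structure3d`.
#' @param ion atom spec of the ion (default "MG") or an atom row.
#' @param cutoff ligand distance cutoff in Angstrom (default 2.6).
#' @param model model number.
#' @return object of class `coordination_shell`.
#' @export
coordination_shell <- function(s, ion = "MG", cutoff = 2.6, model = 1) {
  ion_row <- if (is.data.frame(ion)) ion else resolve_atom(s, ion, model)
  ctr <- atom_xyz(ion_row)
  at <- s$atoms[s$atoms$model == model, , drop = FALSE]
  at <- at[!(at$chain == ion_row$chain[1] & at$resseq == ion_row$resseq[1] &
               at$name == ion_row$name[1]), , drop = FALSE]
  at <- at[toupper(at$element) %in% c("O", "N"), , drop = FALSE]
  d <- sqrt(rowSums(sweep(as.matrix(at[, c("x", "y", "z")]), 2, ctr)^2))
  lig <- at[d <= cutoff, , drop = FALSE]
  dist <- d[d <= cutoff]
  ord <- order(dist)
  lig <- lig[ord, , drop = FALSE]; dist <- dist[ord]
  n <- nrow(lig)
  octa <- if (n >= 2 && n <= 6)
    octahedricity(sweep(as.matrix(lig[, c("x", "y", "z")]), 2, ctr))
  else NA_real_
  labels <- water_label_of(s, lig)
  out <- list(ion = ion_row, center = ctr,
              ligands = data.frame(chain = lig$chain, resseq = lig$resseq,
                                   resname = lig$resname, name = lig$name,
                                   label = labels, distance = dist,
                                   stringsAsFactors = FALSE),
              coordination_number = n, octahedricity = octa,
              sub_octahedral = n < 6, cutoff = cutoff)
  class(out) <- "coordination_shell"
  out
}

#' @export
print.coordination_shell <- function(x, ...) {
  cat("coordination_shell:", x$coordination_number, "ligand(s) within",
      x$cutoff, "A",
      if (x$sub_octahedral) "(sub-octahedral)" else "",
      if (is.finite(x$octahedricity))
        sprintf("; octahedricity deviation %.2f deg", x$octahedricity)
      else "", "\n")
  if (nrow(x$ligands)) print(x$ligands)
  invisible(x)
}

water_label_of <- function(s, rows) {
  if (!nrow(rows)) return(character())
  lab <- paste0(rows$chain, ":", rows$resseq)
  if (!is.null(s$water_labels)) {
    for (nm in names(s$water_labels)) {
      w <- s$water_labels[[nm]]
      hit <- rows$chain == w$chain & rows$resseq == w$resseq
      lab[hit] <- nm
    }
  }
  lab
}

# RMS angular deviation (degrees) of unit ligand directions from the
# best-fitting ideal octahedron (all +/- axis vertices), minimised over
# injective vertex assignments and rigid rotations.
octahedricity <- function(vecs) {
  U <- t(apply(vecs, 1, unitv))
  n <- nrow(U)
  verts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  perms <- perm_inject(6, n)
  best <- Inf
  for (pi_ in seq_len(nrow(perms))) {
    V <- verts[perms[pi_, ], , drop = FALSE]
    sv <- svd(t(V) %*% U)
    dt <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, dt)) %*% t(sv$u)
    ang <- vapply(seq_len(n), function(i) {
      cs <- max(-1, min(1, sum((R %*% V[i, ]) * U[i, ])))
      acos(cs) / DEG
    }, 0)
    best <- min(best, sqrt(mean(ang^2)))
  }
  best
}

# All injective assignments of n slots into 1..m (ordered), as rows.
perm_inject <- function(m, n) {
  if (n == 0) return(matrix(integer(), 1, 0))
  out <- matrix(seq_len(m), ncol = 1)
  for (k in seq_len(n - 1)) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(r) {
      rest <- setdiff(seq_len(m), out[r, ])
      cbind(matrix(out[r, ], length(rest), k, byrow = TRUE), rest)
    }))
  }
  out
}

#' Water displacement by added atoms
#'
#' A shell water is displaced when any added atom comes within the clash
#' threshold of it; clashes of added atoms with non-water context atoms are
#' reported with distances.
#'
#' @param shell a `coordination_shell` computed before the addition.
#' @param added added atom coordinates: n x 3 matrix or a `structure3d`.
#' @param context optional `structure3d` for the non-water clash report.
#' @param clash clash threshold in Angstrom (default 2.3).
#' @param context_clash threshold for the non-water clash report (default
#'   2.3).
#' @return list with `displaced` (water labels), `kept`, and `clashes`
#'   (data.frame).
#' @export
water_displacement <- function(shell, added, context = NULL, clash = 2.3,
                               context_clash = 2.3) {
  add_xyz <- if (inherits(added, "structure3d")) coords3d(added) else
    matrix(added, ncol = 3)
  lig <- shell$ligands
  wat <- lig[residue_class(lig$resname) == "water", , drop = FALSE]
  displaced <- character(); kept <- character()
  src <- if (!is.null(context)) context else attr(shell, "source")
  get_w_xyz <- function(i) {
    if (!is.null(src)) {
      atom_xyz(resolve_atom(src, sprintf("%s:%d:%s", wat$chain[i],
                                         wat$resseq[i], wat$name[i])))
    } else stop("water_displacement needs the context structure")
  }
  for (i in seq_len(nrow(wat))) {
    wx <- get_w_xyz(i)
    dmin <- min(sqrt(rowSums(sweep(add_xyz, 2, wx)^2)))
    if (dmin <= clash) displaced <- c(displaced, wat$label[i])
    else kept <- c(kept, wat$label[i])
  }
  clashes <- NULL
  if (!is.null(context)) {
    at <- context$atoms[residue_class(context$atoms$resname) != "water", ,
                        drop = FALSE]
    cx <- as.matrix(at[, c("x", "y", "z")])
    for (k in seq_len(nrow(add_xyz))) {
      dd <- sqrt(rowSums(sweep(cx, 2, add_xyz[k, ])^2))
      hit <- which(dd <= context_clash & dd > 1e-6)
      if (length(hit))
        clashes <- rbind(clashes, data.frame(
          added_atom = k, chain = at$chain[hit], resseq = at$resseq[hit],
          name = at$name[hit], distance = dd[hit],
          stringsAsFactors = FALSE))
    }
  }
  list(displaced = displaced, kept = kept,
       clashes = if (is.null(clashes))
         data.frame(added_atom = integer(), chain = character(),
                    resseq = integer(), name = character(),
                    distance = numeric()) else clashes)
}

#' Restrained morph of one structure toward another
#'
#' Atoms within `fixed_radius` of `fixed_center` are held exactly at their
#' source coordinates; all other matched atoms relax under harmonic tethers
#' to the target plus a simplified internal-geometry energy (harmonic bonds
#' at source lengths, capped soft-sphere repulsion between nonbonded heavy
#' atoms). Steepest descent with backtracking line search; the energy is
#' non-increasing by construction.
#'
#' @param source,target `structure3d` objects sharing residue numbering.
#' @param fixed_center atom spec of the fixed-core center (e.g. "MG"), or
#'   NULL for no fixed core.
#' @param fixed_radius core radius in Angstrom.
#' @param tether_weight harmonic tether force constant (default 1).
#' @param k_bond,k_rep bond and repulsion force constants.
#' @param max_iter iteration cap (default 500).
#' @param tol gradient convergence threshold.
#' @return object of class `morph_result`: `structure`, per-iteration
#'   `energy`, `max_bond_violation`, `min_clash_distance`, `fixed_atoms`.
#' @export
restrained_morph <- function(source, target, fixed_center = NULL,
                             fixed_radius = 0, tether_weight = 1,
                             k_bond = 20, k_rep = 5, max_iter = 500,
                             tol = 1e-4) {
  src <- resolve_altlocs(source); tgt <- resolve_altlocs(target)
  sa <- src$atoms[src$atoms$model == 1, , drop = FALSE]
  ta <- tgt$atoms[tgt$atoms$model == 1, , drop = FALSE]
  key_s <- paste(sa$chain, sa$resseq, sa$icode, sa$name, sep = "\r")
  key_t <- paste(ta$chain, ta$resseq, ta$icode, ta$name, sep = "\r")
  idx_t <- match(key_s, key_t)
  x <- as.matrix(sa[, c("x", "y", "z")])
  xt <- x
  has_t <- !is.na(idx_t)
  xt[has_t, ] <- as.matrix(ta[idx_t[has_t], c("x", "y", "z")])
  fixed <- rep(FALSE, nrow(sa))
  if (!is.null(fixed_center)) {
    ctr <- atom_xyz(resolve_atom(src, fixed_center))
    fixed <- sqrt(rowSums(sweep(x, 2, ctr)^2)) <= fixed_radius
  }
  # bond list from source geometry (heavy-atom pairs within covalent range)
  bonds <- infer_bonds(sa, x)
  b_len <- sqrt(rowSums((x[bonds[, 1], , drop = FALSE] -
                           x[bonds[, 2], , drop = FALSE])^2))
  nb_excl <- paste(pmin(bonds[, 1], bonds[, 2]),
                   pmax(bonds[, 1], bonds[, 2]))
  energy_grad <- function(x) {
    g <- matrix(0, nrow(x), 3)
    E <- 0
    w <- tether_weight
    dv <- x - xt
    free <- !fixed & has_t
    E <- E + w * sum(dv[free, ]^2)
    g[free, ] <- g[free, ] + 2 * w * dv[free, , drop = FALSE]
    if (nrow(bonds)) {
      d <- x[bonds[, 1], , drop = FALSE] - x[bonds[, 2], , drop = FALSE]
      L <- sqrt(rowSums(d^2))
      dev <- L - b_len
      E <- E + k_bond * sum(dev^2)
      gb <- 2 * k_bond * dev / pmax(L, 1e-6) * d
      for (col in 1:3) {
        g[, col] <- g[, col] + tabulate_add(bonds[, 1], gb[, col], nrow(x))
        g[, col] <- g[, col] - tabulate_add(bonds[, 2], gb[, col], nrow(x))
      }
    }
    # soft repulsion for close nonbonded pairs
    close <- close_pairs(x, 2.0)
    if (nrow(close)) {
      keyc <- paste(pmin(close[, 1], close[, 2]),
                    pmax(close[, 1], close[, 2]))
      close <- close[!(keyc %in% nb_excl), , drop = FALSE]
    }
    if (nrow(close)) {
      d <- x[close[, 1], , drop = FALSE] - x[close[, 2], , drop = FALSE]
      L <- pmax(sqrt(rowSums(d^2)), 0.5)
      E <- E + k_rep * sum((2.0 - L)^2)
      gr <- -2 * k_rep * (2.0 - L) / L * d
      for (col in 1:3) {
        g[, col] <- g[, col] + tabulate_add(close[, 1], gr[, col], nrow(x))
        g[, col] <- g[, col] - tabulate_add(close[, 2], gr[, col], nrow(x))
      }
    }
    g[fixed, ] <- 0
    list(E = E, g = g)
  }
  energies <- numeric()
  eg <- energy_grad(x)
  step <- 0.05
  for (it in seq_len(max_iter)) {
    energies[it] <- eg$E
    if (max(abs(eg$g)) < tol) break
    repeat {
      x_new <- x - step * eg$g
      x_new[fixed, ] <- x[fixed, ]
      eg_new <- energy_grad(x_new)
      if (eg_new$E <= eg$E || step < 1e-8) break
      step <- step / 2
    }
    if (eg_new$E > eg$E) break
    x <- x_new; eg <- eg_new
    step <- min(step * 1.5, 0.1)
  }
  out_s <- src
  out_s$atoms[out_s$atoms$model == 1, c("x", "y", "z")] <- x
  viol <- if (nrow(bonds)) max(abs(sqrt(rowSums((x[bonds[, 1], , drop = FALSE] -
                                                   x[bonds[, 2], , drop = FALSE])^2)) -
                                    b_len)) else 0
  cp <- close_pairs(x, 2.0)
  if (nrow(cp)) {
    keyc <- paste(pmin(cp[, 1], cp[, 2]), pmax(cp[, 1], cp[, 2]))
    cp <- cp[!(keyc %in% nb_excl), , drop = FALSE]
  }
  min_clash <- if (nrow(cp))
    min(sqrt(rowSums((x[cp[, 1], , drop = FALSE] -
                        x[cp[, 2], , drop = FALSE])^2))) else Inf
  out <- list(structure = out_s, energy = energies,
              max_bond_violation = viol, min_clash_distance = min_clash,
              fixed_atoms = sum(fixed), iterations = length(energies))
  class(out) <- "morph_result"
  out
}

#' @export
print.morph_result <- function(x, ...) {
  cat("morph_result:", x$iterations, "iterations;",
      x$fixed_atoms, "fixed atoms; final energy",
      format(utils::tail(x$energy, 1), digits = 4), "\n")
  invisible(x)
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- tapply(val, idx, sum)
  out[as.integer(names(agg))] <- agg
  out
}

infer_bonds <- function(at, x) {
  cp <- close_pairs(x, 1.9)
  if (!nrow(cp)) return(matrix(integer(), 0, 2))
  # covalent if within 1.9 A and not both non-bonding candidates; metals
  # and waters never bond
  no_bond <- residue_class(at$resname) %in% c("ion", "water")
  keep <- !(no_bond[cp[, 1]] | no_bond[cp[, 2]])
  cp[keep, , drop = FALSE]
}

close_pairs <- function(x, cutoff) {
  n <- nrow(x)
  if (n < 2) return(matrix(integer(), 0, 2))
  d2 <- outer(rowSums(x^2), rep(1, n)) + outer(rep(1, n), rowSums(x^2)) -
    2 * x %*% t(x)
  d2[lower.tri(d2, diag = TRUE)] <- Inf
  w <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(w)) return(matrix(integer(), 0, 2))
  unname(as.matrix(w))
}
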
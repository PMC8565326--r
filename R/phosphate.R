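# Internal-coordinate treatment of the 5' phosphate linkage
#   C4'(i-1)-C3'(i-1)-O3'(i-1)-P-O5'-C5'-C4'(i)-C3'(i)[-O3'(i)]
# used for coordinated alpha/gamma rotations and torsion-path driving.
# The linkage is rebuilt forward from the (fixed) upstream sugar with the
# stored bond lengths/angles, so covalent geometry is conserved exactly and
# the driven torsions take their set values exactly; the remaining torsions
# (epsilon, zeta, beta) are free parameters chosen to keep the downstream
# sugar in place.

.linkage_chain <- c("C4'p", "C3'p", "O3'p", "P", "O5'", "C5'", "C4'", "C3'",
                    "O3'")

# Extract linkage geometry for the 5' phosphate of nucleotide (chain, resseq).
linkage_extract <- function(s, chain, resseq, model = 1, altloc = NULL) {
  info <- residue_info(s, model)
  strand <- info[info$chain == chain & info$class == "nucleotide", ,
                 drop = FALSE]
  strand <- strand[order(strand$resseq), , drop = FALSE]
  i <- which(strand$resseq == resseq)
  if (!length(i)) stop("nucleotide ", chain, ":", resseq, " not found")
  if (i == 1) stop("nucleotide ", chain, ":", resseq,
                   " is 5'-terminal: no upstream O3' for its phosphate")
  cur <- res_coords(residue_atoms(s, chain, resseq, strand$icode[i], model),
                    altloc = altloc)
  prv <- res_coords(residue_atoms(s, chain, strand$resseq[i - 1],
                                  strand$icode[i - 1], model),
                    altloc = altloc)
  need_cur <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")
  need_prv <- c("C4'", "C3'", "O3'")
  if (!all(need_cur %in% rownames(cur)))
    stop("nucleotide ", chain, ":", resseq, " lacks atoms: ",
         paste(setdiff(need_cur, rownames(cur)), collapse = ", "))
  if (!all(need_prv %in% rownames(prv)))
    stop("upstream nucleotide lacks atoms: ",
         paste(setdiff(need_prv, rownames(prv)), collapse = ", "))
  pos <- rbind("C4'p" = prv["C4'", ], "C3'p" = prv["C3'", ],
               "O3'p" = prv["O3'", ], cur[c("P", "O5'", "C5'", "C4'", "C3'",
                                            "O3'"), ])
  ch <- .linkage_chain
  g <- function(nm) pos[nm, ]
  bonds <- vapply(2:9, function(k) vnorm(g(ch[k]) - g(ch[k - 1])), 0)
  angs <- vapply(3:9, function(k)
    bond_angle(g(ch[k - 2]), g(ch[k - 1]), g(ch[k])), 0)
  tors <- vapply(4:9, function(k)
    dihedral(g(ch[k - 3]), g(ch[k - 2]), g(ch[k - 1]), g(ch[k])), 0)
  names(tors) <- c("epsilon", "zeta", "alpha", "beta", "gamma", "delta")
  # OP1/OP2 relative to the C5'-O5'-P chain
  op <- lapply(c("OP1", "OP2"), function(nm) {
    list(bond = vnorm(cur[nm, ] - cur["P", ]),
         angle = bond_angle(cur["O5'", ], cur["P", ], cur[nm, ]),
         torsion = dihedral(cur["C5'", ], cur["O5'", ], cur["P", ], cur[nm, ]))
  })
  names(op) <- c("OP1", "OP2")
  list(chain = chain, resseq = resseq, model = model,
       prev_resseq = strand$resseq[i - 1], pos = pos,
       bonds = bonds, angles = angs, torsions = tors, op = op)
}

# Rebuild positions of P, OP1, OP2, O5', C5', C4', C3', O3' from the stored
# internal coordinates with the given torsions (degrees).
linkage_rebuild <- function(lk, epsilon, zeta, alpha, beta, gamma) {
  ch <- .linkage_chain
  pos <- lk$pos
  out <- matrix(NA_real_, 9, 3, dimnames = list(ch, NULL))
  out[1, ] <- pos["C4'p", ]; out[2, ] <- pos["C3'p", ]; out[3, ] <- pos["O3'p", ]
  tors <- c(epsilon, zeta, alpha, beta, gamma, lk$torsions[["delta"]])
  for (k in 4:9) {
    out[k, ] <- place_atom(out[k - 3, ], out[k - 2, ], out[k - 1, ],
                           lk$bonds[k - 1], lk$angles[k - 2], tors[k - 3])
  }
  op1 <- place_atom(out["C5'", ], out["O5'", ], out["P", ],
                    lk$op$OP1$bond, lk$op$OP1$angle, lk$op$OP1$torsion)
  op2 <- place_atom(out["C5'", ], out["O5'", ], out["P", ],
                    lk$op$OP2$bond, lk$op$OP2$angle, lk$op$OP2$torsion)
  rbind(out, OP1 = op1, OP2 = op2)
}

# Sum of squared deviations of the rebuilt downstream sugar anchors
# (C4', C3' of nucleotide i) from their current positions.
linkage_anchor_ss <- function(lk, built) {
  sum((built[c("C4'", "C3'"), ] - lk$pos[c("C4'", "C3'"), ])^2)
}

# Recover the free torsions that reproduce a set of mobile-atom positions
# (P, OP1, OP2, O5', C5') under this linkage's internal coordinates at the
# given driven alpha/gamma. Used to express an end conformer in the start
# conformer's internal-coordinate system.
linkage_fit_free <- function(lk, alpha, gamma, target_pos, init) {
  mobile <- intersect(rownames(target_pos), c("P", "OP1", "OP2", "O5'",
                                              "C5'"))
  obj <- function(p) {
    built <- linkage_rebuild(lk, p[1], p[2], alpha, p[3], gamma)
    sum((built[mobile, , drop = FALSE] -
           target_pos[mobile, , drop = FALSE])^2)
  }
  o <- stats::optim(init, obj, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-14))
  o2 <- stats::optim(o$par, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-14))
  if (o2$value < o$value) o <- o2
  list(free = wrap_angle(o$par), value = o$value)
}

# Optimise the free torsions (epsilon, zeta, beta) at fixed driven
# alpha/gamma. init: length-3 vector of starting values; prev: optional
# previous-step values for the smoothness restraint (weight w_s, A^2/deg^2).
linkage_relax <- function(lk, alpha, gamma, init, prev = NULL, w_s = 1e-4,
                          target = NULL, w_t = w_s, multistart = FALSE) {
  obj <- function(p) {
    built <- linkage_rebuild(lk, p[1], p[2], alpha, p[3], gamma)
    v <- linkage_anchor_ss(lk, built)
    if (!is.null(prev)) v <- v + w_s * sum(angle_diff(p, prev)^2)
    if (!is.null(target)) v <- v + w_t * sum(angle_diff(p, target)^2)
    v
  }
  starts <- list(init)
  if (multistart) {
    offs <- c(-60, 0, 60)
    for (d1 in offs) for (d2 in offs) for (d3 in offs)
      if (d1 || d2 || d3) starts[[length(starts) + 1]] <- init + c(d1, d2, d3)
  }
  best <- NULL
  for (s0 in starts) {
    o <- stats::optim(s0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  o2 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-14))
  if (o2$value < best$value) best <- o2
  list(free = best$par, value = best$value)
}

#' Rotate a 5' phosphate by coordinated alpha/gamma torsion changes
#'
#' Changes the alpha and gamma backbone torsions of the named nucleotide's
#' phosphate linkage by exactly the requested amounts, rotating only the
#' intervening linkage atoms; the remaining linkage torsions (epsilon, zeta,
#' beta) are relaxed so the flanking deoxyriboses stay in place (compensating
#' relaxation), and the small residual rigid motion of the downstream sugar
#' is propagated so covalent geometry stays exact.
#'
#' @param s a `structure3d`.
#' @param nucleotide `c(chain, resseq)` of the nucleotide whose 5' phosphate
#'   is rotated.
#' @param dalpha,dgamma torsion changes in degrees.
#' @param as_altloc keep the original conformer as altloc A and add the
#'   rotated phosphate group as altloc B (occupancies 0.5/0.5) instead of
#'   replacing it.
#' @return the modified `structure3d`. The attribute `"sugar_shift"` records
#'   the maximal displacement (Angstrom) of the downstream sugar anchors.
#' @export
rotate_phosphate <- function(s, nucleotide, dalpha, dgamma,
                             as_altloc = FALSE) {
  chain <- as.character(nucleotide[1]); resseq <- as.integer(nucleotide[2])
  lk <- linkage_extract(s, chain, resseq)
  t0 <- lk$torsions
  if (dalpha == 0 && dgamma == 0 && !as_altloc) {
    attr(s, "sugar_shift") <- 0
    return(s)
  }
  alpha_new <- wrap_angle(t0[["alpha"]] + dalpha)
  gamma_new <- wrap_angle(t0[["gamma"]] + dgamma)
  rx <- linkage_relax(lk, alpha_new, gamma_new,
                      init = c(t0[["epsilon"]], t0[["zeta"]], t0[["beta"]]),
                      multistart = TRUE)
  built <- linkage_rebuild(lk, rx$free[1], rx$free[2], alpha_new,
                           rx$free[3], gamma_new)
  moved <- c("P", "OP1", "OP2", "O5'", "C5'")
  at <- s$atoms
  sel_res <- at$model == lk$model & at$chain == chain & at$resseq == resseq
  if (as_altloc) {
    rows <- which(sel_res & at$name %in% moved)
    dup <- at[rows, , drop = FALSE]
    at$altloc[rows] <- "A"; at$occ[rows] <- 0.5
    dup$altloc <- "B"; dup$occ <- 0.5
    dup[, c("x", "y", "z")] <- built[dup$name, , drop = FALSE]
    dup$serial <- max(at$serial) + seq_len(nrow(dup))
    at <- rbind(at, dup)
    at <- at[order(at$model, at$chain, at$resseq, at$serial), , drop = FALSE]
    shift <- sqrt(max(rowSums((built[c("C4'", "C3'"), ] -
                                 lk$pos[c("C4'", "C3'"), ])^2)))
  } else {
    for (nm in moved) {
      r <- which(sel_res & at$name == nm)
      at[r, c("x", "y", "z")] <- matrix(built[nm, ], length(r), 3,
                                        byrow = TRUE)
    }
    # rigid motion carrying the original downstream triad onto the rebuilt
    # (congruent) one; applied to the rest of the strand 3' of the linkage
    tri <- c("C5'", "C4'", "C3'")
    fit <- kabsch(lk$pos[tri, ], built[tri, ])
    downstream <- at$model == lk$model & at$chain == chain &
      (at$resseq > resseq |
         (at$resseq == resseq & !(at$name %in% moved)))
    xyz <- as.matrix(at[downstream, c("x", "y", "z")])
    at[downstream, c("x", "y", "z")] <-
      sweep(xyz %*% t(fit$rotation), 2, -fit$translation)
    shift <- sqrt(max(rowSums((built[c("C4'", "C3'"), ] -
                                 lk$pos[c("C4'", "C3'"), ])^2)))
  }
  s$atoms <- at
  attr(s, "sugar_shift") <- shift
  s
}
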
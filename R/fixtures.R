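# Synthetic structure generation: full-heavy-atom B-DNA duplexes with
# controllable helicoidal parameters, locally perturbed variants, hydrated
# divalent ions, and toy protein-DNA probe poses. These are the package's
# test inputs and its canonical B-form reference.

.default_step <- c(shift = 0, slide = 0, rise = 3.38, tilt = 0, roll = 0,
                   twist = 36)
.default_intra <- c(shear = 0, stretch = 0, stagger = 0, buckle = 0,
                    propeller = 0, opening = 0)

#' Specification of a synthetic DNA duplex
#'
#' @param sequence strand-1 sequence, 5'->3', over A/C/G/T (length >= 2).
#' @param step optional data.frame (length(sequence) - 1 rows) with any of
#'   shift, slide, rise (Angstrom), tilt, roll, twist (degrees); missing
#'   columns/rows take the fiber-model defaults (twist 36, rise 3.38,
#'   others 0).
#' @param intra optional data.frame (one row per pair) with any of shear,
#'   stretch, stagger, buckle, propeller, opening; defaults 0.
#' @param overhangs optional named list of single-nucleotide unpaired
#'   extensions: entries among `strand1_5p`, `strand1_3p`, `strand2_5p`,
#'   `strand2_3p`, each a single base letter.
#' @param seed integer seed for any randomized perturbation (default
#'   20210923).
#' @return object of class `duplex_spec`.
#' @export
duplex_spec <- function(sequence, step = NULL, intra = NULL,
                        overhangs = NULL, seed = 20210923) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (length(bases) < 2) stop("sequence must have length >= 2")
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("invalid base letter(s): ",
         paste(unique(setdiff(bases, c("A", "C", "G", "T"))), collapse = ""))
  n <- length(bases)
  fill <- function(tbl, defaults, rows) {
    out <- matrix(rep(defaults, each = rows), rows, length(defaults),
                  dimnames = list(NULL, names(defaults)))
    out <- as.data.frame(out)
    if (!is.null(tbl)) {
      tbl <- as.data.frame(tbl)
      if (nrow(tbl) != rows)
        stop("parameter table has ", nrow(tbl), " rows; expected ", rows)
      for (nm in intersect(names(tbl), names(defaults)))
        out[[nm]] <- as.numeric(tbl[[nm]])
    }
    out
  }
  spec <- list(sequence = bases,
               step = fill(step, .default_step, n - 1),
               intra = fill(intra, .default_intra, n),
               overhangs = overhangs, seed = as.integer(seed))
  if (!is.null(overhangs)) {
    bad <- setdiff(names(overhangs),
                   c("strand1_5p", "strand1_3p", "strand2_5p", "strand2_3p"))
    if (length(bad)) stop("unknown overhang slot(s): ",
                          paste(bad, collapse = ", "))
    if (!all(toupper(unlist(overhangs)) %in% c("A", "C", "G", "T")))
      stop("overhangs must be single bases over A/C/G/T")
  }
  class(spec) <- "duplex_spec"
  spec
}

# Atom table for one nucleotide given its base frame.
place_nucleotide <- function(frame, resname, chain, resseq,
                             with_phosphate = TRUE) {
  base <- std_base(resname)
  base <- base[setdiff(rownames(base), "C1'"), , drop = FALSE]
  bb <- backbone_template()
  if (!with_phosphate)
    bb <- bb[setdiff(rownames(bb), c("P", "OP1", "OP2")), , drop = FALSE]
  local <- rbind(bb, base)
  xyz <- sweep(local %*% t(frame$R), 2, -frame$origin)
  dimnames(xyz) <- NULL
  data.frame(record = "ATOM", serial = NA_integer_, name = rownames(local),
             altloc = "", resname = resname, chain = chain, resseq = resseq,
             icode = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occ = 1, b = 0, element = guess_element(rownames(local)),
             model = 1L, rel_pos = NA_integer_, stringsAsFactors = FALSE)
}

#' Build a full-heavy-atom DNA duplex from a specification
#'
#' Base atoms are placed from the embedded standard geometries by composing
#' base-pair and step frames from the requested parameter tables; the
#' sugar-phosphate backbone comes from an idealized B-form nucleotide
#' template oriented by each base frame, followed by a short restrained
#' closure that repairs O3'-P continuity at perturbed steps. The
#' complementary strand is generated antiparallel. 5'-terminal nucleotides
#' (including overhangs) carry no phosphate.
#'
#' @param spec a [duplex_spec()] (or a character sequence, converted with
#'   defaults).
#' @param chain1,chain2 chain identifiers (defaults "A"/"B").
#' @param close_backbone run the O3'-P closure relaxation (default TRUE).
#' @return a `structure3d`; strand 1 runs 5'->3' with increasing resseq.
#' @export
build_duplex <- function(spec, chain1 = "A", chain2 = "B",
                         close_backbone = TRUE) {
  if (is.character(spec)) spec <- duplex_spec(spec)
  stopifnot(inherits(spec, "duplex_spec"))
  n <- length(spec$sequence)
  res1 <- normalize_base_name(spec$sequence)
  res2 <- unname(vapply(res1, complement_base, ""))
  # pair frames from the step table
  pf <- vector("list", n)
  pf[[1]] <- new_frame(diag(3), c(0, 0, 0))
  for (i in seq_len(n - 1)) {
    st <- spec$step[i, ]
    pf[[i + 1]] <- frame_compose(pf[[i]], st$shift, st$slide, st$rise,
                                 st$tilt, st$roll, st$twist)$frame2
  }
  # strand base frames from the intra table
  f1 <- f2 <- vector("list", n)
  for (i in seq_len(n)) {
    ip <- spec$intra[i, ]
    ab <- frames_about_mid(pf[[i]], ip$shear, ip$stretch, ip$stagger,
                           ip$buckle, ip$propeller, ip$opening)
    f1[[i]] <- ab$frame2
    f2[[i]] <- flip_frame(ab$frame1)
  }
  ov <- spec$overhangs
  helix_ext <- function(anchor, forward) {
    d <- .default_step
    sgn <- if (forward) 1 else -1
    frame_compose(anchor, sgn * d[["shift"]], sgn * d[["slide"]],
                  sgn * d[["rise"]], sgn * d[["tilt"]], sgn * d[["roll"]],
                  sgn * d[["twist"]])$frame2
  }
  # strand 1: optional 5' overhang occupies resseq 1
  s1 <- list(); r <- 1
  if (!is.null(ov$strand1_5p)) {
    fr <- frames_about_mid(helix_ext(pf[[1]], FALSE), 0, 0, 0, 0, 0, 0)$frame2
    s1[[length(s1) + 1]] <- place_nucleotide(
      fr, normalize_base_name(ov$strand1_5p), chain1, r, FALSE)
    r <- r + 1
  }
  for (i in seq_len(n)) {
    s1[[length(s1) + 1]] <- place_nucleotide(f1[[i]], res1[i], chain1, r,
                                             with_phosphate = length(s1) > 0)
    r <- r + 1
  }
  if (!is.null(ov$strand1_3p)) {
    fr <- frames_about_mid(helix_ext(pf[[n]], TRUE), 0, 0, 0, 0, 0, 0)$frame2
    s1[[length(s1) + 1]] <- place_nucleotide(
      fr, normalize_base_name(ov$strand1_3p), chain1, r, TRUE)
  }
  # strand 2 runs antiparallel: its 5' end pairs with strand-1 position n
  s2 <- list(); r <- 1
  if (!is.null(ov$strand2_5p)) {
    fr <- flip_frame(frames_about_mid(helix_ext(pf[[n]], TRUE),
                                      0, 0, 0, 0, 0, 0)$frame1)
    s2[[length(s2) + 1]] <- place_nucleotide(
      fr, normalize_base_name(ov$strand2_5p), chain2, r, FALSE)
    r <- r + 1
  }
  for (i in rev(seq_len(n))) {
    s2[[length(s2) + 1]] <- place_nucleotide(f2[[i]], res2[i], chain2, r,
                                             with_phosphate = length(s2) > 0)
    r <- r + 1
  }
  if (!is.null(ov$strand2_3p)) {
    fr <- flip_frame(frames_about_mid(helix_ext(pf[[1]], FALSE),
                                      0, 0, 0, 0, 0, 0)$frame1)
    s2[[length(s2) + 1]] <- place_nucleotide(
      fr, normalize_base_name(ov$strand2_3p), chain2, r, TRUE)
  }
  at <- do.call(rbind, c(s1, s2))
  at$serial <- seq_len(nrow(at))
  s <- structure3d(at, id = paste0("duplex_", paste(spec$sequence,
                                                    collapse = "")))
  if (close_backbone) s <- close_backbone_links(s)
  s
}

# Restrained repair of O3'-P continuity: for every non-terminal phosphate,
# the group {P, OP1, OP2, O5'} is relaxed under harmonic bonds (O3'prev-P
# 1.607, P-O5' 1.593, O5'-C5' 1.427, P-OP 1.485 A) plus tethers to the
# template-placed positions. Runs per linkage (deterministic and helically
# symmetric for uniform helices); linkages already within `tol` of ideal are
# left untouched.
close_backbone_links <- function(s, tol = 0.05, k_bond = 50,
                                 k_tether = 0.5, n_iter = 500,
                                 step_size = 5e-3) {
  info <- residue_info(s)
  for (ch in unique(info$chain[info$class == "nucleotide"])) {
    strand <- info[info$chain == ch & info$class == "nucleotide", ,
                   drop = FALSE]
    strand <- strand[order(strand$resseq), , drop = FALSE]
    for (i in seq_len(nrow(strand))[-1]) {
      cur <- residue_atoms(s, ch, strand$resseq[i], strand$icode[i])
      if (!"P" %in% cur$name) next
      prv <- res_coords(residue_atoms(s, ch, strand$resseq[i - 1],
                                      strand$icode[i - 1]))
      cc <- res_coords(cur)
      if (!all(c("P", "OP1", "OP2", "O5'", "C5'") %in% rownames(cc)) ||
          !"O3'" %in% rownames(prv)) next
      o3 <- prv["O3'", ]; c4 <- cc["C4'", ]
      x0 <- cc[c("P", "OP1", "OP2", "O5'", "C5'"), ]
      if (abs(vnorm(cc["P", ] - o3) - 1.607) <= tol &&
          abs(vnorm(cc["P", ] - cc["O5'", ]) - 1.593) <= tol) next
      energy <- function(x) {
        bdev <- function(a, b, l0) (vnorm(a - b) - l0)^2
        k_bond * (bdev(x["P", ], o3, 1.607) +
                    bdev(x["P", ], x["O5'", ], 1.593) +
                    bdev(x["P", ], x["OP1", ], 1.485) +
                    bdev(x["P", ], x["OP2", ], 1.485) +
                    bdev(x["O5'", ], x["C5'", ], 1.427) +
                    bdev(x["C5'", ], c4, 1.511)) +
          k_tether * sum((x - x0)^2)
      }
      grad <- function(x) {
        g <- matrix(0, 5, 3, dimnames = list(rownames(x0), NULL))
        bond_g <- function(a, b, l0) {
          d <- a - b; L <- vnorm(d)
          2 * k_bond * (L - l0) * d / L
        }
        g["P", ] <- g["P", ] + bond_g(x["P", ], o3, 1.607) +
          bond_g(x["P", ], x["O5'", ], 1.593) +
          bond_g(x["P", ], x["OP1", ], 1.485) +
          bond_g(x["P", ], x["OP2", ], 1.485)
        g["O5'", ] <- g["O5'", ] - bond_g(x["P", ], x["O5'", ], 1.593) +
          bond_g(x["O5'", ], x["C5'", ], 1.427)
        g["C5'", ] <- g["C5'", ] - bond_g(x["O5'", ], x["C5'", ], 1.427) +
          bond_g(x["C5'", ], c4, 1.511)
        g["OP1", ] <- g["OP1", ] - bond_g(x["P", ], x["OP1", ], 1.485)
        g["OP2", ] <- g["OP2", ] - bond_g(x["P", ], x["OP2", ], 1.485)
        g + 2 * k_tether * (x - x0)
      }
      x <- x0
      E <- energy(x)
      step <- step_size
      for (it in seq_len(n_iter)) {
        g <- grad(x)
        if (max(abs(g)) < 1e-5) break
        repeat {
          x_new <- x - step * g
          E_new <- energy(x_new)
          if (E_new <= E || step < 1e-9) break
          step <- step / 2
        }
        if (E_new > E) break
        x <- x_new; E <- E_new
        step <- min(step * 1.3, 0.02)
      }
      sel <- s$atoms$chain == ch & s$atoms$resseq == strand$resseq[i] &
        s$atoms$name %in% rownames(x)
      nm <- s$atoms$name[sel]
      s$atoms[sel, c("x", "y", "z")] <- x[nm, , drop = FALSE]
    }
  }
  s
}

#' By-construction pair table of a built duplex
#'
#' Returns the Watson-Crick pairing a [build_duplex()] structure has by
#' construction (strand-1 position i pairs strand-2 position n+1-i within
#' the paired core), in the format of [detect_base_pairs()]. Useful to
#' decouple parameter-recovery checks from geometric pair detection.
#'
#' @param spec the [duplex_spec()] the duplex was built from.
#' @param chain1,chain2 chain ids used at build time.
#' @return data.frame of pairs.
#' @export
built_duplex_pairs <- function(spec, chain1 = "A", chain2 = "B") {
  if (is.character(spec)) spec <- duplex_spec(spec)
  n <- length(spec$sequence)
  res1 <- normalize_base_name(spec$sequence)
  res2 <- unname(vapply(res1, complement_base, ""))
  off1 <- if (!is.null(spec$overhangs$strand1_5p)) 1L else 0L
  off2 <- if (!is.null(spec$overhangs$strand2_5p)) 1L else 0L
  data.frame(chain1 = chain1, resseq1 = off1 + seq_len(n), icode1 = "",
             resname1 = res1, chain2 = chain2,
             resseq2 = off2 + n + 1L - seq_len(n), icode2 = "",
             resname2 = res2, canonical = TRUE, score = 0,
             stringsAsFactors = FALSE)
}

#' Randomized duplex specification
#'
#' Draws a random sequence and random (but physically plausible) parameter
#' tables; used as the generator behind build-then-analyze roundtrip checks.
#'
#' @param n_bp number of base pairs.
#' @param seed integer seed.
#' @return a [duplex_spec()].
#' @export
random_duplex_spec <- function(n_bp = 8, seed = 1) {
  set.seed(seed)
  seq1 <- paste(sample(c("A", "C", "G", "T"), n_bp, replace = TRUE),
                collapse = "")
  step <- data.frame(shift = runif(n_bp - 1, -0.8, 0.8),
                     slide = runif(n_bp - 1, -0.8, 0.8),
                     rise = runif(n_bp - 1, 3.1, 3.7),
                     tilt = runif(n_bp - 1, -6, 6),
                     roll = runif(n_bp - 1, -8, 8),
                     twist = runif(n_bp - 1, 28, 42))
  intra <- data.frame(shear = runif(n_bp, -0.4, 0.4),
                      stretch = runif(n_bp, -0.3, 0.3),
                      stagger = runif(n_bp, -0.4, 0.4),
                      buckle = runif(n_bp, -10, 10),
                      propeller = runif(n_bp, -15, 5),
                      opening = runif(n_bp, -6, 6))
  duplex_spec(seq1, step = step, intra = intra, seed = seed)
}

#' Build a divalent ion with a water shell
#'
#' @param element ion element (default "MG").
#' @param n_waters number of shell waters.
#' @param geometry "octahedral" (vertices +x,-x,+y,-y,+z,-z, filled in that
#'   order for partial shells), "tetrahedral", or "custom".
#' @param distance ion-O distance in Angstrom (default 2.1).
#' @param site ion position (default origin).
#' @param directions for `geometry = "custom"`: n x 3 matrix of shell
#'   directions.
#' @param chain chain id for the fragment (default "M").
#' @return a `structure3d` with the ion and waters HOH 101..10n, labelled
#'   W1..Wn via [label_waters()].
#' @export
build_ion_shell <- function(element = "MG", n_waters = 4,
                            geometry = c("octahedral", "tetrahedral",
                                         "custom"),
                            distance = 2.1, site = c(0, 0, 0),
                            directions = NULL, chain = "M") {
  geometry <- match.arg(geometry)
  if (n_waters < 0 || distance <= 0) stop("invalid ion-shell spec")
  dirs <- switch(geometry,
    octahedral = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1)),
    tetrahedral = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                        c(-1, -1, 1)) / sqrt(3),
    custom = {
      if (is.null(directions)) stop("custom geometry needs directions")
      t(apply(directions, 1, unitv))
    })
  if (n_waters > nrow(dirs))
    stop("geometry '", geometry, "' supports at most ", nrow(dirs),
         " waters")
  rows <- list(data.frame(record = "HETATM", serial = 1L,
                          name = toupper(element), altloc = "",
                          resname = toupper(element), chain = chain,
                          resseq = 1L, icode = "", x = site[1], y = site[2],
                          z = site[3], occ = 1, b = 0,
                          element = toupper(element), model = 1L,
                          rel_pos = NA_integer_, stringsAsFactors = FALSE))
  for (k in seq_len(n_waters)) {
    p <- site + distance * dirs[k, ]
    rows[[k + 1]] <- data.frame(record = "HETATM", serial = k + 1L,
                                name = "O", altloc = "", resname = "HOH",
                                chain = chain, resseq = 100L + k,
                                icode = "", x = p[1], y = p[2], z = p[3],
                                occ = 1, b = 0, element = "O", model = 1L,
                                rel_pos = NA_integer_,
                                stringsAsFactors = FALSE)
  }
  s <- structure3d(do.call(rbind, rows), id = "ion_shell")
  if (n_waters > 0) {
    labels <- stats::setNames(sprintf("%s:%d", chain, 100L + seq_len(n_waters)),
                              paste0("W", seq_len(n_waters)))
    s <- do.call(label_waters, c(list(s), as.list(labels)))
  }
  s
}

# Minimal side-chain probe templates in a local frame: the anchor atom at
# the origin, the residue body extending along -x.
probe_template <- function(name) {
  rad <- pi / 180
  switch(toupper(name),
    HIS = {
      r <- 1.37 / (2 * sin(pi / 5))
      center <- c(-r, 0, 0)
      ang <- c(NE2 = 0, CE1 = 72, ND1 = 144, CG = 216, CD2 = 288)
      m <- t(vapply(ang, function(a)
        center + r * c(cos(a * rad), sin(a * rad), 0), numeric(3)))
      cb <- center + (r + 1.5) * c(cos(216 * rad), sin(216 * rad), 0)
      rbind(m, CB = cb)
    },
    ASN = rbind(ND2 = c(0, 0, 0), CG = c(-1.33, 0, 0),
                OD1 = c(-1.95, 1.06, 0), CB = c(-2.08, -1.24, 0)),
    SER = rbind(OG = c(0, 0, 0), CB = c(-1.42, 0, 0)),
    HOH = rbind(O = c(0, 0, 0)),
    NULL)
}

#' Pose probe residues against a DNA duplex
#'
#' Places each probe residue so its anchor atom sits at the stated distance
#' from the target DNA atom along the outward normal (away from the duplex
#' centroid); the rest of the residue extends outward. Placements creating
#' inter-residue clashes below 2 Angstrom are rotated about the normal, and
#' rejected with an error if no clash-free orientation exists.
#'
#' @param duplex a `structure3d` DNA duplex.
#' @param probes list of probes, each `list(name, anchor, target, distance)`
#'   with `target` an atom spec (see package docs), e.g.
#'   `list(name = "HIS", anchor = "NE2", target = "A:5:O4'", distance = 3)`.
#' @param chain chain id for the probe residues (default "P").
#' @return combined `structure3d` (duplex + probe residues).
#' @export
make_protein_dna_pose <- function(duplex, probes, chain = "P") {
  if (!length(probes)) return(duplex)
  # outward normal: radially away from the fitted helix axis (principal
  # axis through the C1' cloud)
  c1 <- duplex$atoms[duplex$atoms$name == "C1'", c("x", "y", "z")]
  axis_pt <- colMeans(c1)
  axis_dir <- stats::prcomp(c1)$rotation[, 1]
  placed <- list()
  for (k in seq_along(probes)) {
    pr <- probes[[k]]
    tmpl <- probe_template(pr$name)
    if (is.null(tmpl)) stop("unsupported probe residue: ", pr$name)
    if (!pr$anchor %in% rownames(tmpl))
      stop("probe ", pr$name, " has no anchor atom ", pr$anchor)
    tmpl <- sweep(tmpl, 2, tmpl[pr$anchor, ])
    tgt <- atom_xyz(resolve_atom(duplex, pr$target))
    all_xyz <- coords3d(duplex)
    v <- tgt - axis_pt
    radial <- v - sum(v * axis_dir) * axis_dir
    # candidate outward normals: away from the local atom density around
    # the target, radially away from the helix axis, and their mean
    near <- all_xyz[sqrt(rowSums(sweep(all_xyz, 2, tgt)^2)) < 4.5, ,
                    drop = FALSE]
    local_dir <- tgt - colMeans(near)
    cands <- list()
    if (vnorm(local_dir) > 1e-6) cands$local <- unitv(local_dir)
    if (vnorm(radial) > 1e-6) cands$radial <- unitv(radial)
    if (length(cands) == 2) cands$mean <- unitv(cands$local + cands$radial)
    # widen the search: cones around each base direction
    for (base_dir in cands[names(cands)]) {
      perp1 <- if (abs(base_dir[1]) < 0.9) unitv(cross3(base_dir,
                                                        c(1, 0, 0)))
      else unitv(cross3(base_dir, c(0, 1, 0)))
      perp2 <- cross3(base_dir, perp1)
      for (tilt in c(20, 40)) for (az in seq(0, 315, by = 45)) {
        d2 <- rot_axis(cos(az * DEG) * perp1 + sin(az * DEG) * perp2,
                       tilt) %*% base_dir
        cands[[length(cands) + 1]] <- as.numeric(d2)
      }
    }
    others <- rbind(all_xyz,
                    do.call(rbind, lapply(placed, function(p)
                      as.matrix(p[, c("x", "y", "z")]))))
    not_target <- rowSums(sweep(others, 2, tgt)^2) > 1e-12
    # polar atoms other than the target: the anchor should stand clear of
    # them so the constructed contact is unambiguous
    is_polar <- grepl("^[NOS]", duplex$atoms$element)
    polar_xyz <- all_xyz[is_polar, , drop = FALSE]
    polar_xyz <- polar_xyz[rowSums(sweep(polar_xyz, 2, tgt)^2) > 1e-12, ,
                           drop = FALSE]
    best <- NULL
    for (dir in cands) {
      anchor_pos <- tgt + pr$distance * dir
      # template bodies extend along -x from the anchor; map that outward
      R0 <- rotation_onto(c(-1, 0, 0), dir)
      clearance <- min(proxy_dist(matrix(anchor_pos, 1, 3), polar_xyz),
                       Inf)
      for (spin in seq(0, 330, by = 30)) {
        R <- R0 %*% rot_axis(c(1, 0, 0), spin)
        cand_xyz <- sweep(tmpl %*% t(R), 2, -anchor_pos)
        dmin <- min(proxy_dist(cand_xyz[setdiff(rownames(tmpl),
                                                pr$anchor), ,
                                        drop = FALSE], others), Inf)
        danchor <- min(proxy_dist(cand_xyz[pr$anchor, , drop = FALSE],
                                  others[not_target, , drop = FALSE]),
                       Inf)
        if ((nrow(tmpl) == 1 || dmin >= 2.0) && danchor >= 2.0 &&
            (is.null(best) || clearance > best$clearance)) {
          best <- list(xyz = cand_xyz, clearance = clearance)
        }
      }
    }
    if (is.null(best)) stop("cannot place probe ", k, " (", pr$name,
                            ") without a clash below 2 Angstrom")
    xyz <- best$xyz
    dimnames(xyz) <- NULL
    placed[[k]] <- data.frame(record = "ATOM", serial = NA_integer_,
                              name = rownames(tmpl), altloc = "",
                              resname = toupper(pr$name), chain = chain,
                              resseq = k, icode = "",
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              occ = 1, b = 0,
                              element = guess_element(rownames(tmpl)),
                              model = 1L, rel_pos = NA_integer_,
                              stringsAsFactors = FALSE)
  }
  out <- bind_structures(duplex, do.call(rbind, placed), id = duplex$id)
  out$water_labels <- duplex$water_labels
  out
}

# Rotation carrying unit vector a onto unit vector b (minimal rotation).
rotation_onto <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  c_ <- sum(a * b)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    ax <- cross3(a, c(1, 0, 0))
    if (vnorm(ax) < 1e-6) ax <- cross3(a, c(0, 1, 0))
    return(rot_axis(ax, 180))
  }
  rot_axis(cross3(a, b), acos(c_) / DEG)
}

# Minimal pairwise distance between two coordinate sets.
proxy_dist <- function(a, b) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  if (!nrow(a) || !nrow(b)) return(Inf)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}
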
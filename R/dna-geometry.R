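# Duplex-level geometry: Watson-Crick pair detection, helicoidal parameter
# profiles, backbone torsions, groove widths and bound-vs-reference
# comparison.

# Canonical Watson-Crick hydrogen-bond atom pairs (strand1 base -> partner).
.wc_hbonds <- list(
  "DA.DT" = list(c("N1", "N3"), c("N6", "O4")),
  "DT.DA" = list(c("N3", "N1"), c("O4", "N6")),
  "DG.DC" = list(c("N1", "N3"), c("N2", "O2"), c("O6", "N4")),
  "DC.DG" = list(c("N3", "N1"), c("O2", "N2"), c("N4", "O6"))
)

#' Detect Watson-Crick base pairs geometrically
#'
#' Candidate pairs must satisfy: C1'-C1' distance within `c1c1 +/- c1tol`;
#' base z axes antiparallel (angle > `zmin` degrees); at least one base
#' N/O...N/O contact within `hb_cutoff`; origin separation projected into
#' the mean base plane at most `plane_max`. Ties are resolved by the
#' smallest combined deviation; every nucleotide joins at most one pair.
#'
#' @param s a `structure3d`.
#' @param model model number.
#' @param c1c1,c1tol,zmin,hb_cutoff,plane_max geometric criteria (defaults
#'   10.4 A, 1.5 A, 120 deg, 3.5 A, 2.5 A).
#' @return data.frame with chain1/resseq1/chain2/resseq2/resname1/resname2,
#'   `canonical` flag, and the score used for tie-breaking.
#' @export
detect_base_pairs <- function(s, model = 1, c1c1 = 10.4, c1tol = 1.5,
                              zmin = 120, hb_cutoff = 3.5, plane_max = 2.5) {
  info <- residue_info(s, model)
  nucs <- info[info$class == "nucleotide", , drop = FALSE]
  if (nrow(nucs) < 2) return(empty_pairs())
  frames <- vector("list", nrow(nucs))
  crds <- vector("list", nrow(nucs))
  ok <- logical(nrow(nucs))
  for (i in seq_len(nrow(nucs))) {
    ra <- residue_atoms(s, nucs$chain[i], nucs$resseq[i], nucs$icode[i], model)
    cc <- res_coords(ra)
    crds[[i]] <- cc
    frames[[i]] <- tryCatch(fit_base_frame(cc, nucs$resname[i]),
                            error = function(e) NULL)
    ok[i] <- !is.null(frames[[i]])
  }
  cand <- NULL
  for (i in seq_len(nrow(nucs) - 1)) {
    if (!ok[i] || !("C1'" %in% rownames(crds[[i]]))) next
    for (j in seq(i + 1, nrow(nucs))) {
      if (!ok[j] || !("C1'" %in% rownames(crds[[j]]))) next
      d <- vnorm(crds[[i]]["C1'", ] - crds[[j]]["C1'", ])
      if (abs(d - c1c1) > c1tol) next
      zang <- bond_angle(frames[[i]]$origin + frames[[i]]$R[, 3],
                         frames[[i]]$origin,
                         frames[[i]]$origin + frames[[j]]$R[, 3])
      if (zang <= zmin) next
      # origin separation within the mean base plane
      zm <- unitv(frames[[i]]$R[, 3] - frames[[j]]$R[, 3])
      dv <- frames[[j]]$origin - frames[[i]]$origin
      inplane <- vnorm(dv - sum(dv * zm) * zm)
      if (inplane > plane_max) next
      hb <- min_polar_base_dist(crds[[i]], crds[[j]],
                                nucs$resname[i], nucs$resname[j])
      if (!is.finite(hb) || hb > hb_cutoff) next
      score <- abs(d - c1c1) / c1tol + hb / hb_cutoff + inplane / plane_max
      cand <- rbind(cand, data.frame(i = i, j = j, score = score))
    }
  }
  if (is.null(cand)) return(empty_pairs())
  cand <- cand[order(cand$score), , drop = FALSE]
  used <- logical(nrow(nucs))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used[cand$i[k]] && !used[cand$j[k]]) {
      keep[k] <- TRUE
      used[cand$i[k]] <- used[cand$j[k]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  r1 <- nucs[cand$i, ]; r2 <- nucs[cand$j, ]
  comp <- mapply(function(a, b) {
    na <- normalize_base_name(a)
    identical(unname(complement_base(na)), unname(normalize_base_name(b)))
  }, r1$resname, r2$resname)
  data.frame(chain1 = r1$chain, resseq1 = r1$resseq, icode1 = r1$icode,
             resname1 = r1$resname, chain2 = r2$chain, resseq2 = r2$resseq,
             icode2 = r2$icode, resname2 = r2$resname,
             canonical = as.logical(comp), score = cand$score,
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_pairs <- function() {
  data.frame(chain1 = character(), resseq1 = integer(), icode1 = character(),
             resname1 = character(), chain2 = character(),
             resseq2 = integer(), icode2 = character(),
             resname2 = character(), canonical = logical(),
             score = numeric(), stringsAsFactors = FALSE)
}

min_polar_base_dist <- function(c1, c2, base1, base2) {
  key <- paste(normalize_base_name(base1), normalize_base_name(base2),
               sep = ".")
  pairs <- .wc_hbonds[[key]]
  pick <- function(cc) {
    nm <- rownames(cc)
    base_nm <- setdiff(nm, c("P", "OP1", "OP2", "OP3", "O5'", "C5'", "C4'",
                             "O4'", "C3'", "O3'", "C2'", "C1'"))
    cc[base_nm[grepl("^[NO]", base_nm)], , drop = FALSE]
  }
  if (!is.null(pairs)) {
    d <- vapply(pairs, function(p) {
      if (p[1] %in% rownames(c1) && p[2] %in% rownames(c2))
        vnorm(c1[p[1], ] - c2[p[2], ]) else Inf
    }, 0)
    return(min(d))
  }
  a <- pick(c1); b <- pick(c2)
  if (!nrow(a) || !nrow(b)) return(Inf)
  min(as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                          nrow(a) + seq_len(nrow(b))])
}

#' Backbone and glycosidic torsions of a DNA strand
#'
#' IUPAC convention: alpha O3'(i-1)-P-O5'-C5'; beta P-O5'-C5'-C4'; gamma
#' O5'-C5'-C4'-C3'; delta C5'-C4'-C3'-O3'; epsilon C4'-C3'-O3'-P(i+1); zeta
#' C3'-O3'-P(i+1)-O5'(i+1); chi via N9/C4 (purines) or N1/C2 (pyrimidines).
#' Torsions whose defining atoms are missing (e.g. alpha/gamma at a
#' phosphate-free 5' terminus) are NA.
#'
#' @param s a `structure3d`.
#' @param chain chain id of the strand.
#' @param model model number.
#' @param altloc optional altloc label to follow through alternate conformers.
#' @return data.frame, one row per nucleotide 5'->3', columns alpha...chi.
#' @export
backbone_torsions <- function(s, chain, model = 1, altloc = NULL) {
  info <- residue_info(s, model)
  strand <- info[info$chain == chain & info$class == "nucleotide", ,
                 drop = FALSE]
  strand <- strand[order(strand$resseq), , drop = FALSE]
  n <- nrow(strand)
  if (!n) stop("no nucleotides in chain ", chain)
  cc <- lapply(seq_len(n), function(i)
    res_coords(residue_atoms(s, chain, strand$resseq[i], strand$icode[i],
                             model), altloc = altloc))
  g <- function(i, nm) {
    if (i < 1 || i > n) return(NULL)
    m <- cc[[i]]
    if (!nm %in% rownames(m)) return(NULL)
    m[nm, ]
  }
  dihe <- function(a, b, c, d) {
    if (is.null(a) || is.null(b) || is.null(c) || is.null(d)) return(NA_real_)
    dihedral(a, b, c, d)
  }
  out <- data.frame(chain = chain, resseq = strand$resseq,
                    resname = strand$resname,
                    rel_pos = strand$rel_pos, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    out$alpha[i] <- dihe(g(i - 1, "O3'"), g(i, "P"), g(i, "O5'"), g(i, "C5'"))
    out$beta[i] <- dihe(g(i, "P"), g(i, "O5'"), g(i, "C5'"), g(i, "C4'"))
    out$gamma[i] <- dihe(g(i, "O5'"), g(i, "C5'"), g(i, "C4'"), g(i, "C3'"))
    out$delta[i] <- dihe(g(i, "C5'"), g(i, "C4'"), g(i, "C3'"), g(i, "O3'"))
    out$epsilon[i] <- dihe(g(i, "C4'"), g(i, "C3'"), g(i, "O3'"),
                           g(i + 1, "P"))
    out$zeta[i] <- dihe(g(i, "C3'"), g(i, "O3'"), g(i + 1, "P"),
                        g(i + 1, "O5'"))
    if (is_purine_base(strand$resname[i]) %in% TRUE) {
      out$chi[i] <- dihe(g(i, "O4'"), g(i, "C1'"), g(i, "N9"), g(i, "C4"))
    } else {
      out$chi[i] <- dihe(g(i, "O4'"), g(i, "C1'"), g(i, "N1"), g(i, "C2"))
    }
  }
  out
}

#' Helicoidal geometry profile of a bound duplex
#'
#' Fits base reference frames, computes the six intra-base-pair and six step
#' parameters, and the groove widths, for every Watson-Crick pair of a
#' duplex, ordered 5'->3' along strand 1. Step parameters at row i describe
#' the step from pair i to pair i+1 (NA on the last pair).
#'
#' @param s a `structure3d` (rel_pos labels are used if present).
#' @param strand1,strand2 chain ids; if `strand2` is NULL every chain paired
#'   with strand1 is used.
#' @param model model number.
#' @param groove_offset half-window (in pair steps) of the cross-strand P-P
#'   groove convention (default 2, i.e. P(i-2)...P(i+2)).
#' @param refined_grooves subtract 5.8 A (two phosphate van der Waals radii)
#'   from raw P-P distances (default FALSE).
#' @param pairs optional explicit pair table (as from
#'   [detect_base_pairs()]); by default pairs are detected geometrically.
#'   Useful when the pairing is known by construction.
#' @return data.frame of class `geometry_profile`.
#' @export
geometry_profile <- function(s, strand1, strand2 = NULL, model = 1,
                             groove_offset = 2, refined_grooves = FALSE,
                             pairs = NULL) {
  if (is.null(pairs)) pairs <- detect_base_pairs(s, model)
  sel <- pairs$chain1 == strand1 | pairs$chain2 == strand1
  pairs <- pairs[sel, , drop = FALSE]
  if (!is.null(strand2))
    pairs <- pairs[pairs$chain1 == strand2 | pairs$chain2 == strand2, ,
                   drop = FALSE]
  if (!nrow(pairs)) stop("no base pairs found for strand ", strand1)
  # orient: strand1 residue first
  flip <- pairs$chain1 != strand1
  for (col in c("chain", "resseq", "icode", "resname")) {
    a <- pairs[[paste0(col, "1")]]; b <- pairs[[paste0(col, "2")]]
    pairs[[paste0(col, "1")]] <- ifelse(flip, b, a)
    pairs[[paste0(col, "2")]] <- ifelse(flip, a, b)
  }
  pairs <- pairs[order(pairs$resseq1), , drop = FALSE]
  n <- nrow(pairs)
  rec <- data.frame(position = seq_len(n))
  at <- s$atoms[s$atoms$model == model, , drop = FALSE]
  relmap <- at$rel_pos[match(paste(pairs$chain1, pairs$resseq1),
                             paste(at$chain, at$resseq))]
  if (!anyNA(relmap)) rec$position <- relmap
  rec$resname1 <- pairs$resname1; rec$resname2 <- pairs$resname2
  rec$chain1 <- pairs$chain1; rec$resseq1 <- pairs$resseq1
  rec$chain2 <- pairs$chain2; rec$resseq2 <- pairs$resseq2
  pair_frames <- vector("list", n)
  cc1 <- cc2 <- vector("list", n)
  for (i in seq_len(n)) {
    cc1[[i]] <- res_coords(residue_atoms(s, pairs$chain1[i], pairs$resseq1[i],
                                         pairs$icode1[i], model))
    cc2[[i]] <- res_coords(residue_atoms(s, pairs$chain2[i], pairs$resseq2[i],
                                         pairs$icode2[i], model))
    f1 <- fit_base_frame(cc1[[i]], pairs$resname1[i])
    f2 <- fit_base_frame(cc2[[i]], pairs$resname2[i])
    bp <- basepair_params(f1, f2)
    pair_frames[[i]] <- bp$pair_frame
    rec$shear[i] <- bp$shear; rec$stretch[i] <- bp$stretch
    rec$stagger[i] <- bp$stagger; rec$buckle[i] <- bp$buckle
    rec$propeller[i] <- bp$propeller; rec$opening[i] <- bp$opening
  }
  for (i in seq_len(n)) {
    if (i < n) {
      st <- step_params(pair_frames[[i]], pair_frames[[i + 1]])
      rec$shift[i] <- st$shift; rec$slide[i] <- st$slide
      rec$rise[i] <- st$rise; rec$tilt[i] <- st$tilt
      rec$roll[i] <- st$roll; rec$twist[i] <- st$twist
    } else {
      rec$shift[i] <- rec$slide[i] <- rec$rise[i] <- NA_real_
      rec$tilt[i] <- rec$roll[i] <- rec$twist[i] <- NA_real_
    }
  }
  gw <- groove_widths_from_coords(cc1, cc2, offset = groove_offset,
                                  refined = refined_grooves)
  rec$minor_width <- gw$minor
  rec$major_width <- gw$major
  attr(rec, "groove_offset") <- groove_offset
  attr(rec, "refined_grooves") <- refined_grooves
  class(rec) <- c("geometry_profile", "data.frame")
  rec
}

# Cross-strand P...P groove widths given per-pair coordinate lists ordered
# along strand 1 (5'->3'). Convention (configurable offset k, default 2):
#   minor width at pair i = |P(strand2, i - k) - P(strand1, i + k)|
#   major width at pair i = |P(strand2, i + k) - P(strand1, i - k)|
# Positions lacking a spanning phosphate report NA.
groove_widths_from_coords <- function(cc1, cc2, offset = 2, refined = FALSE) {
  n <- length(cc1)
  p1 <- lapply(cc1, function(m) if ("P" %in% rownames(m)) m["P", ] else NULL)
  p2 <- lapply(cc2, function(m) if ("P" %in% rownames(m)) m["P", ] else NULL)
  minor <- major <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - offset; hi <- i + offset
    if (lo >= 1 && hi <= n) {
      if (!is.null(p2[[lo]]) && !is.null(p1[[hi]]))
        minor[i] <- vnorm(p2[[lo]] - p1[[hi]])
      if (!is.null(p2[[hi]]) && !is.null(p1[[lo]]))
        major[i] <- vnorm(p2[[hi]] - p1[[lo]])
    }
  }
  if (refined) {
    minor <- minor - 5.8
    major <- major - 5.8
  }
  list(minor = minor, major = major)
}

#' Groove widths of a duplex
#'
#' Convenience wrapper returning only position and groove widths from
#' [geometry_profile()].
#'
#' @inheritParams geometry_profile
#' @return data.frame with position, minor_width, major_width.
#' @export
groove_widths <- function(s, strand1, strand2 = NULL, model = 1,
                          groove_offset = 2, refined_grooves = FALSE) {
  gp <- geometry_profile(s, strand1, strand2, model,
                         groove_offset = groove_offset,
                         refined_grooves = refined_grooves)
  gp[, c("position", "minor_width", "major_width")]
}

#' Compare a bound-duplex profile with a reference profile
#'
#' Aligns two [geometry_profile()] tables by position, forms per-position
#' parameter differences (bound minus reference), and summarises the
#' extremes: maximal minor-groove widening and narrowing, and the positions
#' of the largest absolute propeller and roll changes. The scissile bond
#' (between positions -1 and +1 when rel_pos numbering is in use) is
#' annotated.
#'
#' @param bound,reference `geometry_profile` tables.
#' @return list with `deltas` (data.frame) and `summary`.
#' @export
compare_profiles <- function(bound, reference) {
  common <- intersect(bound$position, reference$position)
  if (!length(common)) stop("profiles share no positions; cannot align")
  b <- bound[match(common, bound$position), , drop = FALSE]
  r <- reference[match(common, reference$position), , drop = FALSE]
  params <- c("shear", "stretch", "stagger", "buckle", "propeller",
              "opening", "shift", "slide", "rise", "tilt", "roll", "twist",
              "minor_width", "major_width")
  deltas <- data.frame(position = common)
  for (p in params) deltas[[p]] <- b[[p]] - r[[p]]
  loc_extreme <- function(v) {
    if (all(is.na(v))) return(NA_integer_)
    common[which.max(abs(v))]
  }
  mw <- deltas$minor_width
  summary <- list(
    max_minor_widening = if (all(is.na(mw))) NA_real_ else max(mw, na.rm = TRUE),
    max_minor_widening_pos = if (all(is.na(mw))) NA else
      common[which.max(replace(mw, is.na(mw), -Inf))],
    max_minor_narrowing = if (all(is.na(mw))) NA_real_ else -min(mw, na.rm = TRUE),
    max_minor_narrowing_pos = if (all(is.na(mw))) NA else
      common[which.min(replace(mw, is.na(mw), Inf))],
    extreme_propeller_pos = loc_extreme(deltas$propeller),
    extreme_propeller = if (all(is.na(deltas$propeller))) NA_real_ else
      deltas$propeller[which.max(abs(deltas$propeller))],
    extreme_roll_pos = loc_extreme(deltas$roll),
    extreme_roll = if (all(is.na(deltas$roll))) NA_real_ else
      deltas$roll[which.max(abs(deltas$roll))],
    scissile_between = if (all(c(-1, 1) %in% common)) c(-1, 1) else NULL)
  list(deltas = deltas, summary = summary)
}

#' Plot a geometry profile against its reference
#'
#' Simple per-position line plots (base graphics) of one parameter.
#'
#' @param x a `geometry_profile`.
#' @param parameter column to plot (default "minor_width").
#' @param reference optional reference profile drawn in black.
#' @param ... passed to [plot()].
#' @export
plot.geometry_profile <- function(x, parameter = "minor_width",
                                  reference = NULL, ...) {
  plot(x$position, x[[parameter]], type = "b", col = "red",
       xlab = "position (relative to scissile bond)", ylab = parameter, ...)
  if (!is.null(reference))
    graphics::lines(reference$position, reference[[parameter]],
                    type = "b", col = "black")
  invisible(x)
}
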
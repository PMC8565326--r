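# Rigid-body least-squares superposition and selection-based RMSD between
# structures, including distance-shell selections around an atom (e.g. all
# matched heavy atoms 10-14 Angstrom from a bound metal).

#' Match atom pairs between two structures
#'
#' Atoms are matched by (chain, resseq, icode, atom name) in the given
#' model; alternate locations are resolved (highest occupancy) first.
#'
#' @param a,b `structure3d` objects.
#' @param rule "calpha" (protein CA atoms), "heavy" (all heavy atoms),
#'   `list(names = c(...))` (named atoms only), or
#'   `list(shell = list(center = <atom spec in b>, rmin = , rmax = ))`
#'   keeping matched pairs whose reference-structure (`b`) atom lies within
#'   the radial shell.
#' @param model model number.
#' @return data.frame with row indices `ia`, `ib` into the atom tables of
#'   the altloc-resolved structures, plus the match key.
#' @export
select_pairs <- function(a, b, rule = "calpha", model = 1) {
  a <- resolve_altlocs(a); b <- resolve_altlocs(b)
  ta <- a$atoms[a$atoms$model == model, , drop = FALSE]
  tb <- b$atoms[b$atoms$model == model, , drop = FALSE]
  keep <- function(tt) {
    if (identical(rule, "calpha")) {
      tt$name == "CA" & residue_class(tt$resname) == "protein"
    } else if (identical(rule, "heavy")) {
      toupper(tt$element) != "H"
    } else if (is.list(rule) && !is.null(rule$names)) {
      tt$name %in% rule$names
    } else if (is.list(rule) && !is.null(rule$shell)) {
      toupper(tt$element) != "H"
    } else stop("unknown selection rule")
  }
  ta <- ta[keep(ta), , drop = FALSE]
  tb <- tb[keep(tb), , drop = FALSE]
  key_a <- paste(ta$chain, ta$resseq, ta$icode, ta$name, sep = "\r")
  key_b <- paste(tb$chain, tb$resseq, tb$icode, tb$name, sep = "\r")
  common <- intersect(key_a, key_b)
  if (is.list(rule) && !is.null(rule$shell)) {
    sh <- rule$shell
    ctr <- atom_xyz(resolve_atom(b, sh$center, model = model))
    rb <- tb[match(common, key_b), , drop = FALSE]
    d <- sqrt(rowSums(sweep(as.matrix(rb[, c("x", "y", "z")]), 2, ctr)^2))
    common <- common[d >= sh$rmin & d <= sh$rmax]
  }
  if (!length(common)) stop("selection matches no atom pairs")
  data.frame(ia = match(common, key_a), ib = match(common, key_b),
             key = gsub("\r", ":", common), stringsAsFactors = FALSE)
}

#' Superpose one structure onto another
#'
#' Optimal least-squares rotation and translation (Kabsch/SVD; reflections
#' never returned) over the selected matched atom pairs; the transform is
#' then applied to every atom of the mobile structure, ions and waters
#' included.
#'
#' @param mobile,reference `structure3d` objects.
#' @param selection a rule for [select_pairs()], or a precomputed pair
#'   table.
#' @param model model number.
#' @return list with `rotation`, `translation`, `rmsd` (over the selection,
#'   after fitting), `n_atoms`, `selection` (descriptor), and `mobile`, the
#'   transformed mobile structure.
#' @export
superpose <- function(mobile, reference, selection = "calpha", model = 1) {
  pairs <- if (is.data.frame(selection)) selection else
    select_pairs(mobile, reference, selection, model)
  xm <- pair_coords(mobile, reference, pairs, model)
  fit <- kabsch(xm$a, xm$b)
  out <- mobile
  xyz <- coords3d(mobile)
  out <- set_coords3d(out, sweep(xyz %*% t(fit$rotation), 2,
                                 -fit$translation))
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, n_atoms = nrow(xm$a),
       selection = if (is.data.frame(selection)) "custom pairs" else
         paste(deparse(selection), collapse = ""),
       mobile = out)
}

# Matched coordinate matrices for a pair table (atoms re-resolved by key).
pair_coords <- function(a, b, pairs, model = 1) {
  a <- resolve_altlocs(a); b <- resolve_altlocs(b)
  ta <- a$atoms[a$atoms$model == model, , drop = FALSE]
  tb <- b$atoms[b$atoms$model == model, , drop = FALSE]
  list(a = filtered_coords(ta, pairs$key),
       b = filtered_coords(tb, pairs$key))
}

filtered_coords <- function(tt, keys) {
  key <- paste(tt$chain, tt$resseq, tt$icode, tt$name, sep = ":")
  idx <- match(keys, key)
  if (anyNA(idx)) stop("pair table does not match structure")
  as.matrix(tt[idx, c("x", "y", "z")])
}

#' RMSD between two structures over a selection, without refitting
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
rmsd_selection <- function(mobile, reference, selection = "heavy",
                           model = 1) {
  pairs <- if (is.data.frame(selection)) selection else
    select_pairs(mobile, reference, selection, model)
  xm <- pair_coords(mobile, reference, pairs, model)
  rmsd_no_fit(xm$a, xm$b)
}
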
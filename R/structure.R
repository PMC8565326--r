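# The coordinate container used throughout: an S3 object of class
# "structure3d" wrapping a flat atom table, in the spirit of bio3d's pdb
# object but carrying altlocs, model numbers and scissile-bond-relative
# residue numbering explicitly.

.atom_cols <- c("record", "serial", "name", "altloc", "resname", "chain",
                "resseq", "icode", "x", "y", "z", "occ", "b", "element",
                "model", "rel_pos")

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.nuc_names <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U")
.water_names <- c("HOH", "WAT", "H2O")
.ion_names <- c("MG", "MN", "ZN", "NA", "K", "CA", "CL", "FE", "NI", "CO")

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with (at least) columns name, resname, chain,
#'   resseq, x, y, z. Missing bookkeeping columns are filled with defaults
#'   (occupancy 1, B-factor 0, blank altloc/icode, model 1).
#' @param id label for the structure (e.g. an accession).
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, id = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) > 0) {
    defaults <- list(record = "ATOM", serial = NA_integer_, altloc = "",
                     icode = "", occ = 1, b = 0, element = "",
                     model = 1L, rel_pos = NA_integer_)
    for (nm in names(defaults))
      if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
    if (anyNA(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
    if (any(atoms$element == ""))
      atoms$element[atoms$element == ""] <-
        guess_element(atoms$name[atoms$element == ""])
    miss <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
    if (any(miss)) stop("non-finite coordinates for ", sum(miss), " atom(s)")
    if (any(atoms$occ < 0 | atoms$occ > 1))
      stop("occupancies must lie in [0, 1]")
    if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
    bad0 <- !is.na(atoms$rel_pos) & atoms$rel_pos == 0
    if (any(bad0)) stop("rel_pos 0 is not allowed (numbering skips zero)")
  } else {
    atoms <- as.data.frame(setNames(
      list(character(), integer(), character(), character(), character(),
           character(), integer(), character(), numeric(), numeric(),
           numeric(), numeric(), numeric(), character(), integer(),
           integer()),
      .atom_cols))
  }
  out <- list(id = id, atoms = atoms[, .atom_cols], water_labels = NULL)
  class(out) <- "structure3d"
  out
}

guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("MG", "MN", "ZN", "FE", "NA", "CL", "BR"), two,
               substr(nm, 1, 1))
  # primed names like O5' already reduce correctly; OP1 -> O etc.
  el
}

#' @export
print.structure3d <- function(x, ...) {
  at <- x$atoms
  info <- residue_info(x)
  cat("structure3d", if (nzchar(x$id)) paste0("'", x$id, "'"), "\n")
  cat(" ", nrow(at), "atoms,", length(unique(at$model)), "model(s),",
      length(unique(at$chain[at$model == at$model[1]])), "chain(s)\n")
  if (nrow(info))
    cat("  residues:", paste(sprintf("%s=%d", names(table(info$class)),
                                     table(info$class)), collapse = ", "), "\n")
  invisible(x)
}

residue_class <- function(resname, natoms = NA) {
  rn <- toupper(resname)
  ifelse(rn %in% .nuc_names, "nucleotide",
  ifelse(rn %in% .aa3, "protein",
  ifelse(rn %in% .water_names, "water",
  ifelse(rn %in% .ion_names, "ion", "other"))))
}

#' Residue-level summary of a structure
#'
#' @param s a `structure3d`.
#' @param model model number (default 1).
#' @return data.frame with one row per residue: chain, resseq, icode,
#'   resname, class (nucleotide/protein/water/ion/other), rel_pos, n_atoms.
#' @export
residue_info <- function(s, model = 1) {
  at <- s$atoms[s$atoms$model == model, , drop = FALSE]
  if (!nrow(at)) return(data.frame())
  key <- paste(at$chain, at$resseq, at$icode, sep = "\r")
  idx <- !duplicated(key)
  out <- data.frame(chain = at$chain[idx], resseq = at$resseq[idx],
                    icode = at$icode[idx], resname = at$resname[idx],
                    rel_pos = at$rel_pos[idx], stringsAsFactors = FALSE)
  out$class <- residue_class(out$resname)
  out$n_atoms <- as.integer(table(key)[key[idx]])
  rownames(out) <- NULL
  out
}

#' Extract the atoms of one residue
#'
#' @param s a `structure3d`.
#' @param chain chain identifier.
#' @param resseq author residue number.
#' @param icode insertion code (default "").
#' @param model model number (default 1).
#' @return data.frame of the residue's atom rows.
#' @export
residue_atoms <- function(s, chain, resseq, icode = "", model = 1) {
  at <- s$atoms
  at[at$model == model & at$chain == chain & at$resseq == resseq &
       at$icode == icode, , drop = FALSE]
}

# Named coordinate matrix of a residue's atoms. With duplicated atom names
# (altlocs) keeps the highest-occupancy conformer unless altloc is given.
res_coords <- function(res_at, altloc = NULL) {
  if (!nrow(res_at)) return(matrix(numeric(), 0, 3))
  if (!is.null(altloc))
    res_at <- res_at[res_at$altloc %in% c("", altloc), , drop = FALSE]
  ord <- order(res_at$name, -res_at$occ, res_at$altloc)
  res_at <- res_at[ord, , drop = FALSE]
  res_at <- res_at[!duplicated(res_at$name), , drop = FALSE]
  m <- as.matrix(res_at[, c("x", "y", "z")])
  rownames(m) <- res_at$name
  m
}

#' Coordinates of a structure as a matrix
#'
#' @param s a `structure3d`.
#' @param model optional model number (default: all models).
#' @return n x 3 matrix of coordinates.
#' @export
coords3d <- function(s, model = NULL) {
  at <- s$atoms
  if (!is.null(model)) at <- at[at$model == model, , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Replace the coordinates of a structure
#'
#' @param s a `structure3d`.
#' @param xyz n x 3 matrix matching the selected atoms.
#' @param model optional model number (default: all models).
#' @return the modified structure.
#' @export
set_coords3d <- function(s, xyz, model = NULL) {
  sel <- if (is.null(model)) rep(TRUE, nrow(s$atoms)) else s$atoms$model == model
  s$atoms[sel, c("x", "y", "z")] <- as.matrix(xyz)
  s
}

#' Ion and water atoms of a structure
#'
#' @param s a `structure3d`.
#' @param model model number.
#' @return data.frame of atom rows.
#' @export
ion_atoms <- function(s, model = 1) {
  at <- s$atoms[s$atoms$model == model, , drop = FALSE]
  at[residue_class(at$resname) == "ion", , drop = FALSE]
}

#' @rdname ion_atoms
#' @export
water_atoms <- function(s, model = 1) {
  at <- s$atoms[s$atoms$model == model, , drop = FALSE]
  at[residue_class(at$resname) == "water", , drop = FALSE]
}

#' Bind figure-style water labels (W1, W2, ...) to residues
#'
#' Crystallographic water numbering in figures is an author convention, so
#' labels are user-supplied aliases bound to (chain, resseq), not detected.
#'
#' @param s a `structure3d`.
#' @param ... named specs, e.g. `W5 = "S:105"` (chain:resseq).
#' @return the structure with a `water_labels` lookup attached.
#' @export
label_waters <- function(s, ...) {
  specs <- c(...)
  parsed <- lapply(specs, function(sp) {
    parts <- strsplit(sp, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("water label spec must be 'chain:resseq'")
    list(chain = parts[1], resseq = as.integer(parts[2]))
  })
  for (i in seq_along(parsed)) {
    hit <- residue_atoms(s, parsed[[i]]$chain, parsed[[i]]$resseq)
    if (!nrow(hit)) stop("no residue at ", specs[i], " for label ",
                         names(specs)[i])
  }
  s$water_labels <- parsed
  s
}

#' Resolve an atom specification to an atom record
#'
#' Supported forms: `"A:7:OP1"` (chain:resseq:atom), `"A:7:OP1:B"`
#' (altloc-qualified), `"A:+1:P"` (chain:rel_pos:atom, signed with an
#' explicit + or -), `"W5"` (a water label bound with [label_waters()]),
#' `"MG"` (the single residue with that name, e.g. an ion).
#'
#' @param s a `structure3d`.
#' @param spec atom spec string.
#' @param model model number.
#' @return one-row data.frame of the atom (highest occupancy on ties).
#' @export
resolve_atom <- function(s, spec, model = 1) {
  at <- s$atoms[s$atoms$model == model, , drop = FALSE]
  if (!grepl(":", spec)) {
    if (!is.null(s$water_labels) && spec %in% names(s$water_labels)) {
      w <- s$water_labels[[spec]]
      sub <- at[at$chain == w$chain & at$resseq == w$resseq, , drop = FALSE]
      sub <- sub[sub$element %in% c("O", ""), , drop = FALSE]
      if (!nrow(sub)) stop("water label ", spec, " resolves to no atom")
      return(sub[1, , drop = FALSE])
    }
    sub <- at[toupper(at$resname) == toupper(spec), , drop = FALSE]
    if (nrow(sub) == 1) return(sub)
    stop("cannot resolve atom spec '", spec, "'")
  }
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) < 3) stop("atom spec '", spec, "' needs chain:res:atom")
  chain <- parts[1]
  sub <- at[at$chain == chain, , drop = FALSE]
  if (grepl("^[+-]", parts[2])) {
    sub <- sub[!is.na(sub$rel_pos) & sub$rel_pos == as.integer(parts[2]), ,
               drop = FALSE]
  } else {
    sub <- sub[sub$resseq == as.integer(parts[2]), , drop = FALSE]
  }
  sub <- sub[sub$name == parts[3], , drop = FALSE]
  if (length(parts) >= 4)
    sub <- sub[sub$altloc == parts[4], , drop = FALSE]
  if (!nrow(sub)) stop("atom spec '", spec, "' matches no atom")
  if (nrow(sub) > 1) {
    sub <- sub[order(-sub$occ, sub$altloc), , drop = FALSE][1, , drop = FALSE]
  }
  sub
}

#' Coordinates of a resolved atom row
#'
#' @param atom_row one-row atom data.frame (e.g. from [resolve_atom()]).
#' @return numeric length-3 position.
#' @export
atom_xyz <- function(atom_row) as.numeric(atom_row[1, c("x", "y", "z")])

# Merge several structures'/fragments' atom tables into one structure.
bind_structures <- function(..., id = "") {
  frames <- lapply(list(...), function(s) {
    if (inherits(s, "structure3d")) s$atoms else s
  })
  at <- do.call(rbind, frames)
  at$serial <- seq_len(nrow(at))
  structure3d(at, id = id)
}
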
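# Protein-DNA contact enumeration and classification: polar vs van der
# Waals, DNA moiety (base / sugar / phosphate) and groove face.

# Polar (donor/acceptor) capability tables, heavy atoms only; with no
# hydrogens in the inputs, "both" is used wherever protonation decides.
.protein_polar <- list(
  backbone = c(N = "donor", O = "acceptor", OXT = "acceptor"),
  SER = c(OG = "both"), THR = c(OG1 = "both"), TYR = c(OH = "both"),
  ASN = c(OD1 = "acceptor", ND2 = "donor"),
  GLN = c(OE1 = "acceptor", NE2 = "donor"),
  ASP = c(OD1 = "acceptor", OD2 = "acceptor"),
  GLU = c(OE1 = "acceptor", OE2 = "acceptor"),
  LYS = c(NZ = "donor"),
  ARG = c(NE = "donor", NH1 = "donor", NH2 = "donor"),
  HIS = c(ND1 = "both", NE2 = "both"),
  TRP = c(NE1 = "donor"), CYS = c(SG = "both"), MET = c(SD = "acceptor"))

.dna_polar <- c(
  OP1 = "acceptor", OP2 = "acceptor", OP3 = "acceptor", "O5'" = "acceptor",
  "O3'" = "acceptor", "O4'" = "acceptor",
  O2 = "acceptor", O4 = "acceptor", O6 = "acceptor",
  N7 = "acceptor", N3 = "both", N1 = "both",
  N2 = "donor", N4 = "donor", N6 = "donor")

protein_polar_role <- function(resname, atom) {
  r <- .protein_polar[[toupper(resname)]]
  role <- if (!is.null(r) && atom %in% names(r)) r[[atom]] else
    .protein_polar$backbone[atom]
  if (is.null(role) || is.na(role)) NA_character_ else role
}

dna_polar_role <- function(atom) {
  if (atom %in% names(.dna_polar)) .dna_polar[[atom]] else NA_character_
}

roles_compatible <- function(r1, r2) {
  if (is.na(r1) || is.na(r2)) return(FALSE)
  (r1 %in% c("donor", "both") && r2 %in% c("acceptor", "both")) ||
    (r1 %in% c("acceptor", "both") && r2 %in% c("donor", "both"))
}

#' Classify a DNA atom by moiety
#'
#' @param atom atom name.
#' @return "phosphate", "sugar", or "base".
#' @export
dna_moiety <- function(atom) {
  ifelse(atom %in% c("P", "OP1", "OP2", "OP3"), "phosphate",
         ifelse(grepl("'", atom, fixed = TRUE), "sugar", "base"))
}

#' Groove face of a DNA atom
#'
#' Base atoms are assigned minor or major edge from fixed per-base tables
#' (derived from the sign of x in the standard reference frame, +x toward
#' the major groove); sugar and phosphate atoms are "backbone"; base atoms
#' of unpaired nucleotides are "n/a".
#'
#' @param atom atom name.
#' @param resname nucleotide residue name.
#' @param paired is the nucleotide Watson-Crick paired?
#' @return one of "minor", "major", "backbone", "n/a".
#' @export
classify_groove <- function(atom, resname, paired = TRUE) {
  m <- dna_moiety(atom)
  if (m != "base") return("backbone")
  if (!paired) return("n/a")
  tab <- base_edge_table(resname)
  if (atom %in% names(tab)) unname(tab[[atom]]) else "n/a"
}

#' Enumerate protein-DNA contacts
#'
#' All-pairs heavy-atom search: polar contacts are donor/acceptor pairs
#' within `polar_cutoff`; any remaining heavy-atom pair within `vdw_cutoff`
#' is a van der Waals contact. Each record carries the DNA moiety and
#' groove-face classification.
#'
#' @param s a `structure3d` containing protein and DNA chains.
#' @param polar_cutoff polar heavy-atom cutoff in Angstrom (default 3.5).
#' @param vdw_cutoff van der Waals cutoff in Angstrom (default 4.0).
#' @param model model number.
#' @return data.frame of contact records sorted by (DNA position,
#'   distance).
#' @export
find_contacts <- function(s, polar_cutoff = 3.5, vdw_cutoff = 4.0,
                          model = 1) {
  s <- resolve_altlocs(s)
  at <- s$atoms[s$atoms$model == model, , drop = FALSE]
  cls <- residue_class(at$resname)
  prot <- at[cls == "protein" & toupper(at$element) != "H", , drop = FALSE]
  dna <- at[cls == "nucleotide" & toupper(at$element) != "H", , drop = FALSE]
  if (!nrow(prot) || !nrow(dna))
    stop("structure must contain at least one protein and one DNA chain")
  pairs <- detect_base_pairs(s, model)
  paired_key <- c(paste(pairs$chain1, pairs$resseq1),
                  paste(pairs$chain2, pairs$resseq2))
  pm <- as.matrix(prot[, c("x", "y", "z")])
  dm <- as.matrix(dna[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rep(1, nrow(dm))) +
    outer(rep(1, nrow(pm)), rowSums(dm^2)) - 2 * pm %*% t(dm)
  d2[d2 < 0] <- 0
  hits <- which(d2 <= max(polar_cutoff, vdw_cutoff)^2, arr.ind = TRUE)
  if (!nrow(hits)) return(empty_contacts())
  recs <- lapply(seq_len(nrow(hits)), function(k) {
    ip <- hits[k, 1]; id <- hits[k, 2]
    dist <- sqrt(d2[ip, id])
    rp <- protein_polar_role(prot$resname[ip], prot$name[ip])
    rd <- dna_polar_role(dna$name[id])
    polar <- dist <= polar_cutoff && roles_compatible(rp, rd)
    if (!polar && dist > vdw_cutoff) return(NULL)
    data.frame(
      protein_resname = prot$resname[ip], protein_resseq = prot$resseq[ip],
      protein_chain = prot$chain[ip], protein_atom = prot$name[ip],
      dna_chain = dna$chain[id], dna_resseq = dna$resseq[id],
      dna_rel_pos = dna$rel_pos[id], dna_resname = dna$resname[id],
      dna_atom = dna$name[id], distance = dist,
      class = if (polar) "polar" else "vdw",
      dna_moiety = dna_moiety(dna$name[id]),
      groove = classify_groove(dna$name[id], dna$resname[id],
                               paste(dna$chain[id], dna$resseq[id]) %in%
                                 paired_key),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(out)) return(empty_contacts())
  key <- if (all(!is.na(out$dna_rel_pos))) out$dna_rel_pos else out$dna_resseq
  out <- out[order(key, out$distance, out$protein_atom, out$dna_atom), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_records", "data.frame")
  out
}

empty_contacts <- function() {
  out <- data.frame(protein_resname = character(),
                    protein_resseq = integer(), protein_chain = character(),
                    protein_atom = character(), dna_chain = character(),
                    dna_resseq = integer(), dna_rel_pos = integer(),
                    dna_resname = character(), dna_atom = character(),
                    distance = numeric(), class = character(),
                    dna_moiety = character(), groove = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("contact_records", "data.frame")
  out
}

#' Write a contact report
#'
#' @param records contact records from [find_contacts()].
#' @param path output file.
#' @param format "tsv" (one row per contact, deterministic order) or "json"
#'   (records grouped per DNA position, mirroring interaction-map layouts).
#' @return invisibly, `path`.
#' @export
contact_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(records), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    pos <- if (nrow(records)) ifelse(is.na(records$dna_rel_pos),
                                     records$dna_resseq,
                                     records$dna_rel_pos) else integer()
    grouped <- lapply(split(as.data.frame(records), pos), function(g)
      list(position = unname(pos[match(g$dna_resseq[1], records$dna_resseq)]),
           strand = unique(g$dna_chain),
           contacts = g[, c("protein_resname", "protein_resseq",
                            "protein_atom", "dna_atom", "distance", "class",
                            "dna_moiety", "groove")]))
    jsonlite::write_json(unname(grouped), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Read back a TSV contact report
#'
#' @param path file written by [contact_report()] with `format = "tsv"`.
#' @return data.frame of contact records.
#' @export
read_contact_report <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("contact_records", "data.frame")
  out
}
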
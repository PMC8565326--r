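# Reading (PDB via bio3d::read.pdb, mmCIF via bio3d::read.cif) and writing
# (fixed-column PDB v3.3, single- or multi-model) of structure3d objects,
# alternate-location resolution, and scissile-bond-relative numbering.

#' Read a macromolecular structure
#'
#' Reads PDB or mmCIF files into a [structure3d()] object. All ATOM/HETATM
#' records are kept, including alternate locations, waters and metal ions;
#' multi-model PDB files yield one model per MODEL record.
#'
#' @param path file path.
#' @param format "pdb", "mmcif", or "auto" (by extension, default).
#' @return a `structure3d`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "mmcif", mmcif = "mmcif",
                     pdb = "pdb", ent = "pdb", "pdb")
  }
  parsed <- tryCatch(
    if (format == "pdb")
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- parsed$atom
  n_models <- max(1, nrow(parsed$xyz))
  blank <- function(v, alt = "") { v[is.na(v)] <- alt; v }
  base <- data.frame(
    record = blank(at$type, "ATOM"),
    serial = at$eleno,
    name = blank(at$elety),
    altloc = blank(at$alt),
    resname = blank(at$resid),
    chain = blank(at$chain, " "),
    resseq = at$resno,
    icode = blank(at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    element = blank(at$elesy),
    model = 1L,
    rel_pos = NA_integer_,
    stringsAsFactors = FALSE)
  if (n_models > 1) {
    per <- lapply(seq_len(n_models), function(m) {
      b <- base
      b$model <- as.integer(m)
      b[, c("x", "y", "z")] <- matrix(parsed$xyz[m, ], ncol = 3, byrow = TRUE)
      b
    })
    base <- do.call(rbind, per)
  }
  structure3d(base, id = sub("\\.[^.]*$", "", basename(path)))
}

fmt_atom_name <- function(name, element) {
  # PDB v3.3: element symbol right-justified in columns 13-14; one-letter
  # elements with short names start at column 14.
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 2) sprintf("%-4s", name) else sprintf(" %-3s", name)
}

#' Write a structure as a PDB file
#'
#' Fixed-column PDB v3.3 records; multiple models are emitted as
#' MODEL/ENDMDL blocks (used for torsion-path animations).
#'
#' @param s a `structure3d`.
#' @param path output file path.
#' @param multi_model write all models as MODEL blocks (default: write all
#'   models if more than one is present).
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path, multi_model = NULL) {
  at <- s$atoms
  models <- sort(unique(at$model))
  if (is.null(multi_model)) multi_model <- length(models) > 1
  if (nrow(at) && max(abs(as.matrix(at[, c("x", "y", "z")]))) >= 10000)
    stop("coordinate overflow: |x| must be < 10000 for fixed-width PDB")
  if (nrow(at) && any(nchar(at$name) > 4))
    stop("atom names longer than 4 characters cannot be written")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   4 %s WRITTEN BY NICKSCOPE",
                     toupper(substr(s$id, 1, 20))), con)
  fmt_model <- function(m) {
    a <- at[at$model == m, , drop = FALSE]
    if (!nrow(a)) return(character())
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$record, a$serial %% 100000,
            vapply(seq_len(nrow(a)),
                   function(i) fmt_atom_name(a$name[i], a$element[i]), ""),
            a$altloc, a$resname, substr(paste0(a$chain, " "), 1, 1),
            a$resseq %% 10000, substr(paste0(a$icode, " "), 1, 1),
            a$x, a$y, a$z, a$occ, a$b,
            toupper(a$element))
  }
  if (multi_model && length(models) >= 1) {
    for (m in models) {
      writeLines(sprintf("MODEL %8d", m), con)
      writeLines(fmt_model(m), con)
      writeLines("ENDMDL", con)
    }
  } else if (length(models) >= 1) {
    writeLines(fmt_model(models[1]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Resolve alternate locations
#'
#' @param s a `structure3d`.
#' @param policy "highest_occupancy" (default; ties broken by altloc label in
#'   alphabetical order), "keep_all", or "label:X" to select conformer X.
#' @return a `structure3d` with altlocs resolved per the policy.
#' @export
resolve_altlocs <- function(s, policy = "highest_occupancy") {
  if (identical(policy, "keep_all")) return(s)
  at <- s$atoms
  key <- paste(at$model, at$chain, at$resseq, at$icode, at$name, sep = "\r")
  if (startsWith(policy, "label:")) {
    lab <- sub("^label:", "", policy)
    if (!any(at$altloc == lab))
      stop("altloc label '", lab, "' not present in structure")
    in_alt_group <- key %in% key[at$altloc != ""]
    keep <- !in_alt_group | at$altloc == lab
    # atoms whose alternate group lacks the label fall back to highest occ
    grp_has <- tapply(at$altloc == lab, key, any)
    fallback <- in_alt_group & !grp_has[key] & !keep
    if (any(fallback)) {
      fb <- pick_highest(at[fallback, , drop = FALSE])
      out <- rbind(at[keep, , drop = FALSE], fb)
    } else out <- at[keep, , drop = FALSE]
  } else if (identical(policy, "highest_occupancy")) {
    out <- pick_highest(at)
  } else stop("unknown altloc policy: ", policy)
  out <- out[order(out$model, match(out$serial, at$serial)), , drop = FALSE]
  out$altloc <- ""
  s$atoms <- out
  s
}

pick_highest <- function(at) {
  key <- paste(at$model, at$chain, at$resseq, at$icode, at$name, sep = "\r")
  ord <- order(key, -at$occ, at$altloc)
  at2 <- at[ord, , drop = FALSE]
  at2[!duplicated(key[ord]), , drop = FALSE]
}

#' Assign scissile-bond-relative numbering
#'
#' Labels nucleotides with their position relative to the scissile
#' phosphodiester bond: the nucleotide whose 5' phosphate is the scissile
#' phosphate is +1, positions 5' of the bond on the cleaved strand are -1,
#' -2, ... (no zero). Opposite-strand nucleotides take the label of their
#' Watson-Crick partner; unpaired ones (e.g. overhangs) are left unlabelled.
#'
#' @param s a `structure3d`.
#' @param scissile length-2 spec of the +1 nucleotide: `c(chain, resseq)`.
#' @param label_opposite also label the paired strand (default TRUE).
#' @return the structure with `rel_pos` filled in.
#' @export
assign_relative_numbering <- function(s, scissile, label_opposite = TRUE) {
  chain <- as.character(scissile[1])
  resseq <- as.integer(scissile[2])
  info <- residue_info(s)
  anchor <- info$chain == chain & info$resseq == resseq
  if (!any(anchor)) stop("scissile anchor ", chain, ":", resseq, " not found")
  if (info$class[anchor][1] != "nucleotide")
    stop("scissile anchor ", chain, ":", resseq, " is not a nucleotide")
  strand <- info[info$chain == chain & info$class == "nucleotide", ,
                 drop = FALSE]
  strand <- strand[order(strand$resseq), , drop = FALSE]   # 5' -> 3'
  i1 <- which(strand$resseq == resseq)[1]
  rel <- seq_len(nrow(strand)) - i1                        # 0 at anchor
  rel <- ifelse(rel >= 0, rel + 1L, rel)                   # skip zero
  s$atoms$rel_pos <- NA_integer_
  for (k in seq_len(nrow(strand))) {
    sel <- s$atoms$chain == chain & s$atoms$resseq == strand$resseq[k] &
      s$atoms$icode == strand$icode[k]
    s$atoms$rel_pos[sel] <- as.integer(rel[k])
  }
  if (label_opposite) {
    pairs <- detect_base_pairs(s)
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        if (pairs$chain1[k] == chain) {
          opp <- c(pairs$chain2[k], pairs$resseq2[k])
          own <- pairs$resseq1[k]
        } else if (pairs$chain2[k] == chain) {
          opp <- c(pairs$chain1[k], pairs$resseq1[k])
          own <- pairs$resseq2[k]
        } else next
        lab <- strand$resseq == own
        if (!any(lab)) next
        sel <- s$atoms$chain == opp[1] & s$atoms$resseq == as.integer(opp[2])
        s$atoms$rel_pos[sel] <- as.integer(rel[lab][1])
      }
    }
  }
  s
}
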